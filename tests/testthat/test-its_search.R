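# constraint model and solvers: oracle equivalence, symmetry accounting,
# extended-model pruning

test_that("model domains reflect mode and hydrogen pruning", {
  t2 <- table2_reactions()
  mb <- build_model(t2$R00013, homovalent_cycle(6), mode = "basic")
  expect_true(all(vapply(mb$domains$educt, length, integer(1L)) == 14L))
  expect_true(all(vapply(mb$domains$product, length, integer(1L)) == 14L))
  me <- build_model(t2$R00013, homovalent_cycle(6), mode = "extended")
  rem <- sibling_hydrogen_removal(t2$R00013$educts)
  expect_equal(me$domains$educt[[1]], setdiff(1:14, rem))

  # identity reaction: empty signature difference, no cardinality constraints
  m0 <- build_model(parse_reaction("O>>O"), homovalent_cycle(4),
                    mode = "extended")
  expect_false(m0$infeasible)
  expect_true(all(m0$req_lab == 0L))
  expect_length(enumerate_candidates(m0), 0L)
})

test_that("the solver agrees exactly with the brute-force oracle", {
  t2 <- table2_reactions()
  f1s <- figure1_reaction("suppressed")
  h2 <- hydrogenation_reaction()
  cases <- list(
    list(r = t2$R00013, k = 4), list(r = t2$R00013, k = 6),
    list(r = f1s, k = 4), list(r = f1s, k = 6), list(r = f1s, k = 8),
    list(r = h2, k = 4)
  )
  for (cs in cases) {
    lay <- homovalent_cycle(cs$k)
    for (mode in c("basic", "extended")) {
      cands <- enumerate_candidates(build_model(cs$r, lay, mode = mode))
      oracle <- brute_force_candidates(cs$r, lay, mode = mode)
      expect_identical(cand_keys(cands), cand_keys(oracle),
                       label = paste("mode", mode, "k", cs$k))
    }
  }
  # ambivalent layout oracle equivalence (size guard overridden: 18 atoms)
  mz <- meisenheimer_reaction()
  p5 <- figure2_catalog()$pseudo5
  cands <- enumerate_candidates(build_model(mz, p5, mode = "extended"))
  oracle <- brute_force_candidates(mz, p5, mode = "extended", force = TRUE)
  expect_identical(cand_keys(cands), cand_keys(oracle))
  expect_gt(length(cands), 0L)
})

test_that("every returned candidate passes the invariant re-check", {
  t2 <- table2_reactions()
  lay <- homovalent_cycle(6)
  cands <- enumerate_candidates(build_model(t2$R00013, lay, mode = "basic"))
  expect_equal(length(cands), 346L)
  for (cand in cands) expect_true(candidate_is_valid(t2$R00013, cand))
})

test_that("first_candidate is the head of the enumeration", {
  f1s <- figure1_reaction("suppressed")
  m <- build_model(f1s, homovalent_cycle(6), mode = "extended")
  cands <- enumerate_candidates(m)
  fc <- first_candidate(m)
  expect_false(is.null(fc))
  expect_equal(cand_key(fc), cand_key(cands[[1]]))
  # infeasible size: no candidate
  m8 <- build_model(f1s, homovalent_cycle(8), mode = "extended")
  expect_null(first_candidate(m8))
  # the ITS found covers the six reacting carbons (the nitrogen and the
  # methyl carbon stay outside the cycle)
  res <- run_mapping(f1s, mode = "extended", output = "all")
  chk <- verify_atom_map(f1s, res$maps[[1]]$mapping)
  expect_equal(chk$n_changed, 6L)
})

test_that("disabling the ordering constraint multiplies counts by k", {
  # each geometric cycle admits k/2 phase-preserving rotations in each of
  # the two traversal directions; the ordering constraint keeps exactly one
  h2 <- hydrogenation_reaction()
  f1s <- figure1_reaction("suppressed")
  for (cs in list(list(r = h2, k = 4), list(r = f1s, k = 6))) {
    lay <- homovalent_cycle(cs$k)
    on <- length(enumerate_candidates(build_model(cs$r, lay, mode = "basic",
                                                  symmetry_breaking = TRUE)))
    off <- length(enumerate_candidates(build_model(cs$r, lay, mode = "basic",
                                                   symmetry_breaking = FALSE)))
    expect_equal(off, cs$k * on)
  }
  # the unconstrained count agrees with the independent oracle
  lay4 <- homovalent_cycle(4)
  bf_off <- brute_force_candidates(h2, lay4, symmetry_breaking = FALSE)
  expect_length(bf_off, 4L * length(brute_force_candidates(h2, lay4)))
})

test_that("extended-model candidates are a subset of the basic ones", {
  t2 <- table2_reactions()
  h2 <- hydrogenation_reaction()
  for (cs in list(list(r = t2$R00013, k = 4), list(r = t2$R00013, k = 6),
                  list(r = h2, k = 4))) {
    lay <- homovalent_cycle(cs$k)
    kb <- cand_keys(enumerate_candidates(build_model(cs$r, lay, mode = "basic")))
    ke <- cand_keys(enumerate_candidates(build_model(cs$r, lay, mode = "extended")))
    expect_true(all(ke %in% kb))
  }
})

test_that("an unsatisfiable label requirement makes the model infeasible", {
  t2 <- table2_reactions()
  # R00207 needs five labels in the ITS; k = 4 cannot host them
  m <- build_model(t2$R00207, homovalent_cycle(4), mode = "extended")
  expect_true(m$infeasible)
  expect_length(enumerate_candidates(m), 0L)
})
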