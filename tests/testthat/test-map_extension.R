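# edge relabeling, hydrogen collapsing, isomorphism extension, verification

test_that("relabeling marks exactly the cycle edges and keeps the rest", {
  f1s <- figure1_reaction("suppressed")
  m <- build_model(f1s, homovalent_cycle(6), mode = "extended")
  cands <- enumerate_candidates(m)
  pair <- relabel_its_edges(f1s, cands[[1]])
  for (mat in list(pair$educt_matrix, pair$product_matrix)) {
    expect_equal(sum(mat == itsmapr:::EDGE_BROKEN) / 2L, 3L)
    expect_equal(sum(mat == itsmapr:::EDGE_FORMED) / 2L, 3L)
  }
  # non-cycle entries identical to the originals
  k <- 6L
  marked_e <- matrix(FALSE, f1s$educts$n, f1s$educts$n)
  for (e in seq_len(k)) {
    p <- cands[[1]]$educt[e]; q <- cands[[1]]$educt[if (e == k) 1L else e + 1L]
    marked_e[p, q] <- marked_e[q, p] <- TRUE
  }
  expect_identical(pair$educt_matrix[!marked_e], f1s$educts$adj[!marked_e])
  # broken edges existed in the educts; formed edges exist in the products
  for (e in seq_len(k)) {
    p <- e; q <- if (e == k) 1L else e + 1L
    ch <- cands[[1]]$layout$edge_changes[e]
    oi <- f1s$educts$adj[cands[[1]]$educt[p], cands[[1]]$educt[q]]
    oo <- f1s$products$adj[cands[[1]]$product[p], cands[[1]]$product[q]]
    if (ch < 0L) expect_gte(oi, 1L)
    if (ch > 0L) expect_gte(oo, 1L)
  }
  # candidate/reaction mismatch is rejected
  other <- table2_reactions()$R00013
  expect_error(relabel_its_edges(other, cands[[1]]), "invariants")
})

test_that("hydrogen collapsing absorbs exactly the non-ITS hydrogens", {
  # ethane with a fake 2-atom pin: no carbon hydrogens are in the ITS
  r <- parse_reaction("CC>>CC")
  lay <- homovalent_cycle(4)
  # collapse via the internal helper on an identity relabeling
  cg <- itsmapr:::collapse_one(r$educts, r$educts$adj, integer(0), integer(0))
  expect_equal(cg$n, 2L)
  expect_equal(cg$elem, c("C", "C"))
  expect_equal(cg$absorbed, c(3L, 3L))
  expect_equal(cg$adj[1L, 2L], 1L)
  # water collapses to a single O.2H vertex
  w <- parse_reaction("O>>O")
  cw <- itsmapr:::collapse_one(w$educts, w$educts$adj, integer(0), integer(0))
  expect_equal(cw$n, 1L)
  expect_equal(cw$absorbed, 2L)
  # hydrogen-free graphs are unchanged
  co2 <- parse_reaction("O=C=O>>O=C=O")
  cc <- itsmapr:::collapse_one(co2$educts, co2$educts$adj, integer(0), integer(0))
  expect_equal(cc$n, 3L)
  expect_true(all(cc$absorbed == 0L))
  # total atoms = collapsed vertices + absorbed hydrogens
  expect_equal(cg$n + sum(cg$absorbed), r$educts$n)
})

test_that("the worked example yields exactly one atom map", {
  f1s <- figure1_reaction("suppressed")
  m <- build_model(f1s, homovalent_cycle(6), mode = "extended")
  cands <- enumerate_candidates(m)
  all_maps <- unlist(lapply(cands, function(cand)
    lapply(enumerate_atom_maps(f1s, cand), map_key)))
  expect_length(unique(all_maps), 1L)
  mp <- as.integer(strsplit(all_maps[[1]], ",")[[1]])
  chk <- verify_atom_map(f1s, mp)
  expect_true(chk$valid)
  expect_equal(chk$n_changed, 6L)   # ITS covers six atoms, N and methyl rest
})

test_that("maps restricted to the ITS equal the candidate correspondence", {
  h2 <- hydrogenation_reaction()
  m <- build_model(h2, homovalent_cycle(4), mode = "extended")
  for (cand in enumerate_candidates(m)) {
    for (am in enumerate_atom_maps(h2, cand)) {
      expect_equal(am$mapping[cand$educt], cand$product)
      expect_true(verify_atom_map(h2, am)$valid)
    }
  }
})

test_that("collapse + isomorphism equals exhaustive bijection search", {
  # up to sibling-hydrogen permutations, on small fixtures
  h2 <- hydrogenation_reaction()
  m <- build_model(h2, homovalent_cycle(4), mode = "extended")
  cands <- enumerate_candidates(m)
  expect_gt(length(cands), 0L)
  for (cand in cands) {
    fast <- vapply(enumerate_atom_maps(h2, cand), map_key, character(1L))
    slow <- exhaustive_atom_maps(h2, cand)
    canon <- function(keys) sort(unique(vapply(
      keys, canonical_map_key, character(1L),
      reaction = h2, candidate = cand)))
    expect_identical(canon(fast), canon(slow))
  }
})

test_that("verification reports element and balance violations", {
  r <- parse_reaction("CO>>CO")   # methanol identity
  n <- r$educts$n
  good <- seq_len(n)
  expect_true(verify_atom_map(r, good)$valid)
  # swapping C and O breaks element preservation
  bad <- good; bad[1:2] <- bad[2:1]
  chk <- verify_atom_map(r, bad)
  expect_false(chk$valid)
  expect_match(paste(chk$violations, collapse = " "), "element")
  # non-bijective input errors out
  expect_error(verify_atom_map(r, rep(1L, n)), "bijection")
  # transposing two sibling hydrogens keeps a valid map valid
  hs <- which(r$educts$is_h & r$educts$h_parent == 1L)
  tw <- good; tw[hs[1:2]] <- tw[hs[2:1]]
  expect_true(verify_atom_map(r, tw)$valid)
})

test_that("label-feasible candidates with non-isomorphic residues do not extend", {
  f1s <- figure1_reaction("suppressed")
  m <- build_model(f1s, homovalent_cycle(6), mode = "extended")
  cands <- enumerate_candidates(m)
  n_ext <- vapply(cands, function(cand)
    length(enumerate_atom_maps(f1s, cand)), integer(1L))
  expect_equal(sum(n_ext > 0L), 1L)   # one true ITS, one spurious candidate
  expect_true(any(n_ext == 0L))
})
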