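# molecular graph model: parsing, hydrogen completion, lone pairs, mass
# balance, mapped-SMILES round trips

test_that("parsing completes hydrogens and assigns the documented atom order", {
  r <- parse_reaction("O>>O")
  expect_equal(r$educts$n, 3L)
  expect_equal(r$educts$elem, c("O", "H", "H"))
  expect_identical(r$educts$adj, r$products$adj)

  r13 <- parse_reaction("C(=O)=O.C(C(=O)O)(C=O)O>>C(=O)(C=O)O.C(=O)(C=O)O")
  expect_equal(r13$educts$n, 14L)
  expect_equal(r13$products$n, 14L)
  # carbon dioxide contributes no hydrogens, the aldol fragment four
  expect_equal(sum(r13$educts$is_h), 4L)
  # non-hydrogens come first, in parse order
  expect_equal(r13$educts$elem[1:3], c("C", "O", "O"))
  expect_false(any(r13$educts$is_h[1:10]))

  # hydrogens are attached to the right parents, grouped in parent order
  parents <- r13$educts$h_parent[r13$educts$is_h]
  expect_equal(parents, sort(parents))
})

test_that("single atoms are completed to their standard valence", {
  expect_equal(parse_reaction("C>>C")$educts$n, 5L)       # CH4
  expect_equal(parse_reaction("O=C=O>>O=C=O")$educts$n, 3L)
  g <- parse_reaction("C(C(=O)O)(C=O)O>>C(C(=O)O)(C=O)O")$educts
  expect_equal(g$n, 11L)
  expect_equal(sum(g$is_h), 4L)
})

test_that("charged species follow the charge-adjusted valence model", {
  r <- meisenheimer_reaction()
  gI <- r$educts
  np <- which(gI$elem == "N")
  om <- which(gI$elem == "O")
  expect_equal(gI$charge[np], 1L)
  expect_equal(gI$lp[np], 0L)      # quaternary N+ has no lone pair
  expect_equal(gI$lp[om], 3L)      # O- carries three lone pairs
  gO <- r$products
  expect_equal(gO$lp[gO$elem == "N"], 1L)
  expect_equal(gO$lp[gO$elem == "O"], 2L)
})

test_that("lone pair arithmetic matches the electron bookkeeping", {
  expect_equal(lone_pairs("O", 0, 2), 2L)
  expect_equal(lone_pairs("N", 1, 4), 0L)
  expect_equal(lone_pairs("C", 0, 4), 0L)
  expect_equal(lone_pairs("O", -1, 1), 3L)
  expect_error(lone_pairs("N", 0, 4), "radical")
  # after completion, every atom satisfies the same budget
  g <- table2_reactions()$R00048$educts
  bos <- as.integer(rowSums(g$adj))
  for (v in seq_len(g$n))
    expect_equal(g$lp[v], lone_pairs(g$elem[v], g$charge[v], bos[v]))
})

test_that("unsupported inputs are rejected with explicit errors", {
  expect_error(parse_reaction("c1ccccc1>>c1ccccc1"), "aromaticity")
  expect_error(parse_reaction("C[C@H](N)O>>CC(N)O"), "stereo")
  expect_error(parse_side_wrapper <- parse_reaction("C(C)(C)(C)(C)C>>CC"),
               "hypervalent")
  expect_error(parse_reaction("C(>>C"), "parse failure")
  expect_error(parse_reaction("C>>N"), "imbalance")
})

test_that("mass balance reports per-element deltas", {
  rep <- check_mass_balance(parse_reaction("C>>N", check_balance = FALSE))
  expect_false(rep$pass)
  expect_equal(rep$deltas[["C"]], 1L)
  expect_equal(rep$deltas[["N"]], -1L)
  expect_equal(rep$deltas[["H"]], 1L)   # CH4 vs NH3

  rep2 <- check_mass_balance(parse_reaction("O>>O.O", check_balance = FALSE))
  expect_false(rep2$pass)
  expect_match(rep2$message, "deltas|mismatch")

  for (r in table2_reactions()) expect_true(check_mass_balance(r)$pass)
})

test_that("mapped SMILES round-trips the bijection", {
  # identity on water: single heavy atom carries a class on both sides
  r <- parse_reaction("O>>O")
  m <- seq_len(3L)
  sm <- write_mapped_smiles(r, m)
  expect_equal(length(gregexpr(":1]", sm, fixed = TRUE)[[1]]), 2L)
  rt <- read_mapped_smiles(sm)
  expect_true(verify_atom_map(rt$reaction, rt$mapping)$valid)

  # a computed map on the hydrogenation fixture round-trips structurally
  r2 <- hydrogenation_reaction()
  res <- run_mapping(r2, k_values = 4, mode = "extended", output = "all")
  expect_gt(length(res$maps), 0L)
  m0 <- res$maps[[1]]$mapping
  rt2 <- read_mapped_smiles(write_mapped_smiles(r2, m0))
  # re-parsed graphs are the original ones up to the class correspondence
  pe <- match(seq_len(r2$educts$n), rt2$reaction$educts$atom_class)
  expect_equal(rt2$reaction$educts$elem[pe], r2$educts$elem)
  expect_identical(rt2$reaction$educts$adj[pe, pe], r2$educts$adj)
  pp <- rt2$mapping[pe]
  expect_identical(rt2$reaction$products$adj[pp, pp],
                   r2$products$adj[m0, m0])

  # unverifiable map is refused
  bad <- seq_len(r2$educts$n)
  expect_error(write_mapped_smiles(r2, rev(bad)), "unverified|bijection")
})

test_that("hydrogen-suppressed graphs keep full-graph lone pairs", {
  f1 <- figure1_reaction("suppressed")
  expect_equal(f1$educts$n, 8L)
  n_idx <- which(f1$educts$elem == "N")
  expect_equal(f1$educts$lp[n_idx], 1L)   # from the completed graph
  expect_true(all(f1$educts$lp[f1$educts$elem == "C"] == 0L))
})
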