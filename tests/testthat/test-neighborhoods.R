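# neighborhood signatures, multiset arithmetic, master-hydrogen selection

test_that("signatures of the worked example match the published multisets", {
  f1 <- figure1_reaction("suppressed")
  NI <- signature_multiset(f1$educts)
  NO <- signature_multiset(f1$products)
  expect_lms_equal(NI, FIG1_NI)
  expect_lms_equal(NO, FIG1_NO)

  # individual signatures: methyl carbon and the amine nitrogen
  methyl <- which(vapply(seq_len(f1$educts$n), function(v) {
    s <- neighborhood_signature(f1$educts, v)
    s$key == "C|1C"
  }, logical(1L)))
  expect_length(methyl, 1L)
  nsig <- neighborhood_signature(f1$educts, which(f1$educts$elem == "N"))
  expect_equal(nsig$key, "N|1C")

  dif <- multiset_difference(NI, NO)
  expect_lms_equal(dif, c("C|1N,2C" = 1L, "C|2C" = 3L))
  expect_equal(lms_size(dif), 4L)
  expect_lms_equal(its_label_requirements(f1), c(C = 4L))
})

test_that("an isolated atom has an empty edge multiset", {
  g <- mol_graph("O")
  expect_equal(neighborhood_signature(g, 1L)$edges, character(0))
  expect_equal(neighborhood_signature(g, 1L)$key, "O|")
})

test_that("multiset difference follows the occurrence reduction rule", {
  A <- lmultiset(c("x", "x", "y"))
  expect_equal(lms_size(multiset_difference(A, A)), 0L)
  expect_lms_equal(multiset_difference(A, lmultiset("x")),
                   c(x = 1L, y = 1L))
  expect_equal(occ(multiset_difference(lmultiset("x"), A), "x"), 0L)
  # size(A \ B) + size(min-intersection) = size(A)
  B <- lmultiset(c("x", "z", "z"))
  inter <- sum(pmin(occ(A, c("x")), occ(B, c("x"))),
               pmin(occ(A, "y"), occ(B, "y")), pmin(occ(A, "z"), occ(B, "z")))
  expect_equal(lms_size(multiset_difference(A, B)) + inter, lms_size(A))
})

test_that("signature multisets are invariant under vertex relabeling", {
  set.seed(42)
  g <- table2_reactions()$R00013$educts
  for (rep in 1:5) {
    perm <- sample(g$n)
    gp <- itsmapr:::permute_graph(g, perm)
    expect_equal(signature_multiset(gp), signature_multiset(g))
  }
})

test_that("label requirements reproduce the published per-reaction values", {
  t2 <- table2_reactions()
  expect_lms_equal(its_label_requirements(t2$R00013), c(C = 2L))
  expect_lms_equal(its_label_requirements(t2$R00018), c(N = 2L))
  expect_lms_equal(its_label_requirements(t2$R00048), c(O = 2L))
  expect_lms_equal(its_label_requirements(t2$R00059),
                   c(C = 1L, H = 1L, N = 1L, O = 1L))
  expect_lms_equal(its_label_requirements(t2$R00207), c(C = 1L, O = 4L))
  # identity reaction has no requirements
  expect_equal(lms_size(its_label_requirements(parse_reaction("O>>O"))), 0L)
})

test_that("master-hydrogen selection keeps exactly one hydrogen per heavy atom", {
  methane <- parse_reaction("C>>C")$educts
  expect_length(sibling_hydrogen_removal(methane), 3L)
  co2 <- parse_reaction("O=C=O>>O=C=O")$educts
  expect_length(sibling_hydrogen_removal(co2), 0L)
  ethane <- parse_reaction("CC>>CC")$educts
  rem <- sibling_hydrogen_removal(ethane)
  expect_length(rem, 4L)
  # exactly one attached hydrogen survives per heavy atom
  for (v in which(!ethane$is_h)) {
    hs <- which(ethane$adj[v, ] > 0L & ethane$is_h)
    expect_length(setdiff(hs, rem), 1L)
    expect_equal(setdiff(hs, rem), min(hs))  # the lowest-id one
  }
  # hydrogens of H2 are never removed
  h2 <- hydrogenation_reaction()$educts
  rem2 <- sibling_hydrogen_removal(h2)
  h2_hs <- which(h2$is_h & vapply(seq_len(h2$n), function(v) {
    nb <- which(h2$adj[v, ] > 0L); length(nb) == 1L && h2$is_h[nb]
  }, logical(1L)))
  expect_length(intersect(rem2, h2_hs), 0L)
})
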