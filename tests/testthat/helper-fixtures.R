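# shared helpers: canonical keys for set comparison and a couple of tiny
# fixture reactions built in code

cand_key <- function(x) paste(c(x$educt, x$product), collapse = ",")

cand_keys <- function(cands) sort(vapply(cands, cand_key, character(1L)))

map_key <- function(m) {
  v <- if (inherits(m, "atom_map")) m$mapping else m
  paste(v, collapse = ",")
}

# H2 + ethene -> ethane; the smallest hydrogenation fixture (8 atoms)
hydrogenation_reaction <- function() parse_reaction("[H][H].C=C>>CC")

# printed worked-example multisets (hydrogen-suppressed educts/products)
FIG1_NI <- c("C|1C" = 1L, "C|1C,1C,2C" = 1L, "C|1C,2C" = 1L,
             "C|1N,2C" = 1L, "C|2C" = 3L, "N|1C" = 1L)
FIG1_NO <- c("C|1C" = 1L, "C|1C,1C" = 3L, "C|1C,1C,1N" = 1L,
             "C|1C,1C,2C" = 1L, "C|1C,2C" = 1L, "N|1C" = 1L)

expect_lms_equal <- function(ms, ref) {
  a <- stats::setNames(as.integer(ms), names(ms))
  a <- a[order(names(a), method = "radix")]
  b <- ref[order(names(ref), method = "radix")]
  expect_equal(a, b)
}
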