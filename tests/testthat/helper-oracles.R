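# exhaustive bijection search over the uncollapsed relabeled graphs:
# independent oracle for the collapse + isomorphism map-extension path

exhaustive_atom_maps <- function(reaction, candidate) {
  pair <- relabel_its_edges(reaction, candidate)
  EI <- pair$educt_matrix; EO <- pair$product_matrix
  gI <- reaction$educts; gO <- reaction$products
  n <- gI$n
  stopifnot(n <= 12L)
  mapping <- integer(n); used <- logical(n)
  mapping[candidate$educt] <- candidate$product
  used[candidate$product] <- TRUE
  free <- setdiff(seq_len(n), candidate$educt)
  assigned <- candidate$educt
  out <- character(0)
  rec <- function(idx) {
    if (idx > length(free)) {
      out <<- c(out, paste(mapping, collapse = ","))
      return(invisible())
    }
    x <- free[idx]
    for (y in seq_len(n)) {
      if (used[y]) next
      if (gI$elem[x] != gO$elem[y] || gI$lp[x] != gO$lp[y] ||
          gI$charge[x] != gO$charge[y]) next
      ok <- TRUE
      for (z in assigned) if (EI[x, z] != EO[y, mapping[z]]) { ok <- FALSE; break }
      if (!ok) next
      mapping[x] <<- y; used[y] <<- TRUE; assigned <<- c(assigned, x)
      rec(idx + 1L)
      mapping[x] <<- 0L; used[y] <<- FALSE
      assigned <<- assigned[-length(assigned)]
    }
    invisible()
  }
  rec(1L)
  out
}

# canonical form of a full mapping modulo permutations of sibling non-ITS
# hydrogens: each such hydrogen's image is replaced by its product parent
canonical_map_key <- function(reaction, candidate, mapping_key) {
  mapping <- as.integer(strsplit(mapping_key, ",")[[1]])
  gI <- reaction$educts; gO <- reaction$products
  parentO <- vapply(seq_len(gO$n), function(v) {
    if (!gO$is_h[v]) return(0L)
    nb <- which(gO$adj[v, ] > 0L)
    if (length(nb) == 1L) nb else 0L
  }, integer(1L))
  canon <- vapply(seq_along(mapping), function(x) {
    if (gI$is_h[x] && !(x %in% candidate$educt) && parentO[mapping[x]] > 0L)
      paste0("p", parentO[mapping[x]]) else as.character(mapping[x])
  }, character(1L))
  paste(canon, collapse = ",")
}
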