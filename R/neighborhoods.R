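# Local neighborhood signatures and multiset arithmetic used by the extended
# constraint model: the educt/product signature multisets, their occurrence-
# wise difference (which lower-bounds the atoms that must sit in the reaction
# center), the derived label requirements, and master-hydrogen selection.

#' Neighborhood signature of an atom
#'
#' The signature is the atom's element label together with the multiset of
#' "order + neighbor label" strings over its incident bonds, e.g.
#' `(C, <1C,2C>)`. Entries are kept sorted (C-locale) so signatures compare
#' canonically.
#'
#' @param graph a `mol_graph`.
#' @param v atom id.
#' @return list with `center`, sorted character vector `edges`, and a
#'   canonical string `key` (`"C|1C,2C"`).
#' @export
neighborhood_signature <- function(graph, v) {
  nb <- which(graph$adj[v, ] > 0L)
  edges <- sort(paste0(graph$adj[v, nb], graph$elem[nb]), method = "radix")
  list(center = graph$elem[v], edges = edges,
       key = paste0(graph$elem[v], "|", paste(edges, collapse = ",")))
}

signature_keys <- function(graph)
  vapply(seq_len(graph$n), function(v) neighborhood_signature(graph, v)$key,
         character(1L))

#' Labeled multiset
#'
#' A multiset with non-negative occurrence counts, stored as a named integer
#' vector. Zero-count elements are dropped.
#'
#' @param x character vector of elements (with repetitions) or a named
#'   integer vector of counts.
#' @return an `lmultiset`.
#' @export
lmultiset <- function(x = character(0)) {
  if (is.character(x)) {
    tb <- table(x)
    out <- stats::setNames(as.integer(tb),
                           if (length(tb) == 0L) character(0) else names(tb))
  } else if (length(x) == 0L) {
    out <- stats::setNames(integer(0), character(0))
  } else {
    stopifnot(!is.null(names(x)))
    out <- vapply(split(as.integer(x), names(x)), sum, integer(1L))
  }
  out <- out[out > 0L]
  out <- out[order(names(out), method = "radix")]
  structure(out, class = "lmultiset")
}

#' @export
print.lmultiset <- function(x, ...) {
  if (length(x) == 0L) { cat("< >\n"); return(invisible(x)) }
  cat("<", paste(sprintf("%dx(%s)", as.integer(x), names(x)), collapse = ", "),
      ">\n")
  invisible(x)
}

#' Occurrence count of an element in a labeled multiset
#' @param ms an `lmultiset`.
#' @param x element name.
#' @export
occ <- function(ms, x) {
  i <- match(x, names(ms))
  if (is.na(i)) 0L else as.integer(ms[[i]])
}

#' Total size (with multiplicity) of a labeled multiset
#' @param ms an `lmultiset`.
#' @export
lms_size <- function(ms) sum(as.integer(ms))

#' Occurrence-wise multiset difference
#'
#' `occ_out(x) = max(0, occ_A(x) - occ_B(x))`.
#'
#' @param A,B `lmultiset` objects.
#' @return an `lmultiset`.
#' @export
multiset_difference <- function(A, B) {
  keys <- names(A)
  cnt <- vapply(keys, function(k) max(0L, occ(A, k) - occ(B, k)), integer(1L))
  lmultiset(stats::setNames(cnt, keys))
}

# multiset containment: does A contain B (occurrence-wise)?
lms_contains <- function(A, B)
  all(vapply(names(B), function(k) occ(A, k) >= occ(B, k), logical(1L)))

#' Signature multiset of a graph
#'
#' The multiset of neighborhood signatures over all vertices; the N_I / N_O
#' machinery of the extended constraint model.
#'
#' @param graph a `mol_graph`.
#' @return an `lmultiset` keyed by canonical signature strings.
#' @export
signature_multiset <- function(graph) {
  if (graph$n == 0L) return(lmultiset())
  lmultiset(signature_keys(graph))
}

#' Element labels required in the reaction center
#'
#' Labels (with multiplicity) of the educt-unique neighborhood signatures,
#' `N^L = <l(v) | N(v) in N_I \ N_O>`; computed on the graphs as given, i.e.
#' on the same representation the constraint model uses (explicit hydrogens
#' in the production pipeline, hydrogen-suppressed if the reaction was
#' suppressed).
#'
#' @param reaction a `reaction`.
#' @return an `lmultiset` of element symbols.
#' @export
its_label_requirements <- function(reaction) {
  dif <- multiset_difference(signature_multiset(reaction$educts),
                             signature_multiset(reaction$products))
  if (length(dif) == 0L) return(lmultiset())
  labs <- rep(sub("\\|.*$", "", names(dif)), as.integer(dif))
  lmultiset(labs)
}

#' Sibling hydrogens to remove for symmetry breaking
#'
#' For every non-hydrogen atom with attached hydrogens, the lowest-id
#' hydrogen is kept as the "master" and the remaining siblings are returned
#' for domain removal. Hydrogens bonded to another hydrogen (molecular H2)
#' are never removed.
#'
#' @param graph a `mol_graph` with explicit hydrogens.
#' @return integer vector of hydrogen atom ids (H_rem).
#' @export
sibling_hydrogen_removal <- function(graph) {
  rem <- integer(0)
  for (v in which(!graph$is_h)) {
    hs <- which(graph$adj[v, ] > 0L & graph$is_h)
    if (length(hs) > 1L) rem <- c(rem, sort(hs)[-1L])
  }
  sort(unique(rem))
}
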