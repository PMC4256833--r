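# Extending an ITS candidate to complete atom maps. The cycle edges of the
# candidate are relabeled with formed/broken/pseudo markers in both
# adjacency matrices; non-ITS hydrogens are collapsed into their heavy
# atom's label (removing hydrogen-interchange symmetry and halving the
# graphs); all label- and edge-label-preserving isomorphisms extending the
# pinned ITS correspondence are enumerated; each is expanded back to a full
# bijection and verified.

EDGE_FORMED <- 10L
EDGE_BROKEN <- 11L
EDGE_PSEUDO <- 12L

#' Relabel the ITS cycle edges of a candidate
#'
#' Replaces the adjacency entries of consecutive cycle pairs with a marker:
#' `f` (formed, code 10) where the layout forms a bond, `b` (broken, code
#' 11) where it breaks one, `p` (pseudo, code 12) for 0-change edges. All
#' other entries are kept as in the original matrices.
#'
#' @param reaction a `reaction`.
#' @param candidate a valid `its_candidate` for it.
#' @return a `relabeled_pair` with `educt_matrix`, `product_matrix`,
#'   `candidate`, `reaction`.
#' @export
relabel_its_edges <- function(reaction, candidate) {
  if (!candidate_is_valid(reaction, candidate))
    stop("candidate does not satisfy the ITS invariants for this reaction")
  k <- candidate$layout$k
  cc <- candidate$layout$edge_changes
  EI <- reaction$educts$adj
  EO <- reaction$products$adj
  for (e in seq_len(k)) {
    p <- e; q <- if (e == k) 1L else e + 1L
    marker <- if (cc[e] > 0L) EDGE_FORMED else if (cc[e] < 0L) EDGE_BROKEN
              else EDGE_PSEUDO
    up <- candidate$educt[p]; uq <- candidate$educt[q]
    wp <- candidate$product[p]; wq <- candidate$product[q]
    EI[up, uq] <- EI[uq, up] <- marker
    EO[wp, wq] <- EO[wq, wp] <- marker
  }
  structure(list(educt_matrix = EI, product_matrix = EO,
                 candidate = candidate, reaction = reaction),
            class = "relabeled_pair")
}

collapse_one <- function(graph, mat, its_vertices, pins) {
  absorbable <- graph$is_h & !(seq_len(graph$n) %in% its_vertices) &
    vapply(seq_len(graph$n), function(v) {
      nb <- which(mat[v, ] > 0L)
      length(nb) == 1L && !graph$is_h[nb]
    }, logical(1L))
  keep <- which(!absorbable)
  absorbed <- vapply(keep, function(v)
    sum(absorbable[which(mat[v, ] == 1L)]), integer(1L))
  pin <- integer(length(keep))
  idx <- match(its_vertices, keep)
  pin[idx] <- pins
  structure(list(
    n = length(keep), vids = keep,
    elem = graph$elem[keep], charge = graph$charge[keep],
    lp = graph$lp[keep], absorbed = absorbed, pin = pin,
    adj = mat[keep, keep, drop = FALSE]
  ), class = "collapsed_graph")
}

#' Collapse non-ITS hydrogens of a relabeled pair
#'
#' Hydrogens outside the ITS cycle are merged into the label of their heavy
#' neighbor (as an absorbed-hydrogen count); ITS hydrogens and hydrogens
#' bonded only to hydrogens (molecular H2) are kept as vertices.
#'
#' @param pair a `relabeled_pair` from [relabel_its_edges()].
#' @return list with collapsed `educt` and `product` graphs; each records
#'   the original vertex ids (`vids`), absorbed counts and ITS pins.
#' @export
collapse_nonits_hydrogens <- function(pair) {
  k <- pair$candidate$layout$k
  list(educt = collapse_one(pair$reaction$educts, pair$educt_matrix,
                            pair$candidate$educt, seq_len(k)),
       product = collapse_one(pair$reaction$products, pair$product_matrix,
                              pair$candidate$product, seq_len(k)))
}

collapsed_igraph <- function(cg, color_levels) {
  key <- ifelse(cg$pin > 0L, paste0("pin", cg$pin),
                paste(cg$elem, cg$charge, cg$lp, cg$absorbed, sep = "/"))
  vcol <- match(key, color_levels)
  ut <- which(upper.tri(cg$adj) & cg$adj > 0L, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = cg$n, directed = FALSE)
  if (nrow(ut) > 0L)
    g <- igraph::add_edges(g, as.vector(t(ut)))
  list(g = g, vcol = vcol, ecol = cg$adj[ut])
}

#' Enumerate complete atom maps extending an ITS candidate
#'
#' Enumerates all label- and edge-label-preserving isomorphisms between the
#' collapsed relabeled educt and product graphs that extend the fixed ITS
#' correspondence (cycle positions are pinned with unique colors), expands
#' each to a full bijection by pairing absorbed hydrogens in ascending atom
#' id order, deduplicates, and verifies every result.
#'
#' @param reaction a `reaction`.
#' @param candidate a valid `its_candidate`.
#' @return list of `atom_map`; empty when the candidate does not extend
#'   (i.e. is not a true ITS).
#' @export
enumerate_atom_maps <- function(reaction, candidate) {
  pair <- relabel_its_edges(reaction, candidate)
  col <- collapse_nonits_hydrogens(pair)
  ce <- col$educt; cp <- col$product
  if (ce$n != cp$n) return(list())
  keys <- function(cg) ifelse(cg$pin > 0L, paste0("pin", cg$pin),
                              paste(cg$elem, cg$charge, cg$lp, cg$absorbed,
                                    sep = "/"))
  levs <- sort(unique(c(keys(ce), keys(cp))), method = "radix")
  a <- collapsed_igraph(ce, levs); b <- collapsed_igraph(cp, levs)
  if (!identical(sort(a$vcol), sort(b$vcol))) return(list())
  if (!identical(sort(a$ecol), sort(b$ecol))) return(list())
  isos <- igraph::graph.get.isomorphisms.vf2(
    a$g, b$g, vertex.color1 = a$vcol, vertex.color2 = b$vcol,
    edge.color1 = a$ecol, edge.color2 = b$ecol)
  n <- reaction$educts$n
  gI <- reaction$educts; gO <- reaction$products
  its_e <- candidate$educt; its_p <- candidate$product
  out <- list(); seen <- character(0)
  for (iso in isos) {
    # igraph returns the product->educt direction; invert to educt->product
    ret <- as.integer(iso)
    iso <- integer(length(ret)); iso[ret] <- seq_along(ret)
    mapping <- integer(n)
    mapping[ce$vids] <- cp$vids[iso]
    # absorbed hydrogens: pair ascending per matched heavy atom
    for (x in seq_len(ce$n)) {
      he <- setdiff(which(gI$adj[ce$vids[x], ] > 0L & gI$is_h), its_e)
      he <- he[!(he %in% ce$vids)]
      if (length(he) == 0L) next
      w <- cp$vids[iso[x]]
      hp <- setdiff(which(gO$adj[w, ] > 0L & gO$is_h), its_p)
      hp <- hp[!(hp %in% cp$vids)]
      mapping[sort(he)] <- sort(hp)
    }
    key <- paste(mapping, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    chk <- verify_atom_map(reaction, mapping)
    if (!chk$valid)
      stop("internal error: extension produced an invalid atom map (",
           paste(chk$violations, collapse = "; "), ")")
    out[[length(out) + 1L]] <- structure(
      list(mapping = mapping, candidate = candidate), class = "atom_map")
  }
  out
}

#' Reaction matrix of an atom map
#'
#' Elementwise difference of the product adjacency matrix and the
#' map-reindexed educt matrix, with lone-pair counts on the diagonal; rows
#' sum to zero exactly for valid maps.
#'
#' @param reaction a `reaction`.
#' @param mapping integer bijection educt id -> product id.
#' @return integer matrix indexed by product vertex ids.
#' @export
reaction_matrix <- function(reaction, mapping) {
  n <- reaction$educts$n
  Im <- matrix(0L, n, n)
  Im[mapping, mapping] <- reaction$educts$adj
  lpIm <- integer(n); lpIm[mapping] <- reaction$educts$lp
  (reaction$products$adj + diag(reaction$products$lp)) - (Im + diag(lpIm))
}

#' Verify a complete atom map
#'
#' Checks that the mapping is a bijection, preserves element labels, and
#' that every row of the reaction matrix (bond-order changes plus lone-pair
#' change) sums to zero.
#'
#' @param reaction a `reaction`.
#' @param map an `atom_map` or integer mapping vector.
#' @return list with `valid`, character `violations`, and the number of
#'   vertices showing any incident change (`n_changed`).
#' @export
verify_atom_map <- function(reaction, map) {
  mapping <- if (inherits(map, "atom_map")) map$mapping else as.integer(map)
  n <- reaction$educts$n
  if (length(mapping) != n || anyNA(mapping) ||
      !setequal(mapping, seq_len(n)))
    stop("atom map is not a bijection over all vertices")
  viol <- character(0)
  bad <- which(reaction$educts$elem != reaction$products$elem[mapping])
  if (length(bad) > 0L)
    viol <- c(viol, paste0("element not preserved at educt atom(s) ",
                           paste(bad, collapse = ",")))
  R <- reaction_matrix(reaction, mapping)
  rs <- rowSums(R)
  bad <- which(rs != 0L)
  if (length(bad) > 0L)
    viol <- c(viol, paste0("electron balance violated at product atom(s) ",
                           paste(bad, collapse = ",")))
  list(valid = length(viol) == 0L, violations = viol,
       n_changed = sum(rowSums(R != 0L) > 0L))
}

#' @export
print.atom_map <- function(x, ...) {
  cat("atom_map:", paste(seq_along(x$mapping), x$mapping, sep = "->",
                         collapse = " "), "\n")
  invisible(x)
}
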