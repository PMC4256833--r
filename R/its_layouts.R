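# Cyclic ITS layouts: a layout fixes, around a cycle of k atoms, the
# bond-order change on every cycle edge (edge i joins positions i and i+1,
# edge k closes the cycle) and the lone-pair change at every position.
# Homovalent elementary reactions use even alternating cycles; ambivalent
# reactions use odd cycles with charged vertices and/or an unchanged
# "pseudo" bond (edge change 0, bond required present on both sides).

#' Construct an ITS layout
#'
#' @param name layout name.
#' @param k cycle length (number of ITS atoms).
#' @param edge_changes integer vector c_1..c_k; c_i is the bond-order change
#'   on cycle edge (i, i+1), c_k on the closure (k, 1). 0 marks a pseudo
#'   bond that must exist with equal positive order on both sides.
#' @param vertex_lp_changes integer vector d_1..d_k of lone-pair changes
#'   (product minus educt) per ITS position.
#' @param validate check the electron-balance invariant (default TRUE).
#' @return an `its_layout`.
#' @export
its_layout <- function(name, k, edge_changes, vertex_lp_changes,
                       validate = TRUE) {
  lay <- structure(list(
    name = as.character(name), k = as.integer(k),
    edge_changes = as.integer(edge_changes),
    vertex_lp_changes = as.integer(vertex_lp_changes),
    rotation_symmetric = FALSE
  ), class = "its_layout")
  lay$rotation_symmetric <- layout_rotation_symmetric(lay)
  if (validate) {
    v <- validate_layout(lay)
    if (!v$valid)
      stop("invalid ITS layout '", name, "': ",
           paste(v$violations, collapse = "; "))
  }
  lay
}

# TRUE if some proper cyclic rotation maps (edge_changes, vertex_lp_changes)
# onto itself; such layouts need the order-based symmetry breaking.
layout_rotation_symmetric <- function(layout) {
  k <- layout$k
  rot <- function(x, r) x[((seq_len(k) - 1L + r) %% k) + 1L]
  for (r in seq_len(k - 1L)) {
    if (identical(rot(layout$edge_changes, r), layout$edge_changes) &&
        identical(rot(layout$vertex_lp_changes, r), layout$vertex_lp_changes))
      return(TRUE)
  }
  FALSE
}

#' Validate an ITS layout
#'
#' Checks the per-vertex electron balance `c_{i-1} + c_i + d_i = 0` (indices
#' cyclic; the layout-level form of "every reaction-matrix row sums to
#' zero") and that at least one edge change is nonzero.
#'
#' @param layout an `its_layout`.
#' @return list with `valid` and character `violations`.
#' @export
validate_layout <- function(layout) {
  k <- layout$k; cc <- layout$edge_changes; d <- layout$vertex_lp_changes
  viol <- character(0)
  if (k < 3L) viol <- c(viol, "cycle length must be at least 3")
  if (length(cc) != k || length(d) != k)
    viol <- c(viol, "edge_changes and vertex_lp_changes must have length k")
  else {
    for (i in seq_len(k)) {
      prev <- if (i == 1L) k else i - 1L
      if (cc[prev] + cc[i] + d[i] != 0L)
        viol <- c(viol, sprintf(
          "electron balance violated at vertex %d: %d + %d + %d != 0",
          i, cc[prev], cc[i], d[i]))
    }
    if (all(cc == 0L)) viol <- c(viol, "all edge changes are zero")
  }
  list(valid = length(viol) == 0L, violations = viol)
}

#' Homovalent alternating cycle layout
#'
#' Even cycle with edge changes alternating -1, +1, ... starting with the
#' breaking edge (1,2) and closing with a formed bond; all lone-pair changes
#' zero.
#'
#' @param k even cycle length >= 4.
#' @return an `its_layout`.
#' @export
homovalent_cycle <- function(k) {
  k <- as.integer(k)
  if (k < 4L || k %% 2L != 0L)
    stop("homovalent ITS cycles have an even number of atoms only (k >= 4)")
  its_layout(paste0("homovalent", k), k,
             edge_changes = rep_len(c(-1L, 1L), k),
             vertex_lp_changes = rep(0L, k))
}

# pseudo-bond odd cycle: edges alternate -1,+1,... along 1..k-1, the closure
# (k,1) is an unchanged pseudo bond; position 1 gains a lone pair, position k
# loses one (`inverse = TRUE` flips all signs).
pseudo_cycle <- function(k, inverse = FALSE) {
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("pseudo-bond layouts are odd cycles")
  s <- if (inverse) -1L else 1L
  cc <- c(rep_len(c(-1L, 1L), k - 1L), 0L) * s
  d <- c(1L, rep(0L, k - 2L), -1L) * s
  its_layout(paste0("pseudo", k, if (inverse) "i" else ""), k, cc, d)
}

# single-vertex redox odd cycle: all k edges alternate, which on an odd cycle
# forces the two equal-signed changes to meet at position 1, whose lone-pair
# count changes by +/-2.
redox_cycle <- function(k, inverse = FALSE) {
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop("redox layouts are odd cycles")
  s <- if (inverse) -1L else 1L
  cc <- rep_len(c(-1L, 1L), k) * s
  d <- c(2L, rep(0L, k - 1L)) * s
  its_layout(paste0("redox", k, if (inverse) "i" else ""), k, cc, d)
}

#' Catalog of supported ITS layouts
#'
#' Homovalent even cycles (k = 4, 6, 8), pseudo-bond odd cycles with two
#' oppositely charged endpoints (k = 3, 5, 7) plus their inverses, and
#' single-vertex redox odd cycles (k = 3, 5, 7) plus inverses. Every member
#' passes [validate_layout()]. The catalog can be extended or overridden via
#' [read_layout_catalog()].
#'
#' @return named list of `its_layout` objects (a `layout_catalog`).
#' @export
figure2_catalog <- function() {
  lays <- c(
    lapply(c(4L, 6L, 8L), homovalent_cycle),
    lapply(c(3L, 5L, 7L), pseudo_cycle),
    lapply(c(3L, 5L, 7L), pseudo_cycle, inverse = TRUE),
    lapply(c(3L, 5L, 7L), redox_cycle),
    lapply(c(3L, 5L, 7L), redox_cycle, inverse = TRUE)
  )
  structure(stats::setNames(lays, vapply(lays, `[[`, character(1L), "name")),
            class = "layout_catalog")
}

#' Write a layout catalog to a YAML file
#' @param catalog a `layout_catalog` or list of `its_layout`.
#' @param path file path.
#' @export
write_layout_catalog <- function(catalog, path) {
  yaml::write_yaml(lapply(unclass(catalog), function(l)
    list(name = l$name, k = l$k, edge_changes = l$edge_changes,
         vertex_lp_changes = l$vertex_lp_changes)), path)
  invisible(path)
}

#' Read a layout catalog from a YAML file
#' @param path file path written by [write_layout_catalog()] or hand-edited.
#' @return a `layout_catalog`; every entry is validated.
#' @export
read_layout_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  lays <- lapply(raw, function(l)
    its_layout(l$name, l$k, l$edge_changes, l$vertex_lp_changes))
  structure(stats::setNames(lays, vapply(lays, `[[`, character(1L), "name")),
            class = "layout_catalog")
}

#' @export
print.its_layout <- function(x, ...) {
  cat(sprintf("its_layout '%s': k=%d, edge changes (%s), lp changes (%s)%s\n",
              x$name, x$k, paste(x$edge_changes, collapse = ","),
              paste(x$vertex_lp_changes, collapse = ","),
              if (x$rotation_symmetric) " [rotation-symmetric]" else ""))
  invisible(x)
}
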