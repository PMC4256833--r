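# Constraint model for cyclic ITS identification and its solvers: the
# compiled depth-first search with forward checking (production path) and an
# independent brute-force enumerator used as a testing oracle.

vertex_degrees <- function(graph, semantics = c("edges", "bond_order_sum")) {
  semantics <- match.arg(semantics)
  if (semantics == "edges") as.integer(rowSums(graph$adj > 0L))
  else as.integer(rowSums(graph$adj))
}

#' Build an ITS constraint model
#'
#' Posts the constraints of the basic or extended formulation for one
#' reaction and one cyclic layout: all-different per side, positionwise
#' label equality, lone-pair change `lp(X^O_i) - lp(X^I_i) = d_i`, degree
#' compatibility (at most one edge lost or gained), exact bond-order change
#' on every cycle edge (pseudo bonds present and unchanged), and
#' rotation/direction symmetry breaking for rotation-symmetric layouts. The
#' extended model additionally prunes non-master sibling hydrogens from all
#' domains, posts per-label cardinality lower bounds from the educt-unique
#' neighborhood signatures, and requires the assigned cycle to carry the
#' educt-unique (and product-unique) signatures.
#'
#' @param reaction a mass-balanced `reaction`.
#' @param layout an `its_layout`.
#' @param mode `"basic"` or `"extended"`.
#' @param symmetry_breaking apply the order-based symmetry breaking (only
#'   effective for rotation-symmetric layouts).
#' @param degree_semantics `"edges"` counts distinct incident bonds (the
#'   default); `"bond_order_sum"` counts shared electron pairs.
#' @return an `its_model`.
#' @export
build_model <- function(reaction, layout, mode = c("basic", "extended"),
                        symmetry_breaking = TRUE,
                        degree_semantics = getOption("itsmapr.degree_semantics",
                                                     "edges")) {
  mode <- match.arg(mode)
  stopifnot(inherits(reaction, "reaction"), inherits(layout, "its_layout"))
  gI <- reaction$educts; gO <- reaction$products
  if (gI$n != gO$n)
    stop("reaction is not mass-balanced (atom counts differ)")
  k <- layout$k
  labs <- sort(unique(c(gI$elem, gO$elem)), method = "radix")
  m <- list(
    reaction = reaction, layout = layout, mode = mode,
    symmetry_breaking = symmetry_breaking,
    degree_semantics = degree_semantics,
    n = gI$n, k = k,
    lab_levels = labs,
    labI = match(gI$elem, labs), labO = match(gO$elem, labs),
    lpI = gI$lp, lpO = gO$lp,
    degI = vertex_degrees(gI, degree_semantics),
    degO = vertex_degrees(gO, degree_semantics),
    allowedI = rep(TRUE, gI$n), allowedO = rep(TRUE, gO$n),
    req_lab = integer(length(labs)),
    sigI = integer(gI$n), sigO = integer(gO$n),
    req_sigI = NULL, req_sigO = NULL,
    infeasible = FALSE, infeasible_reason = NULL
  )
  if (mode == "extended") {
    m$allowedI[sibling_hydrogen_removal(gI)] <- FALSE
    m$allowedO[sibling_hydrogen_removal(gO)] <- FALSE
    NI <- signature_multiset(gI); NO <- signature_multiset(gO)
    difI <- multiset_difference(NI, NO)   # educt-unique signatures
    difO <- multiset_difference(NO, NI)
    sig_levels <- sort(unique(c(names(NI), names(NO))), method = "radix")
    m$sig_levels <- sig_levels
    m$sigI <- match(signature_keys(gI), sig_levels)
    m$sigO <- match(signature_keys(gO), sig_levels)
    m$req_sigI <- list(id = match(names(difI), sig_levels),
                       count = as.integer(difI))
    m$req_sigO <- list(id = match(names(difO), sig_levels),
                       count = as.integer(difO))
    NL <- its_label_requirements(reaction)
    for (l in names(NL)) {
      idx <- match(l, labs)
      if (is.na(idx) || !any(m$labI == idx)) {
        m$infeasible <- TRUE
        m$infeasible_reason <- paste0("required ITS label '", l,
                                      "' absent from educts")
      } else m$req_lab[idx] <- occ(NL, l)
    }
    if (lms_size(NL) > k) {
      m$infeasible <- TRUE
      m$infeasible_reason <- sprintf(
        "%d required ITS labels exceed cycle size %d", lms_size(NL), k)
    }
  } else {
    m$req_sigI <- list(id = integer(0), count = integer(0))
    m$req_sigO <- list(id = integer(0), count = integer(0))
    m$req_lab <- integer(0)   # no cardinality constraints in the basic model
  }
  m$domains <- list(
    educt = lapply(seq_len(k), function(i) which(m$allowedI)),
    product = lapply(seq_len(k), function(i) which(m$allowedO))
  )
  class(m) <- "its_model"
  m
}

#' @export
print.its_model <- function(x, ...) {
  cat(sprintf("its_model: %s, layout '%s' (k=%d), %d atoms/side%s\n",
              x$mode, x$layout$name, x$k, x$n,
              if (x$infeasible) paste0(" [infeasible: ", x$infeasible_reason, "]")
              else ""))
  invisible(x)
}

new_its_candidate <- function(educt, product, layout) {
  structure(list(educt = as.integer(educt), product = as.integer(product),
                 layout = layout), class = "its_candidate")
}

#' @export
print.its_candidate <- function(x, ...) {
  cat(sprintf("its_candidate (%s): educts (%s) -> products (%s)\n",
              x$layout$name, paste(x$educt, collapse = ","),
              paste(x$product, collapse = ",")))
  invisible(x)
}

candidate_key <- function(cand)
  paste(c(cand$educt, cand$product), collapse = ",")

run_csp <- function(model, first_only = FALSE, max_solutions = Inf) {
  if (model$infeasible) return(list(educt = matrix(integer(0), model$k, 0L),
                                    product = matrix(integer(0), model$k, 0L),
                                    nodes = 0))
  sym <- model$symmetry_breaking && model$layout$rotation_symmetric
  csp_enumerate_cpp(
    model$reaction$educts$adj, model$reaction$products$adj,
    model$labI, model$labO, model$lpI, model$lpO, model$degI, model$degO,
    model$reaction$educts$is_h, model$reaction$products$is_h,
    model$allowedI, model$allowedO,
    model$layout$edge_changes, model$layout$vertex_lp_changes,
    sym, model$req_lab, model$sigI, model$sigO,
    model$req_sigI$id, model$req_sigI$count,
    model$req_sigO$id, model$req_sigO$count,
    first_only, as.double(max_solutions))
}

#' Enumerate all ITS candidates of a model
#'
#' Complete depth-first enumeration with constraint propagation; branching
#' picks the variable with the smallest current domain and tries
#' non-hydrogen atoms first, so the result order is deterministic.
#'
#' @param model an `its_model`.
#' @param max_solutions optional cap on the number of solutions collected.
#' @return list of `its_candidate` (empty when infeasible).
#' @export
enumerate_candidates <- function(model, max_solutions = Inf) {
  res <- run_csp(model, first_only = FALSE, max_solutions = max_solutions)
  ns <- ncol(res$educt)
  lapply(seq_len(ns), function(s)
    new_its_candidate(res$educt[, s], res$product[, s], model$layout))
}

#' Count ITS candidates without materializing them
#' @param model an `its_model`.
#' @return integer solution count.
#' @export
count_candidates <- function(model) {
  res <- run_csp(model, first_only = FALSE)
  ncol(res$educt)
}

#' First ITS candidate of a model
#'
#' First solution of the same deterministic search, or NULL.
#'
#' @param model an `its_model`.
#' @return an `its_candidate` or NULL.
#' @export
first_candidate <- function(model) {
  res <- run_csp(model, first_only = TRUE)
  if (ncol(res$educt) == 0L) return(NULL)
  new_its_candidate(res$educt[, 1L], res$product[, 1L], model$layout)
}

#' Check the defining invariants of an ITS candidate
#'
#' Re-checks, independently of any solver: distinctness per side,
#' positionwise label equality, lone-pair changes, and the exact bond-order
#' change on every cycle edge (pseudo bonds present and unchanged).
#'
#' @param reaction a `reaction`.
#' @param candidate an `its_candidate`.
#' @return TRUE/FALSE.
#' @export
candidate_is_valid <- function(reaction, candidate) {
  gI <- reaction$educts; gO <- reaction$products
  lay <- candidate$layout
  k <- lay$k
  a <- candidate$educt; b <- candidate$product
  if (length(a) != k || length(b) != k) return(FALSE)
  if (anyDuplicated(a) || anyDuplicated(b)) return(FALSE)
  if (!all(gI$elem[a] == gO$elem[b])) return(FALSE)
  if (!all(gO$lp[b] - gI$lp[a] == lay$vertex_lp_changes)) return(FALSE)
  for (e in seq_len(k)) {
    p <- e; q <- if (e == k) 1L else e + 1L
    oi <- gI$adj[a[p], a[q]]; oo <- gO$adj[b[p], b[q]]
    if (oo - oi != lay$edge_changes[e]) return(FALSE)
    if (lay$edge_changes[e] == 0L && oi < 1L) return(FALSE)
  }
  TRUE
}

#' Brute-force ITS candidate enumeration (testing oracle)
#'
#' Exhaustively tests ordered tuples of distinct educt and product vertices
#' against the candidate invariants plus the same symmetry-breaking filter
#' as the constraint model. Entirely independent of the compiled search
#' engine; intended for small fixtures.
#'
#' @param reaction a `reaction`.
#' @param layout an `its_layout`.
#' @param mode `"basic"` or `"extended"`.
#' @param symmetry_breaking apply the order filter for rotation-symmetric
#'   layouts.
#' @param degree_semantics as in [build_model()].
#' @param max_vertices refuse larger inputs unless `force = TRUE`.
#' @param force override the size guard.
#' @return list of `its_candidate`.
#' @export
brute_force_candidates <- function(reaction, layout,
                                   mode = c("basic", "extended"),
                                   symmetry_breaking = TRUE,
                                   degree_semantics = getOption(
                                     "itsmapr.degree_semantics", "edges"),
                                   max_vertices = 16L, force = FALSE) {
  mode <- match.arg(mode)
  gI <- reaction$educts; gO <- reaction$products
  n <- gI$n
  if (n > max_vertices && !force)
    stop("brute-force oracle refused: ", n, " > ", max_vertices,
         " vertices (use force = TRUE to override)")
  k <- layout$k; cc <- layout$edge_changes; d <- layout$vertex_lp_changes
  degI <- vertex_degrees(gI, degree_semantics)
  degO <- vertex_degrees(gO, degree_semantics)
  allowedI <- rep(TRUE, n); allowedO <- rep(TRUE, n)
  req_lab <- NULL; difI <- difO <- NULL; keysI <- keysO <- NULL
  if (mode == "extended") {
    allowedI[sibling_hydrogen_removal(gI)] <- FALSE
    allowedO[sibling_hydrogen_removal(gO)] <- FALSE
    NI <- signature_multiset(gI); NO <- signature_multiset(gO)
    difI <- multiset_difference(NI, NO)
    difO <- multiset_difference(NO, NI)
    req_lab <- its_label_requirements(reaction)
    keysI <- signature_keys(gI); keysO <- signature_keys(gO)
  }
  sym <- symmetry_breaking && layout$rotation_symmetric
  out <- list()
  a <- integer(k); b <- integer(k)
  usedI <- logical(n); usedO <- logical(n)
  pair_ok <- function(i, u, w) {
    gI$elem[u] == gO$elem[w] &&
      gO$lp[w] - gI$lp[u] == d[i] &&
      abs(degI[u] - degO[w]) <= 1L
  }
  edge_ok <- function(e, up, uq, wp, wq) {
    oi <- gI$adj[up, uq]; oo <- gO$adj[wp, wq]
    oo - oi == cc[e] && (cc[e] != 0L || oi >= 1L)
  }
  recurse <- function(i) {
    if (i > k) {
      if (!edge_ok(k, a[k], a[1L], b[k], b[1L])) return(invisible())
      if (sym && any(a[1L] >= a[-1L])) return(invisible())
      if (mode == "extended") {
        labs <- lmultiset(gI$elem[a])
        if (!lms_contains(labs, req_lab)) return(invisible())
        if (!lms_contains(lmultiset(keysI[a]), difI)) return(invisible())
        if (!lms_contains(lmultiset(keysO[b]), difO)) return(invisible())
      }
      out[[length(out) + 1L]] <<- new_its_candidate(a, b, layout)
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (usedI[u] || !allowedI[u]) next
      for (w in seq_len(n)) {
        if (usedO[w] || !allowedO[w]) next
        if (!pair_ok(i, u, w)) next
        if (i > 1L && !edge_ok(i - 1L, a[i - 1L], u, b[i - 1L], w)) next
        a[i] <<- u; b[i] <<- w
        usedI[u] <<- TRUE; usedO[w] <<- TRUE
        recurse(i + 1L)
        usedI[u] <<- FALSE; usedO[w] <<- FALSE
      }
    }
    invisible()
  }
  recurse(1L)
  out
}
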