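# Reference test inputs (the five KEGG benchmark reactions, the Diels-Alder
# worked example, the Meisenheimer rearrangement) and a planted-ITS random
# reaction generator, so every pipeline stage is testable without external
# data.

TABLE2_SMILES <- c(
  R00013 = "C(=O)=O.C(C(=O)O)(C=O)O>>C(=O)(C=O)O.C(=O)(C=O)O",
  R00018 = "N.N(CCCCN)CCCCN>>C(CCN)CN.C(CCN)CN",
  R00048 = "CC(O)CC(=O)OC(C)CC(O)=O.O>>CC(O)CC(O)=O.CC(O)CC(O)=O",
  R00059 = "N(C(=O)CCCCCN)CCCCCC(=O)O.O>>C(CC(=O)O)CCCN.C(CC(=O)O)CCCN",
  R00207 = "P(=O)(O)(O)O.O=O.CC(=O)C(=O)O>>P(=O)(OC(=O)C)(O)O.OO.C(=O)=O"
)

#' The five elementary homovalent KEGG benchmark reactions
#'
#' Parsed from their published SMILES with explicit hydrogens completed.
#'
#' @return named list of five `reaction` objects (R00013, R00018, R00048,
#'   R00059, R00207).
#' @export
table2_reactions <- function() {
  out <- lapply(names(TABLE2_SMILES), function(id)
    parse_reaction(TABLE2_SMILES[[id]], id = id))
  stats::setNames(out, names(TABLE2_SMILES))
}

#' The Diels-Alder worked example
#'
#' Isoprene + vinylamine -> 4-methyl-cyclohexenylamine skeleton. The
#' structures are reconstructions whose authority is agreement of their
#' neighborhood-signature multisets with the published ones; tests gate on
#' that equality.
#'
#' @param hydrogens `"suppressed"` (as the worked example is printed) or
#'   `"explicit"`.
#' @return a `reaction`.
#' @export
figure1_reaction <- function(hydrogens = c("suppressed", "explicit")) {
  hydrogens <- match.arg(hydrogens)
  r <- parse_reaction("C=C(C)C=C.C=CN>>NC1CCC(C)=CC1", id = "diels-alder")
  if (hydrogens == "suppressed") suppress_hydrogens(r) else r
}

#' A [2,3]-Meisenheimer rearrangement
#'
#' N-allyl-N,N-dimethylamine N-oxide -> O-allyl-N,N-dimethylhydroxylamine.
#' An ambivalent reaction: the charged N/O pair exchanges a lone pair, so no
#' homovalent even alternating cycle describes it, while the odd pseudo-bond
#' layout does.
#'
#' @return a `reaction`.
#' @export
meisenheimer_reaction <- function() {
  parse_reaction("C=CC[N+](C)(C)[O-]>>C=CCON(C)C", id = "meisenheimer")
}

with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# classify a layout for planting
planting_scheme <- function(layout) {
  k <- layout$k; cc <- layout$edge_changes; d <- layout$vertex_lp_changes
  if (all(d == 0L)) return("homovalent")
  pseudo <- sum(cc == 0L) == 1L && cc[k] == 0L &&
    all(d[-c(1L, k)] == 0L) && abs(d[1L]) == 1L && d[k] == -d[1L]
  if (pseudo) return(if (d[1L] == 1L) "pseudo" else "pseudo_inverse")
  "unsupported"
}

#' Generate a random reaction with a planted ITS
#'
#' Builds a random valence-respecting educt graph over elements C/N/O,
#' plants a cycle realizing the given layout (bond orders stay in 0..3,
#' lone pairs non-negative), derives the products by applying the layout's
#' edge and lone-pair changes, completes hydrogens on both sides, and
#' returns the ground-truth atom map and ITS candidate. Charges are
#' introduced only where an ambivalent (pseudo-bond) layout requires them.
#' Deterministic per seed; the caller's RNG state is left untouched.
#'
#' @param n_heavy number of non-hydrogen atoms (>= k).
#' @param k cycle size; must equal `layout$k`.
#' @param layout an `its_layout` (homovalent or pseudo-bond).
#' @param seed integer seed.
#' @param p_extra expected number of random decoration bonds per heavy atom.
#' @return a `planted_reaction`: list with `reaction`, `planted_map`,
#'   `planted_candidate`, `seed`, `layout`.
#' @export
plant_random_reaction <- function(n_heavy, k, layout, seed, p_extra = 0.6) {
  stopifnot(k == layout$k)
  if (n_heavy < k) stop("n_heavy must be at least k")
  scheme <- planting_scheme(layout)
  if (scheme == "unsupported")
    stop("unsupported layout for planting: ", layout$name)
  with_preserved_seed(seed, {
    for (attempt in 1:25) {
      pr <- tryCatch(plant_once(n_heavy, k, layout, scheme, p_extra),
                     error = function(e) NULL)
      if (!is.null(pr)) { pr$seed <- seed; return(pr) }
    }
    stop("infeasible placement after bounded retries (layout ",
         layout$name, ", n_heavy ", n_heavy, ")")
  })
}

plant_once <- function(n_heavy, k, layout, scheme, p_extra) {
  cc <- layout$edge_changes; d <- layout$vertex_lp_changes
  base_val <- c(C = 4L, N = 3L, O = 2L)
  elem <- sample(c("C", "N", "O"), n_heavy, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  charge <- integer(n_heavy)
  cyc <- sample.int(n_heavy, k)
  if (scheme == "pseudo") {            # v1 gains a lone pair: N+ -> N
    elem[cyc[1L]] <- "N"; charge[cyc[1L]] <- 1L
    elem[cyc[k]] <- "O"; charge[cyc[k]] <- -1L
  } else if (scheme == "pseudo_inverse") {
    elem[cyc[1L]] <- "O"; charge[cyc[1L]] <- -1L
    elem[cyc[k]] <- "N"; charge[cyc[k]] <- 1L
  }
  cap <- base_val[elem] + charge
  adj <- matrix(0L, n_heavy, n_heavy)
  bos <- integer(n_heavy)
  add_bond <- function(u, v, o) {
    adj[u, v] <<- o; adj[v, u] <<- o
    bos[u] <<- bos[u] + o; bos[v] <<- bos[v] + o
  }
  cyc_edge <- matrix(FALSE, n_heavy, n_heavy)
  for (e in seq_len(k)) {
    p <- cyc[e]; q <- cyc[if (e == k) 1L else e + 1L]
    cyc_edge[p, q] <- cyc_edge[q, p] <- TRUE
    o <- if (cc[e] < 0L) 1L else if (cc[e] == 0L) 1L else 0L
    # occasionally break a double bond down to a single one
    if (cc[e] < 0L && stats::runif(1) < 0.25 &&
        bos[p] + 2L <= cap[p] && bos[q] + 2L <= cap[q]) o <- 2L
    if (o > 0L) {
      if (bos[p] + o > cap[p] || bos[q] + o > cap[q]) stop("capacity")
      add_bond(p, q, o)
    }
  }
  # formed edges must stay representable: educt order + change <= 3 (holds
  # for order 0) and the endpoints need spare valence in the products
  for (e in seq_len(k)) {
    if (cc[e] > 0L) {
      p <- cyc[e]; q <- cyc[if (e == k) 1L else e + 1L]
      if (adj[p, q] + cc[e] > 3L) stop("order overflow")
    }
  }
  n_extra <- stats::rpois(1L, p_extra * n_heavy)
  for (t in seq_len(n_extra)) {
    uv <- sample.int(n_heavy, 2L)
    u <- uv[1L]; v <- uv[2L]
    if (adj[u, v] > 0L || cyc_edge[u, v]) next
    if (bos[u] + 1L > cap[u] || bos[v] + 1L > cap[v]) next
    add_bond(u, v, 1L)
  }
  # product side: apply layout changes on the same atom ids, then permute
  padj <- adj
  pcharge <- charge
  for (e in seq_len(k)) {
    p <- cyc[e]; q <- cyc[if (e == k) 1L else e + 1L]
    o <- padj[p, q] + cc[e]
    if (o < 0L || o > 3L) stop("order out of range")
    padj[p, q] <- padj[q, p] <- o
  }
  pcharge[cyc] <- pcharge[cyc] - d
  perm <- sample.int(n_heavy)                 # educt heavy i -> product heavy perm[i]
  inv <- integer(n_heavy); inv[perm] <- seq_len(n_heavy)
  padj2 <- padj[inv, inv, drop = FALSE]
  ge <- annotate_lone_pairs(complete_hydrogens(
    mol_graph(elem, adj_to_bonds(adj), charge)))
  gp <- annotate_lone_pairs(complete_hydrogens(
    mol_graph(elem[inv], adj_to_bonds(padj2), pcharge[inv])))
  reaction <- structure(list(educts = ge, products = gp, id = "planted"),
                        class = "reaction")
  if (!check_mass_balance(reaction)$pass) stop("unbalanced plant")
  # ground-truth map: heavy atoms via perm, hydrogens paired ascending
  mapping <- integer(ge$n)
  mapping[seq_len(n_heavy)] <- perm
  for (u in seq_len(n_heavy)) {
    he <- which(ge$adj[u, ] > 0L & ge$is_h)
    hp <- which(gp$adj[perm[u], ] > 0L & gp$is_h)
    if (length(he) != length(hp)) stop("hydrogen count mismatch")
    mapping[sort(he)] <- sort(hp)
  }
  chk <- verify_atom_map(reaction, mapping)
  if (!chk$valid) stop("planted map invalid")
  cand <- normalize_candidate(reaction, cyc, perm[cyc], layout)
  structure(list(reaction = reaction,
                 planted_map = structure(list(mapping = mapping,
                                              candidate = cand),
                                         class = "atom_map"),
                 planted_candidate = cand,
                 layout = layout, seed = NA_integer_),
            class = "planted_reaction")
}

adj_to_bonds <- function(adj) {
  ut <- which(upper.tri(adj) & adj > 0L, arr.ind = TRUE)
  cbind(ut, adj[ut])
}

# Re-orient a planted cycle into the solver's canonical representative: of
# all phase-consistent traversals (rotations, and reversals for layouts that
# admit them) keep the one passing the candidate invariants and, for
# rotation-symmetric layouts, the ordering constraint.
normalize_candidate <- function(reaction, educt_cycle, product_cycle, layout) {
  k <- layout$k
  rot <- function(x, r) x[((seq_len(k) - 1L + r) %% k) + 1L]
  variants <- list()
  for (r in 0:(k - 1L)) {
    variants[[length(variants) + 1L]] <-
      list(e = rot(educt_cycle, r), p = rot(product_cycle, r))
    rev_e <- c(educt_cycle[1L], rev(educt_cycle[-1L]))
    rev_p <- c(product_cycle[1L], rev(product_cycle[-1L]))
    variants[[length(variants) + 1L]] <-
      list(e = rot(rev_e, r), p = rot(rev_p, r))
  }
  sym <- layout$rotation_symmetric
  for (v in variants) {
    cand <- new_its_candidate(v$e, v$p, layout)
    if (!candidate_is_valid(reaction, cand)) next
    if (sym && v$e[1L] != min(v$e)) next
    return(cand)
  }
  stop("planted cycle admits no canonical orientation")
}
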