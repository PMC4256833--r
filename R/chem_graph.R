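# Molecular and reaction graph model: SMILES parsing/writing, hydrogen
# completion, lone-pair annotation and mass-balance validation.
#
# Molecules are undirected labeled graphs. Edges carry integer bond orders
# 1..3; non-bonding electron pairs live on the vertices (conceptually the
# diagonal of the adjacency matrix), computed from element, formal charge and
# bond-order sum. Stereochemistry, isotopes, radicals and aromatic perception
# (beyond rejecting aromatic input) are out of scope.

VALENCE_ELECTRONS <- c(H = 1L, B = 3L, C = 4L, N = 5L, O = 6L, F = 7L,
                       Si = 4L, P = 5L, S = 6L, Cl = 7L, Br = 7L, I = 7L)

# standard valence targets per element; charge-adjusted at use site
VALENCE_TARGETS <- list(H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L,
                        F = 1L, Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L),
                        Cl = 1L, Br = 1L, I = 1L)

#' Construct a molecule graph
#'
#' Low-level constructor used by the SMILES parser and the synthetic-reaction
#' generator. Atom ids are 1-based and stable.
#'
#' @param elem character vector of element symbols.
#' @param bonds three-column matrix (i, j, order) or NULL.
#' @param charge integer formal charges (recycled).
#' @param atom_class integer SMILES atom-map classes, 0 = unmapped (recycled).
#' @return an object of class `mol_graph` with fields `elem`, `charge`, `lp`
#'   (lone pairs, NA until annotated), `is_h`, `adj` (bond-order matrix),
#'   `component`, `h_parent` and `atom_class`.
#' @export
mol_graph <- function(elem, bonds = NULL, charge = 0L, atom_class = 0L) {
  n <- length(elem)
  bad <- setdiff(unique(elem), names(VALENCE_ELECTRONS))
  if (length(bad) > 0L)
    stop("unrecognized element symbol(s): ", paste(bad, collapse = ", "))
  adj <- matrix(0L, n, n)
  if (!is.null(bonds) && NROW(bonds) > 0L) {
    bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 3L)
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1L]; j <- bonds[r, 2L]; o <- bonds[r, 3L]
      if (i == j) stop("self-bond on atom ", i)
      if (i < 1L || j < 1L || i > n || j > n) stop("bond endpoint out of range")
      if (!o %in% 1:3) stop("bond order must be in 1..3")
      if (adj[i, j] != 0L) stop("duplicate bond ", i, "-", j)
      adj[i, j] <- o; adj[j, i] <- o
    }
  }
  g <- structure(list(
    n = n, elem = as.character(elem),
    charge = rep_len(as.integer(charge), n),
    lp = rep_len(NA_integer_, n),
    is_h = elem == "H",
    adj = adj,
    component = integer(n),
    h_parent = rep_len(NA_integer_, n),
    atom_class = rep_len(as.integer(atom_class), n)
  ), class = "mol_graph")
  g$component <- graph_components(g)
  g
}

graph_components <- function(graph) {
  n <- graph$n
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      stack <- c(stack, which(graph$adj[v, ] > 0L & comp == 0L))
    }
  }
  comp
}

bond_order_sums <- function(graph) as.integer(rowSums(graph$adj))

#' Lone pairs of an atom
#'
#' Number of non-bonding electron pairs from the periodic-group valence
#' electron count, the formal charge and the total bond order:
#' `(valence_electrons - charge - bond_order_sum) / 2`, floored at zero.
#'
#' @param element element symbol.
#' @param charge integer formal charge.
#' @param bond_order_sum sum of incident bond orders.
#' @return non-negative integer count of lone pairs.
#' @examples
#' lone_pairs("O", 0, 2)  # 2
#' lone_pairs("N", 1, 4)  # 0
#' @export
lone_pairs <- function(element, charge, bond_order_sum) {
  ve <- VALENCE_ELECTRONS[[element]]
  if (is.null(ve)) stop("unsupported element: ", element)
  nb <- ve - as.integer(charge) - as.integer(bond_order_sum)
  if (nb %% 2L != 0L)
    stop("radical unsupported: odd non-bonding electron count for ", element,
         " (charge ", charge, ", bond order sum ", bond_order_sum, ")")
  max(0L, nb %/% 2L)
}

annotate_lone_pairs <- function(graph) {
  bos <- bond_order_sums(graph)
  graph$lp <- vapply(seq_len(graph$n), function(v)
    lone_pairs(graph$elem[v], graph$charge[v], bos[v]), integer(1L))
  graph
}

#' Complete hydrogens to standard valence
#'
#' Adds explicit hydrogen atoms so every non-hydrogen atom reaches its
#' charge-adjusted standard valence (H 1, C 4, N 3/5, O 2, P 3/5, S 2/4/6,
#' halogens 1; a +1 charge raises the target by one, -1 lowers it). Added
#' hydrogens are appended grouped by their parent heavy atom, in parent-id
#' order, and then lone pairs are annotated for all atoms.
#'
#' @param graph a `mol_graph`.
#' @return the completed `mol_graph`.
#' @export
complete_hydrogens <- function(graph) {
  bos <- bond_order_sums(graph)
  n0 <- graph$n
  add_parent <- integer(0)
  for (v in seq_len(n0)) {
    if (graph$is_h[v]) {
      if (bos[v] > 1L) stop("hydrogen atom ", v, " with more than one bond")
      next
    }
    targets <- VALENCE_TARGETS[[graph$elem[v]]] + graph$charge[v]
    targets <- targets[targets >= 0L]
    fit <- targets[targets >= bos[v]]
    if (length(fit) == 0L)
      stop("hypervalent input: atom ", v, " (", graph$elem[v],
           ", charge ", graph$charge[v], ") has bond order sum ", bos[v])
    add_parent <- c(add_parent, rep(v, min(fit) - bos[v]))
  }
  nh <- length(add_parent)
  if (nh > 0L) {
    n1 <- n0 + nh
    adj <- matrix(0L, n1, n1)
    adj[seq_len(n0), seq_len(n0)] <- graph$adj
    for (t in seq_len(nh)) {
      h <- n0 + t; p <- add_parent[t]
      adj[h, p] <- 1L; adj[p, h] <- 1L
    }
    graph$n <- n1
    graph$elem <- c(graph$elem, rep("H", nh))
    graph$charge <- c(graph$charge, rep(0L, nh))
    graph$lp <- c(graph$lp, rep(NA_integer_, nh))
    graph$is_h <- c(graph$is_h, rep(TRUE, nh))
    graph$adj <- adj
    graph$h_parent <- c(graph$h_parent, add_parent)
    graph$atom_class <- c(graph$atom_class, rep(0L, nh))
    graph$component <- graph_components(graph)
  }
  annotate_lone_pairs(graph)
}

# Reorder atoms to the package convention: non-hydrogens in parse order,
# then hydrogens (parsed ones first, then completed ones, which are already
# grouped by parent in parent order).
canonical_atom_order <- function(graph) {
  prio <- ifelse(!graph$is_h, 0L, ifelse(is.na(graph$h_parent), 1L, 2L))
  ord <- order(prio, seq_len(graph$n))
  permute_graph(graph, ord)
}

# ord[newpos] = old id
permute_graph <- function(graph, ord) {
  inv <- integer(graph$n); inv[ord] <- seq_len(graph$n)
  graph$elem <- graph$elem[ord]
  graph$charge <- graph$charge[ord]
  graph$lp <- graph$lp[ord]
  graph$is_h <- graph$is_h[ord]
  graph$adj <- graph$adj[ord, ord, drop = FALSE]
  graph$component <- graph$component[ord]
  graph$h_parent <- ifelse(is.na(graph$h_parent[ord]), NA_integer_,
                           inv[graph$h_parent[ord]])
  graph$atom_class <- graph$atom_class[ord]
  graph
}

#' Drop explicit hydrogens
#'
#' Removes hydrogen vertices while keeping the lone-pair and charge
#' annotations computed on the full graph. Used to replicate worked examples
#' stated on hydrogen-suppressed graphs.
#'
#' @param x a `mol_graph` or `reaction` object.
#' @return object of the same class without hydrogen atoms.
#' @export
suppress_hydrogens <- function(x) {
  if (inherits(x, "reaction")) {
    x$educts <- suppress_hydrogens(x$educts)
    x$products <- suppress_hydrogens(x$products)
    return(x)
  }
  keep <- which(!x$is_h)
  x$elem <- x$elem[keep]; x$charge <- x$charge[keep]; x$lp <- x$lp[keep]
  x$is_h <- x$is_h[keep]; x$adj <- x$adj[keep, keep, drop = FALSE]
  x$component <- x$component[keep]
  x$h_parent <- rep(NA_integer_, length(keep))
  x$atom_class <- x$atom_class[keep]
  x$n <- length(keep)
  if (x$n > 0L) x$component <- graph_components(x)
  x
}

## ---------------------------------------------------------------------------
## SMILES parsing (kekulized subset: no aromatics, no stereo, no isotopes)

ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")

smiles_error <- function(text, pos, msg)
  stop(sprintf("SMILES parse failure at position %d in \"%s\": %s",
               pos, text, msg), call. = FALSE)

# Parse one dot-free SMILES component into atom/bond lists.
parse_smiles_component <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  np <- length(chars)
  elem <- character(0); charge <- integer(0); hcount <- integer(0)
  aclass <- integer(0)
  bonds <- matrix(integer(0), ncol = 3L)
  prev <- 0L                 # atom awaiting the next bond
  pending <- NA_integer_     # explicit bond order for next connection
  stack <- integer(0)        # branch stack
  rings <- list()            # digit -> c(atom, order or NA)
  i <- 1L
  new_atom <- function(sym, chg, hc, cls) {
    elem <<- c(elem, sym); charge <<- c(charge, chg)
    hcount <<- c(hcount, hc); aclass <<- c(aclass, cls)
    length(elem)
  }
  connect <- function(a, b, order) {
    if (is.na(order)) order <- 1L
    bonds <<- rbind(bonds, c(a, b, order))
  }
  while (i <= np) {
    ch <- chars[i]
    if (ch %in% c("/", "\\", "@")) smiles_error(text, i, "stereochemistry unsupported")
    if (ch %in% c("b", "c", "n", "o", "p", "s"))
      smiles_error(text, i, "aromaticity unsupported (kekulized input required)")
    if (ch == "(") {
      if (prev == 0L) smiles_error(text, i, "branch before any atom")
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (length(stack) == 0L) smiles_error(text, i, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#")) {
      pending <- c("-" = 1L, "=" = 2L, "#" = 3L)[[ch]]
      i <- i + 1L; next
    }
    if (ch == ":") smiles_error(text, i, "aromaticity unsupported (kekulized input required)")
    if (grepl("[0-9%]", ch)) {
      if (prev == 0L) smiles_error(text, i, "ring closure before any atom")
      if (ch == "%") {
        if (i + 2L > np || !grepl("[0-9]", chars[i + 1L]) || !grepl("[0-9]", chars[i + 2L]))
          smiles_error(text, i, "bad %nn ring closure")
        dig <- paste0(chars[i + 1L], chars[i + 2L]); i <- i + 3L
      } else { dig <- ch; i <- i + 1L }
      if (!is.null(rings[[dig]])) {
        op <- rings[[dig]]
        order <- pending
        if (is.na(order)) order <- op[2L]
        if (!is.na(op[2L]) && !is.na(pending) && op[2L] != pending)
          smiles_error(text, i, "conflicting ring-bond orders")
        if (op[1L] == prev) smiles_error(text, i, "ring closure to self")
        connect(op[1L], prev, order)
        rings[[dig]] <- NULL
      } else {
        rings[[dig]] <- c(prev, pending)
      }
      pending <- NA_integer_
      next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= np && chars[j] != "]") j <- j + 1L
      if (j > np) smiles_error(text, i, "unmatched '['")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([A-Z][a-z]?)(H([0-9]*))?(\\+{1,3}|-{1,3}|\\+[0-9]|-[0-9])?(:([0-9]+))?$",
        body))[[1]]
      if (length(m) == 0L) {
        if (grepl("^[0-9]", body)) smiles_error(text, i, "isotopes unsupported")
        if (grepl("@", body)) smiles_error(text, i, "stereochemistry unsupported")
        smiles_error(text, i, paste0("cannot parse bracket atom [", body, "]"))
      }
      sym <- m[2]
      if (!sym %in% names(VALENCE_ELECTRONS))
        smiles_error(text, i, paste0("unrecognized element '", sym, "'"))
      hc <- if (m[3] == "") 0L else if (m[4] == "") 1L else as.integer(m[4])
      chg <- 0L
      if (m[5] != "") {
        chg <- if (grepl("[0-9]", m[5])) {
          as.integer(substr(m[5], 2L, 2L)) * (if (substr(m[5], 1L, 1L) == "+") 1L else -1L)
        } else nchar(m[5]) * (if (substr(m[5], 1L, 1L) == "+") 1L else -1L)
      }
      cls <- if (m[7] == "") 0L else as.integer(m[7])
      a <- new_atom(sym, chg, 0L, cls)
      if (prev > 0L) connect(prev, a, pending)
      pending <- NA_integer_
      prev <- a
      # bracket hydrogens become explicit atoms right away
      if (hc > 0L) for (t in seq_len(hc)) {
        h <- new_atom("H", 0L, 0L, 0L)
        connect(a, h, 1L)
      }
      i <- j + 1L
      next
    }
    # organic-subset atom (two-character symbols first)
    sym <- NULL
    if (i < np) {
      two <- paste0(ch, chars[i + 1L])
      if (two %in% c("Cl", "Br")) sym <- two
    }
    if (is.null(sym) && ch %in% ORGANIC_SUBSET) sym <- ch
    if (is.null(sym)) smiles_error(text, i, paste0("unexpected character '", ch, "'"))
    a <- new_atom(sym, 0L, 0L, 0L)
    if (prev > 0L) connect(prev, a, pending)
    pending <- NA_integer_
    prev <- a
    i <- i + nchar(sym)
  }
  if (length(stack) > 0L) smiles_error(text, np, "unmatched '('")
  if (length(rings) > 0L) smiles_error(text, np, "unclosed ring bond")
  if (length(elem) == 0L) smiles_error(text, 1L, "empty molecule")
  list(elem = elem, charge = charge, aclass = aclass, bonds = bonds)
}

# Parse one reaction side (components separated by ".") into a completed,
# canonically ordered mol_graph.
parse_side <- function(text) {
  comps <- strsplit(text, ".", fixed = TRUE)[[1]]
  comps <- comps[nzchar(comps)]
  if (length(comps) == 0L) stop("empty reaction side")
  elem <- character(0); charge <- integer(0); aclass <- integer(0)
  bonds <- matrix(integer(0), ncol = 3L)
  for (cm in comps) {
    p <- parse_smiles_component(cm)
    off <- length(elem)
    elem <- c(elem, p$elem); charge <- c(charge, p$charge)
    aclass <- c(aclass, p$aclass)
    if (nrow(p$bonds) > 0L) {
      pb <- p$bonds
      pb[, 1:2] <- pb[, 1:2] + off
      bonds <- rbind(bonds, pb)
    }
  }
  g <- mol_graph(elem, bonds, charge, aclass)
  canonical_atom_order(complete_hydrogens(g))
}

#' Parse a reaction SMILES
#'
#' Educts and products are separated by `">>"`, molecules by `"."`. Hydrogens
#' are completed to standard valence and lone pairs annotated. Atom ids are
#' assigned per side: non-hydrogen atoms in parse order, then hydrogens
#' grouped by their parent atom.
#'
#' @param text reaction SMILES string.
#' @param id optional reaction identifier.
#' @param check_balance error on mass imbalance (default TRUE).
#' @return object of class `reaction` with fields `educts`, `products`, `id`.
#' @examples
#' r <- parse_reaction("O>>O")
#' r$educts$n  # 3 atoms: O + 2 H
#' @export
parse_reaction <- function(text, id = NULL, check_balance = TRUE) {
  parts <- strsplit(text, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("reaction SMILES must contain exactly one \">>\" separator")
  r <- structure(list(educts = parse_side(parts[1]),
                      products = parse_side(parts[2]),
                      id = id), class = "reaction")
  if (check_balance) {
    rep <- check_mass_balance(r)
    if (!rep$pass)
      stop("mass imbalance: ", rep$message)
  }
  r
}

#' Check reaction mass balance
#'
#' Passes iff educt and product sides have the same number of atoms and the
#' same element multiset. The report lists per-element educt-minus-product
#' deltas on failure.
#'
#' @param reaction a `reaction`.
#' @return list with `pass`, `size_educts`, `size_products`, `deltas` (named
#'   integer vector) and `message`.
#' @export
check_mass_balance <- function(reaction) {
  nI <- reaction$educts$n; nO <- reaction$products$n
  te <- table(reaction$educts$elem); tp <- table(reaction$products$elem)
  els <- sort(unique(c(names(te), names(tp))))
  deltas <- vapply(els, function(e) {
    as.integer(ifelse(e %in% names(te), te[[e]], 0L)) -
      as.integer(ifelse(e %in% names(tp), tp[[e]], 0L))
  }, integer(1L))
  names(deltas) <- els
  deltas <- deltas[deltas != 0L]
  pass <- nI == nO && length(deltas) == 0L
  msg <- if (pass) "balanced" else if (length(deltas) > 0L) {
    paste0("element deltas (educts - products): ",
           paste(sprintf("%s:%+d", names(deltas), deltas), collapse = ", "))
  } else sprintf("atom count mismatch (%d vs %d)", nI, nO)
  list(pass = pass, size_educts = nI, size_products = nO,
       deltas = deltas, message = msg)
}

## ---------------------------------------------------------------------------
## Mapped SMILES output

charge_token <- function(chg) {
  if (chg == 0L) "" else if (chg == 1L) "+" else if (chg == -1L) "-"
  else if (chg > 0L) paste0("+", chg) else paste0("-", abs(chg))
}

bond_token <- function(order) c("", "=", "#")[order]

# Write one mol_graph as SMILES with the given atom-map classes (0 = none).
write_smiles_graph <- function(graph, classes) {
  n <- graph$n
  comps <- split(seq_len(n), graph$component)
  ring_digit <- 0L
  atom_token <- function(v) {
    cls <- classes[v]
    paste0("[", graph$elem[v], charge_token(graph$charge[v]),
           if (cls > 0L) paste0(":", cls) else "", "]")
  }
  write_component <- function(verts) {
    root <- min(verts)
    ring_at <- vector("list", n)   # per atom: list of c(digit, order)
    pre <- integer(n)              # DFS preorder number, 0 = unvisited
    parent <- integer(n)
    tree_children <- vector("list", n)
    back_edges <- matrix(integer(0), ncol = 2L)
    counter <- 0L
    dfs <- function(v) {
      counter <<- counter + 1L
      pre[v] <<- counter
      for (u in sort(which(graph$adj[v, ] > 0L))) {
        if (u == parent[v]) next
        if (pre[u] > 0L) {
          # non-tree edge; record once, at the later-visited endpoint
          if (pre[u] < pre[v]) back_edges <<- rbind(back_edges, c(v, u))
        } else {
          parent[u] <<- v
          tree_children[[v]] <<- c(tree_children[[v]], u)
          dfs(u)
        }
      }
    }
    dfs(root)
    # assign digits: each back edge present at both endpoints
    if (nrow(back_edges) > 0L) for (r in seq_len(nrow(back_edges))) {
      ring_digit <<- ring_digit + 1L
      v <- back_edges[r, 1L]; u <- back_edges[r, 2L]
      o <- graph$adj[v, u]
      ring_at[[v]] <- c(ring_at[[v]], list(c(ring_digit, o)))
      ring_at[[u]] <- c(ring_at[[u]], list(c(ring_digit, o)))
    }
    digit_token <- function(d, o, first)
      paste0(if (first) bond_token(o) else "", if (d > 9L) paste0("%", d) else d)
    emit <- function(v) {
      out <- atom_token(v)
      for (rd in ring_at[[v]]) {
        out <- paste0(out, digit_token(rd[1L], rd[2L], TRUE))
      }
      ch <- tree_children[[v]]
      if (length(ch) > 0L) {
        for (idx in seq_along(ch)) {
          u <- ch[idx]
          sub <- paste0(bond_token(graph$adj[v, u]), emit(u))
          out <- paste0(out, if (idx < length(ch)) paste0("(", sub, ")") else sub)
        }
      }
      out
    }
    emit(root)
  }
  paste(vapply(comps, write_component, character(1L)), collapse = ".")
}

#' Write an atom-mapped reaction SMILES
#'
#' Emits standard atom-map-class annotations (`:n`): educt atom `i` carries
#' class `i`, and the product atom it maps to carries the same class.
#' Re-parsing the output reproduces the bijection.
#'
#' @param reaction a `reaction`.
#' @param map an `atom_map` or a bare integer bijection (educt id -> product
#'   id); must pass [verify_atom_map()].
#' @return a single reaction SMILES string.
#' @export
write_mapped_smiles <- function(reaction, map) {
  mapping <- if (inherits(map, "atom_map")) map$mapping else as.integer(map)
  chk <- verify_atom_map(reaction, mapping)
  if (!chk$valid)
    stop("refusing to write an unverified atom map: ",
         paste(chk$violations, collapse = "; "))
  ecls <- seq_len(reaction$educts$n)
  pcls <- integer(reaction$products$n)
  pcls[mapping] <- ecls
  paste0(write_smiles_graph(reaction$educts, ecls), ">>",
         write_smiles_graph(reaction$products, pcls))
}

#' Extract the atom-map bijection from a mapped reaction SMILES
#'
#' Atom classes must pair up one-to-one between the sides. Hydrogens added
#' by valence completion (which carry no class) are paired by their parent
#' atoms in ascending id order to complete the bijection.
#'
#' @param text mapped reaction SMILES.
#' @return list with the parsed `reaction`, `class_mapping` (bijection over
#'   the classed atoms only) and `mapping` (full bijection including
#'   completed hydrogens).
#' @export
read_mapped_smiles <- function(text) {
  r <- parse_reaction(text)
  ce <- r$educts$atom_class; cp <- r$products$atom_class
  ke <- which(ce > 0L); kp <- which(cp > 0L)
  if (length(ke) == 0L || anyDuplicated(ce[ke]) || anyDuplicated(cp[kp]) ||
      !setequal(ce[ke], cp[kp]))
    stop("input is not a consistently atom-mapped reaction SMILES")
  class_mapping <- integer(r$educts$n)
  class_mapping[ke] <- kp[match(ce[ke], cp[kp])]
  mapping <- class_mapping
  uncl_e <- which(ce == 0L); uncl_p <- which(cp == 0L)
  if (length(uncl_e) > 0L) {
    if (!all(r$educts$is_h[uncl_e]) || !all(r$products$is_h[uncl_p]))
      stop("unmapped non-hydrogen atoms in mapped SMILES")
    for (u in ke) {
      he <- intersect(which(r$educts$adj[u, ] > 0L), uncl_e)
      hp <- intersect(which(r$products$adj[mapping[u], ] > 0L), uncl_p)
      if (length(he) != length(hp))
        stop("completed hydrogens do not pair up between the sides")
      mapping[sort(he)] <- sort(hp)
    }
  }
  class_mapping[class_mapping == 0L] <- NA_integer_
  list(reaction = r, mapping = mapping, class_mapping = class_mapping)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("mol_graph: %d atoms (%d H), %d molecule(s), %d bond(s)\n",
              x$n, sum(x$is_h), max(x$component),
              sum(x$adj[upper.tri(x$adj)] > 0L)))
  invisible(x)
}

#' @export
print.reaction <- function(x, ...) {
  cat(sprintf("reaction%s: %d educt atoms, %d product atoms\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "",
              x$educts$n, x$products$n))
  invisible(x)
}
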