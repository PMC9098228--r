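#' @name parsimony
#' @title Unit-cost parsimony with MPR uncertainty sets
#'
#' @description
#' The engine implements the generalized (Sankoff) parsimony recursion with a
#' unit step matrix on a rooted, possibly polytomous tree and a binary
#' character whose leaves may be observed (`absent`/`present`) or uncertain
#' (both states at cost 0: missing, inapplicable or polymorphic cells).
#' Polytomies are scored directly as hard multifurcations; no implicit
#' resolution is performed.  All arithmetic is integer.
#'
#' A node's *MPR set* contains a state iff that state is realized at the node
#' in at least one globally minimal full labeling (the union over all most
#' parsimonious reconstructions).  A two-state set is the operational meaning
#' of an "uncertain/equivocal" ancestral call.  Ambiguity is always reported
#' as a set; no tie-breaking is applied.
NULL

# state masks: 1 = absent only, 2 = present only, 3 = either
state_to_mask <- function(state) {
  m <- dplyr::case_match(state,
                         c("absent", "0") ~ 1L,
                         c("present", "1") ~ 2L,
                         c("uncertain", "01", "0/1", "?", "-") ~ 3L,
                         .default = NA_integer_)
  if (anyNA(m)) {
    abort(paste0("unrecognized state(s): ",
                 paste(unique(state[is.na(m)]), collapse = ", ")))
  }
  m
}

tip_masks <- function(tree, column) {
  if (is.data.frame(column)) {
    stopifnot(all(c("taxon", "state") %in% names(column)))
    masks <- stats::setNames(state_to_mask(column$state), column$taxon)
  } else {
    masks <- stats::setNames(state_to_mask(unname(column)), names(column))
  }
  miss <- setdiff(tree$tip.label, names(masks))
  if (length(miss) > 0L) {
    abort(paste0("no character entry for leaf/leaves: ",
                 paste(miss, collapse = ", ")))
  }
  unname(masks[tree$tip.label])
}

#' Downpass cost vectors
#'
#' Computes, for every node, the minimum number of state changes in the
#' subtree rooted there conditional on the node's state (the Sankoff dynamic
#' programme with a unit step matrix).  A leaf costs 0 at each of its allowed
#' states and effectively infinity elsewhere; uncertain leaves cost 0 at both
#' states.
#'
#' @param tree A rooted `phylo` (polytomies allowed).
#' @param column Character column: tibble `taxon`/`state` (from
#'   [apply_coding()]) or a named vector of states.
#' @return Integer matrix, one row per node (tips first, `ape` numbering),
#'   columns `cost_absent`, `cost_present`.  Infeasible leaf states carry a
#'   sentinel larger than any achievable tree length.
#' @export
parsimony_downpass <- function(tree, column) {
  masks <- tip_masks(tree, column)
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  inf <- N + 1L
  cost <- matrix(0L, nrow = N, ncol = 2,
                 dimnames = list(NULL, c("cost_absent", "cost_present")))
  cost[seq_len(n), 1] <- ifelse(bitwAnd(masks, 1L) > 0L, 0L, inf)
  cost[seq_len(n), 2] <- ifelse(bitwAnd(masks, 2L) > 0L, 0L, inf)
  if (n == 1L && tree$Nnode == 0L) return(cost)
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]
    ch <- po[i, 2]
    c0 <- min(cost[ch, 1], cost[ch, 2] + 1L)
    c1 <- min(cost[ch, 2], cost[ch, 1] + 1L)
    cost[p, 1] <- cost[p, 1] + c0
    cost[p, 2] <- cost[p, 2] + c1
  }
  cost
}

#' Minimum tree length (parsimony score)
#'
#' @inheritParams parsimony_downpass
#' @return Integer: the minimum number of state changes over the tree.  The
#'   value is invariant to rerooting on any edge.
#' @export
tree_length <- function(tree, column) {
  cost <- parsimony_downpass(tree, column)
  root <- length(tree$tip.label) + 1L
  if (nrow(cost) == 1L) return(0L)
  as.integer(min(cost[root, ]))
}

#' MPR state sets at every node
#'
#' Runs the downpass and an uppass so that for each node and state the total
#' tree length conditional on fixing that node to that state is known; the
#' node's MPR set collects the states whose conditional length equals the
#' global minimum.  Leaves echo their input sets restricted to states that
#' occur in at least one most parsimonious reconstruction.
#'
#' @inheritParams parsimony_downpass
#' @return An object of class `mpr`: list with `tree_length`, `states`
#'   (tibble: `node`, `label`, `is_tip`, logical `absent`/`present`, and
#'   `call` in `P`/`A`/`U`), and the `tree`.
#' @export
#' @examples
#' tr <- read_newick("((A,B),C);")
#' col <- tibble::tibble(taxon = c("A", "B", "C"),
#'                       state = c("absent", "present", "absent"))
#' mpr_sets(tr, col)
mpr_sets <- function(tree, column) {
  cost <- parsimony_downpass(tree, column)
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  if (N == 1L) {
    masks <- tip_masks(tree, column)
    states <- tibble(node = 1L, label = tree$tip.label, is_tip = TRUE,
                     absent = bitwAnd(masks, 1L) > 0L,
                     present = bitwAnd(masks, 2L) > 0L)
    states$call <- set_call(states$absent, states$present)
    return(new_mpr(0L, states, tree))
  }
  root <- n + 1L
  L <- min(cost[root, ])
  po <- ape::reorder.phylo(tree, "postorder")$edge
  up <- matrix(0L, nrow = N, ncol = 2)
  for (i in rev(seq_len(nrow(po)))) {   # parents before children
    p <- po[i, 1]
    ch <- po[i, 2]
    c0 <- min(cost[ch, 1], cost[ch, 2] + 1L)  # child's contribution to p@absent
    c1 <- min(cost[ch, 2], cost[ch, 1] + 1L)
    e0 <- up[p, 1] + cost[p, 1] - c0          # rest-of-tree cost, p fixed absent
    e1 <- up[p, 2] + cost[p, 2] - c1
    up[ch, 1] <- min(e0, e1 + 1L)
    up[ch, 2] <- min(e1, e0 + 1L)
  }
  total <- cost + up
  absent <- total[, 1] == L
  present <- total[, 2] == L
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label else rep(NA_character_, tree$Nnode))
  states <- tibble(
    node = seq_len(N),
    label = labels,
    is_tip = seq_len(N) <= n,
    absent = absent,
    present = present
  )
  states$call <- set_call(states$absent, states$present)
  new_mpr(as.integer(L), states, tree)
}

set_call <- function(absent, present) {
  ifelse(absent & present, "U", ifelse(present, "P", "A"))
}

new_mpr <- function(len, states, tree) {
  stopifnot(all(states$absent | states$present))
  structure(list(tree_length = len, states = states, tree = tree),
            class = "mpr")
}

#' @export
print.mpr <- function(x, ...) {
  cat("<mpr> tree length:", x$tree_length, "\n")
  tab <- table(factor(x$states$call[!x$states$is_tip], levels = c("A", "P", "U")))
  cat("  internal node calls: A =", tab[["A"]],
      " P =", tab[["P"]], " U =", tab[["U"]], "\n")
  invisible(x)
}

#' @rdname mpr_sets
#' @param x An `mpr` object.
#' @param ... Unused.
#' @export
tidy.mpr <- function(x, ...) {
  x$states
}

#' @rdname mpr_sets
#' @export
glance.mpr <- function(x, ...) {
  internal <- x$states[!x$states$is_tip, ]
  tibble(
    tree_length = x$tree_length,
    n_nodes = nrow(x$states),
    n_internal = nrow(internal),
    n_equivocal = sum(internal$call == "U")
  )
}

#' Serialize an MPR result to JSON
#'
#' @param x An `mpr` object.
#' @return JSON string mapping node labels/ids to state sets plus the length.
#' @export
mpr_json <- function(x) {
  stopifnot(inherits(x, "mpr"))
  sets <- lapply(seq_len(nrow(x$states)), function(i) {
    s <- x$states[i, ]
    c(if (s$absent) "absent", if (s$present) "present")
  })
  key <- ifelse(is.na(x$states$label) | !nzchar(x$states$label),
                paste0("node_", x$states$node), x$states$label)
  jsonlite::toJSON(list(tree_length = x$tree_length,
                        node_sets = stats::setNames(sets, key)),
                   auto_unbox = TRUE)
}

#' Exhaustive-enumeration parsimony oracle
#'
#' Enumerates every assignment of states to internal nodes (and the optimal
#' compatible leaf states), returning the exact minimum length and, per node,
#' the union of states over all minimal labelings.  Exponential in the number
#' of internal nodes; refuses more than 16.  Exists as an independent check
#' on [mpr_sets()] and is used as such by the test-suite.
#'
#' @inheritParams parsimony_downpass
#' @return An `mpr` object (same shape as [mpr_sets()]).
#' @export
brute_force_mpr <- function(tree, column) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  if (m > 16L) abort("brute force refused: more than 16 internal nodes")
  masks <- tip_masks(tree, column)
  if (m == 0L) {
    return(mpr_sets(tree, column))
  }
  K <- as.integer(2^m)
  # S[j, k]: state (0/1) of internal node n+j under labeling k
  S <- vapply(seq_len(m), function(j) {
    bitwAnd(bitwShiftR(seq_len(K) - 1L, j - 1L), 1L)
  }, integer(K))
  S <- t(S)  # m x K
  cost <- integer(K)
  edge <- tree$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1] - n  # internal index of parent
    ch <- edge[i, 2]
    ps <- S[p, ]
    if (ch > n) {
      cost <- cost + as.integer(ps != S[ch - n, ])
    } else {
      mk <- masks[ch]
      # best leaf choice given parent state: 0 if parent state allowed else 1
      allowed <- ifelse(ps == 0L, bitwAnd(mk, 1L) > 0L, bitwAnd(mk, 2L) > 0L)
      cost <- cost + as.integer(!allowed)
    }
  }
  L <- min(cost)
  minimal <- which(cost == L)
  absent <- logical(n + m)
  present <- logical(n + m)
  for (j in seq_len(m)) {
    st <- unique(S[j, minimal])
    absent[n + j] <- 0L %in% st
    present[n + j] <- 1L %in% st
  }
  # realized leaf states among minimal labelings
  parent_of <- integer(n)
  parent_of[edge[edge[, 2] <= n, 2]] <- edge[edge[, 2] <= n, 1]
  for (tip in seq_len(n)) {
    mk <- masks[tip]
    ps <- S[parent_of[tip] - n, minimal]
    for (s in unique(ps)) {
      al <- if (s == 0L) bitwAnd(mk, 1L) > 0L else bitwAnd(mk, 2L) > 0L
      if (al) {
        # parent state allowed: unique best leaf state is the parent state
        if (s == 0L) absent[tip] <- TRUE else present[tip] <- TRUE
      } else {
        # forced to the other state
        if (s == 0L) present[tip] <- TRUE else absent[tip] <- TRUE
      }
    }
  }
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label else rep(NA_character_, m))
  states <- tibble(
    node = seq_len(n + m),
    label = labels,
    is_tip = seq_len(n + m) <= n,
    absent = absent,
    present = present
  )
  states$call <- set_call(states$absent, states$present)
  new_mpr(as.integer(L), states, tree)
}
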