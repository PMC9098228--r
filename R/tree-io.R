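#' Read a rooted tree from a Newick string or file
#'
#' A thin wrapper around [ape::read.tree()] that additionally understands
#' single-quoted labels (`'Nymphaea alba'`), validates leaf-name uniqueness,
#' and reports unbalanced parentheses with the offending position.  Branch
#' lengths and internal node labels are carried through; branch lengths are
#' ignored by every parsimony computation in this package, which is purely
#' topological.
#'
#' @param text A Newick string (must end in `;`).  Exactly one of `text` and
#'   `file` must be given.
#' @param file Path to a Newick file; if the file holds several trees, a list
#'   of trees is returned.
#' @return An object of class `phylo` (rooted; polytomies preserved), or a
#'   list of them when `file` contains several trees.
#' @seealso [write_newick()], [read_trees_nexus()]
#' @export
#' @examples
#' tr <- read_newick("((A,B),C);")
#' tr$tip.label
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    abort("supply exactly one of `text` or `file`")
  }
  if (!is.null(file)) {
    raw <- paste(readLines(file, warn = FALSE), collapse = "")
    # may contain several ;-terminated trees
    parts <- strsplit(raw, ";", fixed = TRUE)[[1]]
    parts <- parts[nzchar(trimws(parts))]
    out <- lapply(paste0(parts, ";"), function(s) read_newick(text = s))
    if (length(out) == 1L) return(out[[1L]])
    class(out) <- "multiPhylo"
    return(out)
  }
  check_newick_balance(text)
  prep <- protect_quoted_labels(text)
  phy <- ape::read.tree(text = prep$text)
  if (is.null(phy)) abort("could not parse Newick string")
  phy$tip.label <- restore_quoted_labels(phy$tip.label, prep$map)
  if (!is.null(phy$node.label)) {
    phy$node.label <- restore_quoted_labels(phy$node.label, prep$map)
  }
  dup <- phy$tip.label[duplicated(phy$tip.label)]
  if (length(dup) > 0L) {
    abort(paste0("duplicate leaf name(s): ", paste(unique(dup), collapse = ", ")))
  }
  phy
}

# Flag unbalanced parentheses with a 1-based character position.
check_newick_balance <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(paste0("unbalanced ')' at position ", i))
      }
    }
  }
  if (in_quote) abort("unterminated quoted label")
  if (depth != 0L) abort(paste0("unbalanced '(': ", depth, " unclosed"))
  invisible(TRUE)
}

protect_quoted_labels <- function(text) {
  map <- character(0)
  k <- 0L
  repeat {
    m <- regmatches(text, regexpr("'[^']*'", text))
    if (length(m) == 0L) break
    k <- k + 1L
    token <- sprintf("RSQUOT%04dX", k)
    map[token] <- substr(m, 2L, nchar(m) - 1L)
    text <- sub("'[^']*'", token, text)
  }
  list(text = text, map = map)
}

restore_quoted_labels <- function(labels, map) {
  if (length(map) == 0L) return(labels)
  hit <- labels %in% names(map)
  labels[hit] <- unname(map[labels[hit]])
  labels
}

#' Write a rooted tree as a Newick string
#'
#' Children are emitted in stored order, so output is deterministic; labels
#' containing characters outside `[A-Za-z0-9_.-]` are single-quoted.  Branch
#' lengths and internal labels are written when present.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  nd <- phylo_to_node(tree)
  out <- paste0(node_newick(nd), ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

quote_label <- function(x) {
  if (is.na(x) || !nzchar(x)) return("")
  if (grepl("[^A-Za-z0-9_.|-]", x)) paste0("'", x, "'") else x
}

node_newick <- function(nd) {
  len <- if (!is.null(nd$length) && !is.na(nd$length)) paste0(":", format(nd$length, scientific = FALSE)) else ""
  if (is.null(nd$children)) {
    return(paste0(quote_label(nd$label), len))
  }
  inner <- paste(vapply(nd$children, node_newick, character(1)), collapse = ",")
  paste0("(", inner, ")", quote_label(nd$label), len)
}

#' Read trees from a NEXUS TREES block
#'
#' Uses [ape::read.nexus()], which supports TRANSLATE tables.
#'
#' @param file Path to a NEXUS file.
#' @return A `phylo` or `multiPhylo`.
#' @export
read_trees_nexus <- function(file) {
  ape::read.nexus(file)
}

## ---- internal nested representation used by tree surgery -------------------

# A node is list(label, length, id, children = NULL | list(...)).
phylo_to_node <- function(phy) {
  n <- length(phy$tip.label)
  has_len <- !is.null(phy$edge.length)
  kids <- vector("list", n + phy$Nnode)
  elen <- rep(NA_real_, n + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    c <- phy$edge[i, 2]
    kids[[p]] <- c(kids[[p]], c)
    if (has_len) elen[c] <- phy$edge.length[i]
  }
  lab <- function(id) {
    if (id <= n) phy$tip.label[id]
    else if (!is.null(phy$node.label)) phy$node.label[id - n]
    else NA_character_
  }
  build <- function(id) {
    ch <- kids[[id]]
    if (is.null(ch)) {
      list(label = lab(id), length = elen[id], id = id, children = NULL)
    } else {
      list(label = lab(id), length = elen[id], id = id,
           children = lapply(ch, build))
    }
  }
  root <- n + 1L
  if (n == 1L && phy$Nnode == 0L) {
    return(list(label = phy$tip.label[1], length = NA_real_, id = 1L, children = NULL))
  }
  build(root)
}

node_to_phylo <- function(nd) {
  if (is.null(nd$children)) {
    # single-leaf tree: represent as root with one tip, as ape does for "(A);"
    nd <- list(label = NA_character_, length = NA_real_, children = list(nd))
  }
  tips <- character(0)
  node_labels <- character(0)
  edges <- list()
  lens <- list()
  n_tip <- count_tips(nd)
  next_internal <- n_tip + 1L
  next_tip <- 0L
  assign_walk <- function(node, parent_id) {
    if (is.null(node$children)) {
      next_tip <<- next_tip + 1L
      id <- next_tip
      tips[id] <<- if (is.na(node$label)) paste0("t", id) else node$label
    } else {
      id <- next_internal
      next_internal <<- next_internal + 1L
      node_labels[id - n_tip] <<- if (is.null(node$label) || is.na(node$label)) "" else node$label
    }
    if (!is.na(parent_id)) {
      edges[[length(edges) + 1L]] <<- c(parent_id, id)
      lens[[length(lens) + 1L]] <<-
        if (is.null(node$length)) NA_real_ else node$length
    }
    if (!is.null(node$children)) {
      for (ch in node$children) assign_walk(ch, id)
    }
    id
  }
  assign_walk(nd, NA_integer_)
  edge <- do.call(rbind, edges)
  el <- unlist(lens)
  phy <- list(edge = edge, tip.label = tips,
              Nnode = next_internal - 1L - n_tip)
  if (any(!is.na(el))) phy$edge.length <- el
  if (any(nzchar(node_labels))) phy$node.label <- node_labels
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

count_tips <- function(nd) {
  if (is.null(nd$children)) return(1L)
  sum(vapply(nd$children, count_tips, integer(1)))
}

## ---- clade addressing ------------------------------------------------------

#' Most recent common ancestor of a set of leaves
#'
#' @param tree A `phylo`.
#' @param taxa Character vector of leaf names (a single name yields that leaf).
#' @return Node id in `tree`'s numbering.
#' @export
tree_mrca <- function(tree, taxa) {
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss) > 0L) {
    abort(paste0("unknown leaf name(s): ", paste(miss, collapse = ", ")))
  }
  if (length(taxa) == 0L) abort("empty taxon set")
  idx <- match(taxa, tree$tip.label)
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

#' Resolve a clade reference to a node id
#'
#' A clade reference is either a single internal-node label or a set of leaf
#' names (resolved to their MRCA); a single leaf name resolves to that leaf.
#' A numeric node id passes through unchanged.
#'
#' @inheritParams tree_mrca
#' @param clade Internal node label, leaf-name vector, or node id.
#' @return Node id.
#' @export
resolve_clade <- function(tree, clade) {
  if (is.numeric(clade)) {
    stopifnot(length(clade) == 1L)
    return(as.integer(clade))
  }
  if (length(clade) == 1L && !is.null(tree$node.label) &&
      clade %in% tree$node.label && !(clade %in% tree$tip.label)) {
    return(length(tree$tip.label) + match(clade, tree$node.label))
  }
  tree_mrca(tree, clade)
}

#' Leaf names descending from a node
#'
#' @inheritParams tree_mrca
#' @param node Node id.
#' @return Character vector of leaf names under `node` (the leaf itself for a
#'   tip id).
#' @export
clade_tips <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  acc <- character(0)
  stack <- node
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v <= n) acc <- c(acc, tree$tip.label[v])
    else stack <- c(kids[[as.character(v)]], stack)
  }
  acc
}

## ---- surgery ---------------------------------------------------------------

#' Remove a clade from a rooted tree
#'
#' The subtree under the resolved clade is removed and any resulting degree-2
#' internal node is suppressed (its label dropped, its child kept), so that
#' tree lengths before and after leaf removal remain comparable.
#'
#' @inheritParams resolve_clade
#' @return A `phylo` with the clade removed.
#' @export
#' @examples
#' write_newick(prune_clade(read_newick("((A,B),C);"), "C"))
prune_clade <- function(tree, clade) {
  target <- resolve_clade(tree, clade)
  root <- length(tree$tip.label) + 1L
  if (length(tree$tip.label) == 1L) abort("cannot prune: tree has a single leaf")
  if (target == root) abort("cannot prune the root")
  nd <- phylo_to_node(tree)
  pruned <- drop_node(nd, target)
  if (is.null(pruned)) abort("pruning removed the whole tree")
  node_to_phylo(suppress_singles(pruned))
}

drop_node <- function(nd, target) {
  if (!is.null(nd$id) && nd$id == target) return(NULL)
  if (is.null(nd$children)) return(nd)
  kept <- Filter(Negate(is.null), lapply(nd$children, drop_node, target = target))
  if (length(kept) == 0L) return(NULL)
  nd$children <- kept
  nd
}

suppress_singles <- function(nd) {
  if (is.null(nd$children)) return(nd)
  nd$children <- lapply(nd$children, suppress_singles)
  while (!is.null(nd$children) && length(nd$children) == 1L) {
    only <- nd$children[[1L]]
    # merge: keep the child's label; sum lengths where both known
    if (!is.null(nd$length) && !is.na(nd$length) &&
        !is.null(only$length) && !is.na(only$length)) {
      only$length <- only$length + nd$length
    } else if (!is.null(nd$length) && !is.na(nd$length) &&
               (is.null(only$length) || is.na(only$length))) {
      only$length <- nd$length
    }
    only$id <- nd$id
    nd <- only
    if (is.null(nd$children)) break
  }
  nd
}

#' Graft a subtree as sister to a clade
#'
#' A new internal node is created on the edge above the resolved target; its
#' children are the target clade and the grafted subtree, in that order.  The
#' new node is the *stem node* of the grafted subtree and is reported
#' alongside the tree.  Grafting with the root as target creates a new root
#' whose children are the old root and the subtree.
#'
#' @inheritParams resolve_clade
#' @param subtree A `phylo`, or a single taxon name (grafted as one leaf).
#' @return A list with elements `tree` (the enlarged `phylo`) and `stem_node`
#'   (node id of the graft-created node in the new tree's numbering).
#' @export
#' @examples
#' g <- graft_sister(read_newick("((A,B),C);"), "X", c("A", "B"))
#' write_newick(g$tree)
graft_sister <- function(tree, subtree, target) {
  if (is.character(subtree) && length(subtree) == 1L) {
    sub_nd <- list(label = subtree, length = NA_real_, children = NULL)
    sub_tips <- subtree
  } else {
    stopifnot(inherits(subtree, "phylo"))
    sub_nd <- phylo_to_node(subtree)
    sub_nd <- strip_ids(sub_nd)
    sub_tips <- subtree$tip.label
  }
  clash <- intersect(sub_tips, tree$tip.label)
  if (length(clash) > 0L) {
    abort(paste0("leaf name collision: ", paste(clash, collapse = ", ")))
  }
  tgt <- resolve_clade(tree, target)
  tgt_tips <- clade_tips(tree, tgt)
  nd <- phylo_to_node(tree)
  root_id <- length(tree$tip.label) + 1L
  if (length(tree$tip.label) == 1L) root_id <- nd$id
  if (tgt == root_id || (length(tree$tip.label) == 1L && tgt == 1L && is.null(nd$children))) {
    new_nd <- list(label = NA_character_, length = NA_real_,
                   children = list(nd, sub_nd))
  } else {
    new_nd <- insert_sister(nd, tgt, sub_nd)
  }
  out <- node_to_phylo(suppress_singles(new_nd))
  stem <- tree_mrca(out, c(sub_tips[1L], tgt_tips[1L]))
  list(tree = out, stem_node = stem)
}

strip_ids <- function(nd) {
  nd$id <- NULL
  if (!is.null(nd$children)) nd$children <- lapply(nd$children, strip_ids)
  nd
}

insert_sister <- function(nd, target, sub_nd) {
  if (!is.null(nd$id) && nd$id == target) {
    return(list(label = NA_character_, length = NA_real_,
                children = list(nd, sub_nd)))
  }
  if (is.null(nd$children)) return(nd)
  nd$children <- lapply(nd$children, insert_sister, target = target, sub_nd = sub_nd)
  nd
}

# Replace the subtree rooted at `target` (often a placeholder leaf) with
# another nested-node subtree.  Internal; used when filling backbone templates.
replace_node <- function(nd, target, sub_nd) {
  if (!is.null(nd$id) && nd$id == target) return(sub_nd)
  if (is.null(nd$children)) return(nd)
  nd$children <- lapply(nd$children, replace_node, target = target, sub_nd = sub_nd)
  nd
}

## ---- isomorphism -----------------------------------------------------------

canonical_form <- function(nd) {
  if (is.null(nd$children)) return(nd$label)
  inner <- sort(vapply(nd$children, canonical_form, character(1)))
  paste0("(", paste(inner, collapse = ","), ")")
}

#' Test two rooted trees for isomorphism
#'
#' Order-insensitive comparison of rooted topology over leaf names; branch
#' lengths and internal labels are ignored.
#'
#' @param a,b `phylo` objects.
#' @return Logical.
#' @export
tree_isomorphic <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  identical(canonical_form(phylo_to_node(a)), canonical_form(phylo_to_node(b)))
}

#' Check that a list of trees is pairwise non-isomorphic
#'
#' @param trees List of `phylo` objects over the same leaf set.
#' @return A list with `distinct` (logical) and `duplicates` (tibble of pair
#'   indices, empty when distinct).
#' @export
trees_pairwise_distinct <- function(trees) {
  if (length(trees) == 0L) abort("no trees supplied")
  leaves <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), leaves)) {
      abort(paste0("tree ", i, " has a differing leaf set"))
    }
  }
  keys <- vapply(trees, function(t) canonical_form(phylo_to_node(t)), character(1))
  dup_idx <- which(duplicated(keys))
  dups <- tibble(
    first = match(keys[dup_idx], keys),
    second = dup_idx
  )
  list(distinct = length(dup_idx) == 0L, duplicates = dups)
}
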