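# Fixtures are generated in code; the oracles here are written independently
# of the package's Sankoff engine (they only use ape's tree bookkeeping).

# random rooted tree newick over given labels; k-furcations up to `max_split`
rand_tree_newick <- function(labels, max_split = 3L) {
  if (length(labels) == 1L) return(labels)
  k <- min(length(labels), sample.int(max_split - 1L, 1L) + 1L)
  groups <- split(sample(labels), sort(rep_len(seq_len(k), length(labels))))
  inner <- vapply(groups, rand_tree_newick, character(1), max_split = max_split)
  paste0("(", paste(inner, collapse = ","), ")")
}

rand_tree <- function(n, max_split = 3L) {
  read_newick(paste0(rand_tree_newick(paste0("t", seq_len(n)), max_split), ";"))
}

# random character column with missing and (implicitly polymorphic) uncertain
rand_column <- function(tree, p_uncertain = 0.2) {
  states <- sample(c("absent", "present"), length(tree$tip.label), replace = TRUE)
  unc <- runif(length(states)) < p_uncertain
  states[unc] <- "uncertain"
  tibble::tibble(taxon = tree$tip.label, state = states)
}

# independent Fitch pass for fully resolved trees: counts set-intersection
# failures incrementally over the postorder edge list
fitch_failures <- function(tree, column) {
  mask_of <- c(absent = 1L, present = 2L, uncertain = 3L)
  masks <- stats::setNames(mask_of[column$state], column$taxon)
  n <- length(tree$tip.label)
  sets <- integer(n + tree$Nnode)
  sets[seq_len(n)] <- masks[tree$tip.label]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  fails <- 0L
  for (i in seq_len(nrow(po))) {
    p <- po[i, 1]; ch <- po[i, 2]
    if (sets[p] == 0L) {
      sets[p] <- sets[ch]
    } else {
      inter <- bitwAnd(sets[p], sets[ch])
      if (inter > 0L) sets[p] <- inter
      else {
        sets[p] <- bitwOr(sets[p], sets[ch])
        fails <- fails + 1L
      }
    }
  }
  fails
}

# ancestor set of a node by walking parent pointers
ancestors_of <- function(tree, node) {
  parent <- integer(length(tree$tip.label) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  out <- integer(0)
  v <- node
  while (parent[v] != 0L) {
    out <- c(out, parent[v])
    v <- parent[v]
  }
  c(node, out)
}

expect_same_mpr <- function(a, b) {
  expect_identical(a$tree_length, b$tree_length)
  sa <- a$states[order(a$states$node), ]
  sb <- b$states[order(b$states$node), ]
  expect_identical(sa$absent, sb$absent)
  expect_identical(sa$present, sb$present)
}

exemplar <- NULL
get_exemplar <- function() {
  if (is.null(exemplar)) exemplar <<- build_exemplar()
  exemplar
}
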