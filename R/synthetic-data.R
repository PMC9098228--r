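#' Configuration for the synthetic-data generators
#'
#' The generators emulate, at desk scale, the statistical structure the
#' sweep assumes in real data: a clade-structured binary character on a
#' rooted tree, with controlled per-clade state frequencies, a tunable
#' fraction of missing cells, and designated rogue terminals.  Every output
#' is a pure function of the configuration (seeds are mandatory; no global
#' random state is consumed).
#'
#' @param n_leaves Number of leaves.
#' @param seed Integer seed (required).
#' @param clade_spec Optional tibble/data frame with columns `clade`, `size`
#'   and `freq` (present-state frequency in `[0, 1]`); sizes must sum to
#'   `n_leaves` and each named clade is generated monophyletic.
#' @param missing_fraction Fraction of leaves masked to the two-state
#'   (uncertain) set, in `[0, 1]`.
#' @param flip_rate Per-edge probability of a state change under the
#'   `markov` model, in `[0, 0.5]`.
#' @param model `"markov"` (symmetric per-edge flips from a root state; the
#'   default) or `"frequency"` (leaf states i.i.d. per clade at the
#'   clade's `freq`; no tree signal).
#' @param root_state Optional fixed root state (`"absent"`/`"present"`);
#'   drawn uniformly when `NULL`.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_leaves, seed, clade_spec = NULL,
                              missing_fraction = 0, flip_rate = 0.05,
                              model = c("markov", "frequency"),
                              root_state = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(n_leaves), n_leaves >= 1,
            is.numeric(seed), length(seed) == 1L,
            missing_fraction >= 0, missing_fraction <= 1,
            flip_rate >= 0, flip_rate <= 0.5)
  if (!is.null(clade_spec)) {
    clade_spec <- as_tibble(clade_spec)
    stopifnot(all(c("clade", "size", "freq") %in% names(clade_spec)))
    if (sum(clade_spec$size) != n_leaves) {
      abort("clade sizes must sum to n_leaves")
    }
    if (any(clade_spec$freq < 0 | clade_spec$freq > 1)) {
      abort("clade frequencies must lie in [0, 1]")
    }
    if (any(clade_spec$size < 1)) abort("clade sizes must be >= 1")
  }
  if (!is.null(root_state)) stopifnot(root_state %in% c("absent", "present"))
  structure(list(n_leaves = as.integer(n_leaves), seed = as.integer(seed),
                 clade_spec = clade_spec, missing_fraction = missing_fraction,
                 flip_rate = flip_rate, model = model, root_state = root_state),
            class = "simulation_config")
}

# random fully resolved rooted subtree over given leaf labels (nested rep)
random_subtree <- function(labels) {
  nodes <- lapply(labels, function(l) list(label = l, length = NA_real_, children = NULL))
  while (length(nodes) > 1L) {
    pick <- sample.int(length(nodes), 2L)
    joined <- list(label = NA_character_, length = NA_real_,
                   children = nodes[pick])
    nodes <- c(nodes[-pick], list(joined))
  }
  nodes[[1L]]
}

#' Simulate a rooted tree
#'
#' A Yule-type construction by recursive random joins.  When a `clade_spec`
#' is present, each named clade is generated as a monophyletic block (its
#' root carries the clade name as a node label) and the blocks are joined at
#' the top; otherwise leaves `t1..tn` are joined freely.
#'
#' @param config A [simulation_config()].
#' @return A fully resolved rooted `phylo`, reproducible bit-for-bit from
#'   the configuration.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    if (is.null(config$clade_spec)) {
      nd <- random_subtree(paste0("t", seq_len(config$n_leaves)))
    } else {
      blocks <- lapply(seq_len(nrow(config$clade_spec)), function(i) {
        cl <- config$clade_spec[i, ]
        sub <- random_subtree(paste0(cl$clade, "_", seq_len(cl$size)))
        sub$label <- cl$clade
        sub
      })
      nd <- blocks[[1L]]
      if (length(blocks) > 1L) {
        while (length(blocks) > 1L) {
          pick <- sample.int(length(blocks), 2L)
          joined <- list(label = NA_character_, length = NA_real_,
                         children = blocks[pick])
          blocks <- c(blocks[-pick], list(joined))
        }
        nd <- blocks[[1L]]
      }
    }
    node_to_phylo(nd)
  })
}

#' Simulate a binary character on a tree
#'
#' Under the `markov` model the root state is drawn (or fixed), every edge
#' flips the state independently with probability `flip_rate`, and
#' `missing_fraction` of the leaves are then masked to the uncertain set;
#' the true internal states and the realized number of changes are returned
#' so recovery can be scored.  Under the `frequency` model leaf states are
#' i.i.d. within clades at the clade frequency and no truth is defined for
#' internal nodes.
#'
#' @param tree A rooted `phylo` (typically from [simulate_tree()]).
#' @param config A [simulation_config()].
#' @param seed Seed for the character simulation; defaults to
#'   `config$seed + 1L` so tree and character draws are decoupled.
#' @return List: `column` (tibble `taxon`/`state`), `true_states` (character
#'   vector over all nodes, `NA` under the frequency model), `n_changes`
#'   (realized flips; `NA` under the frequency model).
#' @export
simulate_character <- function(tree, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "simulation_config"), inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  withr::with_seed(seed, {
    if (config$model == "markov") {
      states <- integer(N)
      root <- n + 1L
      states[root] <- if (is.null(config$root_state)) {
        stats::rbinom(1L, 1L, 0.5)
      } else as.integer(config$root_state == "present")
      edge <- ape::reorder.phylo(tree, "cladewise")$edge
      flips <- stats::rbinom(nrow(edge), 1L, config$flip_rate)
      for (i in seq_len(nrow(edge))) {
        states[edge[i, 2]] <- if (flips[i] == 1L) 1L - states[edge[i, 1]] else states[edge[i, 1]]
      }
      leaf_state <- ifelse(states[seq_len(n)] == 1L, "present", "absent")
      n_changes <- sum(flips)
      true_states <- ifelse(states == 1L, "present", "absent")
    } else {
      spec <- config$clade_spec
      if (is.null(spec)) abort("frequency model needs a clade_spec")
      clade_of <- sub("_[0-9]+$", "", tree$tip.label)
      freq <- stats::setNames(spec$freq, spec$clade)
      if (any(!clade_of %in% names(freq))) {
        abort("tree leaves do not follow the clade naming of the clade_spec")
      }
      leaf_state <- ifelse(stats::runif(n) < freq[clade_of], "present", "absent")
      true_states <- rep(NA_character_, N)
      n_changes <- NA_integer_
    }
    masked <- stats::runif(n) < config$missing_fraction
    leaf_state[masked] <- "uncertain"
    list(
      column = tibble(taxon = tree$tip.label, state = unname(leaf_state)),
      true_states = true_states,
      n_changes = n_changes
    )
  })
}

#' Load the packaged exemplar fixture
#'
#' A ~38-taxon exemplar of the angiosperm-wide analysis: a scaffold tree with
#' named representatives of every clade the topology space addresses
#' (eudicot families including Papaveraceae and other Ranunculales, monocot
#' families including Araceae, Tofieldiaceae and other Alismatales,
#' magnoliids, Chloranthaceae genera, Nymphaeales with *Nuphar* and
#' Cabombaceae, Amborella, and *Ceratophyllum*), plus per-taxon fusion
#' records encoded in a human-editable CSV.  The records follow published
#' clade-level annotations of carpel-fusion types where those are documented
#' and are otherwise editable placeholders: the fixture's job is to exercise
#' every pipeline code path (it includes congenital-only, postgenital-only,
#' both, none, unknown and inapplicable records, and *Ceratophyllum* is
#' scored `?`), not to reproduce the full 792-species analysis.
#'
#' @return List: `scaffold` (`phylo`), `records` (fusion tibble),
#'   `clade_map` (tibble `taxon`/`clade`), `templates` (backbone list).
#' @export
build_exemplar <- function() {
  dir <- system.file("extdata", package = "roguestate")
  csv <- file.path(dir, "exemplar_taxa.csv")
  nwk <- file.path(dir, "exemplar_scaffold.nwk")
  tab <- as_tibble(utils::read.csv(csv, stringsAsFactors = FALSE))
  records <- fusion_records(tab[, c("taxon", "fusion_any", "fusion_type")])
  clade_map <- tab[, c("taxon", "clade")]
  scaffold <- read_newick(file = nwk)
  templates <- backbone_templates()
  check_clade_map(clade_map, scaffold)
  list(scaffold = scaffold, records = records, clade_map = clade_map,
       templates = templates)
}
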