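#' Enumerate the 96-point topology space
#'
#' The space is the Cartesian product of three backbone hypotheses for the
#' relationships among the species-rich mesangiosperm clades (JM, 1KP, DE:
#' the three rooted resolutions of eudicots/monocots/magnoliids) with all
#' candidate placements of four phylogenetically unstable taxa: four
#' positions for *Ceratophyllum*, two for *Nuphar* within Nymphaeales, two
#' for *Euptelea* at the root of Ranunculales and two resolutions of the root
#' of Alismatales (Araceae-first vs Tofieldiaceae-first).  3 x 4 x 2 x 2 x 2
#' = 96 recipes, ordered backbone-major, then *Ceratophyllum*, *Nuphar*,
#' *Euptelea*, Alismatales.
#'
#' @return A tibble of 96 rows with columns `backbone`, `ceratophyllum`,
#'   `nuphar`, `euptelea`, `alismatales_root`.
#' @export
enumerate_recipes <- function() {
  tidyr::expand_grid(
    backbone = c("JM", "1KP", "DE"),
    ceratophyllum = c("sister_chloranthaceae", "sister_eudicots",
                      "sister_monocots", "sister_all_other_mesangiosperms"),
    nuphar = c("sister_nymphaeoideae", "sister_cabombaceae"),
    euptelea = c("sister_other_ranunculales", "sister_papaveraceae"),
    alismatales_root = c("araceae_first", "tofieldiaceae_first")
  )
}

#' Load backbone templates
#'
#' Templates are editable Newick files over four placeholder leaves
#' (`EUDICOTS`, `MONOCOTS`, `MAGNOLIIDS`, `CHLORANTHACEAE`) giving the rooted
#' arrangement of the mesangiosperm crown under each hypothesis.  The
#' packaged defaults put Chloranthaceae sister to magnoliids in all three
#' backbones and realize the three possible resolutions of
#' eudicots/monocots/magnoliids; users with a preferred reading of the
#' published topologies can point `dir` at their own files.
#'
#' @param dir Directory of `<id>.nwk` files; defaults to the packaged set.
#' @return Named list of `phylo` templates (names are backbone ids).
#' @export
backbone_templates <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "backbones", package = "roguestate")
  }
  files <- list.files(dir, pattern = "\\.nwk$", full.names = TRUE)
  if (length(files) == 0L) abort(paste0("no .nwk templates in ", dir))
  ids <- sub("\\.nwk$", "", basename(files))
  ids <- sub("^onekp$", "1KP", ids)
  ids <- toupper(ids)
  out <- stats::setNames(lapply(files, function(f) read_newick(file = f)), ids)
  ph <- c("EUDICOTS", "MONOCOTS", "MAGNOLIIDS", "CHLORANTHACEAE")
  for (id in names(out)) {
    miss <- setdiff(ph, out[[id]]$tip.label)
    if (length(miss) > 0L) {
      abort(paste0("template ", id, " lacks placeholder(s): ",
                   paste(miss, collapse = ", ")))
    }
  }
  out
}

# clade-map helpers ----------------------------------------------------------

rogue_clades <- c("rogue_ceratophyllum", "rogue_nuphar", "rogue_euptelea",
                  "rogue_tofieldiaceae")

map_tips <- function(clade_map, clades) {
  clade_map$taxon[clade_map$clade %in% clades]
}

major_clade_tips <- function(clade_map) {
  list(
    EUDICOTS = map_tips(clade_map, grep("^eudicots", unique(clade_map$clade), value = TRUE)),
    MONOCOTS = map_tips(clade_map, grep("^monocots", unique(clade_map$clade), value = TRUE)),
    MAGNOLIIDS = map_tips(clade_map, "magnoliids"),
    CHLORANTHACEAE = map_tips(clade_map, "chloranthaceae")
  )
}

check_clade_map <- function(clade_map, scaffold) {
  stopifnot(all(c("taxon", "clade") %in% names(clade_map)))
  miss <- setdiff(clade_map$taxon, scaffold$tip.label)
  if (length(miss) > 0L) {
    abort(paste0("clade map taxa absent from scaffold: ", paste(miss, collapse = ", ")))
  }
  un <- setdiff(scaffold$tip.label, clade_map$taxon)
  if (length(un) > 0L) {
    abort(paste0("scaffold taxa missing from clade map: ", paste(un, collapse = ", ")))
  }
  need <- c("chloranthaceae", "magnoliids", "nymphaeoideae", "cabombaceae",
            "monocots_araceae", "monocots_other_alismatales",
            "eudicots_papaveraceae", "eudicots_other_ranunculales",
            rogue_clades)
  absent <- need[!vapply(need, function(cl) any(clade_map$clade == cl), logical(1))]
  if (length(absent) > 0L) {
    abort(paste0("clade map lacks required clade(s): ", paste(absent, collapse = ", ")))
  }
  major <- major_clade_tips(clade_map)
  empty <- names(major)[vapply(major, length, integer(1)) == 0L]
  if (length(empty) > 0L) {
    abort(paste0("no taxa mapped to: ", paste(empty, collapse = ", ")))
  }
  invisible(clade_map)
}

# extract the subtree spanned by `tips`, which must be monophyletic in `tree`
extract_clade_subtree <- function(tree, tips, clade_name) {
  node <- tree_mrca(tree, tips)
  got <- clade_tips(tree, node)
  if (!setequal(got, tips)) {
    abort(paste0("clade ", clade_name, " is not monophyletic in the scaffold (MRCA also spans: ",
                 paste(setdiff(got, tips), collapse = ", "), ")"))
  }
  nd <- phylo_to_node(tree)
  sub <- find_node(nd, node)
  sub <- strip_ids(sub)
  sub$length <- NA_real_
  sub
}

find_node <- function(nd, id) {
  if (!is.null(nd$id) && nd$id == id) return(nd)
  if (is.null(nd$children)) return(NULL)
  for (ch in nd$children) {
    hit <- find_node(ch, id)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Realize one topology recipe as a full tree
#'
#' Builds the analysis tree for one point of the topology space: the four
#' rogue taxa are removed from the scaffold, the mesangiosperm crown is
#' rearranged according to the backbone template (placeholders replaced by
#' the scaffold's own within-clade subtrees, so all relationships not under
#' test are retained as in the scaffold), and the rogues are regrafted at the
#' positions the recipe names — *Ceratophyllum* last, so its stem node is the
#' final graft-created node.
#'
#' @param recipe One-row data frame with the five recipe fields (see
#'   [enumerate_recipes()]).
#' @param templates Named list of backbone templates ([backbone_templates()]).
#' @param scaffold A `phylo` containing all analysis taxa, supplying
#'   within-clade resolution.
#' @param clade_map Tibble `taxon`/`clade`; clade labels follow the packaged
#'   exemplar's vocabulary (`eudicots_*`, `monocots_*`, `magnoliids`,
#'   `chloranthaceae`, `nymphaeoideae`, `cabombaceae`, ANA-grade clades, and
#'   `rogue_*` for the four unstable taxa).
#' @return List: `tree` (the realized `phylo`), `stem_node` (the
#'   *Ceratophyllum* stem node id), `crown_node` (the mesangiosperm crown
#'   node id, including *Ceratophyllum*), and `recipe`.
#' @export
realize_recipe <- function(recipe, templates, scaffold, clade_map) {
  recipe <- as_tibble(recipe)
  stopifnot(nrow(recipe) == 1L)
  check_clade_map(clade_map, scaffold)
  if (!recipe$backbone %in% names(templates)) {
    abort(paste0("no template for backbone ", recipe$backbone))
  }

  cer_tips <- map_tips(clade_map, "rogue_ceratophyllum")
  nup_tips <- map_tips(clade_map, "rogue_nuphar")
  eup_tips <- map_tips(clade_map, "rogue_euptelea")
  tof_tips <- map_tips(clade_map, "rogue_tofieldiaceae")

  base <- scaffold
  for (tp in list(cer_tips, nup_tips, eup_tips, tof_tips)) {
    base <- prune_clade(base, tp)
  }

  # rearrange the mesangiosperm crown per the backbone template
  major <- major_clade_tips(clade_map)
  major <- lapply(major, function(x) setdiff(x, c(cer_tips, nup_tips, eup_tips, tof_tips)))
  tmpl <- templates[[recipe$backbone]]
  tmpl_nd <- phylo_to_node(tmpl)
  for (ph in names(major)) {
    ph_id <- match(ph, tmpl$tip.label)
    sub <- extract_clade_subtree(base, major[[ph]], ph)
    tmpl_nd <- replace_node(tmpl_nd, ph_id, sub)
  }
  tmpl_nd <- strip_ids(tmpl_nd)
  meso_tips <- unlist(major, use.names = FALSE)
  meso_node <- tree_mrca(base, meso_tips)
  if (!setequal(clade_tips(base, meso_node), meso_tips)) {
    abort("mesangiosperms are not monophyletic in the scaffold")
  }
  base_nd <- phylo_to_node(base)
  base_nd <- replace_node(base_nd, meso_node, tmpl_nd)
  tree <- node_to_phylo(strip_ids(base_nd))

  # rogue subtrees, preserving any within-rogue resolution from the scaffold
  rogue_subtree <- function(tips) {
    if (length(tips) == 1L) return(tips)
    node_to_phylo(extract_clade_subtree(scaffold, tips, "rogue clade"))
  }

  graft_target <- function(tree, what) {
    switch(what,
      nuphar_nymph = map_tips(clade_map, "nymphaeoideae"),
      nuphar_cabom = map_tips(clade_map, "cabombaceae"),
      eup_all = map_tips(clade_map, c("eudicots_papaveraceae", "eudicots_other_ranunculales")),
      eup_pap = map_tips(clade_map, "eudicots_papaveraceae"),
      tof_core = map_tips(clade_map, "monocots_other_alismatales"),
      tof_crown = map_tips(clade_map, c("monocots_araceae", "monocots_other_alismatales"))
    )
  }

  tree <- graft_sister(tree, rogue_subtree(nup_tips),
                       graft_target(tree, switch(recipe$nuphar,
                                                 sister_nymphaeoideae = "nuphar_nymph",
                                                 sister_cabombaceae = "nuphar_cabom")))$tree
  tree <- graft_sister(tree, rogue_subtree(eup_tips),
                       graft_target(tree, switch(recipe$euptelea,
                                                 sister_other_ranunculales = "eup_all",
                                                 sister_papaveraceae = "eup_pap")))$tree
  tree <- graft_sister(tree, rogue_subtree(tof_tips),
                       graft_target(tree, switch(recipe$alismatales_root,
                                                 araceae_first = "tof_core",
                                                 tofieldiaceae_first = "tof_crown")))$tree

  # mesangiosperm tips after regrafting Euptelea and Tofieldiaceae
  # (Nuphar sits in Nymphaeales, outside mesangiosperms)
  meso_all <- c(meso_tips, eup_tips, tof_tips)
  cer_target <- switch(recipe$ceratophyllum,
    sister_chloranthaceae = map_tips(clade_map, "chloranthaceae"),
    sister_eudicots = c(major$EUDICOTS, eup_tips),
    sister_monocots = c(major$MONOCOTS, tof_tips),
    sister_all_other_mesangiosperms = meso_all
  )
  g <- graft_sister(tree, rogue_subtree(cer_tips), cer_target)
  tree <- g$tree
  stem <- g$stem_node
  crown <- tree_mrca(tree, c(meso_all, cer_tips))
  list(tree = tree, stem_node = stem, crown_node = crown, recipe = recipe)
}

#' Realize every recipe of the topology space
#'
#' @param recipes Tibble of recipes (defaults to [enumerate_recipes()]).
#' @inheritParams realize_recipe
#' @return List of realizations (see [realize_recipe()]), in recipe order.
#' @export
realize_all <- function(templates, scaffold, clade_map,
                        recipes = enumerate_recipes()) {
  lapply(seq_len(nrow(recipes)), function(i) {
    realize_recipe(recipes[i, ], templates, scaffold, clade_map)
  })
}
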