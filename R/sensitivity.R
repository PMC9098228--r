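#' @name sensitivity
#' @title Reconstruction sweeps over the topology space
#'
#' @description
#' Two reconstruction strategies are swept over all 96 topologies and both
#' character codings.  Strategy 1 leaves *Ceratophyllum* scored as unknown
#' and records the MPR call at its stem node — the node from which the genus
#' diverges — asking whether phylogenetic context by itself pins down the
#' ancestral gynoecium of the *Ceratophyllum* lineage.  Strategy 2 records
#' the MPR call at the mesangiosperm crown node under both interpretations of
#' the *Ceratophyllum* gynoecium (unknown vs syncarpous/pseudomonomerous),
#' asking how sensitive the deeper reconstruction is to rescoring one taxon.
NULL

focal_call <- function(mpr, node) {
  s <- mpr$states[mpr$states$node == node, ]
  s$call
}

ceratophyllum_taxa <- function(clade_map) {
  map_tips(clade_map, "rogue_ceratophyllum")
}

run_sweep <- function(records, templates, scaffold, clade_map,
                      focal = c("ceratophyllum_stem", "mesangiosperm_crown"),
                      scorings, codings = c("any_fusion", "congenital_only")) {
  focal <- match.arg(focal)
  records <- fusion_records(records)
  recipes <- enumerate_recipes()
  realized <- realize_all(templates, scaffold, clade_map, recipes)
  cer <- ceratophyllum_taxa(clade_map)
  columns <- list()
  for (sc in scorings) {
    ov <- stats::setNames(
      rep(if (sc == "fused") "present" else "uncertain", length(cer)), cer)
    for (cd in codings) {
      columns[[paste(sc, cd, sep = ".")]] <-
        apply_coding(records, coding_scheme(cd, overrides = as.list(ov)))
    }
  }
  grid <- tidyr::expand_grid(i = seq_len(nrow(recipes)),
                             ceratophyllum_scoring = scorings,
                             coding = codings)
  grid$call <- pmap(grid, function(i, ceratophyllum_scoring, coding) {
    r <- realized[[i]]
    node <- if (focal == "ceratophyllum_stem") r$stem_node else r$crown_node
    focal_call(mpr_sets(r$tree, columns[[paste(ceratophyllum_scoring, coding, sep = ".")]]),
               node)
  }) |> unlist()
  out <- dplyr::bind_cols(recipes[grid$i, ],
                          grid[, c("ceratophyllum_scoring", "coding", "call")])
  structure(out,
            class = c("sensitivity_grid", class(out)),
            focal = focal)
}

#' Strategy 1: stem-node reconstruction with *Ceratophyllum* unknown
#'
#' For each of the 96 recipes and both codings, reconstructs the character
#' with *Ceratophyllum* scored as uncertain (an override to the two-state
#' set, which preserves the stem node's identity and — by missing-leaf
#' neutrality of unit-cost parsimony — is equivalent to deleting the leaf)
#' and records the MPR call at the *Ceratophyllum* stem node.
#'
#' @param records Fusion-record tibble covering all scaffold taxa.
#' @param templates,scaffold,clade_map See [realize_recipe()].
#' @return A `sensitivity_grid`: recipe columns plus `ceratophyllum_scoring`
#'   (always `"unknown"`), `coding`, and `call` in `P`/`A`/`U`.
#' @export
run_strategy1 <- function(records, templates, scaffold, clade_map) {
  run_sweep(records, templates, scaffold, clade_map,
            focal = "ceratophyllum_stem", scorings = "unknown")
}

#' Strategy 2: mesangiosperm crown reconstruction under both scorings
#'
#' For each recipe and coding, reconstructs the mesangiosperm crown state
#' with *Ceratophyllum* scored unknown and again scored as fused
#' (pseudomonomerous), giving the inputs of the per-backbone tally pies.
#'
#' @inheritParams run_strategy1
#' @return A `sensitivity_grid` with `ceratophyllum_scoring` in
#'   `"unknown"`/`"fused"`.
#' @export
run_strategy2 <- function(records, templates, scaffold, clade_map) {
  run_sweep(records, templates, scaffold, clade_map,
            focal = "mesangiosperm_crown", scorings = c("unknown", "fused"))
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat("<sensitivity_grid> focal node:", attr(x, "focal"), "\n")
  print(glance(x))
  invisible(x)
}

#' @rdname sensitivity
#' @param x A `sensitivity_grid`.
#' @param ... Unused.
#' @export
tidy.sensitivity_grid <- function(x, ...) {
  as_tibble(x)
}

#' @rdname sensitivity
#' @export
glance.sensitivity_grid <- function(x, ...) {
  d <- as_tibble(x)
  tallies <- d |>
    group_by(.data$ceratophyllum_scoring, .data$coding) |>
    summarise(n = n(),
              n_P = sum(.data$call == "P"),
              n_A = sum(.data$call == "A"),
              n_U = sum(.data$call == "U"),
              .groups = "drop")
  sens <- coding_sensitive(x) |>
    group_by(.data$ceratophyllum_scoring) |>
    summarise(n_sensitive = sum(.data$sensitive), .groups = "drop")
  left_join(tallies, sens, by = "ceratophyllum_scoring")
}

#' Which recipes change their call between codings?
#'
#' @param grid A `sensitivity_grid`.
#' @return Tibble: one row per recipe and scoring, the per-coding calls and a
#'   logical `sensitive`.
#' @export
coding_sensitive <- function(grid) {
  as_tibble(grid) |>
    tidyr::pivot_wider(names_from = "coding", values_from = "call",
                       names_prefix = "call_") |>
    mutate(sensitive = .data$call_any_fusion != .data$call_congenital_only)
}

recipe_cols <- c("backbone", "ceratophyllum", "nuphar", "euptelea",
                 "alismatales_root")

check_complete_grid <- function(grid, scoring) {
  d <- as_tibble(grid)
  if (!is.null(scoring)) d <- d[d$ceratophyllum_scoring == scoring, ]
  have <- distinct(d[, c(recipe_cols, "coding")])
  want <- tidyr::expand_grid(enumerate_recipes(),
                             coding = c("any_fusion", "congenital_only"))
  missing <- dplyr::anti_join(want, have, by = c(recipe_cols, "coding"))
  if (nrow(missing) > 0L) {
    abort(paste0("incomplete grid: ", nrow(missing), " missing recipe/coding entries, e.g. ",
                 paste(unlist(missing[1, ]), collapse = " / ")))
  }
  d
}

#' Render a sensitivity grid in the layout of the published summary table
#'
#' Rows are *Ceratophyllum* placement x *Nuphar* position x backbone; the
#' four columns cross the *Euptelea* and Alismatales alternatives.  Each cell
#' prints the any-fusion call and the congenital-only call as `X/Y`;
#' coding-sensitive cells are flagged with surrounding asterisks.
#'
#' @param grid A `sensitivity_grid`.
#' @param scoring Which *Ceratophyllum* scoring to render (default the
#'   grid's only one).
#' @return A tibble with columns `ceratophyllum`, `nuphar`, `backbone` and
#'   one `X/Y` column per *Euptelea*/Alismatales combination.
#' @export
render_table1 <- function(grid, scoring = NULL) {
  if (is.null(scoring)) {
    sc <- unique(grid$ceratophyllum_scoring)
    if (length(sc) > 1L) abort("grid has several scorings; pick one via `scoring`")
    scoring <- sc
  }
  d <- check_complete_grid(grid, scoring)
  wide <- coding_sensitive(d[d$ceratophyllum_scoring == scoring, ]) |>
    mutate(cell = ifelse(.data$sensitive,
                         paste0("*", .data$call_any_fusion, "/", .data$call_congenital_only, "*"),
                         paste0(.data$call_any_fusion, "/", .data$call_congenital_only)),
           column = paste(.data$euptelea, .data$alismatales_root, sep = " & ")) |>
    select(all_of(c("ceratophyllum", "nuphar", "backbone", "column", "cell"))) |>
    tidyr::pivot_wider(names_from = "column", values_from = "cell")
  arrange(wide,
          match(.data$ceratophyllum, c("sister_chloranthaceae", "sister_eudicots",
                                       "sister_monocots", "sister_all_other_mesangiosperms")),
          match(.data$nuphar, c("sister_nymphaeoideae", "sister_cabombaceae")),
          match(.data$backbone, c("JM", "1KP", "DE")))
}

#' Per-backbone tallies of crown calls (pie-chart inputs)
#'
#' For each backbone, coding and *Ceratophyllum* scoring, counts the 32
#' recipes whose focal call is fused (P), free (A) or equivocal (U).
#'
#' @param grid A strategy-2 `sensitivity_grid`.
#' @return A tibble of class `fig13_tallies` with counts `fused`, `free`,
#'   `equivocal` summing to 32 per row.
#' @export
render_fig13 <- function(grid) {
  for (sc in unique(grid$ceratophyllum_scoring)) check_complete_grid(grid, sc)
  out <- as_tibble(grid) |>
    group_by(.data$backbone, .data$coding, .data$ceratophyllum_scoring) |>
    summarise(fused = sum(.data$call == "P"),
              free = sum(.data$call == "A"),
              equivocal = sum(.data$call == "U"),
              .groups = "drop")
  class(out) <- c("fig13_tallies", class(out))
  out
}

#' @rdname render_fig13
#' @param object A `fig13_tallies` table.
#' @param ... Unused.
#' @method autoplot fig13_tallies
#' @export
autoplot.fig13_tallies <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("fused", "free", "equivocal"),
                              names_to = "condition", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = "", y = .data$n, fill = .data$condition)) +
    ggplot2::geom_col(width = 1, colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$coding, .data$ceratophyllum_scoring),
      cols = ggplot2::vars(.data$backbone)) +
    ggplot2::scale_fill_manual(values = c(fused = "#d8b365", free = "#5ab4ac", equivocal = "grey80")) +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "ancestral condition")
}

#' @rdname sensitivity
#' @param object A `sensitivity_grid`.
#' @method autoplot sensitivity_grid
#' @export
autoplot.sensitivity_grid <- function(object, ...) {
  d <- as_tibble(object)
  d$placement <- paste(d$nuphar, d$euptelea, d$alismatales_root, sep = "\n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$placement, y = .data$ceratophyllum,
                                  fill = .data$call)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$coding, .data$ceratophyllum_scoring),
      cols = ggplot2::vars(.data$backbone)) +
    ggplot2::scale_fill_manual(values = c(P = "#d8b365", A = "#5ab4ac", U = "grey80")) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1)) +
    ggplot2::labs(x = "rogue placements", y = "Ceratophyllum position",
                  fill = "MPR call")
}

#' Provenance log for a sweep
#'
#' Records MD5 hashes of the input files (when paths are given) and the
#' recipe list so a sweep can be reproduced and audited.
#'
#' @param matrix_file,scaffold_file Optional file paths to hash.
#' @param template_files Optional character vector of template paths.
#' @return JSON string.
#' @export
sweep_provenance <- function(matrix_file = NULL, scaffold_file = NULL,
                             template_files = NULL) {
  hash <- function(p) if (is.null(p)) NULL else unname(tools::md5sum(p))
  jsonlite::toJSON(list(
    matrix_md5 = hash(matrix_file),
    scaffold_md5 = hash(scaffold_file),
    template_md5 = hash(template_files),
    recipes = enumerate_recipes()
  ), auto_unbox = TRUE, null = "null", dataframe = "rows")
}
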