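#' Validate a table of carpel-fusion records
#'
#' A fusion-record table has one row per taxon and three columns:
#' `taxon`, `fusion_any` (was any carpel fusion observed:
#' `yes`/`no`/`unknown`/`inapplicable`/`polymorphic`) and `fusion_type`
#' (`congenital`/`postgenital`/`both`/`none`/`unknown`).  `inapplicable` is
#' reserved for monomerous (single-carpel) gynoecia, where a between-carpel
#' fusion character has no referent; it is treated as missing downstream but
#' kept distinct here so reports can separate `?` from `-`.
#'
#' @param records A data frame with the three columns above.
#' @return The records as a tibble, invisibly validated.
#' @export
fusion_records <- function(records) {
  records <- as_tibble(records)
  need <- c("taxon", "fusion_any", "fusion_type")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    abort(paste0("fusion records lack column(s): ", paste(miss, collapse = ", ")))
  }
  any_lv <- c("yes", "no", "unknown", "inapplicable", "polymorphic")
  type_lv <- c("congenital", "postgenital", "both", "none", "unknown")
  bad <- setdiff(unique(records$fusion_any), any_lv)
  if (length(bad) > 0L) abort(paste0("invalid fusion_any value(s): ", paste(bad, collapse = ", ")))
  bad <- setdiff(unique(records$fusion_type), type_lv)
  if (length(bad) > 0L) abort(paste0("invalid fusion_type value(s): ", paste(bad, collapse = ", ")))
  dup <- records$taxon[duplicated(records$taxon)]
  if (length(dup) > 0L) abort(paste0("duplicate taxon in records: ", paste(unique(dup), collapse = ", ")))
  viol <- records$taxon[records$fusion_any == "no" & records$fusion_type != "none"]
  if (length(viol) > 0L) {
    abort(paste0("fusion_any = 'no' requires fusion_type = 'none' for: ",
                 paste(viol, collapse = ", ")))
  }
  # coherence both ways: a determinate fusion type implies observed fusion,
  # and observed fusion excludes type 'none'.  Without this, the narrow
  # coding could score taxa as fused that the broad coding does not.
  viol <- records$taxon[records$fusion_any != "yes" &
                          records$fusion_type %in% c("congenital", "postgenital", "both")]
  if (length(viol) > 0L) {
    abort(paste0("a determinate fusion_type requires fusion_any = 'yes' for: ",
                 paste(viol, collapse = ", ")))
  }
  viol <- records$taxon[records$fusion_any == "yes" & records$fusion_type == "none"]
  if (length(viol) > 0L) {
    abort(paste0("fusion_any = 'yes' contradicts fusion_type = 'none' for: ",
                 paste(viol, collapse = ", ")))
  }
  records
}

#' Read a morphological fusion matrix from NEXUS or CSV
#'
#' The CSV dialect has a header `taxon,fusion_any,fusion_type` (extra columns,
#' such as a clade map, are carried through).  A NEXUS CHARACTERS/DATA block
#' is read with [ape::read.nexus.data()]; the cell of `char_any` codes
#' presence of any carpel fusion and, when `char_congenital` is given, a
#' second binary character restricted to congenital fusion refines
#' `fusion_type`.  Cells map as: `1` present, `0` absent, `?` unknown,
#' `-` (gap) inapplicable, `{01}` polymorphic.
#'
#' @param file Path; format is sniffed (`#NEXUS` magic) unless forced.
#' @param format `"auto"`, `"csv"` or `"nexus"`.
#' @param char_any Column index of the any-fusion character in a NEXUS matrix.
#' @param char_congenital Optional column index of a congenital-only character.
#' @param symbols Named character vector mapping states to matrix symbols
#'   (defaults `absent = "0"`, `present = "1"`); the missing and gap symbols
#'   follow the file's FORMAT line via `ape`.
#' @return A fusion-record tibble (see [fusion_records()]).
#' @export
read_fusion_records <- function(file, format = c("auto", "csv", "nexus"),
                                char_any = 1L, char_congenital = NULL,
                                symbols = c(absent = "0", present = "1")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- toupper(trimws(readLines(file, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "csv"
  }
  if (format == "csv") {
    records <- utils::read.csv(file, stringsAsFactors = FALSE)
    return(fusion_records(records))
  }
  cells <- read_nexus_cells(file)
  decode <- function(x, taxon, column) {
    x <- gsub("[{}() ]", "", x)
    if (x == symbols[["present"]]) return("present")
    if (x == symbols[["absent"]]) return("absent")
    if (x == "?") return("unknown")
    if (x == "-") return("inapplicable")
    if (grepl("/", x) || nchar(x) > 1L) {
      parts <- strsplit(x, "/", fixed = TRUE)[[1]]
      if (all(parts %in% symbols)) return("polymorphic")
    }
    abort(paste0("undeclared symbol '", x, "' for taxon ", taxon,
                 ", character ", column))
  }
  taxa <- names(cells)
  any_state <- vapply(seq_along(taxa), function(i) {
    decode(cells[[i]][char_any], taxa[i], char_any)
  }, character(1))
  cong_state <- if (!is.null(char_congenital)) {
    vapply(seq_along(taxa), function(i) {
      decode(cells[[i]][char_congenital], taxa[i], char_congenital)
    }, character(1))
  } else rep(NA_character_, length(taxa))
  fusion_any <- dplyr::case_match(
    any_state,
    "present" ~ "yes", "absent" ~ "no",
    "unknown" ~ "unknown", "inapplicable" ~ "inapplicable",
    "polymorphic" ~ "polymorphic"
  )
  fusion_type <- mapply(function(a, cg) {
    if (a == "no") return("none")
    if (a != "yes") return("unknown")
    if (is.na(cg)) return("unknown")
    switch(cg,
           present = "congenital",   # congenital (possibly plus postgenital)
           absent = "postgenital",
           "unknown")
  }, fusion_any, cong_state, USE.NAMES = FALSE)
  fusion_records(tibble(taxon = taxa, fusion_any = fusion_any,
                        fusion_type = fusion_type))
}

# read.nexus.data returns a list of per-taxon character vectors with
# polymorphic cells already collapsed to "0/1".
read_nexus_cells <- function(file) {
  ape::read.nexus.data(file)
}

#' Write one or more character columns as a NEXUS DATA block
#'
#' Cells must be in `0`, `1`, `0/1` (written `{01}`), `?`, `-`.  Used for
#' round-trip fixtures and for exporting coded characters to other parsimony
#' software.
#'
#' @param cells A data frame: `taxon` column plus one column per character.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_nexus_characters <- function(cells, file) {
  stopifnot("taxon" %in% names(cells))
  chars <- setdiff(names(cells), "taxon")
  enc <- function(x) {
    vapply(x, function(v) {
      switch(v, "0" = "0", "1" = "1", "0/1" = "{01}", "?" = "?", "-" = "-",
             abort(paste0("cannot encode cell '", v, "'")))
    }, character(1))
  }
  mat <- vapply(chars, function(cn) enc(cells[[cn]]), character(nrow(cells)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(cells))
  rows <- paste(format(cells$taxon, width = max(nchar(cells$taxon)) + 2L),
                apply(mat, 1L, paste, collapse = ""))
  out <- c("#NEXUS", "BEGIN DATA;",
           sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(cells), length(chars)),
           "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=-;",
           "MATRIX", rows, ";", "END;")
  writeLines(out, file)
  invisible(file)
}

#' Define a coding scheme for the fusion character
#'
#' Two modes mirror the two ways of delimiting "syncarpy": `any_fusion`
#' scores a taxon as fused whenever any between-carpel fusion is recorded
#' (congenital or postgenital), while `congenital_only` restricts the fused
#' state to congenital fusion (syncarpy in the narrow sense), rescoring
#' taxa with purely postgenital fusion as free-carpellate.  Per-taxon
#' overrides are applied after the mode mapping and win over it; the classic
#' use is forcing *Ceratophyllum* to `present` (the pseudomonomery
#' interpretation) or leaving it `uncertain`.
#'
#' @param mode `"any_fusion"` or `"congenital_only"`.
#' @param overrides Named list/vector, taxon -> `"present"`, `"absent"` or
#'   `"uncertain"`.
#' @param note Free-text metadata (e.g. the measurement convention defining
#'   "fused", such as a united-for->5%-of-length rule).  Documentation only;
#'   never consulted by any computation.
#' @return A `coding_scheme` object.
#' @export
coding_scheme <- function(mode = c("any_fusion", "congenital_only"),
                          overrides = list(), note = NULL) {
  mode <- match.arg(mode)
  overrides <- unlist(overrides)
  if (length(overrides) > 0L) {
    bad <- setdiff(overrides, c("present", "absent", "uncertain"))
    if (length(bad) > 0L) abort(paste0("invalid override state(s): ", paste(bad, collapse = ", ")))
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      abort("overrides must be named by taxon")
    }
  }
  structure(list(mode = mode, overrides = overrides, note = note),
            class = "coding_scheme")
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat("<coding_scheme> mode:", x$mode, "\n")
  if (length(x$overrides) > 0L) {
    cat("  overrides:", paste(names(x$overrides), "->", x$overrides, collapse = "; "), "\n")
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Serialize a coding scheme to JSON (for provenance logs)
#'
#' @param scheme A [coding_scheme()].
#' @return A JSON string.
#' @export
coding_scheme_json <- function(scheme) {
  jsonlite::toJSON(list(mode = scheme$mode,
                        overrides = as.list(scheme$overrides),
                        note = scheme$note),
                   auto_unbox = TRUE, null = "null")
}

#' Apply a coding scheme to fusion records
#'
#' Produces the analysis character: a per-taxon state in `absent`, `present`
#' or `uncertain` (the two-state set).  Under `any_fusion`, `present` iff any
#' fusion was recorded; under `congenital_only`, `present` iff the fusion type
#' is congenital or both, `absent` if postgenital or none, `uncertain`
#' otherwise.  Unknown, polymorphic and inapplicable records are `uncertain`
#' (cost 0 for either state in the parsimony engine).  Overrides are applied
#' last.
#'
#' @param records A fusion-record tibble (see [fusion_records()]).
#' @param scheme A [coding_scheme()].
#' @return A tibble with columns `taxon` and `state`.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   taxon = c("A", "B"),
#'   fusion_any = c("yes", "yes"),
#'   fusion_type = c("postgenital", "congenital")
#' )
#' apply_coding(recs, coding_scheme("congenital_only"))
apply_coding <- function(records, scheme) {
  records <- fusion_records(records)
  stopifnot(inherits(scheme, "coding_scheme"))
  state <- if (scheme$mode == "any_fusion") {
    dplyr::case_match(records$fusion_any,
                      "yes" ~ "present",
                      "no" ~ "absent",
                      .default = "uncertain")
  } else {
    ifelse(records$fusion_type %in% c("congenital", "both"), "present",
           ifelse(records$fusion_type %in% c("postgenital", "none"), "absent",
                  "uncertain"))
  }
  col <- tibble(taxon = records$taxon, state = state)
  if (length(scheme$overrides) > 0L) {
    missing_taxa <- setdiff(names(scheme$overrides), col$taxon)
    if (length(missing_taxa) > 0L) {
      abort(paste0("override names absent from records: ",
                   paste(missing_taxa, collapse = ", ")))
    }
    idx <- match(names(scheme$overrides), col$taxon)
    col$state[idx] <- unname(scheme$overrides)
  }
  col
}

#' Summarise a character column
#'
#' @param column A tibble as returned by [apply_coding()].
#' @return One-row tibble with counts of absent-only, present-only and
#'   uncertain (both-state/missing) taxa; the counts sum to the taxon count.
#' @export
column_summary <- function(column) {
  stopifnot(all(c("taxon", "state") %in% names(column)))
  tibble(
    n_taxa = nrow(column),
    n_absent = sum(column$state == "absent"),
    n_present = sum(column$state == "present"),
    n_uncertain = sum(column$state == "uncertain")
  )
}
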