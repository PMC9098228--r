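all_records <- function() {
  # every coherent (fusion_any, fusion_type) combination
  combos <- tidyr::expand_grid(
    fusion_any = c("yes", "no", "unknown", "inapplicable", "polymorphic"),
    fusion_type = c("congenital", "postgenital", "both", "none", "unknown")
  )
  combos <- combos[
    !(combos$fusion_any == "no" & combos$fusion_type != "none") &
      !(combos$fusion_any != "yes" &
          combos$fusion_type %in% c("congenital", "postgenital", "both")) &
      !(combos$fusion_any == "yes" & combos$fusion_type == "none"), ]
  combos$taxon <- paste0("t", seq_len(nrow(combos)))
  combos[, c("taxon", "fusion_any", "fusion_type")]
}

test_that("record validation enforces the vocabulary and its invariant", {
  expect_s3_class(fusion_records(all_records()), "tbl_df")
  expect_error(fusion_records(tibble::tibble(taxon = "a", fusion_any = "maybe",
                                             fusion_type = "none")),
               "invalid fusion_any")
  expect_error(fusion_records(tibble::tibble(taxon = "a", fusion_any = "no",
                                             fusion_type = "congenital")),
               "fusion_type = 'none'")
  expect_error(fusion_records(rbind(all_records(), all_records()[1, ])),
               "duplicate taxon")
})

test_that("the two codings map records as documented", {
  recs <- all_records()
  any_col <- apply_coding(recs, coding_scheme("any_fusion"))
  cong_col <- apply_coding(recs, coding_scheme("congenital_only"))
  get <- function(col, fa, ft) {
    col$state[recs$fusion_any == fa & recs$fusion_type == ft]
  }
  # postgenital fusion counts as fused under any_fusion ...
  expect_equal(get(any_col, "yes", "postgenital"), "present")
  # ... but is rescored free-carpellate under congenital_only
  expect_equal(get(cong_col, "yes", "postgenital"), "absent")
  expect_equal(get(cong_col, "yes", "congenital"), "present")
  expect_equal(get(cong_col, "yes", "both"), "present")
  expect_equal(get(any_col, "no", "none"), "absent")
  expect_equal(get(any_col, "unknown", "unknown"), "uncertain")
  expect_equal(get(any_col, "inapplicable", "unknown"), "uncertain")
  expect_equal(get(any_col, "polymorphic", "unknown"), "uncertain")
  # totality: every record yields a state
  expect_false(anyNA(any_col$state))
  expect_false(anyNA(cong_col$state))
})

test_that("narrowing the coding never adds fused taxa (exhaustive)", {
  recs <- all_records()
  any_col <- apply_coding(recs, coding_scheme("any_fusion"))
  cong_col <- apply_coding(recs, coding_scheme("congenital_only"))
  p_any <- any_col$taxon[any_col$state == "present"]
  p_cong <- cong_col$taxon[cong_col$state == "present"]
  expect_true(all(p_cong %in% p_any))
  s_any <- column_summary(any_col)
  s_cong <- column_summary(cong_col)
  expect_lte(s_cong$n_present, s_any$n_present)
  expect_equal(s_any$n_absent + s_any$n_present + s_any$n_uncertain, s_any$n_taxa)
})

test_that("overrides win over the mode mapping and must name known taxa", {
  recs <- tibble::tibble(taxon = c("Ceratophyllum", "Other"),
                         fusion_any = c("unknown", "no"),
                         fusion_type = c("unknown", "none"))
  sch <- coding_scheme("any_fusion", overrides = list(Ceratophyllum = "present"))
  col <- apply_coding(recs, sch)
  expect_equal(col$state[col$taxon == "Ceratophyllum"], "present")
  bad <- coding_scheme("any_fusion", overrides = list(Nobody = "absent"))
  expect_error(apply_coding(recs, bad), "Nobody")
  expect_error(coding_scheme("any_fusion", overrides = list(A = "fused")),
               "invalid override")
  js <- jsonlite::fromJSON(coding_scheme_json(sch))
  expect_equal(js$mode, "any_fusion")
  expect_equal(js$overrides$Ceratophyllum, "present")
})

test_that("column summary counts sum to the taxon count", {
  col <- tibble::tibble(taxon = c("a", "b", "c"),
                        state = c("absent", "present", "uncertain"))
  s <- column_summary(col)
  expect_equal(unlist(s[, c("n_absent", "n_present", "n_uncertain")],
                      use.names = FALSE), c(1L, 1L, 1L))
  allmiss <- tibble::tibble(taxon = letters[1:4], state = "uncertain")
  expect_equal(column_summary(allmiss)$n_uncertain, 4L)
})

test_that("NEXUS matrices round-trip cell-for-cell", {
  cells <- tibble::tibble(
    taxon = c("Taxon_one", "Taxon_two", "Taxon_three", "Taxon_four"),
    fusion = c("1", "0", "0/1", "?"),
    extra = c("-", "1", "?", "0")
  )
  f <- withr::local_tempfile(fileext = ".nex")
  write_nexus_characters(cells, f)
  back <- ape::read.nexus.data(f)
  expect_equal(names(back), cells$taxon)
  expect_equal(vapply(back, `[`, character(1), 1L),
               stats::setNames(cells$fusion, cells$taxon))
  expect_equal(vapply(back, `[`, character(1), 2L),
               stats::setNames(cells$extra, cells$taxon))
})

test_that("fusion records load from NEXUS with the documented cell mapping", {
  cells <- tibble::tibble(
    taxon = c("Fused", "Free", "Unknown", "Mono", "Poly"),
    any_f = c("1", "0", "?", "-", "0/1"),
    cong_f = c("0", "0", "?", "-", "?")
  )
  f <- withr::local_tempfile(fileext = ".nex")
  write_nexus_characters(cells, f)
  recs <- read_fusion_records(f, char_any = 1L, char_congenital = 2L)
  expect_equal(recs$fusion_any,
               c("yes", "no", "unknown", "inapplicable", "polymorphic"))
  # any = yes with congenital char absent -> postgenital-only fusion
  expect_equal(recs$fusion_type[1], "postgenital")
  expect_equal(recs$fusion_type[2], "none")

  recs2 <- read_fusion_records(f, char_any = 1L)
  expect_equal(recs2$fusion_type[1], "unknown")
})

test_that("fusion records load from CSV and the format is sniffed", {
  df <- all_records()
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  recs <- read_fusion_records(f)
  expect_equal(recs$taxon, df$taxon)
  expect_equal(recs$fusion_type, df$fusion_type)
})

test_that("undeclared matrix symbols are reported with taxon and column", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               "DIMENSIONS NTAX=2 NCHAR=1;",
               "FORMAT DATATYPE=STANDARD SYMBOLS=\"012\" MISSING=? GAP=-;",
               "MATRIX", "Good 1", "Weird 2", ";", "END;"), f)
  expect_error(read_fusion_records(f), "Weird")
})
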