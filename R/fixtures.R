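#' Packaged data fixtures
#'
#' Four fixtures ship with the package:
#'
#' * `table1_variants` - the 17-variant genetic summary (gnomAD v2.1.1 and
#'   v4.0.0 allele/hemizygote counts and frequencies, MetaDome, REVEL,
#'   CADD, AlphaMissense, PolyPhen-2 scores).
#' * `table3_criteria` - the 12 group 2 variants with the ACMG evidence
#'   codes applied to them and the resulting classification.
#' * `wt_profiles` - wild-type biophysical profiles per channel
#'   configuration plus the beta-subunit effect components.
#' * `variant_effects` - synthetic per-variant generator perturbations.
#'
#' @param name Fixture name.
#' @return `table1_variants` and `table3_criteria` return data.frames;
#'   the JSON fixtures return nested lists.
#' @export
load_fixture <- function(name = c("table1_variants", "table3_criteria",
                                  "wt_profiles", "variant_effects")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, switch(
    name, table1_variants = ".tsv", table3_criteria = ".tsv", ".json")),
    package = "kv4class")
  if (!nzchar(path)) stop("fixture not found: ", name)
  switch(name,
    table1_variants = validate_table1(utils::read.delim(
      path, stringsAsFactors = FALSE, check.names = FALSE)),
    table3_criteria = validate_table3(utils::read.delim(
      path, stringsAsFactors = FALSE, check.names = FALSE)),
    wt_profiles = jsonlite::read_json(path, simplifyVector = TRUE),
    variant_effects = jsonlite::read_json(path, simplifyVector = FALSE))
}

validate_table1 <- function(df) {
  need <- c("individual", "cdna", "protein", "group",
            "v2_allele_count", "v2_n_hemizygotes", "v2_allele_freq",
            "v2_hemizygote_freq", "v4_allele_count", "v4_n_hemizygotes",
            "v4_allele_freq", "v4_hemizygote_freq",
            "metadome", "revel", "cadd", "alphamissense", "polyphen2")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("table1_variants fixture schema mismatch; missing: ",
         paste(missing, collapse = ", "))
  if (nrow(df) != 17L)
    stop("table1_variants must have 17 rows, found ", nrow(df))
  for (v in c("v2", "v4")) {
    ac <- df[[paste0(v, "_allele_count")]]
    nh <- df[[paste0(v, "_n_hemizygotes")]]
    if (any(ac < 0 | nh < 0)) stop("negative counts in ", v, " block")
    if (any(nh > ac)) stop("hemizygote count exceeds allele count in ", v)
  }
  in_range <- function(x, lo, hi) all(is.na(x) | (x >= lo & x <= hi))
  if (!in_range(df$revel, 0, 1) || !in_range(df$alphamissense, 0, 1) ||
      !in_range(df$polyphen2, 0, 1))
    stop("predictor score outside its documented [0, 1] range")
  if (!in_range(df$cadd, 1, 99)) stop("CADD score outside [1, 99]")
  if (!all(df$group %in% c(1L, 2L))) stop("group must be 1 or 2")
  df
}

validate_table3 <- function(df) {
  need <- c("individual", "cdna", "protein", "criteria", "classification")
  if (length(setdiff(need, names(df))))
    stop("table3_criteria fixture schema mismatch")
  if (nrow(df) != 12L)
    stop("table3_criteria must have 12 rows, found ", nrow(df))
  known <- c("PS3", "PM2_sup", "PP3", "BP4", "BS2")
  crits <- strsplit(df$criteria, ",", fixed = TRUE)
  bad <- setdiff(unlist(crits), known)
  if (length(bad)) stop("unknown ACMG codes in fixture: ",
                        paste(bad, collapse = ", "))
  classes <- c("pathogenic", "likely pathogenic", "VUS", "likely benign",
               "benign")
  if (!all(df$classification %in% classes))
    stop("unknown classification label in fixture")
  df
}

#' Look up one variant's genetic record
#'
#' @param protein Protein-level variant name, e.g. `"p.Ala202Thr"`.
#' @param table1 Optional pre-loaded fixture data.frame.
#' @return One-row data.frame.
#' @export
variant_record <- function(protein, table1 = load_fixture("table1_variants")) {
  row <- table1[table1$protein == protein, , drop = FALSE]
  if (nrow(row) != 1L) stop("variant not found in fixture: ", protein)
  row
}
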