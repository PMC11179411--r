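#' Points-based ACMG variant classification
#'
#' Supported evidence codes and their point values: PS3 +4 (strong
#' functional evidence), PM2_sup +1 (absent from hemizygotes in the
#' population database, applied at supporting strength), PP3 +1
#' (computational consensus deleterious), BP4 -1 (computational consensus
#' benign), BS2 -4 (observed hemizygous more often than compatible with
#' disease). Summed points map to classes: >= 10 pathogenic, 6-9 likely
#' pathogenic, 0-5 VUS, -6..-1 likely benign, <= -7 benign; when both
#' pathogenic and benign evidence are applied and the total stays below
#' the likely-pathogenic band, the class is forced to VUS (mixed,
#' conflicting evidence).
#'
#' @name acmg_classifier
NULL

CRITERION_POINTS <- c(PS3 = 4L, PM2_sup = 1L, PP3 = 1L, BP4 = -1L,
                      BS2 = -4L)

CLASS_LEVELS <- c("pathogenic", "likely pathogenic", "VUS",
                  "likely benign", "benign")

#' Frequency-based criteria from gnomAD hemizygote counts
#'
#' PM2_sup applies when the gnomAD v4 hemizygote count is at most
#' `pm2_max_hemi` (default 0: absent from hemizygotes); BS2 applies when
#' it is at least `bs2_min_hemi` (default 20). The two can never co-occur.
#'
#' @param record One-row data.frame in the Table-1 fixture schema (see
#'   [variant_record()]).
#' @param pm2_max_hemi,bs2_min_hemi Integer thresholds.
#' @return Character vector: subset of `c("PM2_sup", "BS2")`.
#' @export
assign_frequency_criteria <- function(record, pm2_max_hemi = 0L,
                                      bs2_min_hemi = 20L) {
  if (pm2_max_hemi >= bs2_min_hemi)
    stop("pm2_max_hemi must be below bs2_min_hemi")
  nh <- record$v4_n_hemizygotes
  if (is.null(nh) || !is.finite(nh)) {
    message("missing gnomAD v4 hemizygote count for ", record$protein,
            "; no frequency criterion assigned")
    return(character(0))
  }
  if (nh <= pm2_max_hemi) "PM2_sup"
  else if (nh >= bs2_min_hemi) "BS2"
  else character(0)
}

#' Default in-silico consensus thresholds
#' @return Nested list with `deleterious` and `benign` cutoffs per score.
#' @export
default_insilico_thresholds <- function() {
  list(deleterious = list(revel = 0.5, cadd = 25, alphamissense = 0.5,
                          polyphen2 = 0.9),
       benign = list(revel = 0.3, cadd = 20, alphamissense = 0.34,
                     polyphen2 = 0.15),
       min_calls = 3L)
}

#' Computational-evidence criteria from predictor scores
#'
#' A score calls deleterious when it meets or exceeds its deleterious
#' cutoff, benign when it falls below its benign cutoff (defaults:
#' REVEL >= 0.5 / < 0.3, CADD >= 25 / < 20, AlphaMissense >= 0.5 / < 0.34,
#' PolyPhen-2 >= 0.9 / < 0.15). PP3 applies with at least `min_calls`
#' deleterious calls, BP4 with at least `min_calls` benign calls; never
#' both. At least three of the four scores must be present.
#'
#' @param record One-row Table-1-schema data.frame.
#' @param thresholds See [default_insilico_thresholds()].
#' @return Character vector: subset of `c("PP3", "BP4")`.
#' @export
assign_insilico_criteria <- function(record,
                                     thresholds = default_insilico_thresholds()) {
  scores <- c(revel = record$revel, cadd = record$cadd,
              alphamissense = record$alphamissense,
              polyphen2 = record$polyphen2)
  present <- names(scores)[is.finite(scores)]
  if (length(present) < 3L) {
    message("fewer than 3 predictor scores for ", record$protein,
            "; no computational criterion assigned")
    return(character(0))
  }
  del <- sum(vapply(present, function(s)
    scores[[s]] >= thresholds$deleterious[[s]], logical(1)))
  ben <- sum(vapply(present, function(s)
    scores[[s]] < thresholds$benign[[s]], logical(1)))
  if (del >= thresholds$min_calls && ben >= thresholds$min_calls)
    stop("inconsistent thresholds: PP3 and BP4 both triggered")
  if (del >= thresholds$min_calls) "PP3"
  else if (ben >= thresholds$min_calls) "BP4"
  else character(0)
}

#' Combine evidence criteria into a classification
#'
#' @param criteria Character vector of applied codes (subset of the
#'   supported set).
#' @param variant_id Optional variant name carried through.
#' @return A `classification`: list with `variant_id`, `criteria`,
#'   `points` (per-criterion), `total`, `class`,
#'   `conflict_override_applied`.
#' @export
combine_points <- function(criteria, variant_id = NA_character_) {
  criteria <- unique(criteria)
  bad <- setdiff(criteria, names(CRITERION_POINTS))
  if (length(bad)) stop("unsupported criterion code(s): ",
                        paste(bad, collapse = ", "))
  pts <- CRITERION_POINTS[criteria]
  total <- sum(pts)
  cls <- if (total >= 10) "pathogenic"
  else if (total >= 6) "likely pathogenic"
  else if (total >= 0) "VUS"
  else if (total >= -6) "likely benign"
  else "benign"
  has_path <- any(pts > 0)
  has_ben <- any(pts < 0)
  override <- has_path && has_ben && total < 6 && cls != "VUS"
  if (override) cls <- "VUS"
  structure(list(variant_id = variant_id, criteria = criteria,
                 points = pts, total = as.integer(total), class = cls,
                 conflict_override_applied = override),
            class = "classification")
}

#' Classify one variant from its genetic record and PS3 flag
#'
#' @param record One-row Table-1-schema data.frame.
#' @param ps3_applied Logical: did the functional assessment reach the
#'   PS3 threshold?
#' @param pm2_max_hemi,bs2_min_hemi Frequency thresholds.
#' @param thresholds In-silico thresholds.
#' @return A `classification`.
#' @export
classify_variant <- function(record, ps3_applied,
                             pm2_max_hemi = 0L, bs2_min_hemi = 20L,
                             thresholds = default_insilico_thresholds()) {
  criteria <- c(if (isTRUE(ps3_applied)) "PS3",
                assign_frequency_criteria(record, pm2_max_hemi,
                                          bs2_min_hemi),
                assign_insilico_criteria(record, thresholds))
  combine_points(criteria, variant_id = record$protein)
}

#' Classify the group 2 cohort
#'
#' Derives the frequency and computational criteria from the Table-1-style
#' fixture and combines them with PS3 flags. In replication mode the
#' criteria are taken verbatim from the Table-3-style fixture and only the
#' points combiner is exercised.
#'
#' @param table1 Table-1-schema data.frame, default the packaged fixture.
#' @param ps3 Named logical vector of PS3 flags per protein id, or
#'   `"replication"` to take all criteria (including PS3) from `table3`.
#' @param table3 Table-3-schema data.frame (used for the variant list and
#'   in replication mode).
#' @return A `cohort_classification`: data.frame with one row per variant
#'   (`protein`, `criteria`, `total`, `class`,
#'   `conflict_override_applied`) and a `summary` attribute of class
#'   counts.
#' @export
classify_cohort <- function(table1 = load_fixture("table1_variants"),
                            ps3 = "replication",
                            table3 = load_fixture("table3_criteria")) {
  replication <- identical(ps3, "replication")
  rows <- lapply(seq_len(nrow(table3)), function(i) {
    prot <- table3$protein[i]
    if (replication) {
      crits <- strsplit(table3$criteria[i], ",", fixed = TRUE)[[1]]
      cl <- combine_points(crits, variant_id = prot)
    } else {
      if (!prot %in% names(ps3))
        stop("no PS3 flag supplied for ", prot)
      cl <- classify_variant(variant_record(prot, table1), ps3[[prot]])
    }
    data.frame(protein = prot,
               criteria = paste(sort(cl$criteria), collapse = ","),
               total = cl$total, class = cl$class,
               conflict_override_applied = cl$conflict_override_applied,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  counts <- table(factor(out$class, levels = CLASS_LEVELS))
  attr(out, "summary") <- counts
  class(out) <- c("cohort_classification", class(out))
  out
}
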