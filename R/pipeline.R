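#' Pipeline orchestration
#'
#' [run_pipeline()] ties the stages together: simulate experiments for the
#' wild type and each requested variant in every channel configuration,
#' extract per-oocyte features, build the 29-item assessment matrices,
#' score PS3, and classify (combining the genetic fixture criteria when
#' the variant has a Table-1 record, PS3 alone otherwise). All randomness
#' flows from the single root seed through fixed per-stage offsets, so a
#' run is reproducible end to end.
#'
#' @name cli_and_report
NULL

#' Default pipeline configuration
#'
#' A small demonstration cohort: wild type plus one constructed variant
#' with a single-parameter effect (doubled recovery time constant) in all
#' four configurations and one null variant. Sampling is reduced to 1 ms
#' to keep the demo under a few minutes on one CPU.
#'
#' @return A `pipeline_config` list.
#' @export
default_config <- function() {
  structure(list(
    seed = 20240520L,
    variants = c("demo.SingleParamAllConfigs", "demo.Null"),
    configurations = CONFIGURATIONS,
    n_oocytes = 6L,
    noise_sd = 0.15,
    variability = default_variability(),
    alpha = 0.05,
    ps3_threshold = 4L,
    registry_path = NULL,
    sample_interval = 1,
    outdir = NULL), class = "pipeline_config")
}

validate_config <- function(config) {
  if (is.null(config$seed) || !is.finite(config$seed))
    stop("config error: seed required")
  if (!length(config$variants)) stop("config error: no variants requested")
  if (!all(config$configurations %in% CONFIGURATIONS))
    stop("config error: unknown configuration")
  if (config$alpha <= 0 || config$alpha >= 1)
    stop("config error: alpha must lie in (0, 1)")
  if (!is.null(config$registry_path) && !file.exists(config$registry_path))
    stop("config error: registry file not found: ", config$registry_path)
  invisible(config)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file; fields as in [default_config()] (missing fields
#'   take the defaults).
#' @return A validated `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
}

pipeline_protocols <- function(dt) {
  list(IV_FAMILY = build_protocol("IV_FAMILY", list(sample_interval = dt)),
       DECAY = build_protocol("DECAY", list(sample_interval = dt)),
       RECOVERY = build_protocol("RECOVERY", list(sample_interval = dt)),
       SSI = build_protocol("SSI", list(sample_interval = dt)))
}

#' Run the full pipeline
#'
#' @param config A `pipeline_config`, see [default_config()] /
#'   [read_config()].
#' @return A `pipeline_result` list: `features` (combined feature table),
#'   `assessments` (per-variant assessment matrices), `ps3` (per-variant
#'   `ps3_result`), `classifications` (per-variant `classification`),
#'   `config`. When `config$outdir` is set, TSV/JSON artifacts and the
#'   rendered report are written there.
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  effects <- load_fixture("variant_effects")$variants
  unknown <- setdiff(config$variants, names(effects))
  if (length(unknown))
    stop("simulate stage: no variant-effect entry for ",
         paste(unknown, collapse = ", "))
  protocols <- pipeline_protocols(config$sample_interval %||% 1)
  groups <- c("WT", config$variants)
  feats <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    for (ci in seq_along(config$configurations)) {
      cf <- config$configurations[ci]
      seed_gc <- (config$seed + 1000L * gi + ci) %% .Machine$integer.max
      set <- simulate_experiment(
        wt_profile(cf),
        variant_effect = if (g == "WT") NULL else effects[[g]],
        protocol_set = protocols,
        n_oocytes = config$n_oocytes,
        variability = config$variability,
        noise_sd = config$noise_sd,
        seed = seed_gc,
        meta = list(variant = g, configuration = cf))
      feats[[length(feats) + 1L]] <- extract_features(set)
    }
  }
  features <- do.call(rbind, feats)
  registry <- default_registry(config$registry_path)
  assessments <- lapply(config$variants, function(v)
    build_assessment(features, v, registry, control = "WT",
                     alpha = config$alpha))
  names(assessments) <- config$variants
  ps3 <- lapply(assessments, score_ps3, threshold = config$ps3_threshold)
  table1 <- load_fixture("table1_variants")
  classifications <- lapply(config$variants, function(v) {
    applied <- ps3[[v]]$ps3_applied
    if (v %in% table1$protein)
      classify_variant(variant_record(v, table1), applied)
    else
      combine_points(if (applied) "PS3" else character(0), variant_id = v)
  })
  names(classifications) <- config$variants
  result <- structure(list(features = features, assessments = assessments,
                           ps3 = ps3, classifications = classifications,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_artifacts(result)
  result
}

write_pipeline_artifacts <- function(result) {
  dir.create(result$config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(result$config$outdir, ...)
  utils::write.table(result$features, out("features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  am <- do.call(rbind, lapply(names(result$assessments), function(v) {
    m <- result$assessments[[v]]
    cbind(variant = v, as.data.frame(m))
  }))
  utils::write.table(am, out("assessment_matrix.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(result$ps3, unclass), out("ps3.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cohort <- cohort_table(result)
  utils::write.table(cohort, out("cohort.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  writeLines(render_report(result), out("report.md"))
  jsonlite::write_json(report_json(result), out("report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(result$config$outdir)
}

cohort_table <- function(result) {
  do.call(rbind, lapply(names(result$classifications), function(v) {
    cl <- result$classifications[[v]]
    data.frame(variant = v,
               altered_count = result$ps3[[v]]$altered_count,
               ps3_applied = result$ps3[[v]]$ps3_applied,
               criteria = paste(sort(cl$criteria), collapse = ","),
               total_points = cl$total, class = cl$class,
               stringsAsFactors = FALSE)
  }))
}

report_json <- function(result) {
  list(seed = result$config$seed,
       n_oocytes = result$config$n_oocytes,
       variants = lapply(names(result$classifications), function(v)
         list(variant = v,
              altered_count = result$ps3[[v]]$altered_count,
              ps3_applied = result$ps3[[v]]$ps3_applied,
              criteria = result$classifications[[v]]$criteria,
              total_points = result$classifications[[v]]$total,
              class = result$classifications[[v]]$class)))
}

#' Render a human-readable pipeline report
#'
#' @param result A `pipeline_result` (or a `cohort_classification` from
#'   [classify_cohort()]).
#' @return Character vector of markdown lines.
#' @export
render_report <- function(result) {
  if (inherits(result, "cohort_classification")) {
    if (!nrow(result)) stop("no variants to report")
    lines <- c("# ACMG classification", "",
               "| variant | criteria | points | class |",
               "|---|---|---|---|",
               sprintf("| %s | %s | %d | %s |", result$protein,
                       result$criteria, result$total, result$class),
               "",
               paste0("Class counts: ",
                      paste(sprintf("%s = %d",
                                    names(attr(result, "summary")),
                                    as.integer(attr(result, "summary"))),
                            collapse = ", ")))
    return(lines)
  }
  if (!inherits(result, "pipeline_result")) stop("unsupported report input")
  cohort <- cohort_table(result)
  if (!nrow(cohort)) stop("no variants to report")
  feats <- result$features
  num <- vapply(feats, is.numeric, logical(1)) &
    !(names(feats) %in% c("oocyte"))
  summ <- stats::aggregate(feats[num],
                           by = list(variant = feats$variant,
                                     configuration = feats$configuration),
                           FUN = function(x) mean(x, na.rm = TRUE))
  fmt_row <- function(df) apply(df, 1, function(r)
    paste0("| ", paste(r, collapse = " | "), " |"))
  c(sprintf("# Kv4.1 functional assessment pipeline (seed %d)",
            as.integer(result$config$seed)),
    "",
    "## Group feature means",
    "",
    paste0("| ", paste(names(summ), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(summ)), collapse = "|"), "|"),
    fmt_row(cbind(summ[1:2], round(summ[-(1:2)], 3))),
    "",
    "## Assessment and classification",
    "",
    paste0("| ", paste(names(cohort), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(cohort)), collapse = "|"), "|"),
    fmt_row(cohort))
}
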