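#' Functional assessment registry and PS3 scoring
#'
#' The default registry enumerates 29 items: the five biophysical
#' parameters (peak amplitude, macroscopic inactivation, recovery from
#' inactivation, voltage dependence of activation, voltage dependence of
#' steady-state inactivation) in each of the four channel configurations
#' (20 items), plus nine beta-subunit modulation items (five expected
#' KChIP effects, four expected DPP effects). A configuration-parameter
#' item is "altered" when any of its sub-statistics differs significantly
#' from wild type (Dunnett-adjusted p < alpha); a beta-modulation item is
#' "altered" (modulation lost) when the expected directional effect of the
#' subunit, tested one-sided within the variant (binary complex versus
#' the variant alone), is not significant.
#'
#' @name functional_assessment
NULL

PARAM_SUBSTATS <- list(
  peak = "peak_amp",
  decay = c("tau1", "tau2", "rel_a1"),
  recovery = "tau_rec",
  activation = c("v_half_act", "k_act"),
  inactivation = c("v_half_inact", "k_inact"))

BETA_ITEMS <- data.frame(
  id = c("kchip_tau1_slowed", "kchip_tau2_accelerated",
         "kchip_recovery_accelerated", "kchip_ssi_positive_shift",
         "kchip_amplitude_increase",
         "dpp_tau1_accelerated", "dpp_recovery_accelerated",
         "dpp_activation_negative_shift", "dpp_ssi_negative_shift"),
  beta_config = c(rep("KCHIP", 5), rep("DPP", 4)),
  column = c("tau1", "tau2", "tau_rec", "v_half_inact", "peak_amp",
             "tau1", "tau_rec", "v_half_act", "v_half_inact"),
  direction = c("greater", "less", "less", "greater", "greater",
                "less", "less", "less", "less"),
  stringsAsFactors = FALSE)

#' The default 29-item assessment registry
#'
#' @param path Optional TSV file overriding the enumeration; it must have
#'   the registry columns (`id`, `kind`, `configuration`, `parameter`,
#'   `substats`, `beta_config`, `column`, `direction`).
#' @return An `item_registry` data.frame with one row per item.
#' @export
default_registry <- function(path = NULL) {
  if (!is.null(path)) {
    reg <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("id", "kind", "configuration", "parameter", "substats",
              "beta_config", "column", "direction")
    if (length(setdiff(need, names(reg))))
      stop("registry file schema mismatch")
    if (anyDuplicated(reg$id)) stop("registry item ids must be unique")
    class(reg) <- c("item_registry", class(reg))
    return(reg)
  }
  cfg <- expand.grid(parameter = names(PARAM_SUBSTATS),
                     configuration = CONFIGURATIONS,
                     stringsAsFactors = FALSE)
  config_items <- data.frame(
    id = paste(cfg$configuration, cfg$parameter, sep = ":"),
    kind = "config_param",
    configuration = cfg$configuration,
    parameter = cfg$parameter,
    substats = vapply(cfg$parameter,
                      function(p) paste(PARAM_SUBSTATS[[p]], collapse = ","),
                      character(1)),
    beta_config = NA_character_, column = NA_character_,
    direction = NA_character_, stringsAsFactors = FALSE)
  beta_items <- data.frame(
    id = BETA_ITEMS$id, kind = "beta_modulation",
    configuration = NA_character_, parameter = NA_character_,
    substats = NA_character_, beta_config = BETA_ITEMS$beta_config,
    column = BETA_ITEMS$column, direction = BETA_ITEMS$direction,
    stringsAsFactors = FALSE)
  reg <- rbind(config_items, beta_items)
  rownames(reg) <- NULL
  class(reg) <- c("item_registry", class(reg))
  reg
}

#' Assess one configuration-parameter item
#'
#' @param features A `feature_set` data.frame holding (at least) the
#'   control and variant rows for the configuration; the Dunnett family is
#'   every variant present in it.
#' @param variant Variant id to assess.
#' @param parameter One of `peak`, `decay`, `recovery`, `activation`,
#'   `inactivation`.
#' @param configuration Channel configuration.
#' @param control Control label.
#' @param alpha Significance level.
#' @return List with `altered` (logical, `NA` when not assessable),
#'   `evidence` (data.frame of per-sub-statistic Dunnett results).
#' @export
assess_config_item <- function(features, variant, parameter, configuration,
                               control = "WT", alpha = 0.05) {
  substats <- PARAM_SUBSTATS[[parameter]]
  if (is.null(substats)) stop("unknown parameter: ", parameter)
  sub <- features[features$configuration == configuration, , drop = FALSE]
  if (!variant %in% sub$variant || !control %in% sub$variant) {
    message("item not assessable: ", variant, " / ", configuration, " / ",
            parameter, " (configuration missing)")
    return(list(altered = NA, evidence = NULL))
  }
  ev <- list()
  for (s in substats) {
    if (!s %in% names(sub)) next
    ok <- is.finite(sub[[s]])
    cmp <- tryCatch(
      dunnett_many_to_one(sub[[s]][ok], sub$variant[ok], control = control,
                          parameter = s),
      error = function(e) NULL)
    if (!is.null(cmp)) ev[[s]] <- cmp[cmp$group == variant, , drop = FALSE]
  }
  if (!length(ev)) return(list(altered = NA, evidence = NULL))
  ev <- do.call(rbind, ev)
  list(altered = any(ev$p_adj < alpha), evidence = ev)
}

#' Assess one beta-subunit modulation item
#'
#' Tests the expected directional beta effect within the variant: the
#' feature in the binary complex against the same feature for the variant
#' alone, one-sided. The item is altered (modulation lost) when the
#' expected effect is not significant.
#'
#' @param alone Numeric feature values for the variant without auxiliary
#'   subunits.
#' @param with_beta Feature values for the variant in the binary complex.
#' @param direction `"greater"` if the subunit is expected to increase the
#'   feature (binary > alone), `"less"` for a decrease.
#' @param alpha Significance level.
#' @return List with `altered`, `p`.
#' @export
assess_beta_modulation_item <- function(alone, with_beta,
                                        direction = c("greater", "less"),
                                        alpha = 0.05) {
  direction <- match.arg(direction)
  alone <- alone[is.finite(alone)]
  with_beta <- with_beta[is.finite(with_beta)]
  if (length(alone) < 2L || length(with_beta) < 2L)
    return(list(altered = NA, p = NA_real_))
  tt <- tryCatch(
    t_test_two_sample(with_beta, alone, two_sided = FALSE,
                      alternative = direction),
    error = function(e) NULL)
  if (is.null(tt)) return(list(altered = NA, p = NA_real_))
  list(altered = !(tt$p < alpha), p = tt$p)
}

#' Build a variant's assessment matrix over the registry
#'
#' @param features Combined `feature_set` data.frame for all
#'   configurations, containing the control and (at least) the assessed
#'   variant; all variants present define the Dunnett family.
#' @param variant Variant id.
#' @param registry Item registry, default [default_registry()].
#' @param control Control label.
#' @param alpha Significance level.
#' @return An `assessment_matrix`: data.frame with one row per item
#'   (`id`, `kind`, `altered`, `p`) plus attributes `variant_id` and
#'   `altered_count` (items that are `NA` -- not assessable -- are
#'   excluded from the count).
#' @export
build_assessment <- function(features, variant,
                             registry = default_registry(),
                             control = "WT", alpha = 0.05) {
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    it <- registry[i, ]
    if (it$kind == "config_param") {
      res <- assess_config_item(features, variant, it$parameter,
                                it$configuration, control, alpha)
      p <- if (is.null(res$evidence)) NA_real_ else min(res$evidence$p_adj)
      data.frame(id = it$id, kind = it$kind, altered = res$altered, p = p,
                 stringsAsFactors = FALSE)
    } else {
      al <- features[features$configuration == "ALONE" &
                       features$variant == variant, it$column]
      wb <- features[features$configuration == it$beta_config &
                       features$variant == variant, it$column]
      if (is.null(al)) al <- numeric(0)
      if (is.null(wb)) wb <- numeric(0)
      res <- assess_beta_modulation_item(al, wb, it$direction, alpha)
      if (is.na(res$altered))
        message("item not assessable: ", variant, " / ", it$id,
                " (configuration missing)")
      data.frame(id = it$id, kind = it$kind, altered = res$altered,
                 p = res$p, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "variant_id") <- variant
  attr(out, "altered_count") <- sum(out$altered, na.rm = TRUE)
  class(out) <- c("assessment_matrix", class(out))
  out
}

#' Score ACMG criterion PS3 from an assessment matrix
#'
#' PS3 (strong functional evidence) applies when at least `threshold`
#' registry items are significantly altered.
#'
#' @param matrix An `assessment_matrix`, or an integer altered count.
#' @param threshold Minimum altered-item count, default 4.
#' @return A `ps3_result`: list with `variant_id`, `altered_count`,
#'   `ps3_applied`, `threshold`, `strength`.
#' @export
score_ps3 <- function(matrix, threshold = 4L) {
  if (inherits(matrix, "assessment_matrix")) {
    count <- attr(matrix, "altered_count")
    vid <- attr(matrix, "variant_id")
  } else {
    count <- as.integer(matrix)
    vid <- NA_character_
  }
  if (count < 0 || count > 29L + 1e-9)
    stopifnot(count >= 0)
  structure(list(variant_id = vid, altered_count = count,
                 ps3_applied = count >= threshold, threshold = threshold,
                 strength = "strong"),
            class = "ps3_result")
}
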