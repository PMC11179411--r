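#' Wild-type versus variant group statistics
#'
#' One-way ANOVA layout with Dunnett many-to-one comparisons against the
#' wild-type control, classical pooled two-sample t-tests, and the
#' two-tier significance annotation (`*` p < 0.05, `**` p < 0.0001).
#'
#' The Dunnett adjustment is computed from the joint null distribution of
#' the k-1 correlated t statistics. With group sizes `n_i` and control
#' size `n_0`, the statistics share the product correlation
#' `rho_ij = lambda_i lambda_j`, `lambda_i = (1/sqrt(n_0)) /
#' sqrt(1/n_i + 1/n_0)`, which admits the classic one-factor reduction:
#' conditioning on the control variate and the pooled scale leaves the
#' comparisons independent, so the family-wise probability is a double
#' integral evaluated here by adaptive quadrature (default) or by seeded
#' Monte Carlo.
#'
#' @name group_stats
NULL

## Golub-Welsch nodes/weights, cached
.quad_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(n) {
  key <- paste0("gh", n)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  res <- list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
  .quad_cache[[key]] <- res
  res
}

gauss_legendre <- function(n, a = 0, b = 1) {
  key <- paste0("gl", n)
  gl <- .quad_cache[[key]]
  if (is.null(gl)) {
    i <- seq_len(n - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- i / sqrt(4 * i^2 - 1)
    e <- eigen(J, symmetric = TRUE)
    gl <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
    .quad_cache[[key]] <- gl
  }
  list(nodes = (b - a) / 2 * gl$nodes + (a + b) / 2,
       weights = (b - a) / 2 * gl$weights)
}

## P(max_j |T_j| < q) (or max T_j < q one-sided) for Dunnett statistics
## with factor loadings lambda and error df nu. Gauss-Hermite over the
## control variate, Gauss-Legendre over the pooled scale.
dunnett_pmax <- function(q, lambda, nu, two_sided = TRUE) {
  if (q <= 0) return(0)
  sq1 <- sqrt(pmax(1 - lambda^2, .Machine$double.eps))
  gh <- gauss_hermite(64L)
  z <- sqrt(2) * gh$nodes
  wz <- gh$weights / sqrt(pi)
  inner <- function(s_vec) {
    ## matrix [s x z] of conditional joint probabilities
    pr <- matrix(1, length(s_vec), length(z))
    for (j in seq_along(lambda)) {
      up <- stats::pnorm((outer(q * s_vec, lambda[j] * z, `-`)) / sq1[j])
      lo <- if (two_sided)
        stats::pnorm((outer(-q * s_vec, lambda[j] * z, `-`)) / sq1[j])
      else 0
      pr <- pr * pmax(up - lo, 0)
    }
    as.numeric(pr %*% wz)
  }
  if (is.infinite(nu)) return(min(1, max(0, inner(1))))
  ## scale S = sqrt(chisq_nu / nu), concentrated near 1
  s_hi <- 1 + 12 / sqrt(2 * nu)
  gl <- gauss_legendre(96L, max(1e-12, 1 - 12 / sqrt(2 * nu)), s_hi)
  f_s <- exp(log(2) + (nu / 2) * log(nu / 2) - lgamma(nu / 2) +
               (nu - 1) * log(gl$nodes) - nu * gl$nodes^2 / 2)
  min(1, max(0, sum(gl$weights * f_s * inner(gl$nodes))))
}

dunnett_pmax_mc <- function(q, lambda, nu, two_sided = TRUE, n_sim = 2e5,
                            seed = 1L) {
  with_seed(seed, {
    z0 <- stats::rnorm(n_sim)
    s <- sqrt(stats::rchisq(n_sim, nu) / nu)
    mx <- rep(-Inf, n_sim)
    for (j in seq_along(lambda)) {
      tj <- (lambda[j] * z0 +
               sqrt(1 - lambda[j]^2) * stats::rnorm(n_sim)) / s
      if (two_sided) tj <- abs(tj)
      mx <- pmax(mx, tj)
    }
    mean(mx < q)
  })
}

#' Dunnett many-to-one comparisons
#'
#' @param values Numeric vector of observations.
#' @param groups Factor/character vector of group labels, same length.
#' @param control Label of the control (wild-type) group.
#' @param two_sided Two-sided tests (default, matching directionless
#'   significance stars).
#' @param method `"quadrature"` (deterministic, tolerance well below 1e-4)
#'   or `"montecarlo"` (seeded).
#' @param seed Seed for the Monte Carlo path.
#' @param parameter Optional parameter name carried into the result.
#' @return A `group_comparison` data.frame: one row per non-control group
#'   with `group`, `mean`, `sd`, `n`, `diff` (group minus control),
#'   `t`, `p_unadj`, `p_adj`, `tier`.
#' @export
dunnett_many_to_one <- function(values, groups, control = "WT",
                                two_sided = TRUE,
                                method = c("quadrature", "montecarlo"),
                                seed = 1L, parameter = NA_character_) {
  method <- match.arg(method)
  keep <- is.finite(values)
  values <- values[keep]
  groups <- as.character(groups)[keep]
  labs <- unique(groups)
  if (!(control %in% labs)) stop("control group '", control, "' not found")
  if (length(labs) < 2L) stop("need the control plus at least one group")
  ns <- table(groups)
  if (any(ns < 2L))
    stop("singleton (or empty) group(s): ",
         paste(names(ns)[ns < 2L], collapse = ", "))
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, stats::var)
  nu <- sum(ns) - length(labs)
  s2 <- sum((ns - 1) * vars) / nu
  if (s2 <= 0) stop("zero pooled within-group variance; nothing to test")
  others <- setdiff(labs, control)
  n0 <- ns[[control]]
  lambda_all <- vapply(others, function(g)
    (1 / sqrt(n0)) / sqrt(1 / ns[[g]] + 1 / n0), numeric(1))
  tstat <- vapply(others, function(g)
    (means[[g]] - means[[control]]) /
      sqrt(s2 * (1 / ns[[g]] + 1 / n0)), numeric(1))
  p_adj <- vapply(seq_along(others), function(i) {
    q <- if (two_sided) abs(tstat[i]) else tstat[i]
    if (length(others) == 1L && method == "quadrature") {
      ## single comparison: the joint distribution is a plain t, so the
      ## adjusted p equals the pooled two-sample t-test p exactly
      pr <- stats::pt(q, nu) - if (two_sided) stats::pt(-q, nu) else 0
    } else {
      pr <- if (method == "quadrature")
        dunnett_pmax(q, lambda_all, nu, two_sided)
      else
        dunnett_pmax_mc(q, lambda_all, nu, two_sided, seed = seed)
    }
    min(1, max(0, 1 - pr))
  }, numeric(1))
  p_unadj <- if (two_sided) 2 * stats::pt(abs(tstat), nu, lower.tail = FALSE)
    else stats::pt(tstat, nu, lower.tail = FALSE)
  out <- data.frame(
    parameter = parameter, control = control, group = others,
    mean = as.numeric(means[others]),
    sd = sqrt(as.numeric(vars[others])),
    n = as.integer(ns[others]),
    diff = as.numeric(means[others] - means[[control]]),
    t = as.numeric(tstat), p_unadj = as.numeric(p_unadj),
    p_adj = as.numeric(p_adj),
    tier = vapply(p_adj, tier, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Family-wise Dunnett critical value
#'
#' Smallest `q` with `P(max_j |T_j| >= q) = alpha` under the joint null;
#' useful for fast family-wise error simulations.
#'
#' @param alpha Family-wise error rate.
#' @param n Integer vector of group sizes, control first.
#' @param two_sided Two-sided comparisons.
#' @return Critical value on the t scale.
#' @export
dunnett_critical <- function(alpha, n, two_sided = TRUE) {
  n0 <- n[1]
  lambda <- (1 / sqrt(n0)) / sqrt(1 / n[-1] + 1 / n0)
  nu <- sum(n) - length(n)
  stats::uniroot(function(q) dunnett_pmax(q, lambda, nu, two_sided) -
                   (1 - alpha),
                 c(0.1, 15), tol = 1e-8)$root
}

#' Classical pooled-variance two-sample t-test
#'
#' @param a,b Numeric samples (n >= 2 each).
#' @param two_sided Two-sided (default) or one-sided
#'   (`alternative = "greater"` tests mean(a) > mean(b),
#'   `"less"` the reverse).
#' @param alternative Used when `two_sided = FALSE`.
#' @return List with `p`, `t`, `df`, `direction` (sign of mean(a) -
#'   mean(b)).
#' @export
t_test_two_sample <- function(a, b, two_sided = TRUE,
                              alternative = c("greater", "less")) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 in each sample")
  nu <- length(a) + length(b) - 2L
  s2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / nu
  if (s2 <= 0) stop("zero pooled variance")
  tstat <- (mean(a) - mean(b)) / sqrt(s2 * (1 / length(a) + 1 / length(b)))
  p <- if (two_sided) 2 * stats::pt(abs(tstat), nu, lower.tail = FALSE)
  else {
    alternative <- match.arg(alternative)
    if (alternative == "greater") stats::pt(tstat, nu, lower.tail = FALSE)
    else stats::pt(tstat, nu, lower.tail = TRUE)
  }
  list(p = min(1, p), t = tstat, df = nu,
       direction = sign(mean(a) - mean(b)))
}

#' Significance tier
#'
#' `ns` for p >= 0.05, `*` for 0.0001 <= p < 0.05, `**` for p < 0.0001
#' (both thresholds exclusive at the upper bound).
#'
#' @param p p-value in \[0, 1\].
#' @return `"ns"`, `"*"` or `"**"`.
#' @export
tier <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p < 1e-4) "**" else if (p < 0.05) "*" else "ns"
}
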