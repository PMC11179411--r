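#' @export
print.biophysical_profile <- function(x, ...) {
  cat("Kv4.1 biophysical profile",
      if (!is.na(x$configuration)) paste0("(", x$configuration, ")"), "\n")
  cat(sprintf("  g_max %.3f uS | tau1 %.3g tau2 %.3g ms (rel_a1 %.2f) | tau_rec %.3g ms\n",
              x$g_max, x$tau1, x$tau2, x$rel_a1, x$tau_rec))
  cat(sprintf("  act: V1/2 %.2f mV, k %.2f | inact: V1/2 %.2f mV, k %.2f | tau_act %.2f ms, e_rev %.1f mV\n",
              x$v_half_act, x$k_act, x$v_half_inact, x$k_inact, x$tau_act,
              x$e_rev))
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("double-exponential decay fit: tau1 %.3g ms, tau2 %.3g ms, rel_a1 %.3f, offset %.3g (rss %.3g, %s)\n",
              x$tau1, x$tau2, x$rel_a1, x$offset, x$rss,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf("recovery fit: tau_rec %.4g ms, amplitude %.3f (%s)\n",
              x$tau_rec, x$amplitude,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann %s fit: V1/2 %.2f mV, k %.2f mV (%s%s)\n",
              x$direction, x$v_half, x$k,
              if (isTRUE(x$converged)) "converged" else "NOT converged",
              if (isTRUE(x$residual_warning)) "; residual warning" else ""))
  invisible(x)
}

#' @export
print.ps3_result <- function(x, ...) {
  cat(sprintf("PS3: %s (%d altered items, threshold %d)\n",
              if (x$ps3_applied) "applied" else "not applied",
              x$altered_count, x$threshold))
  invisible(x)
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("%s: %s (%+d points) -> %s%s\n",
              x$variant_id %||% "variant",
              if (length(x$criteria)) paste(x$criteria, collapse = ", ")
              else "no criteria",
              x$total, x$class,
              if (x$conflict_override_applied)
                " [conflicting evidence, forced VUS]" else ""))
  invisible(x)
}
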