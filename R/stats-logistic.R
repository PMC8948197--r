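#' Single-predictor logistic odds ratio
#'
#' Fits `label ~ score` by maximum likelihood (IRLS via [stats::glm()],
#' convergence tolerance 1e-8, at most 100 iterations) on complete
#' observations only, and reports the odds ratio per unit of the score with
#' a 95% Wald confidence interval, alongside the odds ratio per standard
#' deviation of the score (the per-unit OR of a continuous index depends on
#' its scale, so both are reported). Complete separation is detected and
#' flagged with an infinite-OR sentinel rather than returning a silently
#' diverged estimate; a constant score is flagged as degenerate.
#'
#' @param data A data frame.
#' @param score Column with the predictor (tidy-eval).
#' @param label Column with the binary outcome (tidy-eval).
#' @param positive Value of `label` modelled as the event; defaults as in
#'   [roc_with_bootstrap()].
#' @return An object of class `imflux_or` with fields `or`, `ci_low`,
#'   `ci_high`, `p_value`, `or_per_sd`, `ci_low_per_sd`, `ci_high_per_sd`,
#'   `separated`, `degenerate`, `n`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
logistic_odds_ratio <- function(data, score, label, positive = NULL) {
  x <- dplyr::pull(data, {{ score }})
  g <- as.character(dplyr::pull(data, {{ label }}))
  keep <- is.finite(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  y <- resolve_binary(g, positive)
  n <- length(x)

  if (length(unique(x)) < 2) {
    return(structure(
      list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           p_value = NA_real_, or_per_sd = NA_real_,
           ci_low_per_sd = NA_real_, ci_high_per_sd = NA_real_,
           separated = FALSE, degenerate = TRUE, n = n),
      class = "imflux_or"
    ))
  }

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  # complete separation: every positive scores above every negative (or below)
  if (max(x[!y]) < min(x[y]) || max(x[y]) < min(x[!y])) separated <- TRUE

  b <- unname(coef(fit)[2])
  se <- sqrt(diag(stats::vcov(fit)))[2]
  z <- qnorm(0.975)
  s <- sd(x)
  if (separated) {
    or <- if (b > 0) Inf else 0
    return(structure(
      list(or = or, ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
           or_per_sd = if (b > 0) Inf else 0,
           ci_low_per_sd = NA_real_, ci_high_per_sd = NA_real_,
           separated = TRUE, degenerate = FALSE, n = n),
      class = "imflux_or"
    ))
  }
  p <- 2 * pnorm(-abs(b / se))
  structure(
    list(or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
         p_value = p,
         or_per_sd = exp(b * s), ci_low_per_sd = exp((b - z * se) * s),
         ci_high_per_sd = exp((b + z * se) * s),
         separated = FALSE, degenerate = FALSE, n = n),
    class = "imflux_or"
  )
}

#' @export
print.imflux_or <- function(x, ...) {
  if (x$degenerate) {
    cat("Logistic fit degenerate: constant score, OR undefined\n")
  } else if (x$separated) {
    cat(sprintf("Complete separation: OR sentinel %s, n = %d\n",
                format(x$or), x$n))
  } else {
    cat(sprintf("OR per unit = %.4g (95%% CI %.4g-%.4g, p = %.3g); OR per SD = %.4g; n = %d\n",
                x$or, x$ci_low, x$ci_high, x$p_value, x$or_per_sd, x$n))
  }
  invisible(x)
}
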