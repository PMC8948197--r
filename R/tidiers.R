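# broom-style tidiers for fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
#' @rdname imflux_tidiers
#' @param x A result object.
#' @param ... Unused.
#' @name imflux_tidiers
#' @title Tidiers for imflux result objects
#' @description `tidy()` returns per-element detail (ROC curve points for a
#'   ROC fit, bootstrap draws for a comparison, coefficient-style rows for an
#'   odds-ratio fit); `glance()` returns a one-row summary.
tidy.imflux_roc <- function(x, ...) {
  # ROC curve: one point per distinct threshold (score descending)
  thr <- c(Inf, sort(unique(x$scores), decreasing = TRUE))
  pts <- lapply(thr, function(t) {
    called <- x$scores >= t
    tibble(threshold = t,
           tpr = sum(called & x$positive) / sum(x$positive),
           fpr = sum(called & !x$positive) / sum(!x$positive))
  })
  dplyr::bind_rows(pts)
}

#' @export
#' @rdname imflux_tidiers
glance.imflux_roc <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n_pos = x$n_pos, n_neg = x$n_neg, n_boot = x$n_boot)
}

#' @export
#' @rdname imflux_tidiers
tidy.imflux_cmp <- function(x, ...) {
  tibble(replicate = seq_along(x$d_boot), auc_difference = x$d_boot)
}

#' @export
#' @rdname imflux_tidiers
glance.imflux_cmp <- function(x, ...) {
  tibble(auc_index = x$auc_index, auc_other = x$auc_other,
         p_one_sided = x$p_one_sided, n_boot = x$n_boot)
}

#' @export
#' @rdname imflux_tidiers
tidy.imflux_or <- function(x, ...) {
  tibble(
    term = c("score (per unit)", "score (per SD)"),
    odds_ratio = c(x$or, x$or_per_sd),
    ci_low = c(x$ci_low, x$ci_low_per_sd),
    ci_high = c(x$ci_high, x$ci_high_per_sd),
    p_value = rep(x$p_value, 2)
  )
}

#' @export
#' @rdname imflux_tidiers
glance.imflux_or <- function(x, ...) {
  tibble(or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
         p_value = x$p_value, or_per_sd = x$or_per_sd,
         separated = x$separated, degenerate = x$degenerate, n = x$n)
}
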