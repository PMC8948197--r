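# Midrank AUC, stratified-bootstrap confidence intervals, and one-sided
# bootstrap comparison of two classifiers scored on the same samples.

#' Midrank AUC of a score against a binary label
#'
#' The area under the ROC curve computed as the midrank Mann-Whitney
#' estimator: ties between a positive and a negative score count one half.
#' Equals U / (n_pos * n_neg) with U the Mann-Whitney statistic.
#'
#' @param scores Numeric vector.
#' @param positive Logical vector, `TRUE` for the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_midrank <- function(scores, positive) {
  positive <- as.logical(positive)
  if (length(scores) != length(positive)) {
    stop_validation("scores and labels differ in length")
  }
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) {
    stop_validation("both classes must be present to compute an AUC")
  }
  r <- rank(scores)  # midranks
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

resolve_binary <- function(g, positive = NULL) {
  lev <- sort(unique(g))
  if (length(lev) != 2) {
    stop_validation(paste0("need exactly two classes, found: ",
                           paste(lev, collapse = ", ")))
  }
  if (is.null(positive)) {
    positive <- if ("malignant" %in% lev) "malignant" else lev[2]
  }
  if (!positive %in% lev) {
    stop_validation(paste0("positive class '", positive, "' not present"))
  }
  g == positive
}

#' ROC analysis with stratified-bootstrap confidence interval
#'
#' Computes the midrank AUC of a score for discriminating a positive class,
#' with a 95% percentile-bootstrap confidence interval. Resampling is
#' stratified by class (positives and negatives resampled separately with
#' replacement), which preserves the class counts and keeps the AUC defined
#' in every replicate. Deterministic given `seed`.
#'
#' @param data A data frame.
#' @param score Column with the classifier score (tidy-eval).
#' @param label Column with the class label (tidy-eval).
#' @param positive Value of `label` treated as positive; defaults to
#'   `"malignant"` when present, otherwise the later class in sort order.
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap; `NULL` uses the current RNG.
#' @return An object of class `imflux_roc`: `auc`, `ci_low`, `ci_high`,
#'   `n_pos`, `n_neg`, `n_boot`, plus the scores/labels and bootstrap draws
#'   for plotting. Supports [generics::tidy()] (ROC curve points),
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
roc_with_bootstrap <- function(data, score, label, positive = NULL,
                               n_boot = 2000, seed = NULL) {
  if (!is_scalar_number(n_boot) || n_boot < 1) {
    stop_validation("n_boot must be at least 1")
  }
  x <- dplyr::pull(data, {{ score }})
  g <- as.character(dplyr::pull(data, {{ label }}))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  pos <- resolve_binary(g, positive)
  auc <- auc_midrank(x, pos)
  ip <- which(pos); ineg <- which(!pos)
  boot <- with_seed_maybe(seed, {
    vapply(seq_len(n_boot), function(b) {
      xp <- x[sample(ip, length(ip), replace = TRUE)]
      xn <- x[sample(ineg, length(ineg), replace = TRUE)]
      auc_midrank(c(xp, xn), c(rep(TRUE, length(xp)), rep(FALSE, length(xn))))
    }, numeric(1))
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  structure(
    list(auc = auc, ci_low = ci[1], ci_high = ci[2],
         n_pos = length(ip), n_neg = length(ineg),
         n_boot = as.integer(n_boot), seed = seed,
         scores = x, positive = pos, boot_auc = boot),
    class = "imflux_roc"
  )
}

#' @export
print.imflux_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f), %d pos / %d neg, %d bootstrap replicates\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg, x$n_boot))
  invisible(x)
}

#' One-sided bootstrap comparison of two classifiers
#'
#' Tests the null hypothesis that a competing score classifies as well as or
#' better than the index score, against the alternative that the index is
#' better. Both scores must rate the same samples. For each stratified
#' bootstrap replicate (classes resampled separately, the SAME resampled
#' samples used for both scores), the AUC difference
#' `d* = auc_index* - auc_other*` is computed, and the one-sided p-value is
#' `(1 + #\{d* <= 0\}) / (n_boot + 1)` (add-one Monte-Carlo correction, so p
#' is never exactly zero). Deterministic given `seed`.
#'
#' @param data A data frame.
#' @param score_index Column with the index score (tidy-eval).
#' @param score_other Column with the competing score (tidy-eval).
#' @param label,positive,n_boot,seed As in [roc_with_bootstrap()].
#' @return An object of class `imflux_cmp`: `auc_index`, `auc_other`,
#'   `p_one_sided`, `n_boot`.
#' @export
compare_classifiers_bootstrap <- function(data, score_index, score_other,
                                          label, positive = NULL,
                                          n_boot = 2000, seed = NULL) {
  if (!is_scalar_number(n_boot) || n_boot < 1) {
    stop_validation("n_boot must be at least 1")
  }
  xi <- dplyr::pull(data, {{ score_index }})
  xo <- dplyr::pull(data, {{ score_other }})
  g <- as.character(dplyr::pull(data, {{ label }}))
  keep <- !is.na(xi) & !is.na(xo) & !is.na(g)
  xi <- xi[keep]; xo <- xo[keep]; g <- g[keep]
  if (length(xi) == 0) stop_validation("no complete observations")
  pos <- resolve_binary(g, positive)
  ip <- which(pos); ineg <- which(!pos)
  d_boot <- with_seed_maybe(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
      lab <- c(rep(TRUE, length(ip)), rep(FALSE, length(ineg)))
      auc_midrank(xi[idx], lab) - auc_midrank(xo[idx], lab)
    }, numeric(1))
  })
  structure(
    list(auc_index = auc_midrank(xi, pos), auc_other = auc_midrank(xo, pos),
         p_one_sided = (1 + sum(d_boot <= 0)) / (n_boot + 1),
         n_boot = as.integer(n_boot), seed = seed, d_boot = d_boot),
    class = "imflux_cmp"
  )
}

#' @export
print.imflux_cmp <- function(x, ...) {
  cat(sprintf("AUC comparison: index %.3f vs other %.3f, one-sided bootstrap p = %.4g (%d replicates)\n",
              x$auc_index, x$auc_other, x$p_one_sided, x$n_boot))
  invisible(x)
}
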