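# Rank-based group tests, Spearman screening, and per-pathway differential
# flux with Bonferroni correction.

pull_score_group <- function(data, score, group) {
  score <- enquo(score); group <- enquo(group)
  x <- dplyr::pull(data, !!score)
  g <- as.character(dplyr::pull(data, !!group))
  keep <- !is.na(x) & !is.na(g)
  list(x = x[keep], g = g[keep])
}

#' Kruskal-Wallis test on a score across groups
#'
#' Midrank Kruskal-Wallis H with tie correction; p from the chi-square
#' approximation with (groups - 1) degrees of freedom. When every observation
#' is tied (tie-correction denominator zero) the test degenerates and the
#' convention H = 0, p = 1 is returned: total ties carry no evidence of a
#' group difference.
#'
#' @param data A data frame.
#' @param score Column holding the numeric score (tidy-eval).
#' @param group Column holding the group label (tidy-eval).
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(data, score, group) {
  v <- pull_score_group(data, {{ score }}, {{ group }})
  groups <- unique(v$g)
  if (length(groups) < 2) stop_validation("need at least two nonempty groups")
  if (any(table(v$g) == 0)) stop_validation("every group must be nonempty")
  if (length(unique(v$x)) == 1L) {
    return(tibble(statistic = 0, df = length(groups) - 1, p_value = 1,
                  n = length(v$x)))
  }
  kt <- stats::kruskal.test(v$x, factor(v$g))
  tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
         p_value = kt$p.value, n = length(v$x))
}

#' Two-group Wilcoxon rank-sum test
#'
#' Rank-sum test on midranks, two-sided. With small samples and no ties the
#' exact null distribution is used (so small fixtures match enumeration over
#' rank assignments); otherwise the normal approximation with tie correction
#' applies.
#'
#' @inheritParams kruskal_wallis
#' @return A one-row tibble: `statistic` (W for the first group in sort
#'   order), `p_value`, `n1`, `n2`.
#' @export
wilcoxon_two_group <- function(data, score, group) {
  v <- pull_score_group(data, {{ score }}, {{ group }})
  groups <- sort(unique(v$g))
  if (length(groups) != 2) {
    stop_validation("wilcoxon_two_group needs exactly two nonempty groups")
  }
  x <- v$x[v$g == groups[1]]
  y <- v$x[v$g == groups[2]]
  if (length(x) == 0 || length(y) == 0) {
    stop_validation("both groups must be nonempty")
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         n1 = length(x), n2 = length(y))
}

#' Spearman correlation of a score against covariate columns
#'
#' Midrank Spearman rho (Pearson correlation of midranks) per covariate with
#' a t-approximation p-value on n - 2 degrees of freedom. Covariates with
#' fewer than three complete pairs are skipped with a warning.
#'
#' @param data A data frame.
#' @param score Column holding the score (tidy-eval).
#' @param ... Covariate columns (tidyselect); defaults to every numeric
#'   column other than the score.
#' @return A tibble with one row per covariate: `covariate`, `rho`,
#'   `p_value`, `n`.
#' @export
spearman_matrix <- function(data, score, ...) {
  score_name <- names(tidyselect::eval_select(enquo(score), data))[1]
  x <- data[[score_name]]
  dots <- rlang::enquos(...)
  if (length(dots)) {
    cov_names <- names(tidyselect::eval_select(rlang::expr(c(!!!dots)), data))
  } else {
    cov_names <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                         score_name)
  }
  rows <- lapply(cov_names, function(cv) {
    y <- data[[cv]]
    keep <- is.finite(x) & is.finite(y)
    n <- sum(keep)
    if (n < 3) {
      warn(paste0("covariate ", cv, " skipped: fewer than 3 complete pairs"))
      return(NULL)
    }
    rho <- stats::cor(rank(x[keep]), rank(y[keep]))
    p <- if (abs(rho) >= 1) {
      0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tval), df = n - 2)
    }
    tibble(covariate = cv, rho = rho, p_value = p, n = n)
  })
  dplyr::bind_rows(rows)
}

#' Per-pathway differential flux between groups
#'
#' For every pathway column of a flux matrix, tests whether flux differs
#' between groups: Kruskal-Wallis when three or more groups are present,
#' Wilcoxon rank-sum for two. Raw p-values are Bonferroni-corrected across
#' the number of pathways tested (`p_bonferroni = min(1, p_raw * m)`), and
#' rows are sorted by raw p ascending.
#'
#' @param flux A flux tibble (`sample_id` + one column per pathway).
#' @param labels A labels tibble (`sample_id`, `group`).
#' @return A tibble with columns `pathway_id`, `statistic`, `p_raw`,
#'   `p_bonferroni`.
#' @export
differential_pathway_flux <- function(flux, labels) {
  flux <- as_tibble(flux)
  joined <- dplyr::inner_join(flux, labels[c("sample_id", "group")],
                              by = "sample_id")
  if (nrow(joined) == 0) stop_validation("no labelled samples in flux matrix")
  groups <- unique(joined$group)
  if (length(groups) < 2) stop_validation("need at least two groups")
  pathway_cols <- setdiff(names(flux), "sample_id")
  m <- length(pathway_cols)
  rows <- lapply(pathway_cols, function(p) {
    res <- if (length(groups) >= 3) {
      kruskal_wallis(joined, !!rlang::sym(p), .data$group)
    } else {
      wilcoxon_two_group(joined, !!rlang::sym(p), .data$group)
    }
    tibble(pathway_id = p, statistic = res$statistic, p_raw = res$p_value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- pmin(1, out$p_raw * m)
  dplyr::arrange(out, .data$p_raw)
}
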