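# End-to-end orchestration: network + expression + labels -> flux matrix,
# IM-Index table, statistics report, all written to disk deterministically.

#' Build a pipeline run configuration
#'
#' @param network,expression,labels Paths to the network JSON, expression TSV
#'   and label TSV inputs.
#' @param out_dir Output directory; created if missing.
#' @param alpha,beta IM-Index weights (default 1 and 1).
#' @param n_boot Bootstrap replicates for ROC and classifier comparison
#'   (default 2000).
#' @param seed Master seed; every stochastic step draws a child stream from
#'   it via [child_seed()].
#' @param gene_floor Concentration used for network genes missing from the
#'   expression matrix (default 0).
#' @param positive_group,comparison_group Two groups contrasted in the ROC,
#'   logistic and classifier-comparison analyses (defaults: malignant vs
#'   benign).
#' @return A list of class `imflux_config`.
#' @export
run_config <- function(network, expression, labels, out_dir,
                       alpha = 1, beta = 1, n_boot = 2000, seed = 1,
                       gene_floor = 0, positive_group = "malignant",
                       comparison_group = "benign") {
  if (!is_scalar_number(n_boot) || n_boot < 1) {
    stop_validation("n_boot must be at least 1")
  }
  if (!is_scalar_number(alpha) || !is_scalar_number(beta)) {
    stop_validation("alpha and beta must be finite")
  }
  structure(
    list(network = network, expression = expression, labels = labels,
         out_dir = out_dir, alpha = alpha, beta = beta,
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         gene_floor = gene_floor, positive_group = positive_group,
         comparison_group = comparison_group),
    class = "imflux_config"
  )
}

#' Read a pipeline configuration from a flat key=value file
#'
#' Lines are `key = value`; `#` starts a comment. Recognised keys mirror the
#' arguments of [run_config()]. Unknown keys are an error.
#'
#' @param path Config file path.
#' @param ... Overrides applied after the file is read (CLI flags beat the
#'   config file).
#' @return A list of class `imflux_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop_io(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lines[vapply(kv, length, integer(1)) != 2]
  if (length(bad)) {
    stop_format(paste0("cannot parse config line(s): ",
                       paste(bad, collapse = "; ")))
  }
  vals <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  numeric_keys <- c("alpha", "beta", "n_boot", "seed", "gene_floor")
  known <- c("network", "expression", "labels", "out_dir", numeric_keys,
             "positive_group", "comparison_group")
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop_format(paste0("unknown config key(s): ",
                       paste(unknown, collapse = ", ")))
  }
  for (k in intersect(names(vals), numeric_keys)) {
    vals[[k]] <- as.numeric(vals[[k]])
  }
  vals <- utils::modifyList(vals, list(...))
  do.call(run_config, vals)
}

#' Run the full analysis pipeline
#'
#' Loads and validates the network, expression matrix and labels; computes
#' the flux matrix and IM-Index; runs the statistical battery (group tests on
#' the index, ROC with stratified-bootstrap CI for the configured two-group
#' contrast, per-unit and per-SD logistic odds ratios, Spearman correlation
#' and one-sided bootstrap comparison against every numeric biomarker column
#' in the labels file, and per-pathway differential flux with Bonferroni
#' correction); and writes `flux.tsv` (+ `flux_klass.tsv`), `im_index.tsv`
#' and `stats.json` into the output directory. The stats document carries a
#' run-metadata block with every effective parameter, the seed, the package
#' version and MD5 checksums of the inputs; it contains no timestamp, so a
#' re-run with identical inputs and config is byte-identical.
#'
#' @param cfg A configuration from [run_config()] or [read_run_config()].
#' @return The stats report (a list, class `imflux_report`), invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "imflux_config"))
  for (key in c("network", "expression", "labels")) {
    if (!file.exists(cfg[[key]])) {
      stop_io(paste0(key, " file not found: ", cfg[[key]]))
    }
  }
  net <- read_network(cfg$network)
  expr <- read_expression(cfg$expression)
  labels <- read_labels(cfg$labels)

  flux <- compute_flux_matrix(expr, net, floor = cfg$gene_floor)
  index <- compute_im_index(flux, labels, alpha = cfg$alpha, beta = cfg$beta)

  groups <- unique(index$group)
  group_tests <- list()
  if (length(groups) >= 2) {
    kw <- if (length(groups) >= 3) {
      kruskal_wallis(index, .data$im_index, .data$group)
    } else {
      NULL
    }
    group_tests$kruskal_wallis <- if (!is.null(kw)) as.list(kw)
    pair <- index[index$group %in% c(cfg$positive_group, cfg$comparison_group), ]
    if (length(unique(pair$group)) == 2) {
      group_tests$wilcoxon <- as.list(
        wilcoxon_two_group(pair, .data$im_index, .data$group))
      group_tests$contrast <- c(cfg$positive_group, cfg$comparison_group)
    }
  }

  roc <- NULL; or <- NULL
  pair <- index[index$group %in% c(cfg$positive_group, cfg$comparison_group), ]
  if (length(unique(pair$group)) == 2) {
    roc <- roc_with_bootstrap(pair, .data$im_index, .data$group,
                              positive = cfg$positive_group,
                              n_boot = cfg$n_boot,
                              seed = child_seed(cfg$seed, "roc"))
    or <- logistic_odds_ratio(pair, .data$im_index, .data$group,
                              positive = cfg$positive_group)
  }

  biomarker_cols <- setdiff(
    names(labels)[vapply(labels, is.numeric, logical(1))], "sample_id")
  spearman <- NULL
  comparisons <- list()
  if (length(biomarker_cols)) {
    with_cov <- dplyr::left_join(
      index, labels[c("sample_id", biomarker_cols)], by = "sample_id")
    spearman <- spearman_matrix(with_cov, "im_index",
                                dplyr::all_of(biomarker_cols))
    pair_cov <- with_cov[with_cov$group %in%
                           c(cfg$positive_group, cfg$comparison_group), ]
    if (length(unique(pair_cov$group)) == 2) {
      for (bm in biomarker_cols) {
        cmp <- compare_classifiers_bootstrap(
          pair_cov, .data$im_index, !!rlang::sym(bm), .data$group,
          positive = cfg$positive_group, n_boot = cfg$n_boot,
          seed = child_seed(cfg$seed, "compare"))
        comparisons[[bm]] <- list(auc_index = cmp$auc_index,
                                  auc_other = cmp$auc_other,
                                  p_one_sided = cmp$p_one_sided,
                                  n_boot = cmp$n_boot)
      }
    }
  }

  diff_flux <- differential_pathway_flux(flux, labels)

  if (!dir.exists(cfg$out_dir)) {
    ok <- dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(paste0("cannot create output directory ", cfg$out_dir))
  }
  write_flux(flux, file.path(cfg$out_dir, "flux.tsv"))
  readr::write_tsv(as_tibble(index), file.path(cfg$out_dir, "im_index.tsv"),
                   progress = FALSE)

  report <- list(
    im_index = list(
      alpha = cfg$alpha, beta = cfg$beta,
      n_samples = nrow(index),
      group_medians = as.list(tapply(index$im_index, index$group, median))
    ),
    group_tests = group_tests,
    roc = if (!is.null(roc)) {
      list(auc = roc$auc, ci_low = roc$ci_low, ci_high = roc$ci_high,
           n_pos = roc$n_pos, n_neg = roc$n_neg, n_boot = roc$n_boot)
    },
    odds_ratio = if (!is.null(or)) {
      list(or = or$or, ci_low = or$ci_low, ci_high = or$ci_high,
           p_value = or$p_value, or_per_sd = or$or_per_sd,
           separated = or$separated, degenerate = or$degenerate, n = or$n)
    },
    spearman = if (!is.null(spearman)) {
      lapply(seq_len(nrow(spearman)), function(i) as.list(spearman[i, ]))
    },
    comparisons = comparisons,
    differential_flux = lapply(seq_len(nrow(diff_flux)), function(i) {
      as.list(diff_flux[i, ])
    }),
    run_metadata = list(
      config = cfg[c("network", "expression", "labels", "out_dir", "alpha",
                     "beta", "n_boot", "seed", "gene_floor",
                     "positive_group", "comparison_group")],
      package_version = as.character(utils::packageVersion("imflux")),
      input_md5 = as.list(stats::setNames(
        tools::md5sum(c(cfg$network, cfg$expression, cfg$labels)),
        c("network", "expression", "labels")))
    )
  )
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = I(12),
                           pretty = 2, null = "null")
  writeLines(json, file.path(cfg$out_dir, "stats.json"), useBytes = TRUE)
  invisible(structure(report, class = "imflux_report"))
}
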