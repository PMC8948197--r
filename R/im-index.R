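#' Compute the IM-Index from a flux matrix
#'
#' The IM-Index of a sample is a weighted sum of its pathway fluxes,
#' `alpha * sum(flux over signaling-transduction pathways) +
#'  beta * sum(flux over energy-metabolism pathways)`,
#' with both weights defaulting to 1. The score summarises how much
#' information flows through the immune signaling and energy-metabolism
#' machinery of a sample and is used as a diagnostic score for group
#' discrimination.
#'
#' @param flux A flux tibble from [compute_flux_matrix()] (or [read_flux()]
#'   with a klass companion file).
#' @param labels Optional labels tibble (`sample_id`, `group`, ...); when
#'   given, the group column is joined onto the result.
#' @param alpha Weight on the signaling-transduction flux sum.
#' @param beta Weight on the energy-metabolism flux sum.
#' @param klass Optional named character vector `pathway_id -> klass`,
#'   overriding the attribute carried by `flux`.
#' @return A tibble of class `imflux_index` with columns `sample_id`,
#'   `im_index` and (when labels are supplied) `group`; `alpha` and `beta`
#'   are recorded as attributes.
#' @export
compute_im_index <- function(flux, labels = NULL, alpha = 1, beta = 1,
                             klass = NULL) {
  if (!is_scalar_number(alpha) || !is_scalar_number(beta)) {
    stop_config("alpha and beta must be finite numbers")
  }
  klass <- klass %||% attr(flux, "klass")
  flux <- as_tibble(flux)
  pathway_cols <- setdiff(names(flux), "sample_id")
  if (is.null(klass)) {
    stop_config("flux table carries no pathway-to-klass mapping; pass `klass`")
  }
  missing_klass <- setdiff(pathway_cols, names(klass))
  if (length(missing_klass)) {
    stop_config(paste0("pathway(s) without a klass: ",
                       paste(missing_klass, collapse = ", ")))
  }
  bad <- setdiff(unique(unname(klass[pathway_cols])), KLASSES)
  if (length(bad)) {
    stop_config(paste0("unknown klass value(s): ", paste(bad, collapse = ", ")))
  }
  sig_cols <- pathway_cols[klass[pathway_cols] == "signaling_transduction"]
  met_cols <- pathway_cols[klass[pathway_cols] == "energy_metabolism"]
  row_sum <- function(cols) {
    if (length(cols) == 0) rep(0, nrow(flux))
    else rowSums(as.matrix(flux[cols]))
  }
  out <- tibble(
    sample_id = flux$sample_id,
    im_index = alpha * row_sum(sig_cols) + beta * row_sum(met_cols)
  )
  if (!is.null(labels)) {
    missing <- setdiff(out$sample_id, labels$sample_id)
    if (length(missing)) {
      stop_validation(paste0("unlabelled sample(s): ",
                             paste(missing, collapse = ", ")))
    }
    out <- dplyr::left_join(out, labels[c("sample_id", "group")],
                            by = "sample_id")
  }
  structure(out, alpha = alpha, beta = beta,
            class = c("imflux_index", class(out)))
}
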