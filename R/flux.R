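# Mass-action flux engine: expression profile -> species concentrations ->
# reaction fluxes -> pathway fluxes.
#
# A reaction's flux is rate_constant times the product of the concentrations
# of its activating participants (roles e, g, s, tr_a), attenuated divisively
# by each inhibiting participant (roles i, tr_r) through a 1/(1 + c) factor,
# so an absent inhibitor leaves the flux untouched and flux stays nonnegative.
# A pathway's base flux is the mean of its reactions' fluxes; its reported
# flux subtracts the mean BASE flux of its crosstalk pathways (one level only,
# never recursed), and may therefore be negative.

as_profile <- function(profile) {
  if (is.data.frame(profile)) {
    if (!"gene_id" %in% names(profile) || ncol(profile) < 2) {
      stop_format("a profile data frame needs a 'gene_id' column and one value column")
    }
    stats::setNames(as.numeric(profile[[2]]), profile$gene_id)
  } else if (is.numeric(profile) && !is.null(names(profile))) {
    profile
  } else {
    stop_format("profile must be a named numeric vector or a two-column data frame")
  }
}

# Scalar concentration lookup; `id` may name a species or a gene.
concentration_scalar <- function(net, values, id, floor = 0) {
  idx <- match(id, net$species$id)
  if (!is.na(idx)) {
    if (isTRUE(net$species$is_constant[idx])) {
      return(net$species$constant_value[idx])
    }
    cons <- net$species$constituents[[idx]]
    if (length(cons) == 0) {
      stop_config(paste0("species ", id, " has no constituents and is not ",
                         "constant: concentration undefined"))
    }
    vals <- values[cons]
    vals[is.na(vals)] <- floor
    return(prod(vals))
  }
  if (id %in% net$genes$id) {
    v <- unname(values[id])
    if (is.na(v)) v <- floor
    return(v)
  }
  stop_validation(paste0("unknown species or gene id: ", id))
}

#' Concentration of a species under an expression profile
#'
#' Constant species return their `constant_value` regardless of the profile.
#' Otherwise the concentration is the product of the expression values of the
#' species' constituent genes (mass-action convention for complexes). Genes
#' absent from the profile contribute the floor value (default 0).
#'
#' @param net A validated `knowledge_network`.
#' @param profile Named numeric vector of gene abundances, or a two-column
#'   data frame (`gene_id`, value).
#' @param species_id A species id (or gene id, whose expression is returned).
#' @param floor Concentration substituted for genes missing from the profile.
#' @return A nonnegative number.
#' @export
species_concentration <- function(net, profile, species_id, floor = 0) {
  concentration_scalar(net, as_profile(profile), species_id, floor)
}

#' Mass-action flux of a single reaction
#'
#' @inheritParams species_concentration
#' @param reaction_id A reaction id in `net`.
#' @return A nonnegative number: `rate_constant` times the product of
#'   activating concentrations divided by `prod(1 + c)` over inhibiting
#'   participants.
#' @export
reaction_flux <- function(net, profile, reaction_id, floor = 0) {
  values <- as_profile(profile)
  idx <- match(reaction_id, net$reactions$id)
  if (is.na(idx)) stop_validation(paste0("unknown reaction id: ", reaction_id))
  p <- net$reactions$participants[[idx]]
  flux <- net$reactions$rate_constant[idx]
  for (j in seq_len(nrow(p))) {
    conc <- concentration_scalar(net, values, p$species_id[j], floor)
    if (p$role[j] %in% ROLES_ACTIVATING) {
      flux <- flux * conc
    } else {
      flux <- flux / (1 + conc)
    }
  }
  flux
}

pathway_base_flux <- function(net, values, pathway_idx, floor = 0) {
  rids <- net$pathways$reaction_ids[[pathway_idx]]
  mean(vapply(rids, function(r) {
    reaction_flux(net, values, r, floor)
  }, numeric(1)))
}

#' Flux of a pathway under an expression profile
#'
#' Base flux is the mean reaction flux over the pathway's reactions; the
#' reported flux subtracts the mean base flux of the pathway's crosstalk
#' pathways (zero if it has none). Crosstalk is evaluated one level deep only,
#' so the value is well defined even when crosstalk links form cycles; the
#' subtraction can make the reported flux negative, and it is not clamped.
#'
#' @inheritParams species_concentration
#' @param pathway_id A pathway id in `net`.
#' @return A real number.
#' @export
pathway_flux <- function(net, profile, pathway_id, floor = 0) {
  values <- as_profile(profile)
  idx <- match(pathway_id, net$pathways$id)
  if (is.na(idx)) stop_validation(paste0("unknown pathway id: ", pathway_id))
  base <- pathway_base_flux(net, values, idx, floor)
  ct <- net$pathways$crosstalk_ids[[idx]]
  if (length(ct) == 0) return(base)
  ct_idx <- match(ct, net$pathways$id)
  base - mean(vapply(ct_idx, function(i) {
    pathway_base_flux(net, values, i, floor)
  }, numeric(1)))
}

#' Compute the sample-by-pathway flux matrix
#'
#' Evaluates [pathway_flux()] for every sample and every pathway, vectorised
#' across samples. Column order follows the network's pathway order. Network
#' genes absent from the expression table are treated as expressed at the
#' floor value; a warning reports the gene-coverage fraction when it is below
#' one, and coverage zero is an error.
#'
#' @param expr Expression tibble (`gene_id` + one numeric column per sample).
#' @param net A validated `knowledge_network`.
#' @param floor Concentration substituted for genes missing from `expr`.
#' @return A tibble of class `imflux_flux` with columns `sample_id` and one
#'   column per pathway, carrying the pathway-to-klass mapping as the
#'   `"klass"` attribute.
#' @export
compute_flux_matrix <- function(expr, net, floor = 0) {
  validate_network(net)
  expr <- validate_expression(expr)
  samples <- names(expr)[-1]
  n_s <- length(samples)
  E <- as.matrix(expr[-1])
  rownames(E) <- expr$gene_id

  net_genes <- net$genes$id
  if (length(net_genes)) {
    covered <- net_genes %in% expr$gene_id
    coverage <- mean(covered)
    if (coverage == 0) {
      stop_validation("no network gene is present in the expression matrix")
    }
    if (coverage < 1) {
      warn(sprintf(
        "expression matrix covers %.1f%% of network genes; %d missing gene(s) set to floor %g",
        100 * coverage, sum(!covered), floor))
    }
  }

  gene_rows <- function(g) {
    # genes x samples values with the floor filled in for absent genes
    idx <- match(g, rownames(E))
    out <- matrix(floor, nrow = length(g), ncol = n_s)
    hit <- !is.na(idx)
    if (any(hit)) out[hit, ] <- E[idx[hit], , drop = FALSE]
    out
  }

  # concentration vectors (length n_s) per species/gene id, memoised
  conc_cache <- new.env(parent = emptyenv())
  conc_vec <- function(id) {
    if (!is.null(conc_cache[[id]])) return(conc_cache[[id]])
    sidx <- match(id, net$species$id)
    v <- if (!is.na(sidx)) {
      if (isTRUE(net$species$is_constant[sidx])) {
        rep(net$species$constant_value[sidx], n_s)
      } else {
        cons <- net$species$constituents[[sidx]]
        if (length(cons) == 0) {
          stop_config(paste0("species ", id, " has no constituents and is ",
                             "not constant: concentration undefined"))
        }
        rows <- gene_rows(cons)
        apply(rows, 2, prod)
      }
    } else {
      drop(gene_rows(id))
    }
    conc_cache[[id]] <- v
    v
  }

  # reaction fluxes: reactions x samples
  RX <- matrix(NA_real_, nrow = nrow(net$reactions), ncol = n_s)
  for (i in seq_len(nrow(net$reactions))) {
    p <- net$reactions$participants[[i]]
    f <- rep(net$reactions$rate_constant[i], n_s)
    for (j in seq_len(nrow(p))) {
      cv <- conc_vec(p$species_id[j])
      f <- if (p$role[j] %in% ROLES_ACTIVATING) f * cv else f / (1 + cv)
    }
    RX[i, ] <- f
  }
  rownames(RX) <- net$reactions$id

  # pathway base fluxes: pathways x samples
  BASE <- t(vapply(seq_len(nrow(net$pathways)), function(i) {
    rows <- match(net$pathways$reaction_ids[[i]], net$reactions$id)
    colMeans(RX[rows, , drop = FALSE])
  }, numeric(n_s)))
  if (n_s == 1) BASE <- matrix(BASE, ncol = 1)

  FLUX <- BASE
  for (i in seq_len(nrow(net$pathways))) {
    ct <- net$pathways$crosstalk_ids[[i]]
    if (length(ct)) {
      rows <- match(ct, net$pathways$id)
      FLUX[i, ] <- BASE[i, ] - colMeans(BASE[rows, , drop = FALSE])
    }
  }

  out <- as_tibble(as.data.frame(t(FLUX)))
  names(out) <- net$pathways$id
  out <- dplyr::bind_cols(tibble(sample_id = samples), out)
  new_flux_tbl(out, stats::setNames(net$pathways$klass, net$pathways$id))
}

#' Reference (scalar) flux-matrix evaluator
#'
#' Straightforward per-entry evaluation that re-walks the network through the
#' scalar [pathway_flux()] path for every sample and pathway. Slower than
#' [compute_flux_matrix()] but independent of its vectorised internals; used
#' to generate expected-flux fixture files and as a cross-check.
#'
#' @inheritParams compute_flux_matrix
#' @return Same shape as [compute_flux_matrix()].
#' @export
flux_matrix_reference <- function(expr, net, floor = 0) {
  validate_network(net)
  expr <- validate_expression(expr)
  samples <- names(expr)[-1]
  rows <- lapply(samples, function(s) {
    prof <- stats::setNames(as.numeric(expr[[s]]), expr$gene_id)
    vals <- vapply(net$pathways$id, function(p) {
      pathway_flux(net, prof, p, floor)
    }, numeric(1))
    dplyr::bind_cols(tibble(sample_id = s), as_tibble(as.list(vals)))
  })
  out <- dplyr::bind_rows(rows)
  new_flux_tbl(out, stats::setNames(net$pathways$klass, net$pathways$id))
}
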