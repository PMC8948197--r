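# Synthetic knowledge networks and three-group expression cohorts.
#
# The generator emulates the study conditions the pipeline is meant for: a
# blood-leukocyte cohort of malignant / benign / control participants in
# which the genes feeding designated driver pathways are multiplicatively
# up-shifted over a lognormal baseline, with the ordering
# malignant >= benign >= control (control is the reference, multiplier 1).

#' Specification for a synthetic knowledge network
#'
#' Genes are partitioned round-robin into one disjoint pool per pathway, and
#' each pathway's species draw their constituent genes from its own pool, so
#' simulated group effects on one pathway's genes shift exactly that pathway.
#' Pathway classes are assigned by rounding: the first
#' `round(klass_fractions["signaling_transduction"] * n_pathways)` pathways
#' are signaling transduction, the rest energy metabolism.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_pathways Number of pathways (>= 1).
#' @param reactions_per_pathway Reactions per pathway (>= 1).
#' @param genes_per_species Constituent genes per non-constant species; must
#'   not exceed the per-pathway gene pool size.
#' @param klass_fractions Named numeric vector over the two pathway classes,
#'   summing to 1.
#' @param crosstalk_density Probability that an ordered pathway pair is a
#'   crosstalk link.
#' @param inhibitor_fraction Probability that a reaction carries an
#'   inhibiting participant.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `imflux_network_spec`.
#' @export
network_spec <- function(n_genes = 60, n_pathways = 6,
                         reactions_per_pathway = 5, genes_per_species = 2,
                         klass_fractions = c(signaling_transduction = 0.6,
                                             energy_metabolism = 0.4),
                         crosstalk_density = 0.15,
                         inhibitor_fraction = 0.25, seed = 1) {
  problems <- list()
  for (nm in c("n_genes", "n_pathways", "reactions_per_pathway",
               "genes_per_species")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 1 || v != floor(v)) {
      problems <- c(problems, paste0(nm, " must be a positive integer"))
    }
  }
  if (!setequal(names(klass_fractions), KLASSES) ||
      abs(sum(klass_fractions) - 1) > 1e-8 || any(klass_fractions < 0)) {
    problems <- c(problems,
                  "klass_fractions must be named over both classes and sum to 1")
  }
  for (nm in c("crosstalk_density", "inhibitor_fraction")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v < 0 || v > 1) {
      problems <- c(problems, paste0(nm, " must be a probability in [0, 1]"))
    }
  }
  check_all(problems, "network spec")
  structure(
    list(n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
         reactions_per_pathway = as.integer(reactions_per_pathway),
         genes_per_species = as.integer(genes_per_species),
         klass_fractions = klass_fractions[KLASSES],
         crosstalk_density = crosstalk_density,
         inhibitor_fraction = inhibitor_fraction,
         seed = as.integer(seed)),
    class = "imflux_network_spec"
  )
}

#' Generate a synthetic knowledge network
#'
#' Builds a valid miniature network with the spec's exact layer counts:
#' `n_genes` genes and `n_pathways * reactions_per_pathway` reactions. Every
#' reaction has the same activating backbone -- a gene-driven substrate
#' species, an enzyme or transcriptional-activator species, and one direct
#' gene participant -- so reaction fluxes are commensurate across pathways
#' (structurally heterogeneous reactions would make pathway-flux magnitudes
#' differ by orders under the multiplicative engine, and a summed index would
#' be dominated by one arbitrary pathway). An inhibiting participant
#' (inhibitor or transcriptional repressor) is added with probability
#' `inhibitor_fraction`, a shared constant water-like compound at
#' concentration 1 joins some reactions, and each reaction emits one product
#' species. Crosstalk links are drawn independently per ordered pathway pair.
#' Deterministic given the spec (including its seed).
#'
#' @param spec An [network_spec()].
#' @return A validated `knowledge_network`.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "imflux_network_spec"))
  min_pool <- spec$n_genes %/% spec$n_pathways
  if (min_pool < spec$genes_per_species) {
    stop_config(paste0("infeasible spec: genes_per_species (",
                       spec$genes_per_species,
                       ") exceeds the per-pathway gene pool (", min_pool, ")"))
  }
  withr::with_seed(spec$seed, {
    gene_ids <- sprintf("G%03d", seq_len(spec$n_genes))
    pools <- split(gene_ids,
                   rep_len(seq_len(spec$n_pathways), spec$n_genes))
    n_sig <- max(0L, min(spec$n_pathways, as.integer(round(
      spec$klass_fractions[["signaling_transduction"]] * spec$n_pathways))))
    klass <- c(rep("signaling_transduction", n_sig),
               rep("energy_metabolism", spec$n_pathways - n_sig))

    species <- list(tibble(
      id = "CONST_H2O", kind = "compound", constituents = list(character()),
      is_constant = TRUE, constant_value = 1.0))
    reactions <- list()
    pathway_rows <- list()

    for (p in seq_len(spec$n_pathways)) {
      pool <- pools[[p]]
      rids <- character(spec$reactions_per_pathway)
      for (j in seq_len(spec$reactions_per_pathway)) {
        rid <- sprintf("R_P%02d_%02d", p, j)
        rids[j] <- rid
        parts <- list()
        sub_id <- sprintf("S_P%02d_%02d_sub", p, j)
        species <- c(species, list(tibble(
          id = sub_id, kind = sample(c("rna", "protein", "complex"), 1),
          constituents = list(sample(pool, spec$genes_per_species)),
          is_constant = FALSE, constant_value = NA_real_)))
        parts <- c(parts, list(tibble(species_id = sub_id, role = "s")))
        enz_id <- sprintf("S_P%02d_%02d_act", p, j)
        species <- c(species, list(tibble(
          id = enz_id, kind = "protein",
          constituents = list(sample(pool, spec$genes_per_species)),
          is_constant = FALSE, constant_value = NA_real_)))
        parts <- c(parts, list(tibble(species_id = enz_id,
                                      role = sample(c("e", "tr_a"), 1))))
        parts <- c(parts, list(tibble(species_id = sample(pool, 1),
                                      role = "g")))
        if (runif(1) < spec$inhibitor_fraction) {
          inh_id <- sprintf("S_P%02d_%02d_inh", p, j)
          species <- c(species, list(tibble(
            id = inh_id, kind = "protein",
            constituents = list(sample(pool, spec$genes_per_species)),
            is_constant = FALSE, constant_value = NA_real_)))
          parts <- c(parts, list(tibble(species_id = inh_id,
                                        role = sample(c("i", "tr_r"), 1))))
        }
        if (runif(1) < 0.3) {
          parts <- c(parts, list(tibble(species_id = "CONST_H2O", role = "s")))
        }
        prod_id <- sprintf("S_P%02d_%02d_out", p, j)
        species <- c(species, list(tibble(
          id = prod_id, kind = "compound", constituents = list(character()),
          is_constant = TRUE, constant_value = 1.0)))
        reactions <- c(reactions, list(tibble(
          id = rid, participants = list(dplyr::bind_rows(parts)),
          products = list(prod_id), rate_constant = 1)))
      }
      pathway_rows[[p]] <- tibble(
        id = sprintf("P%02d", p), name = sprintf("pathway %02d", p),
        klass = klass[p], reaction_ids = list(rids),
        crosstalk_ids = list(character()))
    }

    pathways <- dplyr::bind_rows(pathway_rows)
    for (p in seq_len(spec$n_pathways)) {
      others <- setdiff(pathways$id, pathways$id[p])
      link <- others[runif(length(others)) < spec$crosstalk_density]
      pathways$crosstalk_ids[[p]] <- link
    }

    knowledge_network(
      genes = tibble(id = gene_ids, name = gene_ids),
      species = dplyr::bind_rows(species),
      reactions = dplyr::bind_rows(reactions),
      pathways = pathways
    )
  })
}

#' Specification for a synthetic three-group cohort
#'
#' Emulates a blood-transcriptome study with malignant, benign and control
#' groups. Expression of gene g in a sample of group G is
#' `baseline_g * effect^{driver(g)} * exp(N(0, noise_log_sd))`, where
#' `baseline_g ~ LogNormal(baseline_log_mean, baseline_log_sd)` is drawn once
#' per gene, `effect = effect_multipliers[G]`, and `driver(g)` is 1 when g
#' feeds a driver pathway. The conventional ordering of multipliers is
#' malignant >= benign >= control = 1; a violation is warned about, not
#' rejected.
#'
#' The default baseline spread (`baseline_log_sd = 0.25`) is deliberately
#' narrow compared with real TPM distributions: because reaction fluxes are
#' products over several genes, a wide per-gene spread makes pathway-flux
#' magnitudes span orders of magnitude, and a sum-over-pathways index is then
#' dominated by a single arbitrary pathway. The narrow default yields
#' commensurate pathway fluxes -- the structure a summed index presupposes --
#' which is the statistical structure this generator exists to emulate.
#'
#' @param group_sizes Named integer vector over malignant/benign/control.
#' @param driver_pathways Pathway ids whose feeding genes receive the group
#'   effect; `NULL` selects the network's first pathway at generation time.
#' @param effect_multipliers Named positive multipliers per group.
#' @param baseline_log_mean,baseline_log_sd Lognormal baseline parameters
#'   (natural-log scale, TPM-like linear values).
#' @param noise_log_sd Per-gene-per-sample lognormal noise (log scale).
#' @param seed Integer seed.
#' @return An object of class `imflux_cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(malignant = 78, benign = 21,
                                        control = 40),
                        driver_pathways = NULL,
                        effect_multipliers = c(malignant = 2.0, benign = 1.4,
                                               control = 1.0),
                        baseline_log_mean = log(5), baseline_log_sd = 0.25,
                        noise_log_sd = 0.3, seed = 1) {
  groups <- c("malignant", "benign", "control")
  problems <- list()
  if (!setequal(names(group_sizes), groups) || any(group_sizes < 0)) {
    problems <- c(problems,
                  "group_sizes must be named over malignant/benign/control, all >= 0")
  }
  if (!setequal(names(effect_multipliers), groups) ||
      any(effect_multipliers <= 0)) {
    problems <- c(problems, "effect_multipliers must be positive and named per group")
  }
  if (!is_scalar_number(baseline_log_sd) || baseline_log_sd < 0 ||
      !is_scalar_number(noise_log_sd) || noise_log_sd < 0) {
    problems <- c(problems, "baseline_log_sd and noise_log_sd must be nonnegative")
  }
  check_all(problems, "cohort spec")
  if (sum(group_sizes) == 0) stop_validation("cohort must contain at least one sample")
  m <- effect_multipliers
  if (!(m[["malignant"]] >= m[["benign"]] && m[["benign"]] >= m[["control"]])) {
    warn("effect multipliers violate the malignant >= benign >= control convention")
  }
  structure(
    list(group_sizes = round(group_sizes[groups]),
         driver_pathways = driver_pathways,
         effect_multipliers = effect_multipliers[groups],
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd,
         noise_log_sd = noise_log_sd, seed = as.integer(seed)),
    class = "imflux_cohort_spec"
  )
}

#' Genes feeding a set of pathways
#'
#' A gene feeds a pathway when it is a constituent of a species participating
#' in one of the pathway's reactions in any non-inhibiting role, or when it
#' participates directly as a gene in such a role. Inhibitor-fed genes are
#' excluded: shifting them would invert the intended effect direction.
#'
#' @param net A validated `knowledge_network`.
#' @param pathway_ids Character vector of pathway ids.
#' @return Character vector of gene ids.
#' @export
feeding_genes <- function(net, pathway_ids) {
  missing <- setdiff(pathway_ids, net$pathways$id)
  if (length(missing)) {
    stop_validation(paste0("unknown pathway id(s): ",
                           paste(missing, collapse = ", ")))
  }
  rids <- unique(unlist(
    net$pathways$reaction_ids[match(pathway_ids, net$pathways$id)]))
  genes <- character()
  for (i in match(rids, net$reactions$id)) {
    p <- net$reactions$participants[[i]]
    act <- p$species_id[p$role %in% ROLES_ACTIVATING]
    for (id in act) {
      sidx <- match(id, net$species$id)
      if (!is.na(sidx)) {
        genes <- c(genes, net$species$constituents[[sidx]])
      } else if (id %in% net$genes$id) {
        genes <- c(genes, id)
      }
    }
  }
  sort(unique(genes))
}

#' Generate a synthetic expression cohort over a network
#'
#' @param net A validated `knowledge_network`.
#' @param spec A [cohort_spec()].
#' @return A list with `expression` (gene-by-sample tibble), `labels`
#'   (`sample_id`, `group` tibble) and `ground_truth` (list: driver pathways,
#'   driver genes, effect multipliers). Deterministic given the spec.
#' @export
generate_cohort <- function(net, spec) {
  stopifnot(inherits(spec, "imflux_cohort_spec"))
  validate_network(net)
  drivers <- spec$driver_pathways %||% net$pathways$id[1]
  missing <- setdiff(drivers, net$pathways$id)
  if (length(missing)) {
    stop_validation(paste0("driver pathway(s) not in network: ",
                           paste(missing, collapse = ", ")))
  }
  driver_genes <- feeding_genes(net, drivers)
  genes <- net$genes$id
  sizes <- spec$group_sizes
  prefix <- c(malignant = "M", benign = "B", control = "C")
  sample_ids <- unlist(lapply(names(sizes), function(g) {
    if (sizes[[g]] == 0) return(character())
    sprintf("%s%03d", prefix[[g]], seq_len(sizes[[g]]))
  }))
  groups <- rep(names(sizes), times = sizes)

  mat <- withr::with_seed(spec$seed, {
    baseline <- rlnorm(length(genes), spec$baseline_log_mean,
                       spec$baseline_log_sd)
    mult <- ifelse(genes %in% driver_genes, 1, 0)
    m <- matrix(NA_real_, nrow = length(genes), ncol = length(sample_ids))
    for (j in seq_along(sample_ids)) {
      eff <- spec$effect_multipliers[[groups[j]]]
      noise <- exp(rnorm(length(genes), 0, spec$noise_log_sd))
      m[, j] <- baseline * eff^mult * noise
    }
    m
  })
  expr <- dplyr::bind_cols(
    tibble(gene_id = genes),
    as_tibble(as.data.frame(mat, col.names = sample_ids))
  )
  names(expr) <- c("gene_id", sample_ids)
  list(
    expression = expr,
    labels = tibble(sample_id = sample_ids, group = groups),
    ground_truth = list(driver_pathways = drivers,
                        driver_genes = driver_genes,
                        effect_multipliers = as.list(spec$effect_multipliers))
  )
}

#' Write a canonical small fixture bundle
#'
#' Generates a network and cohort from the given specs and writes
#' `network.json`, `expression.tsv`, `labels.tsv`, `ground_truth.json` and
#' `expected_flux.tsv` (plus its klass companion) into `dir`. The expected
#' fluxes come from the scalar reference evaluator
#' ([flux_matrix_reference()]), not the vectorised production path, so the
#' bundle doubles as a cross-check fixture. Byte-identical on regeneration
#' with the same specs.
#'
#' @param dir Output directory (created if absent).
#' @param net_spec An [network_spec()]; default is a small bundle-sized spec.
#' @param coh_spec A [cohort_spec()]; default is a small three-group cohort.
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(dir,
                                 net_spec = network_spec(
                                   n_genes = 12, n_pathways = 3,
                                   reactions_per_pathway = 3,
                                   genes_per_species = 2, seed = 7),
                                 coh_spec = cohort_spec(
                                   group_sizes = c(malignant = 6, benign = 6,
                                                   control = 6),
                                   seed = 7)) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io(paste0("cannot create directory ", dir))
  }
  net <- generate_network(net_spec)
  coh <- generate_cohort(net, coh_spec)
  paths <- c(
    network = file.path(dir, "network.json"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    expected_flux = file.path(dir, "expected_flux.tsv")
  )
  write_network(net, paths[["network"]])
  write_expression(coh$expression, paths[["expression"]])
  write_labels(coh$labels, paths[["labels"]])
  writeLines(jsonlite::toJSON(coh$ground_truth, auto_unbox = TRUE,
                              digits = NA, pretty = 2),
             paths[["ground_truth"]], useBytes = TRUE)
  expected <- flux_matrix_reference(coh$expression, net)
  write_flux(expected, paths[["expected_flux"]])
  invisible(paths)
}
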