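#' Construct a layered knowledge network
#'
#' The network has four layers: genes, molecular species (RNA, protein,
#' complex, compound), typed reactions, and pathways. A species' concentration
#' is driven by the expression of its constituent genes; compounds held fixed
#' during flux evaluation (water, oxygen, ...) are marked `is_constant` and
#' carry a `constant_value`. Reactions list typed participants -- enzyme
#' (`"e"`), gene (`"g"`), inhibitor (`"i"`), substrate (`"s"`), transcriptional
#' activator (`"tr_a"`) and repressor (`"tr_r"`) -- and pathways group
#' reactions, carry a class (signaling transduction vs. energy metabolism) and
#' may name crosstalk pathways whose flux is discounted from their own.
#' Feedback from pathways to genes exists only through `tr_a`/`tr_r`
#' participants; there is no separate edge type.
#'
#' @param genes Data frame with columns `id` and optionally `name`.
#' @param species Data frame with columns `id`, `kind` (one of `"rna"`,
#'   `"protein"`, `"complex"`, `"compound"`), `constituents` (list column of
#'   character vectors of gene ids), `is_constant` (logical) and
#'   `constant_value` (numeric, required where `is_constant`).
#' @param reactions Data frame with columns `id`, `participants` (list column
#'   of data frames with `species_id`, `role`), `products` (list column of
#'   character vectors of species ids) and `rate_constant` (positive numeric,
#'   default 1).
#' @param pathways Data frame with columns `id`, `name`, `klass`
#'   (`"signaling_transduction"` or `"energy_metabolism"`), `reaction_ids` and
#'   `crosstalk_ids` (list columns of character vectors).
#' @return A validated object of class `knowledge_network`.
#' @seealso [read_network()], [write_network()], [network_summary()],
#'   [generate_network()]
#' @export
knowledge_network <- function(genes, species, reactions, pathways) {
  net <- structure(
    list(
      genes = normalise_genes(genes),
      species = normalise_species(species),
      reactions = normalise_reactions(reactions),
      pathways = normalise_pathways(pathways)
    ),
    class = "knowledge_network"
  )
  validate_network(net)
}

normalise_genes <- function(genes) {
  genes <- as_tibble(as.data.frame(genes, stringsAsFactors = FALSE))
  if (!"name" %in% names(genes)) genes$name <- NA_character_
  genes$name <- as.character(genes$name)
  genes$id <- as.character(genes$id)
  genes[c("id", "name")]
}

normalise_species <- function(species) {
  species <- as_tibble(species)
  if (!"constituents" %in% names(species)) {
    species$constituents <- rep(list(character()), nrow(species))
  }
  if (!"is_constant" %in% names(species)) species$is_constant <- FALSE
  if (!"constant_value" %in% names(species)) species$constant_value <- NA_real_
  species$id <- as.character(species$id)
  species$kind <- as.character(species$kind)
  species$is_constant <- as.logical(species$is_constant)
  species$constant_value <- as.numeric(species$constant_value)
  species$constituents <- lapply(species$constituents, as.character)
  species[c("id", "kind", "constituents", "is_constant", "constant_value")]
}

normalise_reactions <- function(reactions) {
  reactions <- as_tibble(reactions)
  if (!"products" %in% names(reactions)) {
    reactions$products <- rep(list(character()), nrow(reactions))
  }
  if (!"rate_constant" %in% names(reactions)) reactions$rate_constant <- 1
  reactions$id <- as.character(reactions$id)
  reactions$rate_constant <- as.numeric(reactions$rate_constant)
  reactions$products <- lapply(reactions$products, as.character)
  reactions$participants <- lapply(reactions$participants, function(p) {
    p <- as_tibble(as.data.frame(p, stringsAsFactors = FALSE))
    p$species_id <- as.character(p$species_id)
    p$role <- as.character(p$role)
    p[c("species_id", "role")]
  })
  reactions[c("id", "participants", "products", "rate_constant")]
}

normalise_pathways <- function(pathways) {
  pathways <- as_tibble(pathways)
  if (!"name" %in% names(pathways)) pathways$name <- pathways$id
  if (!"crosstalk_ids" %in% names(pathways)) {
    pathways$crosstalk_ids <- rep(list(character()), nrow(pathways))
  }
  pathways$id <- as.character(pathways$id)
  pathways$name <- as.character(pathways$name)
  pathways$klass <- as.character(pathways$klass)
  pathways$reaction_ids <- lapply(pathways$reaction_ids, as.character)
  pathways$crosstalk_ids <- lapply(pathways$crosstalk_ids, as.character)
  pathways[c("id", "name", "klass", "reaction_ids", "crosstalk_ids")]
}

#' Validate a knowledge network
#'
#' Checks every structural invariant: unique non-empty ids, disjoint id
#' namespaces across the four layers, known role and klass strings, resolvable
#' cross-references (constituents to genes, participants to species or genes,
#' products to species, pathway reactions and crosstalk to their tables),
#' positive rate constants, at least one activating participant per reaction,
#' no self-crosstalk, and at least one pathway. All problems are reported in
#' one error.
#'
#' @param net A `knowledge_network`.
#' @return `net`, invisibly-validated (returned unchanged on success).
#' @export
validate_network <- function(net) {
  if (!inherits(net, "knowledge_network")) {
    stop_validation("not a knowledge_network object")
  }
  g <- net$genes; sp <- net$species; rx <- net$reactions; pw <- net$pathways
  problems <- list()
  add <- function(p) problems[[length(problems) + 1L]] <<- p

  check_ids <- function(ids, what) {
    out <- character()
    if (any(is.na(ids) | !nzchar(ids))) {
      out <- c(out, paste0("empty or missing ", what, " id"))
    }
    dup <- unique(ids[duplicated(ids)])
    if (length(dup)) {
      out <- c(out, paste0("duplicate ", what, " id(s): ",
                           paste(dup, collapse = ", ")))
    }
    out
  }
  add(check_ids(g$id, "gene"))
  add(check_ids(sp$id, "species"))
  add(check_ids(rx$id, "reaction"))
  add(check_ids(pw$id, "pathway"))

  all_ids <- c(g$id, sp$id, rx$id, pw$id)
  cross_dup <- unique(all_ids[duplicated(all_ids)])
  cross_dup <- setdiff(cross_dup,
                       c(unique(g$id[duplicated(g$id)]),
                         unique(sp$id[duplicated(sp$id)]),
                         unique(rx$id[duplicated(rx$id)]),
                         unique(pw$id[duplicated(pw$id)])))
  if (length(cross_dup)) {
    add(paste0("id(s) shared across layers: ",
               paste(cross_dup, collapse = ", ")))
  }

  # species invariants
  bad_kind <- setdiff(unique(sp$kind), SPECIES_KINDS)
  if (length(bad_kind)) {
    add(paste0("unknown species kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  for (i in seq_len(nrow(sp))) {
    miss <- setdiff(sp$constituents[[i]], g$id)
    if (length(miss)) {
      add(paste0("species ", sp$id[i], " references unknown gene(s): ",
                 paste(miss, collapse = ", ")))
    }
    if (isTRUE(sp$is_constant[i])) {
      if (length(sp$constituents[[i]])) {
        add(paste0("constant species ", sp$id[i], " must have no constituents"))
      }
      if (!is_scalar_number(sp$constant_value[i]) || sp$constant_value[i] < 0) {
        add(paste0("constant species ", sp$id[i],
                   " needs a nonnegative constant_value"))
      }
    }
  }

  # reaction invariants
  participant_ids <- c(sp$id, g$id)
  for (i in seq_len(nrow(rx))) {
    p <- rx$participants[[i]]
    if (nrow(p) == 0) {
      add(paste0("reaction ", rx$id[i], " has no participants"))
      next
    }
    bad_role <- setdiff(unique(p$role), ROLES_ALL)
    if (length(bad_role)) {
      add(paste0("reaction ", rx$id[i], " has unknown role(s): ",
                 paste(bad_role, collapse = ", ")))
    }
    miss <- setdiff(p$species_id, participant_ids)
    if (length(miss)) {
      add(paste0("reaction ", rx$id[i],
                 " references unresolved participant id(s): ",
                 paste(miss, collapse = ", ")))
    }
    if (!any(p$role %in% ROLES_ACTIVATING)) {
      add(paste0("reaction ", rx$id[i],
                 " has no activating participant (role e/g/s/tr_a)"))
    }
    missp <- setdiff(rx$products[[i]], sp$id)
    if (length(missp)) {
      add(paste0("reaction ", rx$id[i], " has unknown product species: ",
                 paste(missp, collapse = ", ")))
    }
    if (!is_scalar_number(rx$rate_constant[i]) || rx$rate_constant[i] <= 0) {
      add(paste0("reaction ", rx$id[i], " needs a positive rate_constant"))
    }
  }

  # pathway invariants
  if (nrow(pw) == 0) add("network must contain at least one pathway")
  bad_klass <- setdiff(unique(pw$klass), KLASSES)
  if (length(bad_klass)) {
    add(paste0("unknown pathway klass(es): ",
               paste(bad_klass, collapse = ", ")))
  }
  for (i in seq_len(nrow(pw))) {
    if (length(pw$reaction_ids[[i]]) == 0) {
      add(paste0("pathway ", pw$id[i], " has no reactions"))
    }
    miss <- setdiff(pw$reaction_ids[[i]], rx$id)
    if (length(miss)) {
      add(paste0("pathway ", pw$id[i], " references unknown reaction(s): ",
                 paste(miss, collapse = ", ")))
    }
    missx <- setdiff(pw$crosstalk_ids[[i]], pw$id)
    if (length(missx)) {
      add(paste0("pathway ", pw$id[i], " references unknown crosstalk pathway(s): ",
                 paste(missx, collapse = ", ")))
    }
    if (pw$id[i] %in% pw$crosstalk_ids[[i]]) {
      add(paste0("pathway ", pw$id[i], " lists itself as crosstalk"))
    }
  }

  check_all(problems, "knowledge network")
  net
}

#' Summarise a knowledge network
#'
#' Reports counts per layer, pathway counts per class, and a histogram of
#' participant roles across all reactions.
#'
#' @param net A validated `knowledge_network`.
#' @return A list with elements `n_genes`, `n_species`, `n_reactions`,
#'   `n_pathways`, `klass_counts` (named integer vector over both classes) and
#'   `role_counts` (named integer vector over the six roles).
#' @export
network_summary <- function(net) {
  validate_network(net)
  roles <- unlist(lapply(net$reactions$participants, function(p) p$role))
  role_counts <- vapply(ROLES_ALL, function(r) sum(roles == r), integer(1))
  klass_counts <- vapply(KLASSES, function(k) sum(net$pathways$klass == k),
                         integer(1))
  structure(
    list(
      n_genes = nrow(net$genes),
      n_species = nrow(net$species),
      n_reactions = nrow(net$reactions),
      n_pathways = nrow(net$pathways),
      klass_counts = klass_counts,
      role_counts = role_counts
    ),
    class = "knowledge_network_summary"
  )
}

#' @export
print.knowledge_network_summary <- function(x, ...) {
  cat("Knowledge network:", x$n_genes, "genes,", x$n_species, "species,",
      x$n_reactions, "reactions,", x$n_pathways, "pathways\n")
  cat("  pathway classes:",
      paste(names(x$klass_counts), x$klass_counts, sep = "=", collapse = ", "),
      "\n")
  cat("  participant roles:",
      paste(names(x$role_counts), x$role_counts, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
print.knowledge_network <- function(x, ...) {
  s <- network_summary(x)
  print(s)
  invisible(x)
}

#' Pathway-to-class mapping of a network
#'
#' @param net A validated `knowledge_network`.
#' @return A tibble with columns `pathway_id` and `klass`.
#' @export
pathway_klass <- function(net) {
  tibble(pathway_id = net$pathways$id, klass = net$pathways$klass)
}
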