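# Serialization of networks (JSON dialect) and tabular inputs/outputs (TSV).

#' Read a knowledge network from its JSON file
#'
#' The file is a single UTF-8 JSON object with keys `genes`, `species`,
#' `reactions` and `pathways`; see [write_network()] for the exact shape.
#' Role strings are exactly `"e"`, `"g"`, `"i"`, `"s"`, `"tr_a"`, `"tr_r"`;
#' klass strings exactly `"signaling_transduction"` and `"energy_metabolism"`.
#' The parsed network is fully validated before being returned; dangling
#' references are reported with every unresolved id named.
#'
#' @param path Path to the network JSON file.
#' @return A validated `knowledge_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) {
    stop_io(paste0("network file not found: ", path))
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop_format(paste0("cannot parse network JSON at ", path, ": ",
                         conditionMessage(e)))
    }
  )
  for (key in c("genes", "species", "reactions", "pathways")) {
    if (is.null(raw[[key]])) {
      stop_format(paste0("network JSON at ", path, " is missing the '",
                         key, "' array"))
    }
  }
  chr0 <- function(x) as.character(unlist(x %||% list(), use.names = FALSE))
  genes <- tibble(
    id = vapply(raw$genes, function(x) as.character(x$id %||% NA), character(1)),
    name = vapply(raw$genes, function(x) as.character(x$name %||% NA), character(1))
  )
  species <- tibble(
    id = vapply(raw$species, function(x) as.character(x$id %||% NA), character(1)),
    kind = vapply(raw$species, function(x) as.character(x$kind %||% NA), character(1)),
    constituents = lapply(raw$species, function(x) chr0(x$constituents)),
    is_constant = vapply(raw$species, function(x) isTRUE(x$is_constant), logical(1)),
    constant_value = vapply(raw$species, function(x)
      as.numeric(x$constant_value %||% NA_real_), numeric(1))
  )
  reactions <- tibble(
    id = vapply(raw$reactions, function(x) as.character(x$id %||% NA), character(1)),
    participants = lapply(raw$reactions, function(x) {
      tibble(
        species_id = vapply(x$participants %||% list(),
                            function(p) as.character(p$species_id %||% NA),
                            character(1)),
        role = vapply(x$participants %||% list(),
                      function(p) as.character(p$role %||% NA), character(1))
      )
    }),
    products = lapply(raw$reactions, function(x) chr0(x$products)),
    rate_constant = vapply(raw$reactions, function(x)
      as.numeric(x$rate_constant %||% 1), numeric(1))
  )
  pathways <- tibble(
    id = vapply(raw$pathways, function(x) as.character(x$id %||% NA), character(1)),
    name = vapply(raw$pathways, function(x)
      as.character(x$name %||% x$id %||% NA), character(1)),
    klass = vapply(raw$pathways, function(x) as.character(x$klass %||% NA), character(1)),
    reaction_ids = lapply(raw$pathways, function(x) chr0(x$reaction_ids)),
    crosstalk_ids = lapply(raw$pathways, function(x) chr0(x$crosstalk_ids))
  )
  knowledge_network(genes, species, reactions, pathways)
}

#' Write a knowledge network to its canonical JSON file
#'
#' Emits the canonical dialect with deterministic key ordering, so writing the
#' same network twice yields byte-identical files. The network is validated
#' before anything is written.
#'
#' @param net A validated `knowledge_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  validate_network(net)
  sp <- net$species
  obj <- list(
    genes = lapply(seq_len(nrow(net$genes)), function(i) {
      g <- list(id = net$genes$id[i])
      if (!is.na(net$genes$name[i])) g$name <- net$genes$name[i]
      g
    }),
    species = lapply(seq_len(nrow(sp)), function(i) {
      s <- list(id = sp$id[i], kind = sp$kind[i],
                constituents = as.list(sp$constituents[[i]]),
                is_constant = sp$is_constant[i])
      if (isTRUE(sp$is_constant[i])) s$constant_value <- sp$constant_value[i]
      s
    }),
    reactions = lapply(seq_len(nrow(net$reactions)), function(i) {
      r <- net$reactions[i, ]
      p <- r$participants[[1]]
      list(
        id = r$id,
        participants = lapply(seq_len(nrow(p)), function(j) {
          list(species_id = p$species_id[j], role = p$role[j])
        }),
        products = as.list(r$products[[1]]),
        rate_constant = r$rate_constant
      )
    }),
    pathways = lapply(seq_len(nrow(net$pathways)), function(i) {
      w <- net$pathways[i, ]
      list(id = w$id, name = w$name, klass = w$klass,
           reaction_ids = as.list(w$reaction_ids[[1]]),
           crosstalk_ids = as.list(w$crosstalk_ids[[1]]))
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = 2)
  res <- tryCatch(writeLines(json, path, useBytes = TRUE),
                  error = function(e) stop_io(paste0(
                    "cannot write network to ", path, ": ",
                    conditionMessage(e))))
  invisible(path)
}

#' Read a gene-by-sample expression matrix (TSV)
#'
#' First column header must be `gene_id`; remaining headers are sample ids.
#' Values are nonnegative abundances on linear TPM scale.
#'
#' @param path Path to the tab-delimited file.
#' @return A tibble with a `gene_id` column and one numeric column per sample.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop_io(paste0("expression file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_expression(tbl)
}

#' @rdname read_expression
#' @param expr An expression tibble as returned by [read_expression()].
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

validate_expression <- function(tbl) {
  problems <- list()
  if (names(tbl)[1] != "gene_id") {
    problems <- c(problems, "first column must be 'gene_id'")
  } else {
    dup <- unique(tbl$gene_id[duplicated(tbl$gene_id)])
    if (length(dup)) {
      problems <- c(problems, paste0("duplicate gene id(s): ",
                                     paste(dup, collapse = ", ")))
    }
  }
  if (ncol(tbl) < 2) problems <- c(problems, "no sample columns")
  sample_cols <- names(tbl)[-1]
  if (anyDuplicated(sample_cols)) {
    problems <- c(problems, "duplicate sample ids")
  }
  for (s in sample_cols) {
    v <- tbl[[s]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      problems <- c(problems,
                    paste0("sample ", s, " has non-finite or negative values"))
    }
  }
  check_all(problems, "expression matrix")
  as_tibble(tbl)
}

#' Read a sample-label table (TSV)
#'
#' Columns: `sample_id`, `group`, plus optional numeric biomarker columns.
#'
#' @param path Path to the tab-delimited file.
#' @return A tibble.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_io(paste0("labels file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(tbl))) {
    stop_format(paste0("labels file ", path,
                       " must have 'sample_id' and 'group' columns"))
  }
  tbl$sample_id <- as.character(tbl$sample_id)
  tbl$group <- as.character(tbl$group)
  as_tibble(tbl)
}

#' @rdname read_labels
#' @param labels A labels tibble.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels, path, progress = FALSE)
  invisible(path)
}

#' Write a sample-by-pathway flux matrix (TSV)
#'
#' Writes the flux table with first column `sample_id`, and, when the table
#' carries a klass attribute, a companion two-column TSV mapping pathway id to
#' class next to it (suffix `_klass.tsv`).
#'
#' @param flux A flux tibble from [compute_flux_matrix()].
#' @param path Output path for the flux TSV.
#' @param klass_path Output path for the companion klass TSV; `NULL` derives
#'   it from `path`, `NA` skips it.
#' @return `path`, invisibly.
#' @export
write_flux <- function(flux, path, klass_path = NULL) {
  readr::write_tsv(as_tibble(flux), path, progress = FALSE)
  klass <- attr(flux, "klass")
  if (!is.null(klass) && !isTRUE(is.na(klass_path))) {
    if (is.null(klass_path)) {
      klass_path <- sub("\\.tsv$", "_klass.tsv", path)
      if (identical(klass_path, path)) klass_path <- paste0(path, "_klass.tsv")
    }
    readr::write_tsv(tibble(pathway_id = names(klass), klass = unname(klass)),
                     klass_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a flux matrix written by [write_flux()]
#'
#' @param path Flux TSV path.
#' @param klass_path Optional companion klass TSV; if present the returned
#'   table carries the klass attribute needed by [compute_im_index()].
#' @return A flux tibble (class `imflux_flux`).
#' @export
read_flux <- function(path, klass_path = NULL) {
  if (!file.exists(path)) stop_io(paste0("flux file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(tbl)[1] != "sample_id") {
    stop_format("flux file must have 'sample_id' as its first column")
  }
  klass <- NULL
  if (is.null(klass_path)) {
    guess <- sub("\\.tsv$", "_klass.tsv", path)
    if (!identical(guess, path) && file.exists(guess)) klass_path <- guess
  }
  if (!is.null(klass_path)) {
    ktbl <- readr::read_tsv(klass_path, show_col_types = FALSE, progress = FALSE)
    klass <- stats::setNames(ktbl$klass, ktbl$pathway_id)
  }
  new_flux_tbl(tbl, klass)
}

new_flux_tbl <- function(tbl, klass = NULL) {
  structure(as_tibble(tbl), klass = klass,
            class = c("imflux_flux", class(as_tibble(tbl))))
}
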