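# Tiny hand-built networks and profiles used across tests.

# One gene, one RNA species, one single-substrate reaction, one pathway.
minimal_network <- function() {
  knowledge_network(
    genes = tibble::tibble(id = "G1", name = "gene one"),
    species = tibble::tibble(
      id = "S1", kind = "rna", constituents = list("G1"),
      is_constant = FALSE, constant_value = NA_real_),
    reactions = tibble::tibble(
      id = "R1", participants = list(tibble::tibble(species_id = "S1",
                                                    role = "s")),
      products = list(character()), rate_constant = 1),
    pathways = tibble::tibble(
      id = "P1", name = "p one", klass = "signaling_transduction",
      reaction_ids = list("R1"), crosstalk_ids = list(character()))
  )
}

# Two genes, substrate + enzyme + inhibitor species, constant compound,
# two pathways (one crosstalk link), mixed roles.
toy_network <- function() {
  species <- tibble::tibble(
    id = c("Srna", "Senz", "Sinh", "Scplx", "H2O"),
    kind = c("rna", "protein", "protein", "complex", "compound"),
    constituents = list("G1", "G2", "G2", c("G1", "G2"), character()),
    is_constant = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    constant_value = c(NA, NA, NA, NA, 1.0)
  )
  reactions <- tibble::tibble(
    id = c("R1", "R2", "R3"),
    participants = list(
      tibble::tibble(species_id = c("Srna", "Senz"), role = c("s", "e")),
      tibble::tibble(species_id = c("Srna", "Sinh"), role = c("s", "i")),
      tibble::tibble(species_id = c("Scplx", "H2O"), role = c("s", "s"))
    ),
    products = list("Scplx", character(), character()),
    rate_constant = c(1, 1, 2)
  )
  pathways <- tibble::tibble(
    id = c("PA", "PB"),
    name = c("path A", "path B"),
    klass = c("signaling_transduction", "energy_metabolism"),
    reaction_ids = list(c("R1", "R2"), "R3"),
    crosstalk_ids = list("PB", character())
  )
  knowledge_network(
    genes = tibble::tibble(id = c("G1", "G2")),
    species = species, reactions = reactions, pathways = pathways
  )
}

toy_profile <- function(g1 = 2, g2 = 3) {
  c(G1 = g1, G2 = g2)
}

expr_tbl <- function(..., gene_ids = NULL) {
  cols <- list(...)
  vals <- do.call(cbind, cols)
  tibble::as_tibble(cbind(
    tibble::tibble(gene_id = gene_ids %||% rownames(vals)),
    tibble::as_tibble(as.data.frame(vals))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_expression_for <- function(net, samples = 3, rate = 1) {
  genes <- net$genes$id
  m <- matrix(stats::rexp(length(genes) * samples, rate = rate),
              nrow = length(genes))
  tbl <- tibble::as_tibble(as.data.frame(m))
  names(tbl) <- sprintf("smp%02d", seq_len(samples))
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tbl)
}
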