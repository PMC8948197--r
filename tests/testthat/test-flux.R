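test_that("species concentration follows the mass-action product convention", {
  net <- toy_network()
  prof <- toy_profile(g1 = 5)
  expect_equal(species_concentration(net, prof, "Srna"), 5)
  # constant compound is profile-independent
  expect_equal(species_concentration(net, prof, "H2O"), 1)
  expect_equal(species_concentration(net, toy_profile(1e6, 1e6), "H2O"), 1)
  # complex: product over constituents
  expect_equal(species_concentration(net, toy_profile(2, 3), "Scplx"), 6)
  # a bare gene id resolves to its expression
  expect_equal(species_concentration(net, toy_profile(2, 3), "G2"), 3)
  # missing gene contributes the floor
  expect_equal(species_concentration(net, c(G2 = 3), "Scplx"), 0)
  expect_equal(species_concentration(net, c(G2 = 3), "Scplx", floor = 0.5), 1.5)
})

test_that("undefined concentrations are configuration errors", {
  net <- toy_network()
  net$species$constituents[[1]] <- character()  # Srna, not constant
  expect_error(species_concentration(net, toy_profile(), "Srna"),
               class = "imflux_config_error")
})

test_that("reaction flux multiplies activators and divides by 1 + inhibitor", {
  net <- toy_network()
  # single substrate, rate 1
  one_sub <- minimal_network()
  expect_equal(reaction_flux(one_sub, c(G1 = 4), "R1"), 4)
  # substrate x enzyme
  expect_equal(reaction_flux(net, toy_profile(2, 3), "R1"), 6)
  # substrate 2 with inhibitor at 1 -> 2 / (1 + 1) = 1
  expect_equal(reaction_flux(net, toy_profile(2, 1), "R2"), 1)
  # divisive inhibition at the spec worked example: 2 * 3 / (1 + 1) = 3
  net2 <- net
  net2$reactions$participants[[2]] <- tibble::tibble(
    species_id = c("Srna", "Senz", "Sinh"), role = c("s", "e", "i"))
  expect_equal(reaction_flux(net2, toy_profile(2, 3), "R2"), 6 / (1 + 3))
  # rate constant scales linearly: R3 = 2 * (2*3) * 1(H2O)
  expect_equal(reaction_flux(net, toy_profile(2, 3), "R3"), 12)
})

test_that("pathway flux is the mean reaction flux minus mean crosstalk base", {
  net <- toy_network()
  prof <- toy_profile(2, 3)
  r1 <- reaction_flux(net, prof, "R1")
  r2 <- reaction_flux(net, prof, "R2")
  r3 <- reaction_flux(net, prof, "R3")
  expect_equal(pathway_flux(net, prof, "PB"), r3)
  expect_equal(pathway_flux(net, prof, "PA"), mean(c(r1, r2)) - r3)
  # zero expression everywhere -> zero base flux, zero crosstalk
  z <- toy_profile(0, 0)
  expect_equal(pathway_flux(net, z, "PB"), 0)
  expect_equal(pathway_flux(net, z, "PA"), 0)
})

test_that("crosstalk is evaluated one level deep only", {
  net <- toy_network()
  # make the crosstalk circular: PA <-> PB
  net$pathways$crosstalk_ids[[2]] <- "PA"
  net <- validate_network(net)
  prof <- toy_profile(2, 3)
  base_a <- mean(c(reaction_flux(net, prof, "R1"),
                   reaction_flux(net, prof, "R2")))
  base_b <- reaction_flux(net, prof, "R3")
  # subtracted term uses the partner's BASE flux, never its crosstalked flux
  expect_equal(pathway_flux(net, prof, "PA"), base_a - base_b)
  expect_equal(pathway_flux(net, prof, "PB"), base_b - base_a)
})

test_that("flux matrix equals single-profile evaluation and respects sample order", {
  net <- toy_network()
  expr <- expr_tbl(s1 = c(2, 3), s2 = c(4, 5), gene_ids = c("G1", "G2"))
  fm <- compute_flux_matrix(expr, net)
  expect_equal(fm$sample_id, c("s1", "s2"))
  for (s in c("s1", "s2")) {
    prof <- stats::setNames(expr[[s]], expr$gene_id)
    for (p in c("PA", "PB")) {
      expect_equal(fm[[p]][fm$sample_id == s], pathway_flux(net, prof, p))
    }
  }
  # permuting samples permutes rows, values unchanged
  fm_perm <- compute_flux_matrix(expr[c("gene_id", "s2", "s1")], net)
  expect_equal(fm_perm$sample_id, c("s2", "s1"))
  expect_equal(fm_perm$PA, rev(fm$PA))
})

test_that("missing network genes trigger a coverage warning; zero coverage errors", {
  net <- toy_network()
  partial <- expr_tbl(s1 = 2, gene_ids = "G1")
  expect_warning(compute_flux_matrix(partial, net), "50\\.0%")
  none <- expr_tbl(s1 = 2, gene_ids = "GX")
  expect_error(suppressWarnings(compute_flux_matrix(none, net)),
               class = "imflux_validation_error")
})

test_that("monotonicity: activators never decrease flux, inhibitors never increase it", {
  net <- toy_network()
  withr::with_seed(42, {
    for (rep in 1:20) {
      g1 <- stats::rexp(1); g2 <- stats::rexp(1)
      up <- g2 + stats::rexp(1)
      # G1 feeds substrate Srna of R2 (activating), G2 feeds inhibitor Sinh
      f0 <- reaction_flux(net, c(G1 = g1, G2 = g2), "R2")
      f_act_up <- reaction_flux(net, c(G1 = g1 + 1, G2 = g2), "R2")
      f_inh_up <- reaction_flux(net, c(G1 = g1, G2 = up), "R2")
      expect_gte(f_act_up, f0)
      expect_lte(f_inh_up, f0)
    }
  })
})

test_that("scaling law: k-fold expression scales flux by k^(number of activating genes)", {
  net <- toy_network()
  prof <- toy_profile(2, 3)
  k <- 1.7
  # R1 has substrate (1 gene) and enzyme (1 gene): a = 2, no inhibitors
  expect_equal(reaction_flux(net, prof * k, "R1"),
               k^2 * reaction_flux(net, prof, "R1"))
  # R3: complex of 2 genes plus constant substrate: a = 2
  expect_equal(reaction_flux(net, prof * k, "R3"),
               k^2 * reaction_flux(net, prof, "R3"))
})

test_that("zero-propagation: a zero activating concentration silences the reaction", {
  net <- toy_network()
  expect_equal(reaction_flux(net, c(G1 = 0, G2 = 5), "R1"), 0)
  fm <- compute_flux_matrix(expr_tbl(s = c(0, 0), gene_ids = c("G1", "G2")), net)
  expect_equal(fm$PA, 0)
  expect_equal(fm$PB, 0)
})

test_that("vectorised and reference evaluators agree with the brute-force oracle", {
  withr::with_seed(99, {
    for (rep in 1:5) {
      spec <- network_spec(
        n_genes = sample(10:24, 1), n_pathways = sample(2:4, 1),
        reactions_per_pathway = sample(2:4, 1), genes_per_species = 2,
        crosstalk_density = 0.3, inhibitor_fraction = 0.4,
        seed = sample.int(1e6, 1))
      net <- generate_network(spec)
      expr <- random_expression_for(net, samples = 4)
      fast <- compute_flux_matrix(expr, net)
      slow <- flux_matrix_reference(expr, net)
      oracle <- oracle_flux_matrix(expr, net)
      fast_m <- as.matrix(fast[-1]); rownames(fast_m) <- fast$sample_id
      slow_m <- as.matrix(slow[-1]); rownames(slow_m) <- slow$sample_id
      expect_equal(fast_m, oracle, tolerance = 1e-12)
      expect_equal(slow_m, oracle, tolerance = 1e-12)
    }
  })
})
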