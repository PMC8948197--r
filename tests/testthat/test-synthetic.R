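test_that("network generation is deterministic and round-trips through the readers", {
  spec <- network_spec(n_genes = 12, n_pathways = 3,
                       reactions_per_pathway = 4, seed = 7)
  n1 <- generate_network(spec)
  n2 <- generate_network(spec)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_network(n1, f1); write_network(n2, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_network(f1)
  expect_equal(back$pathways, n1$pathways)
  expect_equal(back$reactions, n1$reactions)
})

test_that("klass counts follow the rounding convention", {
  for (frac in c(0, 0.34, 0.5, 0.68, 1)) {
    spec <- network_spec(
      n_genes = 10, n_pathways = 5, reactions_per_pathway = 2,
      genes_per_species = 2,
      klass_fractions = c(signaling_transduction = frac,
                          energy_metabolism = 1 - frac), seed = 2)
    s <- network_summary(generate_network(spec))
    expect_equal(unname(s$klass_counts[["signaling_transduction"]]),
                 round(frac * 5))
  }
})

test_that("infeasible network specs are rejected", {
  expect_error(
    generate_network(network_spec(n_genes = 4, n_pathways = 4,
                                  reactions_per_pathway = 1,
                                  genes_per_species = 3, seed = 1)),
    class = "imflux_config_error")
  expect_error(network_spec(n_pathways = 0), class = "imflux_validation_error")
  expect_error(network_spec(crosstalk_density = 1.4),
               class = "imflux_validation_error")
})

test_that("every pathway reaches at least one gene", {
  net <- generate_network(network_spec(n_genes = 20, n_pathways = 4,
                                       reactions_per_pathway = 3, seed = 13))
  for (p in net$pathways$id) {
    expect_gt(length(feeding_genes(net, p)), 0)
  }
})

test_that("cohort generation is deterministic and honours group sizes", {
  net <- generate_network(network_spec(n_genes = 12, n_pathways = 3,
                                       reactions_per_pathway = 2, seed = 1))
  spec <- cohort_spec(group_sizes = c(malignant = 4, benign = 3, control = 2),
                      seed = 9)
  c1 <- generate_cohort(net, spec)
  c2 <- generate_cohort(net, spec)
  expect_identical(c1$expression, c2$expression)
  expect_equal(table(c1$labels$group)[c("malignant", "benign", "control")],
               table(factor(rep(c("malignant", "benign", "control"),
                                c(4, 3, 2)))) [c("malignant", "benign", "control")])
  expect_true(all(as.matrix(c1$expression[-1]) >= 0))
  # ground truth names the drivers and the multipliers
  expect_equal(c1$ground_truth$driver_pathways, net$pathways$id[1])
  expect_equal(c1$ground_truth$effect_multipliers$malignant, 2.0)
})

test_that("driver genes feed the driver pathway in activating roles only", {
  net <- generate_network(network_spec(n_genes = 30, n_pathways = 3,
                                       reactions_per_pathway = 4,
                                       inhibitor_fraction = 1, seed = 3))
  coh <- generate_cohort(net, cohort_spec(
    group_sizes = c(malignant = 2, benign = 2, control = 2), seed = 3))
  drivers <- coh$ground_truth$driver_genes
  p1 <- net$pathways$id[1]
  expect_setequal(drivers, feeding_genes(net, p1))
  # genes appearing only as inhibitor fuel are never drivers
  rids <- net$pathways$reaction_ids[[1]]
  act_genes <- character(); inh_genes <- character()
  for (i in match(rids, net$reactions$id)) {
    parts <- net$reactions$participants[[i]]
    for (j in seq_len(nrow(parts))) {
      sid <- parts$species_id[j]
      k <- match(sid, net$species$id)
      genes <- if (!is.na(k)) net$species$constituents[[k]] else sid
      if (parts$role[j] %in% c("i", "tr_r")) {
        inh_genes <- union(inh_genes, genes)
      } else {
        act_genes <- union(act_genes, genes)
      }
    }
  }
  inhibitor_only <- setdiff(inh_genes, act_genes)
  expect_length(intersect(inhibitor_only, drivers), 0)
})

test_that("multiplier ordering violations warn but equal multipliers stay silent", {
  expect_warning(
    cohort_spec(effect_multipliers = c(malignant = 1, benign = 2, control = 1)),
    "convention")
  expect_silent(
    cohort_spec(effect_multipliers = c(malignant = 1, benign = 1, control = 1)))
  expect_error(
    cohort_spec(effect_multipliers = c(malignant = -1, benign = 1, control = 1)),
    class = "imflux_validation_error")
  expect_error(
    cohort_spec(group_sizes = c(malignant = 0, benign = 0, control = 0)),
    class = "imflux_validation_error")
})

test_that("stronger malignant multipliers never reduce expected separation", {
  net <- generate_network(network_spec(n_genes = 20, n_pathways = 2,
                                       reactions_per_pathway = 3,
                                       crosstalk_density = 0, seed = 19))
  mean_auc <- vapply(c(1.2, 1.6, 2.2), function(mult) {
    aucs <- vapply(1:10, function(s) {
      coh <- generate_cohort(net, cohort_spec(
        group_sizes = c(malignant = 15, benign = 15, control = 0),
        effect_multipliers = c(malignant = mult, benign = 1, control = 1),
        seed = 100 + s))
      fm <- compute_flux_matrix(coh$expression, net)
      idx <- compute_im_index(fm, coh$labels)
      auc_midrank(idx$im_index, idx$group == "malignant")
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  expect_true(all(diff(mean_auc) >= -0.02))
})

test_that("fixture bundle is regenerable byte-identically and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture_bundle(d1)
  p2 <- write_fixture_bundle(d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  # loads through the public readers without warnings
  expect_no_warning({
    net <- read_network(p1[["network"]])
    expr <- read_expression(p1[["expression"]])
    labels <- read_labels(p1[["labels"]])
  })
  # the expected-flux file matches the production engine to 1e-9
  expected <- read_flux(p1[["expected_flux"]])
  fm <- compute_flux_matrix(expr, net)
  expect_equal(as.matrix(fm[-1]), as.matrix(expected[-1]), tolerance = 1e-9)
})
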