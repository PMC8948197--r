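# Independent brute-force oracles. These deliberately re-derive everything
# from the raw definitions with plain loops and no imflux internals, so they
# can stand as a second route against the package's implementations.

# Naive flux-matrix evaluator: per sample, per pathway, re-walk the network.
oracle_flux_matrix <- function(expr, net, floor = 0) {
  gene_ids <- expr$gene_id
  samples <- names(expr)[-1]
  sp <- net$species; rx <- net$reactions; pw <- net$pathways

  conc_of <- function(id, prof) {
    k <- which(sp$id == id)
    if (length(k) == 1) {
      if (sp$is_constant[k]) return(sp$constant_value[k])
      total <- 1
      for (g in sp$constituents[[k]]) {
        v <- if (g %in% names(prof)) prof[[g]] else floor
        total <- total * v
      }
      return(total)
    }
    if (id %in% prof_names) {
      return(prof[[id]])
    }
    floor
  }

  out <- matrix(NA_real_, nrow = length(samples), ncol = nrow(pw),
                dimnames = list(samples, pw$id))
  for (s in samples) {
    prof <- as.list(stats::setNames(expr[[s]], gene_ids))
    prof_names <- names(prof)
    rflux <- numeric(nrow(rx))
    names(rflux) <- rx$id
    for (i in seq_len(nrow(rx))) {
      f <- rx$rate_constant[i]
      p <- rx$participants[[i]]
      for (j in seq_len(nrow(p))) {
        cc <- conc_of(p$species_id[j], prof)
        if (p$role[j] %in% c("e", "g", "s", "tr_a")) {
          f <- f * cc
        } else {
          f <- f / (1 + cc)
        }
      }
      rflux[i] <- f
    }
    base <- numeric(nrow(pw))
    names(base) <- pw$id
    for (i in seq_len(nrow(pw))) {
      base[i] <- mean(rflux[pw$reaction_ids[[i]]])
    }
    for (i in seq_len(nrow(pw))) {
      ct <- pw$crosstalk_ids[[i]]
      out[s, i] <- if (length(ct) == 0) base[i] else base[i] - mean(base[ct])
    }
  }
  out
}

# AUC by explicit pair counting: concordant pairs count 1, ties 1/2.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Kruskal-Wallis H from the raw midrank formula with tie correction.
oracle_kruskal_h <- function(x, g) {
  n <- length(x)
  r <- rank(x)
  groups <- unique(g)
  h <- 12 / (n * (n + 1)) *
    sum(vapply(groups, function(k) {
      sum(r[g == k])^2 / sum(g == k)
    }, numeric(1))) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all group
# assignments (no ties; small n only).
oracle_wilcoxon_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(n, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * (n - nx) / 2
  # two-sided: as extreme or more, measured by distance from the mean
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}
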