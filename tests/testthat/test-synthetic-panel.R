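test_that("config validation rejects impossible panels", {
  expect_error(sim_config(n_markers_per_chrom = 0L), "at least one")
  expect_error(sim_config(missing_rate = 1.2), "rate parameters")
  expect_error(sim_config(n_accessions_per_pop = 0L), "positive")
  expect_error(sim_config(maf_floor = 0.6), "maf_floor")
})

test_that("generator is deterministic and respects the configured layout", {
  cfg <- sim_config(seed = 3L)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$truth$true_Q, s2$truth$true_Q)

  g <- s1$genotypes
  expect_equal(ncol(g$calls), sum(cfg$n_accessions_per_pop) + cfg$n_admixed)
  expect_equal(nrow(g$calls), cfg$n_chromosomes * cfg$n_markers_per_chrom)
  # positions strictly increasing within chromosome
  for (cc in unique(g$chrom))
    expect_true(all(diff(g$pos[g$chrom == cc]) > 0))
  # Q rows sum to one
  expect_equal(unname(rowSums(s1$truth$true_Q)), rep(1, ncol(g$calls)))
})

test_that("missing-data fraction matches the configured rate", {
  g <- simulate_genotypes(sim_config(seed = 11L))$genotypes
  expect_gt(length(g$calls), 10000)
  expect_lt(abs(mean(is.na(g$calls)) - 0.10), 0.01)
})

test_that("no drift means no differentiation; no recombination means clones", {
  # F_subsp = F_pop = 0: labeled groups are draws from one population
  sim <- simulate_genotypes(sim_config(
    populations_per_pool = c(1L, 1L), pop_fst = 0, pools_fst = 0,
    n_accessions_per_pop = 60L, n_admixed = 0L, n_chromosomes = 2L,
    n_markers_per_chrom = 500L, founder_haplotypes_per_pop = 200L,
    switch_rate = 1, missing_rate = 0, seed = 5L))
  fst <- pairwise_fst(sim$genotypes, sim$truth$pop_labels)[1, 2]
  expect_lt(abs(fst), 0.01)

  # switch_rate = 0 and a single founder: all accessions in a population
  # carry that founder's haplotype
  sim0 <- simulate_genotypes(sim_config(
    populations_per_pool = c(1L, 1L), pop_fst = 0.3, pools_fst = 0.2,
    n_accessions_per_pop = 10L, n_admixed = 0L, n_chromosomes = 2L,
    n_markers_per_chrom = 50L, founder_haplotypes_per_pop = 1L,
    switch_rate = 0, missing_rate = 0, seed = 6L))
  for (pop in c("I1", "J1")) {
    cols <- sim0$genotypes$calls[, sim0$truth$pop_labels == pop]
    expect_true(all(cols == cols[, 1]))
  }
})

test_that("Weir-Cockerham estimate matches the realized-frequency oracle", {
  sim <- two_pop_panel(f = 0.3, seed = 7L, missing_rate = 0.05)
  est <- pairwise_fst(sim$genotypes, sim$truth$pop_labels)[1, 2]
  p <- sim$truth$pop_freq
  expect_lt(abs(est - fst_oracle_from_freqs(p[, 1], p[, 2])), 0.05)
})

test_that("mean pool FST increases with the subspecies divergence parameter", {
  mean_fst <- vapply(c(0.1, 0.3, 0.5), function(fs) {
    sim <- simulate_genotypes(sim_config(
      populations_per_pool = c(1L, 1L), pop_fst = 0, pools_fst = fs,
      n_accessions_per_pop = 40L, n_admixed = 0L, n_chromosomes = 2L,
      n_markers_per_chrom = 400L, founder_haplotypes_per_pop = 100L,
      switch_rate = 1, missing_rate = 0, seed = 20L))
    pairwise_fst(sim$genotypes, sim$truth$pool_labels)[1, 2]
  }, 0)
  expect_true(all(diff(mean_fst) > 0))
})

test_that("fitted LD half-decay shortens as the switch rate grows", {
  half_decay <- vapply(c(2e-6, 6e-6, 2e-5), function(sw) {
    g <- ld_panel(sw, seed = 31L)
    fit <- fit_power_law(bin_r2(do.call(rbind, lapply(1:4, function(cc)
      pairwise_r2(g, cc)))))
    distance_at_r2(fit, 0.2)
  }, 0)
  expect_true(all(diff(half_decay) < 0))
})

test_that("phenotype realizes the requested variance fractions and is reproducible", {
  sim <- simulate_genotypes(sim_config(seed = 9L, n_qtl = 3L))
  ph1 <- simulate_phenotype(sim, qtl_variance = 0.3, pop_effect_sd = 5)
  ph2 <- simulate_phenotype(sim, qtl_variance = 0.3, pop_effect_sd = 5)
  expect_identical(ph1$phenotype, ph2$phenotype)
  expect_equal(ph1$truth$heritability, 0.3, tolerance = 1e-10)

  expect_error(simulate_phenotype(sim, qtl_variance = 1.0), "invalid config")

  # qtl_variance = 0, pop_effect_sd = 0: pure noise, flat QQ
  ph0 <- simulate_phenotype(sim, qtl_variance = 0, pop_effect_sd = 0)
  y <- setNames(ph0$phenotype$days_to_flowering, ph0$phenotype$accession_id)
  g <- maf_filter(filter_gbs(sim$genotypes)$matrix, 0.05)
  gi <- impute_missing(g, seed = 2L)$genotypes
  scan <- mlm_assoc(y, gi)
  qq <- qq_data(scan)
  expect_lt(abs(attr(qq, "lambda_gc") - 1), 0.2)
})

test_that("a planted 30%-variance QTL is detected in nearly all replicates", {
  detected <- vapply(1:10, function(s) {
    cfg <- sim_config(populations_per_pool = c(2L, 1L), pop_fst = 0.2,
                      pools_fst = 0, n_accessions_per_pop = 60L,
                      n_admixed = 0L, n_chromosomes = 3L,
                      n_markers_per_chrom = 100L, missing_rate = 0.05,
                      n_qtl = 1L, seed = 40L + s)
    sim <- simulate_phenotype(simulate_genotypes(cfg), qtl_variance = 0.3,
                              pop_effect_sd = 5)
    g <- maf_filter(filter_gbs(sim$genotypes)$matrix, 0.05)
    gi <- impute_missing(g, seed = s)$genotypes
    K <- kinship(gi)
    y <- setNames(sim$phenotype$days_to_flowering,
                  sim$phenotype$accession_id)
    scan <- mlm_assoc(y, gi, K = K)
    p <- scan$results$p_value[match(sim$truth$qtl_markers,
                                    scan$results$marker)]
    isTRUE(p < 5e-4)
  }, NA)
  expect_gte(sum(detected), 9L)
})

test_that("fixture files round-trip and record the planted truth", {
  outdir <- withr::local_tempdir()
  sim <- simulate_phenotype(simulate_genotypes(sim_config(seed = 2L)))
  files <- write_fixture(sim, outdir)
  expect_true(all(file.exists(files)))

  g2 <- read_hapmap(files[["genotypes"]])
  expect_identical(g2$calls, sim$genotypes$calls)
  expect_identical(g2$marker_ids, sim$genotypes$marker_ids)

  truth <- jsonlite::read_json(files[["truth"]])
  expect_identical(unlist(truth$qtl_markers), sim$truth$qtl_markers)

  ph <- read_tables(files[["phenotype"]], "phenotype")
  expect_identical(ph$accession_id, sim$phenotype$accession_id)
  pp <- read_tables(files[["passport"]], "passport")
  expect_true(all(pp$ecosystem %in% c("irrigated", "rainfed lowland",
                                      "upland", "mangrove", "unknown")))
})
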