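# Shared fixtures and small oracles, all built in code.

# tiny genotype matrix with known content
tiny_geno <- function() {
  calls <- rbind(
    c(0L, 1L, 0L, 1L),
    c(1L, 1L, NA, 0L),
    c(0L, 0L, 0L, 0L))
  geno_matrix(calls, c("m1", "m2", "m3"), c(1L, 1L, 2L),
              c(100L, 5000L, 200L), c("a1", "a2", "a3", "a4"),
              ref = c("A", "C", "G"), alt = c("G", "T", "A"))
}

# two-population panel with unlinked markers (independent draws per marker:
# founder pool as large as the panel, switch at every bp)
two_pop_panel <- function(f = 0.3, n_per_pop = 50L, n_markers = 2000L,
                          seed = 1L, missing_rate = 0) {
  cfg <- sim_config(populations_per_pool = c(1L, 1L), pop_fst = f,
                    pools_fst = 0, n_accessions_per_pop = n_per_pop,
                    n_admixed = 0L, n_chromosomes = 4L,
                    n_markers_per_chrom = as.integer(ceiling(n_markers / 4)),
                    founder_haplotypes_per_pop = 200L, switch_rate = 1,
                    missing_rate = missing_rate, seed = seed)
  simulate_genotypes(cfg)
}

# FST oracle computed directly from the realized simulated population
# frequencies (infinite-sample variance components, ratio of sums)
fst_oracle_from_freqs <- function(p1, p2) {
  num <- (p1 - p2)^2 / 2
  den <- num + (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  sum(num) / sum(den)
}

# additive distance matrix from a random topology with known branch lengths;
# returns the matrix and the generating tree
random_additive_matrix <- function(n_leaves, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  list(tree = tr, d = d[ord, ord])
}

as_dist_matrix <- function(d) {
  labs <- rownames(d)
  support <- matrix(1L, nrow(d), ncol(d), dimnames = dimnames(d))
  structure(list(labels = labs, d = d, pairwise_support = support),
            class = "dist_matrix")
}

# the mosaic switch rate whose theoretical binned decay curve, fitted with
# the same log-log power law, inverts to `target_bp` at r2 = 0.2; derivation:
# within one population with 2 founder haplotypes, r2(d) = exp(-2cd), sample
# r2 uplifted by (1-r2)^2/n_eff
calibrated_switch_rate <- function(target_bp = 1e5, n_eff = 90,
                                   max_d = 1e6, target_r2 = 0.2) {
  oracle_inv <- function(c_rate) {
    mids <- seq(12500, max_d - 12500, by = 25000)
    r2 <- exp(-2 * c_rate * mids)
    y <- r2 + (1 - r2)^2 / n_eff
    fit <- lm(log(y) ~ log(mids))
    unname((target_r2 / exp(coef(fit)[1]))^(1 / coef(fit)[2]))
  }
  uniroot(function(cc) oracle_inv(cc) - target_bp, c(1e-6, 2e-5),
          tol = 1e-12)$root
}

ld_panel <- function(switch_rate, seed, n_acc = 100L) {
  cfg <- sim_config(populations_per_pool = c(1L, 1L), pop_fst = 0,
                    pools_fst = 0,
                    n_accessions_per_pop = c(n_acc, 2L), n_admixed = 0L,
                    n_chromosomes = 4L, chrom_length_bp = 1e6,
                    n_markers_per_chrom = 100L,
                    founder_haplotypes_per_pop = 2L,
                    switch_rate = switch_rate, missing_rate = 0.05,
                    maf_floor = 0.2, seed = seed)
  sim <- simulate_genotypes(cfg)
  subset_geno(sim$genotypes,
              accessions = which(sim$truth$pop_labels == "I1"))
}

# three-population panel used for admixture-recovery checks
three_pop_panel <- function(seed, f = 0.3, n_per_pop = 30L) {
  sim_config(populations_per_pool = c(2L, 1L), pop_fst = f, pools_fst = 0,
             n_accessions_per_pop = n_per_pop, n_admixed = 0L,
             n_chromosomes = 4L, n_markers_per_chrom = 80L,
             missing_rate = 0.05, seed = seed)
}
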