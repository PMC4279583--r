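# Synthetic diversity panel with known ground truth.
#
# The generator emulates the structure of a two-subspecies rice panel:
# two deeply diverged gene pools (indica-like "I", japonica-like "J") each
# split into nested populations by Balding-Nichols drift, inbred accessions
# built as founder-haplotype mosaics (Li-Stephens-style copying, geometric
# segment lengths) so that within-population LD decays on a tunable physical
# scale, plus a configurable number of admixed accessions.

#' Configuration for the synthetic panel generator
#'
#' Defaults describe a 182-accession panel shaped like a Vietnamese rice
#' landrace collection: two subspecies pools split into 6 + 4 populations
#' (114 indica-like, 62 japonica-like accessions, 6 admixed), 12 chromosomes
#' with markers every ~17 kb, ~10% missing data and stronger drift among the
#' japonica-like populations.
#'
#' @param n_subspecies_pools number of top-level gene pools (fixed at 2).
#' @param pools_fst Balding-Nichols divergence of each pool from the
#'   ancestral frequencies (F_subsp, in \[0,1\]).
#' @param populations_per_pool integer vector: populations nested in each pool.
#' @param pop_fst per-population drift from the pool frequencies (recycled to
#'   the total number of populations).
#' @param n_accessions_per_pop accessions per population (recycled likewise).
#' @param n_admixed number of two-population admixed accessions.
#' @param n_chromosomes,chrom_length_bp,n_markers_per_chrom genome layout;
#'   markers are equally spaced with jitter (~17 kb spacing by default).
#' @param founder_haplotypes_per_pop founder haplotypes each population's
#'   accessions copy from.
#' @param switch_rate per-bp probability of switching founder while copying;
#'   controls the LD-decay scale (smaller = longer-range LD).
#' @param missing_rate fraction of calls masked completely at random.
#' @param maf_floor minimum ancestral allele frequency (frequencies are drawn
#'   Uniform(maf_floor, 1 - maf_floor)).
#' @param n_qtl number of flowering-time QTLs planted among common markers.
#' @param seed master RNG seed; every downstream draw derives from it.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_subspecies_pools = 2L,
                       pools_fst = 0.40,
                       populations_per_pool = c(6L, 4L),
                       pop_fst = c(0.25, 0.30, 0.35, 0.30, 0.40, 0.50,
                                   0.45, 0.50, 0.55, 0.60),
                       n_accessions_per_pop = c(30L, 25L, 20L, 15L, 13L, 11L,
                                                20L, 17L, 13L, 12L),
                       n_admixed = 6L,
                       n_chromosomes = 12L,
                       chrom_length_bp = 2.55e6,
                       n_markers_per_chrom = 150L,
                       founder_haplotypes_per_pop = 6L,
                       switch_rate = 5e-6,
                       missing_rate = 0.10,
                       maf_floor = 0.05,
                       n_qtl = 3L,
                       seed = 1L) {
  if (n_subspecies_pools != 2L)
    stop("the generator models exactly two subspecies pools")
  if (length(populations_per_pool) != 2L || any(populations_per_pool < 1L))
    stop("populations_per_pool must give a positive count for each pool")
  n_pops <- sum(populations_per_pool)
  pop_fst <- rep_len(pop_fst, n_pops)
  n_accessions_per_pop <- rep_len(as.integer(n_accessions_per_pop), n_pops)
  rates <- c(pools_fst, pop_fst, switch_rate, missing_rate, maf_floor)
  if (any(rates < 0 | rates > 1))
    stop("all rate parameters must lie in [0, 1]")
  if (maf_floor >= 0.5) stop("maf_floor must be below 0.5")
  if (n_chromosomes < 1L || n_markers_per_chrom < 1L)
    stop("invalid config: need at least one chromosome and one marker")
  if (any(n_accessions_per_pop < 1L) || n_admixed < 0L)
    stop("invalid config: accession counts must be positive")
  structure(list(
    n_subspecies_pools = 2L,
    pools_fst = pools_fst,
    populations_per_pool = as.integer(populations_per_pool),
    pop_fst = pop_fst,
    n_accessions_per_pop = n_accessions_per_pop,
    n_admixed = as.integer(n_admixed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    founder_haplotypes_per_pop = as.integer(founder_haplotypes_per_pop),
    switch_rate = as.numeric(switch_rate),
    missing_rate = as.numeric(missing_rate),
    maf_floor = as.numeric(maf_floor),
    n_qtl = as.integer(n_qtl),
    seed = as.integer(seed)
  ), class = "sim_config")
}

balding_nichols <- function(p, f) {
  # Beta((1-F)/F * p, (1-F)/F * (1-p)); F = 0 degenerates to p itself
  if (f <= 0) return(p)
  if (f >= 1) return(as.numeric(runif(length(p)) < p))
  a <- (1 - f) / f
  rbeta(length(p), a * p, a * (1 - p))
}

# founder index path along one chromosome: switch with prob 1-exp(-c*d)
# between adjacent markers, then re-draw the founder uniformly
copy_path <- function(n_markers, gaps, n_founders, switch_rate) {
  idx <- integer(n_markers)
  idx[1] <- sample.int(n_founders, 1L)
  if (n_markers > 1L) {
    sw <- runif(n_markers - 1L) < (1 - exp(-switch_rate * gaps))
    for (j in seq_len(n_markers - 1L)) {
      idx[j + 1L] <- if (sw[j]) sample.int(n_founders, 1L) else idx[j]
    }
  }
  idx
}

#' Simulate a structured inbred genotype panel
#'
#' Draws ancestral allele frequencies Uniform(`maf_floor`, 1 - `maf_floor`),
#' pool frequencies by Balding-Nichols drift at `pools_fst`, population
#' frequencies by Balding-Nichols drift at `pop_fst` around their pool, then
#' samples founder haplotypes site-wise from the population frequencies and
#' builds each inbred accession as a single haplotype copied from the
#' founders with per-bp switch probability `switch_rate` (geometric segment
#' lengths), duplicated to homozygosity (haploid coding). Admixed accessions
#' copy founders from two randomly chosen populations with a random mixture
#' weight. Missing calls are masked completely at random. Everything is
#' deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list of class `panel_sim` with elements
#'   \describe{
#'     \item{genotypes}{a [geno_matrix()] (markers x accessions).}
#'     \item{truth}{ground truth: `true_Q` (accessions x populations),
#'       `pop_labels`, `pool_labels`, `pop_freq` (markers x populations
#'       realized frequencies), planted `qtl_positions` / `qtl_effects` /
#'       complete `qtl_geno`, the waxy endosperm locus, and `heritability`
#'       (filled by [simulate_phenotype()]).}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n_pops <- sum(cfg$populations_per_pool)
    pop_pool <- rep(1:2, cfg$populations_per_pool)
    pop_names <- unlist(lapply(1:2, function(p)
      paste0(c("I", "J")[p], seq_len(cfg$populations_per_pool[p]))))
    m_chr <- cfg$n_markers_per_chrom
    m <- m_chr * cfg$n_chromosomes
    spacing <- cfg$chrom_length_bp / m_chr

    chrom <- rep(seq_len(cfg$n_chromosomes), each = m_chr)
    pos <- unlist(lapply(seq_len(cfg$n_chromosomes), function(cc) {
      p <- round((seq_len(m_chr) - 1) * spacing +
                   runif(m_chr, 0.05, 0.95) * spacing)
      p <- pmax(p, seq_len(m_chr))            # guard degenerate tiny spacing
      as.integer(cummax(p) + cumsum(c(0, diff(cummax(p)) == 0)))
    }))

    p_anc <- runif(m, cfg$maf_floor, 1 - cfg$maf_floor)
    p_pool <- sapply(1:2, function(k) balding_nichols(p_anc, cfg$pools_fst))
    p_pop <- sapply(seq_len(n_pops), function(k)
      balding_nichols(p_pool[, pop_pool[k]], cfg$pop_fst[k]))
    p_pop <- matrix(p_pop, nrow = m)

    nf <- cfg$founder_haplotypes_per_pop
    founders <- lapply(seq_len(n_pops), function(k)
      matrix(rbinom(m * nf, 1L, p_pop[, k]), nrow = m, ncol = nf))

    n_pure <- sum(cfg$n_accessions_per_pop)
    n <- n_pure + cfg$n_admixed
    calls <- matrix(NA_integer_, m, n)
    chr_index <- split(seq_len(m), chrom)
    gaps <- lapply(chr_index, function(ii) diff(pos[ii]))

    pop_of <- rep(seq_len(n_pops), cfg$n_accessions_per_pop)
    true_Q <- matrix(0, n, n_pops, dimnames = list(NULL, pop_names))
    pop_labels <- character(n)
    for (i in seq_len(n_pure)) {
      k <- pop_of[i]
      hap <- integer(m)
      for (cc in seq_along(chr_index)) {
        ii <- chr_index[[cc]]
        path <- copy_path(length(ii), gaps[[cc]], nf, cfg$switch_rate)
        hap[ii] <- founders[[k]][cbind(ii, path)]
      }
      calls[, i] <- hap
      true_Q[i, k] <- 1
      pop_labels[i] <- pop_names[k]
    }
    if (cfg$n_admixed > 0L) {
      for (a in seq_len(cfg$n_admixed)) {
        i <- n_pure + a
        ks <- sample.int(n_pops, 2L)
        w <- runif(1, 0.25, 0.75)
        hap <- integer(m)
        for (cc in seq_along(chr_index)) {
          ii <- chr_index[[cc]]
          path <- copy_path(length(ii), gaps[[cc]], nf, cfg$switch_rate)
          # each copied segment comes from pop ks[1] with prob w
          seg <- c(TRUE, path[-1] != path[-length(path)])
          seg_pop <- ks[1 + (runif(sum(seg)) > w)]
          from <- rep(seg_pop, diff(c(which(seg), length(ii) + 1L)))
          hap[ii] <- ifelse(from == ks[1],
                            founders[[ks[1]]][cbind(ii, path)],
                            founders[[ks[2]]][cbind(ii, path)])
        }
        calls[, i] <- hap
        true_Q[i, ks[1]] <- w
        true_Q[i, ks[2]] <- 1 - w
        pop_labels[i] <- "admixed"
      }
    }

    accession_ids <- sprintf("ACC%03d", seq_len(n))
    marker_ids <- sprintf("S%02d_%08d", chrom, pos)

    # plant QTLs and the waxy endosperm locus among common markers that
    # also segregate within populations: a locus fixed differentially
    # between populations is collinear with structure and its effect is
    # unidentifiable under a structure-corrected association model
    p_obs <- rowMeans(calls)
    within_het <- rowMeans(p_pop * (1 - p_pop))
    common <- which(pmin(p_obs, 1 - p_obs) > 0.10 & within_het > 0.08)
    if (!length(common)) common <- which(pmin(p_obs, 1 - p_obs) > 0.10)
    n_qtl <- min(cfg$n_qtl, length(common))
    qtl_idx <- if (n_qtl > 0L) sort(sample(common, n_qtl)) else integer(0)
    qtl_effects <- if (n_qtl > 0L)
      3 * rep_len(c(1, -1), n_qtl) * runif(n_qtl, 0.7, 1.3) else numeric(0)
    waxy_idx <- if (length(setdiff(common, qtl_idx)) > 0L)
      sample(setdiff(common, qtl_idx), 1L) else NA_integer_

    qtl_geno <- calls[qtl_idx, , drop = FALSE]
    waxy_geno <- if (!is.na(waxy_idx)) calls[waxy_idx, ] else NULL

    if (cfg$missing_rate > 0) {
      # GBS missingness is strongly marker-heterogeneous: per-marker rates
      # drawn Beta(0.5, .) with mean missing_rate, cells masked at random
      # within marker; many markers end up nearly complete, some very holey
      mu <- cfg$missing_rate
      rate_l <- rbeta(m, 0.5, 0.5 * (1 - mu) / mu)
      mask <- matrix(runif(m * n) < rate_l, m, n)
      calls[mask] <- NA_integer_
    }

    g <- geno_matrix(calls, marker_ids, chrom, pos, accession_ids)
    # geno_matrix sorts by (chrom, pos) which is already the build order
    truth <- list(
      true_Q = `rownames<-`(true_Q, accession_ids),
      pop_labels = setNames(pop_labels, accession_ids),
      pool_labels = setNames(
        c(c("indica", "japonica")[pop_pool[pop_of]],
          rep("admixed", cfg$n_admixed)), accession_ids),
      pop_names = pop_names,
      pop_freq = `colnames<-`(p_pop, pop_names),
      anc_freq = p_anc,
      qtl_positions = qtl_idx,
      qtl_markers = marker_ids[qtl_idx],
      qtl_effects = qtl_effects,
      qtl_geno = qtl_geno,
      waxy_index = waxy_idx,
      waxy_marker = if (!is.na(waxy_idx)) marker_ids[waxy_idx] else NA_character_,
      waxy_geno = waxy_geno,
      heritability = NA_real_
    )
    structure(list(genotypes = g, truth = truth, config = cfg),
              class = "panel_sim")
  })
}

#' Simulate phenotypes on a synthetic panel
#'
#' Days to flowering is built as grand mean + planted QTL allele effects +
#' population effect + Gaussian noise. Components are rescaled so the
#' *realized* variance fractions match the request exactly: the QTL
#' component explains `qtl_variance` of the total phenotypic variance and
#' population effects have realized standard deviation `pop_effect_sd` (in
#' days). Grain length/width (mm, pool-typical means) and a biallelic waxy
#' endosperm locus (iodine-test color) are also emitted.
#'
#' @param sim a `panel_sim` from [simulate_genotypes()].
#' @param qtl_variance fraction of phenotypic variance explained jointly by
#'   the planted QTLs, in \[0, 1).
#' @param pop_effect_sd standard deviation of population effects, in days.
#' @param resid_sd residual standard deviation, in days (default 8).
#' @param seed RNG seed (defaults to a substream of the config seed).
#' @return the `panel_sim` with `$phenotype` (data frame: `accession_id`,
#'   `days_to_flowering`, `grain_length_mm`, `grain_width_mm`, `endosperm`)
#'   and `truth$heritability` filled with the realized QTL variance fraction.
#' @export
simulate_phenotype <- function(sim, qtl_variance = 0.3, pop_effect_sd = 5,
                               resid_sd = 8, seed = NULL) {
  stopifnot(inherits(sim, "panel_sim"))
  if (qtl_variance < 0 || qtl_variance >= 1)
    stop("invalid config: qtl_variance must lie in [0, 1)")
  if (pop_effect_sd < 0 || resid_sd <= 0)
    stop("invalid config: negative variance component")
  if (is.null(seed)) seed <- substream_seed(sim$config$seed, "phenotype")
  truth <- sim$truth
  n <- length(truth$pop_labels)
  with_seed(seed, {
    # population effects (admixed accessions get their Q-weighted mixture)
    n_pops <- ncol(truth$true_Q)
    pop_eff_raw <- rnorm(n_pops)
    z <- as.numeric(truth$true_Q %*% pop_eff_raw)
    if (pop_effect_sd > 0 && sd(z) > 0) z <- z / sd(z) * pop_effect_sd
    else z <- rep(0, n)

    g <- rep(0, n)
    if (qtl_variance > 0) {
      if (length(truth$qtl_positions) == 0L)
        stop("qtl_variance > 0 requested but no QTLs were planted")
      g <- as.numeric(crossprod(truth$qtl_geno, truth$qtl_effects))
      if (var(g) == 0) stop("planted QTLs are monomorphic; cannot scale")
    }
    e <- rnorm(n)
    e <- e / sd(e) * resid_sd
    if (qtl_variance > 0) {
      # realized fraction: Vq / (Vq + Vp + Ve) = qtl_variance
      vq_target <- qtl_variance * (var(z) + var(e)) / (1 - qtl_variance)
      g <- (g - mean(g)) / sd(g) * sqrt(vq_target)
    }
    days <- 110 + g + z + e
    realized_h2 <- if (qtl_variance > 0)
      var(g) / (var(g) + var(z) + var(e)) else 0

    pool <- truth$pool_labels
    base_l <- ifelse(pool == "japonica", 5.8, 7.2)
    base_w <- ifelse(pool == "japonica", 3.3, 2.2)
    grain_l <- pmax(3, base_l + rnorm(n, 0, 0.35))
    grain_w <- pmax(1.2, base_w + rnorm(n, 0, 0.18))

    endo <- rep("unknown", n)
    if (!is.null(truth$waxy_geno))
      endo <- ifelse(truth$waxy_geno == 1L, "dark-blue", "brown")

    sim$phenotype <- data.frame(
      accession_id = names(truth$pop_labels),
      days_to_flowering = round(days, 4),
      grain_length_mm = round(grain_l, 4),
      grain_width_mm = round(grain_w, 4),
      endosperm = endo,
      stringsAsFactors = FALSE
    )
    sim$truth$heritability <- realized_h2
    sim
  })
}

REGION_POOL <- c("Northern Mountains", "Red River Delta", "North Central Coast",
                 "South Central Coast", "Central Highlands", "Mekong Delta")
ECO_POOL <- c("irrigated", "rainfed lowland", "upland", "mangrove")

# passport metadata with planted population-specific multinomials: each
# population favors one region and one ecosystem (70% weight)
simulate_passport <- function(sim, seed = NULL) {
  if (is.null(seed)) seed <- substream_seed(sim$config$seed, "passport")
  truth <- sim$truth
  with_seed(seed, {
    pops <- truth$pop_names
    fav_region <- setNames(REGION_POOL[(seq_along(pops) - 1L) %% length(REGION_POOL) + 1L], pops)
    fav_eco <- setNames(ECO_POOL[(seq_along(pops) - 1L) %% length(ECO_POOL) + 1L], pops)
    draw <- function(fav, universe) {
      if (runif(1) < 0.7) fav else sample(universe, 1L)
    }
    lab <- truth$pop_labels
    region <- vapply(lab, function(l)
      if (l == "admixed") sample(REGION_POOL, 1L)
      else draw(fav_region[[l]], REGION_POOL), "")
    eco <- vapply(lab, function(l)
      if (l == "admixed") sample(ECO_POOL, 1L)
      else draw(fav_eco[[l]], ECO_POOL), "")
    vt <- sample(c("traditional", "improved"), length(lab), replace = TRUE,
                 prob = c(0.8, 0.2))
    data.frame(accession_id = names(lab), region = region, ecosystem = eco,
               varietal_type = vt, stringsAsFactors = FALSE)
  })
}

#' Write a simulated panel as plain-text fixture files
#'
#' Emits `genotypes.hmp.txt` (hapmap dialect), `passport.csv`,
#' `phenotype.csv` and `truth.json` into `outdir`. The genotype file
#' round-trips losslessly through [read_hapmap()] / [write_hapmap()].
#'
#' @param sim a `panel_sim`; run [simulate_phenotype()] first if phenotypes
#'   are wanted (otherwise a phenotype file with default settings is built).
#' @param outdir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_fixture <- function(sim, outdir) {
  stopifnot(inherits(sim, "panel_sim"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(sim$phenotype)) sim <- simulate_phenotype(sim)
  files <- c(genotypes = file.path(outdir, "genotypes.hmp.txt"),
             passport = file.path(outdir, "passport.csv"),
             phenotype = file.path(outdir, "phenotype.csv"),
             truth = file.path(outdir, "truth.json"))
  write_hapmap(sim$genotypes, files[["genotypes"]])
  write.table(simulate_passport(sim), files[["passport"]], sep = ",",
              quote = FALSE, row.names = FALSE, eol = "\n")
  write.table(sim$phenotype, files[["phenotype"]], sep = ",",
              quote = FALSE, row.names = FALSE, eol = "\n")
  truth <- sim$truth
  jsonlite::write_json(list(
    pop_labels = as.list(truth$pop_labels),
    pool_labels = as.list(truth$pool_labels),
    true_Q = unname(apply(truth$true_Q, 1L, function(r) as.list(r))),
    pop_names = truth$pop_names,
    qtl_markers = truth$qtl_markers,
    qtl_effects = truth$qtl_effects,
    waxy_marker = truth$waxy_marker,
    heritability = truth$heritability,
    seed = sim$config$seed
  ), files[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
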