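# End-to-end orchestration: simulate or ingest -> QC -> tree/selection ->
# structure -> FST -> LD -> GWAS -> characterization, with a single master
# seed expanded into per-stage substreams and a manifest of every artifact.

#' Pipeline configuration
#'
#' Assembles and validates the full-analysis configuration. Defaults equal
#' the standard workflow thresholds: quality P >= 0.8 and <= 10% missing for
#' DArT markers, <= 20% missing for GBS markers, < 2.5% missing and >= 100 kb
#' spacing for the structure subset, membership threshold q > 0.75, 1000
#' permutations for FST, MAF > 10% and 25-kb classes for LD, MAF >= 5% and
#' P < 5e-4 for GWAS. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults listed above (see the source for the
#'   full set of keys).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # input: either a simulation block or file paths
    simulate = TRUE,
    sim = sim_config(),
    genotype_file = NULL, passport_file = NULL, phenotype_file = NULL,
    # QC
    gbs_max_missing = 0.20,
    # structure
    structure_max_missing = 0.025, structure_min_spacing = 1e5,
    k_max = 10L, replicates = 10L, assign_threshold = 0.75,
    # tree / core selection
    n_keep = NULL,
    # FST
    n_permutations = 1000L,
    # LD
    ld_maf = 0.10, ld_bin = 25e3, ld_targets = c(0.1, 0.2),
    # GWAS
    gwas_maf = 0.05, gwas_alpha = 5e-4, impute_window = 20L,
    trait = "days_to_flowering",
    seed = 1L,
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (!cfg$simulate && is.null(cfg$genotype_file))
    stop("either simulate = TRUE or a genotype_file is required")
  stopifnot(cfg$gbs_max_missing >= 0, cfg$gbs_max_missing <= 1,
            cfg$assign_threshold > 0, cfg$assign_threshold < 1,
            cfg$k_max >= 2L, cfg$replicates >= 1L)
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  path
}

#' Run the full panel-characterization pipeline
#'
#' Executes the stages in dependency order, writing every artifact (TSV /
#' newick / JSON) plus a `manifest.json` with parameters, seed and file
#' checksums into `out_dir`. Reruns with the same configuration and seed are
#' bit-identical for the deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param quiet suppress progress messages.
#' @return list with the in-memory stage results and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir)) config$out_dir <- out_dir
  if (is.null(config$out_dir)) config$out_dir <- tempfile("panelforge_run_")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  seed <- config$seed
  say <- function(...) if (!quiet) message("[panelforge] ", sprintf(...))
  files <- character(0)
  res <- list(config = config)
  stage <- "input"
  tryCatch({
    # ---- input ----
    if (config$simulate) {
      say("simulating panel (seed %d)", config$sim$seed)
      sim <- simulate_phenotype(simulate_genotypes(config$sim))
      files <- c(files, write_fixture(sim, file.path(od, "fixture")))
      g <- sim$genotypes
      passport <- simulate_passport(sim)
      phenotype <- sim$phenotype
      res$sim <- sim
    } else {
      say("reading %s", config$genotype_file)
      g <- read_hapmap(config$genotype_file)
      passport <- if (!is.null(config$passport_file))
        read_tables(config$passport_file, "passport") else NULL
      phenotype <- if (!is.null(config$phenotype_file))
        read_tables(config$phenotype_file, "phenotype") else NULL
    }

    # ---- QC ----
    stage <- "qc"
    qc <- filter_gbs(g, max_missing = config$gbs_max_missing)
    g <- qc$matrix
    dens <- density_report(g)
    res$qc <- qc$report
    res$density <- dens
    files <- c(files, write_tsv(dens$per_chromosome, file.path(od, "density.tsv")))
    say("QC: %d/%d markers kept", qc$report$n_kept, qc$report$n_input)

    # ---- distance tree ----
    stage <- "tree"
    dm <- shared_allele_distance(g)
    tr <- nj_tree(dm)
    res$tree <- tr
    files <- c(files, {
      p <- file.path(od, "nj_tree.nwk")
      writeLines(ape::write.tree(tr), p)
      p
    })
    if (!is.null(config$n_keep)) {
      sel <- max_length_subtree(dm, config$n_keep)
      res$core <- sel
      files <- c(files, write_tsv(data.frame(accession_id = sel$kept),
                                  file.path(od, "core_selection.tsv")))
    }

    # ---- structure ----
    stage <- "structure"
    sub <- subset_markers(g, config$structure_max_missing,
                          config$structure_min_spacing,
                          seed = substream_seed(seed, "subset"))
    gs <- subset_geno(g, markers = sub)
    say("structure: %d markers in subset, K grid 1..%d x %d",
        length(sub), config$k_max, config$replicates)
    runs <- run_grid(gs, K_max = config$k_max, replicates = config$replicates,
                     seed = substream_seed(seed, "structure"))
    ev <- evanno_delta_k(runs)
    best_k <- attr(ev, "best_K")
    cand <- runs$runs[runs$runs$K == best_k & runs$runs$converged, ]
    best_rep <- cand$replicate[which.max(cand$loglik)]
    fit <- runs$fits[[sprintf("%d/%d", best_k, best_rep)]]
    assignments <- assign_populations(fit$Q, config$assign_threshold)
    res$structure <- list(runs = runs$runs, evanno = ev, best_K = best_k,
                          fit = fit, assignments = assignments)
    files <- c(files,
               write_tsv(runs$runs, file.path(od, "structure_runs.tsv")),
               write_tsv(ev, file.path(od, "evanno.tsv")),
               write_tsv(data.frame(accession_id = rownames(fit$Q), fit$Q,
                                    assignment = assignments,
                                    check.names = FALSE),
                         file.path(od, "q_matrix.tsv")))
    say("structure: best K = %d, %d admixed", best_k,
        sum(assignments == "admixed"))

    # ---- FST ----
    stage <- "fst"
    sizes <- table(assignments[assignments != "admixed"])
    if (length(sizes) >= 2L && all(sizes >= 2L)) {
      fst <- fst_permutation_test(gs, assignments,
                                  n_perm = config$n_permutations,
                                  seed = substream_seed(seed, "fst"))
      res$fst <- fst
      files <- c(files, {
        p <- file.path(od, "fst.tsv")
        write_fst_table(fst, p)
        p
      })
    } else say("fst: skipped (fewer than two populations of size >= 2)")

    # ---- LD ----
    stage <- "ld"
    pools <- split(names(assignments), assignments)
    pools <- pools[names(pools) != "admixed"]
    res$ld <- list()
    panel_sets <- c(list(panel = g$accession_ids),
                    if (length(pools) >= 2L) pools)
    for (nm in names(panel_sets)) {
      rep_ld <- decay_report(g, accessions = panel_sets[[nm]],
                             targets = config$ld_targets,
                             maf_min = config$ld_maf,
                             bin_width = config$ld_bin)
      res$ld[[nm]] <- rep_ld
      files <- c(files, write_tsv(rep_ld$table,
                                  file.path(od, sprintf("ld_%s.tsv", nm))))
    }

    # ---- GWAS ----
    stage <- "gwas"
    if (!is.null(phenotype) && config$trait %in% names(phenotype)) {
      gg <- maf_filter(g, config$gwas_maf)
      imp <- impute_missing(gg, window = config$impute_window,
                            seed = substream_seed(seed, "impute"))
      gi <- imp$genotypes
      Kmat <- kinship(gi)
      y <- setNames(phenotype[[config$trait]], phenotype$accession_id)
      scan <- mlm_assoc(y, gi, Q = fit$Q, K = Kmat)
      hits <- significant_hits(list(panel = scan), alpha = config$gwas_alpha)
      res$gwas <- list(panel = scan)
      res$hits <- hits
      files <- c(files,
                 write_tsv(scan$results, file.path(od, "gwas_panel.tsv")),
                 write_tsv(hits, file.path(od, "gwas_hits.tsv")),
                 write_tsv(qq_data(scan), file.path(od, "gwas_qq_panel.tsv")))
      # subpanels: the two-subspecies level of the structure analysis
      cand2 <- runs$runs[runs$runs$K == 2L & runs$runs$converged, ]
      rep2 <- cand2$replicate[which.max(cand2$loglik)]
      fit2 <- runs$fits[[sprintf("2/%d", rep2)]]
      pool_assign <- assign_populations(fit2$Q, config$assign_threshold)
      subp <- subpanel_split(g, pool_assign, maf_min = config$gwas_maf)
      for (nm in names(subp$matrices)) {
        gsub <- subp$matrices[[nm]]
        if (ncol(gsub$calls) < 10L) next
        imps <- impute_missing(gsub, window = config$impute_window,
                               seed = substream_seed(seed, paste0("impute-", nm)))
        Ks <- kinship(imps$genotypes)
        ys <- y[imps$genotypes$accession_ids]
        scan_s <- mlm_assoc(ys, imps$genotypes, Q = NULL, K = Ks)
        res$gwas[[nm]] <- scan_s
        files <- c(files, write_tsv(scan_s$results,
                                    file.path(od, sprintf("gwas_%s.tsv", nm))))
      }
      res$hits <- significant_hits(res$gwas, alpha = config$gwas_alpha)
      say("gwas: %d hit(s) at P < %g", nrow(res$hits), config$gwas_alpha)
    }

    # ---- characterization ----
    stage <- "characterize"
    if (!is.null(passport) || !is.null(phenotype)) {
      tabs <- characterize_populations(assignments, passport, phenotype)
      res$characterization <- tabs
      for (nm in names(tabs))
        files <- c(files, write_tsv(
          data.frame(level = rownames(tabs[[nm]]), tabs[[nm]],
                     check.names = FALSE),
          file.path(od, sprintf("table1_%s.tsv", nm))))
    }
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  # ---- manifest ----
  files <- unique(unname(files))
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    parameters = config[setdiff(names(config), c("sim", "out_dir"))],
    sim = if (config$simulate) unclass(config$sim) else NULL,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  res$manifest <- manifest
  res$out_dir <- od
  invisible(res)
}

#' Split a panel into subspecies subpanels
#'
#' Builds one genotype matrix per assigned population group (collapsing
#' population labels to their subpanel prefix when `group_map` is given),
#' excluding admixed accessions, and re-filters each subpanel with the
#' GWAS MAF rule so markers that became monomorphic or rare within a
#' subpanel are dropped.
#'
#' @param g a [geno_matrix()].
#' @param assignments named population labels (admixed excluded).
#' @param group_map optional named vector mapping population label ->
#'   subpanel name; by default the leading non-digit prefix of the label is
#'   used (so populations `I1..I6` form subpanel `I`).
#' @param maf_min subpanel MAF threshold (default 0.05).
#' @param min_size warn when a subpanel has fewer accessions than this.
#' @return list with `matrices` (named list of [geno_matrix()]) and
#'   `counts` (accessions per subpanel, admixed included under
#'   `"admixed"`).
#' @export
subpanel_split <- function(g, assignments, group_map = NULL, maf_min = 0.05,
                           min_size = 10L) {
  stopifnot(inherits(g, "geno_matrix"))
  lab <- assignments[g$accession_ids]
  if (is.null(group_map)) {
    collapsed <- sub("[0-9]+$", "", lab[lab != "admixed"])
    # collapse I1..I6 -> I, J1..J4 -> J, but keep labels as-is when the
    # prefixes are not informative (e.g. P1/P2 would all collapse to P)
    use_prefix <- length(unique(collapsed)) > 1L
    grp <- ifelse(lab == "admixed", "admixed",
                  if (use_prefix) sub("[0-9]+$", "", lab) else lab)
  } else {
    grp <- ifelse(lab == "admixed", "admixed", group_map[lab])
  }
  out <- list()
  for (nm in sort(setdiff(unique(grp), "admixed"))) {
    acc <- which(grp == nm)
    if (length(acc) < min_size)
      warning(sprintf("subpanel %s has only %d accessions", nm, length(acc)))
    sub <- subset_geno(g, accessions = acc)
    out[[nm]] <- tryCatch(maf_filter(sub, maf_min),
                          error = function(e) sub)
  }
  list(matrices = out, counts = table(grp))
}
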