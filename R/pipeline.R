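#' Default pipeline configuration
#'
#' Flat list of stage toggles and module parameters consumed by
#' [run_pipeline()]. Any element can be overridden by passing a named list
#' (or a YAML file path) to `run_pipeline()`; the effective configuration
#' is serialized into the output directory so every run is reproducible
#' from its artifacts.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "snps", "paint", "cluster", "flux",
               "pangenome", "rmin"),
    seed = 1L,
    out = "phageflux_run",
    # simulate
    n_pops = 3L, pop_sizes = c(6L, 6L, 6L), genome_len = 20000L,
    divergence = 0.02, mutation_rate = 5e-4, segment_mean = 2000L,
    migration = NULL,                 # NULL -> identity
    # paint
    switch_scale = NULL, miscopy = NULL,    # NULL -> estimate_params()
    # cluster
    burn_in = 5000L, iterations = 5000L, dirichlet_beta = 1,
    # flux
    flux_denominator = "all",
    # pangenome
    identity = 70, split_paralogs = FALSE,
    n_gene_families = 6L, family_identity = 75, n_genomes = 10L,
    # rmin / regression genes
    n_genes = 8L, gene_sites = 400L, gene_crossovers = 3L,
    # inputs for real (non-simulated) data
    alignment = NULL, labels = NULL
  )
}

#' Run the full analysis pipeline
#'
#' Executes, as toggled in `config$stages`: synthetic-data simulation (or
#' loading of a user alignment), core-SNP extraction, chromosome painting,
#' partition MCMC with merge tree, inter-population flux with a Wilcoxon
#' comparison, the pan-genome sweep, and the gene-level rmin/regression
#' stage. Every stage writes its tabular outputs into `config$out` and a
#' manifest records the artifacts; outputs are pure functions of (inputs,
#' config, seed).
#'
#' @param config named list overriding [default_config()], or a path to a
#'   YAML file with such a list.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_config(), config)
  stages <- cfg$stages
  if (!"simulate" %in% stages && is.null(cfg$alignment)) {
    if (any(c("snps", "paint", "cluster", "flux", "rmin") %in% stages)) {
      stop("config error: no 'simulate' stage and no input alignment",
           call. = FALSE)
    }
  }
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    cfg[!vapply(cfg, is.function, TRUE)],
    file.path(cfg$out, "config.json"), auto_unbox = TRUE, null = "null")
  res <- list()
  manifest <- character()
  emit <- function(path) manifest <<- c(manifest, path)

  if ("simulate" %in% stages) {
    sc <- sim_config(
      n_pops = cfg$n_pops, pop_sizes = cfg$pop_sizes,
      genome_len = cfg$genome_len, divergence = cfg$divergence,
      migration = if (is.null(cfg$migration)) diag(cfg$n_pops) else
        matrix(unlist(cfg$migration), cfg$n_pops, byrow = TRUE),
      mutation_rate = cfg$mutation_rate, segment_mean = cfg$segment_mean,
      seed = cfg$seed)
    sim <- simulate_populations(sc)
    res$sim <- sim
    emit(write_alignment(sim$alignment,
                         file.path(cfg$out, "genomes.fasta")))
    utils::write.table(
      data.frame(sample = names(sim$labels),
                 population = unname(sim$labels)),
      file.path(cfg$out, "labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    emit(file.path(cfg$out, "labels.tsv"))
    aln <- sim$alignment
    labels <- sim$labels
  } else if (!is.null(cfg$alignment)) {
    aln <- read_alignment(cfg$alignment, alphabet = "nt")
    labels <- if (!is.null(cfg$labels)) read_labels(cfg$labels) else NULL
    aln$labels <- labels
  }

  if ("snps" %in% stages) {
    res$snps <- extract_core_snps(aln)
    emit(write_snp_tsv(res$snps, file.path(cfg$out, "core_snps.tsv")))
  }

  if ("paint" %in% stages) {
    params <- estimate_params(res$snps, switch_scale = cfg$switch_scale,
                              miscopy = cfg$miscopy)
    res$coancestry <- coancestry(res$snps, params)
    emit(write_coancestry(res$coancestry,
                          file.path(cfg$out, "coancestry.tsv")))
  }

  if ("cluster" %in% stages) {
    mc <- mcmc_config(burn_in = cfg$burn_in, iterations = cfg$iterations,
                      seed = cfg$seed, dirichlet_beta = cfg$dirichlet_beta)
    res$mcmc <- run_mcmc(res$coancestry, mc)
    res$map <- merge_tree(res$coancestry, res$mcmc$map,
                          beta = cfg$dirichlet_beta)
    emit(write_partition(res$map, file.path(cfg$out, "partition.tsv")))
    writeLines(res$map$tree, file.path(cfg$out, "merge_tree.nwk"))
    emit(file.path(cfg$out, "merge_tree.nwk"))
    utils::write.table(res$mcmc$trace,
                       file.path(cfg$out, "mcmc_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(cfg$out, "mcmc_trace.tsv"))
  }

  if ("flux" %in% stages) {
    if (is.null(labels)) {
      stop("config error: flux stage requires population labels",
           call. = FALSE)
    }
    res$flux <- import_fractions(res$coancestry, labels,
                                 denominator = cfg$flux_denominator)
    emit(write_flux_table(res$flux, file.path(cfg$out, "flux.tsv")))
    pops <- sort(unique(res$flux$recipient_pop))
    if (length(pops) >= 2L) {
      focal <- pops[1L]
      a <- group_flux(res$flux, recipient_pops = focal)
      b <- group_flux(res$flux,
                      recipient_pops = setdiff(pops, focal))
      wt <- ranksum_test(a$values, b$values)
      res$flux_test <- wt
      jsonlite::write_json(
        list(focal_recipient = focal, median_focal = a$median,
             median_other = b$median, U = wt$statistic,
             p_two_sided = wt$p_two_sided, method = wt$method),
        file.path(cfg$out, "flux_test.json"), auto_unbox = TRUE,
        digits = NA)
      emit(file.path(cfg$out, "flux_test.json"))
    }
  }

  if ("pangenome" %in% stages) {
    fam <- data.frame(
      identity = rep(cfg$family_identity, cfg$n_gene_families),
      presence = seq(1, 0.3, length.out = cfg$n_gene_families),
      interrupted = FALSE)
    gf <- simulate_gene_families(cfg$n_genomes, fam, seed = cfg$seed)
    res$pangenome <- cluster_genes(gf$genes, cfg$identity,
                                   cfg$split_paralogs,
                                   genomes = sprintf("genome%02d",
                                                     seq_len(cfg$n_genomes)))
    res$sweep <- pangenome_sweep(gf$genes,
                                 genomes = sprintf("genome%02d",
                                                   seq_len(cfg$n_genomes)))
    emit(write_pangenome(res$pangenome,
                         file.path(cfg$out, "pangenome_membership.tsv"),
                         file.path(cfg$out, "pangenome_presence.tsv")))
    utils::write.table(res$sweep, file.path(cfg$out, "pangenome_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(cfg$out, "pangenome_sweep.tsv"))
  }

  if ("rmin" %in% stages) {
    stats_rows <- list()
    for (g in seq_len(cfg$n_genes)) {
      sim_g <- simulate_recombining_gene(
        n_haps = 8L + (g %% 3L), n_sites = cfg$gene_sites,
        crossovers = cfg$gene_crossovers, seed = cfg$seed + g)
      stats_rows[[g]] <- gene_stats(sprintf("gene%02d", g),
                                    sim_g$alignment)
    }
    res$gene_stats <- do.call(rbind, stats_rows)
    res$fit <- regress(res$gene_stats)
    res$intensity <- intensity_report(res$gene_stats, res$fit)
    utils::write.table(res$gene_stats, file.path(cfg$out, "gene_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(cfg$out, "gene_stats.tsv"))
    jsonlite::write_json(
      list(beta0 = res$fit$beta0, beta1 = res$fit$beta1,
           beta2 = res$fit$beta2, r_squared = res$fit$r_squared),
      file.path(cfg$out, "regression.json"), auto_unbox = TRUE,
      digits = NA)
    emit(file.path(cfg$out, "regression.json"))
  }

  writeLines(manifest, file.path(cfg$out, "manifest.txt"))
  invisible(res)
}
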