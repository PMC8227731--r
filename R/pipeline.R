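file_md5 <- function(paths) {
  unname(tools::md5sum(paths))
}

write_manifest <- function(path, inputs, outputs, params, seed) {
  manifest <- list(
    tool = "tfcoop",
    version = as.character(utils::packageVersion("tfcoop")),
    seed = seed,
    parameters = params,
    inputs = inputs,
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = file_md5(p)))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

config_params <- function(profile, config) {
  list(core_cutoff = profile$core_cutoff,
       matrix_cutoff = profile$matrix_cutoff,
       d_min = config$d_min, d_max = config$d_max, alpha = config$alpha,
       z_threshold = config$z_threshold, n_shuffles = config$n_shuffles,
       log_base = config$log_base, distance = config$distance,
       homotypic = config$homotypic, shuffle = config$shuffle)
}

#' Run the cooperation pipeline for one phenotype
#'
#' Executes the full chain for one gene list: subset the promoters,
#' remove overlapping and duplicate-sequence promoters, predict binding
#' sites, score TF-pair cooperation against the shuffled background, and
#' build the z >= threshold cooperation network. All intermediates are
#' written to `outdir` together with a JSON manifest recording
#' parameters, the seed and the MD5 of every output, so a run is
#' reproducible from the manifest alone.
#'
#' @param promoters A `promoter_set` covering (at least) the gene list.
#' @param pwms List of `pwm` objects.
#' @param phenotype Label for this run; also names the output
#'   subdirectory files.
#' @param gene_list Optional character vector of gene ids to keep
#'   (default: all promoters).
#' @param profile A [scan_profile].
#' @param config A [scoring_config]; the shuffle seed used for this
#'   phenotype is derived from `config$seed` and the phenotype label so
#'   the two arms of a study draw independent background streams.
#' @param outdir Output directory (created), or `NULL` to skip writing.
#' @param overlap_policy Passed to [filter_overlapping].
#' @return List with `promoters` (kept), `sites`, `stats`, `network`,
#'   `removed` and (when writing) `paths`.
#' @export
run_phenotype <- function(promoters, pwms, phenotype = "phenotype",
                          gene_list = NULL, profile = scan_profile(),
                          config = scoring_config(), outdir = NULL,
                          overlap_policy = "drop-all") {
  if (!is.null(gene_list)) {
    missing <- setdiff(gene_list, promoters$gene_id)
    if (length(missing))
      warning("phenotype '", phenotype, "': no promoter for gene(s) ",
              paste(utils::head(missing, 5L), collapse = ", "))
    promoters <- promoters[promoters$gene_id %in% gene_list, , drop = FALSE]
  }
  if (nrow(promoters) == 0L)
    stop("phenotype '", phenotype, "': no promoters")
  ov <- filter_overlapping(promoters, policy = overlap_policy)
  dd <- filter_duplicate_sequences(ov$kept)
  kept <- dd$kept
  removed <- rbind(ov$removed, dd$removed)
  if (nrow(kept) == 0L)
    stop("phenotype '", phenotype, "': no promoters left after filtering")
  pheno_config <- config
  pheno_config$seed <- derive_seed(config$seed, paste0("phenotype_", phenotype))
  sites <- scan_promoters(kept, pwms, profile)
  stats <- score_pairs(kept, pwms, profile, pheno_config, sites = sites)
  sig <- significant_pairs(stats, pheno_config)
  net <- build_network(sig, phenotype)
  res <- list(promoters = kept, sites = sites, stats = stats,
              network = net, removed = removed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      promoters = file.path(outdir, paste0(phenotype, "_promoters.fa")),
      removed = file.path(outdir, paste0(phenotype, "_removed.tsv")),
      sites = file.path(outdir, paste0(phenotype, "_sites.tsv")),
      pairs = file.path(outdir, paste0(phenotype, "_pairs.tsv")),
      network_graphml = file.path(outdir, paste0(phenotype, "_network.graphml")),
      network_tsv = file.path(outdir, paste0(phenotype, "_network.tsv")),
      manifest = file.path(outdir, paste0(phenotype, "_manifest.json")))
    write_promoter_fasta(kept, paths$promoters)
    utils::write.table(removed, paths$removed, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_sites_tsv(sites, paths$sites)
    write_pairs_tsv(stats, paths$pairs)
    export_network(net, paths$network_graphml, "graphml")
    export_network(net, paths$network_tsv, "tsv")
    write_manifest(paths$manifest,
                   inputs = list(phenotype = phenotype,
                                 n_promoters_in = nrow(promoters),
                                 n_promoters_kept = nrow(kept),
                                 n_pwms = length(pwms)),
                   outputs = paths[names(paths) != "manifest"],
                   params = config_params(profile, config),
                   seed = config$seed)
    res$paths <- paths
  }
  res
}

#' Run a two-phenotype cooperation study
#'
#' Two [run_phenotype] invocations sharing one motif library and one
#' parameter set, followed by [compare_networks]: the study-shaped entry
#' point (two gene lists in, two phenotype networks plus their
#' comparison out).
#'
#' @param promoters_a,promoters_b `promoter_set`s for the two phenotypes
#'   (may be the same object subset by the gene lists).
#' @param pwms Shared motif library.
#' @param phenotype_a,phenotype_b Labels.
#' @param gene_list_a,gene_list_b Optional gene-id subsets.
#' @param profile A [scan_profile].
#' @param config A [scoring_config].
#' @param outdir Output directory, or `NULL` to skip writing.
#' @return List with `run_a`, `run_b` (each a [run_phenotype] result)
#'   and `comparison` (a `network_comparison`).
#' @export
run_study <- function(promoters_a, promoters_b, pwms,
                      phenotype_a = "phenotype_a",
                      phenotype_b = "phenotype_b",
                      gene_list_a = NULL, gene_list_b = NULL,
                      profile = scan_profile(), config = scoring_config(),
                      outdir = NULL) {
  run_a <- run_phenotype(promoters_a, pwms, phenotype_a, gene_list_a,
                         profile, config, outdir)
  run_b <- run_phenotype(promoters_b, pwms, phenotype_b, gene_list_b,
                         profile, config, outdir)
  cmp <- compare_networks(run_a$network, run_b$network)
  res <- list(run_a = run_a, run_b = run_b, comparison = cmp)
  if (!is.null(outdir)) {
    cmp_tsv <- file.path(outdir, "comparison.tsv")
    cmp_graphml <- file.path(outdir, "comparison.graphml")
    export_network(cmp, cmp_tsv, "tsv")
    export_network(cmp, cmp_graphml, "graphml")
    switching <- file.path(outdir, "switching_tfs.txt")
    writeLines(cmp$switching_nodes, switching)
    write_manifest(file.path(outdir, "study_manifest.json"),
                   inputs = list(phenotype_a = phenotype_a,
                                 phenotype_b = phenotype_b,
                                 manifest_a = file_md5(run_a$paths$manifest),
                                 manifest_b = file_md5(run_b$paths$manifest)),
                   outputs = list(comparison_tsv = cmp_tsv,
                                  comparison_graphml = cmp_graphml,
                                  switching = switching),
                   params = config_params(profile, config),
                   seed = config$seed)
    res$paths <- list(comparison_tsv = cmp_tsv,
                      comparison_graphml = cmp_graphml,
                      switching = switching)
  }
  res
}
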