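#' Run the full synthetic demonstration pipeline
#'
#' Simulates a complete dataset to \code{out_dir/data}, reads the
#' annotation, chromosome sizes, coverage, super-enhancer regions and
#' proteomics table back from disk, runs every analysis stage and writes its
#' result tables plus a machine-readable run log under \code{out_dir}. All
#' randomness derives from \code{seed}; two runs with the same seed produce
#' byte-identical artefacts.
#'
#' @param seed master seed.
#' @param out_dir output directory (created).
#' @param spec generator spec (defaults to [demo_spec()] at \code{seed}).
#' @param params [analysis_params()].
#' @return invisibly, a named list of the result tables.
#' @export
run_demo <- function(seed = 1L, out_dir, spec = demo_spec(seed),
                     params = analysis_params()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")
  ds <- simulate_dataset(spec, data_dir)

  # everything below consumes the on-disk artefacts, exercising the I/O
  chrom_lengths <- read_chrom_sizes(file.path(data_dir, "chrom.sizes"))
  genes <- read_annotation(file.path(data_dir, "annotation.gtf"), "gtf")
  cov_ctrl <- read_bedgraph(file.path(data_dir, "control.rep1.plus.bedgraph"),
                            file.path(data_dir, "control.rep1.minus.bedgraph"),
                            chrom_lengths)
  cov_dep <- read_bedgraph(file.path(data_dir, "depleted.rep1.plus.bedgraph"),
                           file.path(data_dir, "depleted.rep1.minus.bedgraph"),
                           chrom_lengths)
  se_regions <- read_bed(file.path(data_dir, "se_regions.bed"))

  # expression: exonic counting on emitted control reads, TPM, filters
  reads <- simulate_reads(spec, ds$ann)
  counts <- count_exonic_all(reads, genes)
  tpm <- compute_tpm(counts, exonic_length(genes))
  expr <- filter_expressed(data.frame(gene_id = genes$gene_id, tpm = tpm),
                           params)
  nonneigh <- filter_nonneighbouring(genes, params)
  cohort <- nonneigh[!expr$low_expression[match(nonneigh$gene_id,
                                                expr$gene_id)], ,
                     drop = FALSE]
  class(cohort) <- class(genes)
  upstream <- upstream_readthrough_filter(cohort, cov_ctrl, cov_dep, params)

  rt <- readthrough_table(cov_ctrl, cov_dep, genes, params,
                          tpm = stats::setNames(expr$tpm, expr$gene_id))

  prompts <- define_prompt_windows(cohort, params$prompt_window,
                                   chrom_lengths)
  prompts <- prompt_fc(prompts, cov_ctrl, cov_dep, params)
  extents <- data.frame(
    gene_id = cohort$gene_id,
    extent_bp = vapply(seq_len(nrow(cohort)), function(i) {
      estimate_prompt_extent(cov_dep, cohort[i, , drop = FALSE])
    }, 0),
    stringsAsFactors = FALSE)

  dens <- pas_density(prompts, file.path(data_dir, "genome.fa"))
  pas_split <- split_density_by_class(dens, prompts)

  se <- se_metaplot(cov_dep, cov_ctrl, se_regions,
                    pseudocount = params$pseudocount,
                    seed = spec$seed + 71L)

  profile <- strand_split_profile(cov_dep, cohort)

  de_sim <- simulate_counts(n_genes = 400L, n_planted = 8L, fold = 6,
                            base_meanlog = log(200), base_sdlog = 0,
                            seed = spec$seed + 51L)
  de <- call_upregulated(de_sim$counts_ctrl, de_sim$counts_cond, params)

  quants <- load_quant_table(file.path(data_dir, "proteomics.tsv"),
                             file.path(data_dir, "contaminants.txt"))
  candidates <- filter_candidates(quants, params)

  wt <- function(x, f) {
    utils::write.table(x, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(expr, "expression.tsv")
  wt(upstream, "upstream_filter.tsv")
  wt(rt, "readthrough.tsv")
  wt(prompts, "prompts.tsv")
  wt(extents, "prompt_extents.tsv")
  wt(dens[, c("prompt_id", "length_bp", "n_sites", "density_per_kb")],
     "pas_density.tsv")
  wt(pas_split$summary, "pas_summary.tsv")
  wt(se, "se_metaplot.tsv")
  wt(profile, "metagene_profile.tsv")
  wt(de, "de_results.tsv")
  wt(candidates[, c("protein_id", "peptide_count", "n_ratios", "mean_ratio")],
     "proteomics_candidates.tsv")
  log <- list(seed = seed,
              params = unclass(params),
              n_genes = nrow(genes),
              n_cohort = nrow(cohort),
              n_prompts = nrow(prompts),
              n_se = nrow(se_regions),
              n_de_genes = nrow(de),
              n_candidates = nrow(candidates))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(expr = expr, upstream = upstream, readthrough = rt,
                 prompts = prompts, extents = extents, pas = dens,
                 pas_summary = pas_split$summary, se = se,
                 profile = profile, de = de, candidates = candidates))
}
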