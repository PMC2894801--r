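#' Pipeline configuration
#'
#' Parameter defaults are the published pipeline values: at most one
#' mismatch, a 100-location promiscuity cap, and a doubled annotated
#' 3' UTR.
#'
#' @param genome,gtf,probes Paths to the genome FASTA, gene-model GTF and
#'   probe table TSV (required).
#' @param vcf,paralogs,est_gtf Optional paths: variants, paralog pairs,
#'   and an alternative gene set for the second unannotated profile.
#' @param out_dir Output directory.
#' @param max_mismatch,max_hits Aligner parameters.
#' @param utr_multiplier,extension,clip_at_neighbor Extension policy
#'   parameters (see [compute_extension_policy()]).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(genome, gtf, probes, vcf = NULL,
                            paralogs = NULL, est_gtf = NULL,
                            out_dir = tempfile("probemapr_run_"),
                            max_mismatch = 1, max_hits = 100,
                            utr_multiplier = 2, extension = NULL,
                            clip_at_neighbor = FALSE, seed = 1) {
  structure(list(genome = genome, gtf = gtf, probes = probes, vcf = vcf,
                 paralogs = paralogs, est_gtf = est_gtf, out_dir = out_dir,
                 max_mismatch = max_mismatch, max_hits = max_hits,
                 utr_multiplier = utr_multiplier, extension = extension,
                 clip_at_neighbor = clip_at_neighbor, seed = seed),
            class = "pipeline_config")
}

#' Run the full mapping and annotation pipeline
#'
#' Stages: read inputs, collapse probes to a non-redundant set, align to
#' the genome (0/1 mismatch, promiscuity cap), align to spliced cDNA and
#' project junction hits back to genomic blocks, merge, compute the
#' extension policy, extend transcripts and annotate probesets under the
#' 50% rule, profile unannotated probesets, and run the downstream audits
#' (multi-gene explanation; SNP overlap when a VCF is given).  All stage
#' outputs are written under `out_dir`; the run manifest records counts
#' and parameters.  Outputs are a pure function of inputs and
#' configuration: re-running reproduces them byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return A `probemapr_run` object with all stage tables, the manifest,
#'   and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (inp in c("genome", "gtf", "probes")) {
    if (is.null(config[[inp]]) || !file.exists(config[[inp]]))
      abort_input(paste0("missing required input: ", inp, " (",
                         config[[inp]] %||% "unset", ")"))
  }
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(name) {
    stages[[name]] <<- proc.time()[["elapsed"]] - t0
    t0 <<- proc.time()[["elapsed"]]
  }

  genome <- read_genome(config$genome)
  transcripts <- read_gene_models(config$gtf)
  probes <- read_probe_table(config$probes)
  variants <- if (!is.null(config$vcf)) read_variants(config$vcf, genome)
  paralogs <- if (!is.null(config$paralogs))
    readr::read_tsv(config$paralogs, show_col_types = FALSE,
                    progress = FALSE)
  else tibble(gene_a = character(), gene_b = character())
  est <- if (!is.null(config$est_gtf)) read_gene_models(config$est_gtf)
  tick("read")

  collapsed <- collapse_probes(probes)
  tick("collapse")

  pm <- map_probes(probes, genome, transcripts,
                   max_mismatch = config$max_mismatch,
                   max_hits = config$max_hits)
  tick("align")

  policy <- compute_extension_policy(transcripts,
                                     utr_multiplier = config$utr_multiplier,
                                     clip_at_neighbor = config$clip_at_neighbor,
                                     extension = config$extension)
  extended <- extend_transcripts(transcripts, policy, genome)
  annotations <- annotate_probesets(probes, pm$alignments, extended,
                                    pm$dispositions)
  tick("annotate")

  profiles <- profile_probesets(probes, pm$alignments, transcripts,
                                annotations)
  est_profiles <- if (!is.null(est))
    profile_against_second_geneset(probes, pm$alignments, est, annotations)
  tick("classify")

  multi_gene <- explain_multi_gene(annotations, paralogs, extended)
  histogram <- genes_per_probeset(annotations)
  snp <- if (!is.null(variants)) {
    rec <- snp_overlap(pm$alignments, variants, genome)
    list(records = rec, summary = summarize_snp_overlap(rec, probes))
  }
  tick("analyze")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_run_outputs(config$out_dir, collapsed, pm, annotations,
                             profiles, est_profiles, multi_gene, histogram,
                             snp)
  summary <- run_summary(probes, pm, annotations, multi_gene, snp)
  manifest <- list(
    parameters = config[c("max_mismatch", "max_hits", "utr_multiplier",
                          "clip_at_neighbor", "seed")],
    extension_length = policy$extension_length,
    counts = list(
      probes = nrow(probes),
      unique_sequences = nrow(collapsed),
      alignments = nrow(pm$alignments),
      alignments_genomic = sum(pm$alignments$source == "genomic"),
      alignments_cdna_projected =
        sum(pm$alignments$source == "cdna_projected"),
      probes_mapped = sum(pm$dispositions$disposition == "mapped"),
      probes_discarded_promiscuous =
        sum(pm$dispositions$disposition == "discarded_promiscuous"),
      probes_unmapped = sum(pm$dispositions$disposition == "unmapped"),
      probesets = length(unique(probes$probeset_id)),
      probesets_annotated =
        length(unique(annotations$probeset_id[annotations$annotated])),
      probesets_unannotated = nrow(profiles),
      probesets_multi_gene = nrow(multi_gene)),
    package_version = as.character(utils::packageVersion("probemapr")))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  structure(list(config = config, manifest = manifest, summary = summary,
                 policy = policy, collapsed = collapsed,
                 alignments = pm$alignments,
                 dispositions = pm$dispositions,
                 annotations = annotations, profiles = profiles,
                 est_profiles = est_profiles, multi_gene = multi_gene,
                 histogram = histogram, snp = snp, paths = paths,
                 elapsed = stages),
            class = "probemapr_run")
}

write_run_outputs <- function(out_dir, collapsed, pm, annotations, profiles,
                              est_profiles, multi_gene, histogram, snp) {
  paths <- list()
  w <- function(name, fn, ...) {
    p <- file.path(out_dir, name)
    fn(..., p)
    paths[[name]] <<- p
  }
  w("nonredundant.fa", write_nonredundant_fasta, collapsed)
  w("hits.bed", write_probe_features, pm$alignments)
  w("alignments.tsv", write_alignments, pm$alignments)
  w("dispositions.tsv", function(x, p) readr::write_tsv(x, p,
                                                        progress = FALSE),
    pm$dispositions)
  w("annotations.tsv", write_annotations, annotations)
  w("profiles.tsv", function(x, p) readr::write_tsv(x, p, progress = FALSE),
    profiles)
  if (!is.null(est_profiles))
    w("profiles_est.tsv",
      function(x, p) readr::write_tsv(x, p, progress = FALSE), est_profiles)
  w("multi_gene.tsv", function(x, p) {
    readr::write_tsv(x |> mutate(genes = map_chr(.data$genes, paste,
                                                 collapse = ";")), p,
                     progress = FALSE)
  }, multi_gene)
  w("genes_per_probeset.tsv",
    function(x, p) readr::write_tsv(x, p, progress = FALSE), histogram)
  if (!is.null(snp)) {
    w("snp_records.tsv",
      function(x, p) readr::write_tsv(x, p, progress = FALSE), snp$records)
    w("snp_summary.tsv",
      function(x, p) readr::write_tsv(x, p, progress = FALSE), snp$summary)
  }
  unlist(paths)
}

run_summary <- function(probes, pm, annotations, multi_gene, snp) {
  n_probes <- nrow(probes)
  n_mapped <- sum(pm$dispositions$disposition == "mapped")
  n_ps <- length(unique(probes$probeset_id))
  n_ann <- length(unique(annotations$probeset_id[annotations$annotated]))
  tibble(
    array_name = probes$array_name[1],
    n_probes = n_probes,
    frac_probes_mapped = n_mapped / n_probes,
    n_probesets = n_ps,
    frac_probesets_annotated = n_ann / n_ps,
    frac_probesets_multi_gene = nrow(multi_gene) / n_ps,
    frac_probesets_snp = if (!is.null(snp))
      snp$summary$frac_probesets_snp else NA_real_
  )
}

#' @export
print.probemapr_run <- function(x, ...) {
  cat("<probemapr_run>\n")
  cn <- x$manifest$counts
  cat(sprintf("  probes: %d (%d unique sequences), mapped %d, promiscuous %d, unmapped %d\n",
              cn$probes, cn$unique_sequences, cn$probes_mapped,
              cn$probes_discarded_promiscuous, cn$probes_unmapped))
  cat(sprintf("  alignments: %d (%d genomic + %d cDNA-projected)\n",
              cn$alignments, cn$alignments_genomic,
              cn$alignments_cdna_projected))
  cat(sprintf("  probesets: %d, annotated %d (%.1f%%), multi-gene %d\n",
              cn$probesets, cn$probesets_annotated,
              100 * cn$probesets_annotated / cn$probesets,
              cn$probesets_multi_gene))
  cat(sprintf("  extension length: %d bp\n", x$manifest$extension_length))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `probemapr_run`.
#' @param ... Unused.
#' @method tidy probemapr_run
#' @export
tidy.probemapr_run <- function(x, ...) {
  cn <- x$manifest$counts
  tibble(stage = c("ingest", "align", "annotate", "classify", "analyze"),
         records = c(cn$probes, cn$alignments,
                     cn$probesets_annotated, cn$probesets_unannotated,
                     cn$probesets_multi_gene),
         unit = c("probes", "alignments", "probesets annotated",
                  "probesets profiled", "multi-gene probesets"))
}

#' @rdname run_pipeline
#' @method glance probemapr_run
#' @export
glance.probemapr_run <- function(x, ...) {
  x$summary
}
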