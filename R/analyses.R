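#' Explain probesets annotated to multiple genes
#'
#' For every probeset annotated to two or more genes, all gene pairs are
#' evaluated: a pair is *overlapping* when the genes' extended spans (the
#' union of their extended transcript footprints, strand ignored --
#' tail-to-tail pairs sit on opposite strands) intersect, and *paralogous*
#' when the pair appears in the supplied paralog table.  The probeset
#' verdict summarises the pairs: any unexplained pair makes the probeset
#' `unexplained`; otherwise both relation types present give `both`, else
#' the single observed type.
#'
#' @param annotations Output of [annotate_probesets()].
#' @param paralogs Two-column tibble (`gene_a`, `gene_b`); symmetrised on
#'   load.
#' @param extended Output of [extend_transcripts()].
#' @return A tibble `probeset_id`, `genes` (list-column), `n_genes`,
#'   `verdict` with one row per multi-gene probeset.
#' @export
explain_multi_gene <- function(annotations, paralogs, extended) {
  ann <- annotations |> filter(.data$annotated)
  gene_sets <- ann |>
    distinct(.data$probeset_id, .data$gene_id) |>
    group_by(.data$probeset_id) |>
    summarise(genes = list(sort(unique(.data$gene_id))), .groups = "drop") |>
    mutate(n_genes = map_int(.data$genes, length)) |>
    filter(.data$n_genes >= 2)
  if (nrow(gene_sets) == 0)
    return(tibble(probeset_id = character(), genes = list(),
                  n_genes = integer(), verdict = character()))
  missing <- setdiff(unique(unlist(gene_sets$genes)), extended$gene_id)
  if (length(missing))
    abort_input(paste0("gene in annotation absent from models: ",
                       missing[1]))
  pkey <- unique(c(paste(paralogs$gene_a, paralogs$gene_b),
                   paste(paralogs$gene_b, paralogs$gene_a)))
  gspan <- extended |>
    mutate(f_start = map_int(.data$footprint, ~ min(.x[, 1])),
           f_end = map_int(.data$footprint, ~ max(.x[, 2]))) |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), g_start = min(.data$f_start),
              g_end = max(.data$f_end), .groups = "drop")
  overlap_pair <- function(a, b) {
    ga <- gspan[gspan$gene_id == a, ]
    gb <- gspan[gspan$gene_id == b, ]
    ga$chrom == gb$chrom && ga$g_start <= gb$g_end && gb$g_start <= ga$g_end
  }
  gene_sets |>
    mutate(verdict = map_chr(.data$genes, function(gs) {
      pairs <- utils::combn(gs, 2, simplify = FALSE)
      par <- map_lgl(pairs, ~ paste(.x[1], .x[2]) %in% pkey)
      ovl <- map_lgl(pairs, ~ overlap_pair(.x[1], .x[2]))
      if (any(!par & !ovl)) return("unexplained")
      has_par <- any(par)
      has_ovl <- any(ovl)
      if (has_par && has_ovl) "both"
      else if (has_par) "paralogous"
      else "overlapping"
    }))
}

#' Histogram of genes per annotated probeset
#'
#' @param annotations Output of [annotate_probesets()].
#' @return A tibble `n_genes`, `n_probesets` over all annotated probesets.
#' @export
genes_per_probeset <- function(annotations) {
  annotations |>
    filter(.data$annotated) |>
    distinct(.data$probeset_id, .data$gene_id) |>
    count(.data$probeset_id, name = "n_genes") |>
    count(.data$n_genes, name = "n_probesets") |>
    arrange(.data$n_genes)
}

#' Group probe placements by mismatch status and SNP overlap
#'
#' A SNP overlaps a placement when its position falls within any alignment
#' block (1-based inclusive; the intron gap of a junction placement does
#' not count).  Placements split into four groups crossing the alignment's
#' match status with SNP presence.  Only single-nucleotide variants are
#' used; indels are skipped with a warning.
#'
#' @param alignments Alignment tibble.
#' @param variants Variant tibble from [read_variants()].
#' @param genome Optional genome; variants on chromosomes absent from it
#'   are skipped with a warning.
#' @return The alignments with `has_snp` and
#'   `group` (`perfect_match_no_snp`, `perfect_match_snp`,
#'   `mismatch_no_snp`, `mismatch_snp`) added.
#' @export
snp_overlap <- function(alignments, variants, genome = NULL) {
  snv <- variants |>
    filter(nchar(.data$ref) == 1, nchar(.data$alt) == 1)
  if (nrow(snv) < nrow(variants))
    warn(sprintf("skipped %d non-SNV variant(s)",
                 nrow(variants) - nrow(snv)))
  if (!is.null(genome)) {
    known <- names(genome)
    bad <- !snv$chrom %in% known
    if (any(bad)) {
      warn(sprintf("skipped %d variant(s) on unknown chromosome(s)",
                   sum(bad)))
      snv <- snv[!bad, , drop = FALSE]
    }
  }
  has_snp <- logical(nrow(alignments))
  if (nrow(snv) && nrow(alignments)) {
    bl <- parse_blocks(alignments$blocks)
    by_chrom <- split(snv$pos, snv$chrom)
    has_snp <- vapply(seq_len(nrow(alignments)), function(i) {
      pos <- by_chrom[[alignments$chrom[i]]]
      if (is.null(pos)) return(FALSE)
      b <- bl[[i]]
      any(vapply(seq_len(nrow(b)), function(k) {
        any(pos >= b[k, 1] & pos <= b[k, 2])
      }, logical(1)))
    }, logical(1))
  }
  alignments |>
    mutate(has_snp = has_snp,
           group = paste0(
             if_else(.data$match_status == "full_match",
                     "perfect_match", "mismatch"),
             if_else(has_snp, "_snp", "_no_snp")))
}

#' Aggregate SNP overlap over probes and probesets
#'
#' A probe counts as affected when any of its placements overlaps a SNP;
#' a probeset counts as affected when any member probe is affected.
#' Denominators are mapped probes (probes with at least one placement) and
#' probesets with at least one mapped probe.
#'
#' @param records Output of [snp_overlap()].
#' @param probes Probe tibble.
#' @return A one-row tibble: `n_probes_mapped`, `n_probes_snp`,
#'   `frac_probes_snp`, `n_probesets_mapped`, `n_probesets_snp`,
#'   `frac_probesets_snp`.
#' @export
summarize_snp_overlap <- function(records, probes) {
  mapped <- unique(records$probe_name)
  affected <- unique(records$probe_name[records$has_snp])
  member <- probes |> select("probe_name", "probeset_id")
  ps_mapped <- member |> filter(.data$probe_name %in% mapped) |>
    pull("probeset_id") |> unique()
  ps_aff <- member |> filter(.data$probe_name %in% affected) |>
    pull("probeset_id") |> unique()
  tibble(
    n_probes_mapped = length(mapped),
    n_probes_snp = length(affected),
    frac_probes_snp = if (length(mapped)) length(affected) / length(mapped)
      else NA_real_,
    n_probesets_mapped = length(ps_mapped),
    n_probesets_snp = length(ps_aff),
    frac_probesets_snp = if (length(ps_mapped))
      length(ps_aff) / length(ps_mapped) else NA_real_
  )
}

#' Compare two probeset annotation tables by external identifiers
#'
#' For each external database, the probesets present with that database in
#' both tables are compared; one accession identifier in common is enough
#' to call the annotations connected.
#'
#' @param ours,theirs Long tibbles with columns `probeset_id`, `database`,
#'   `identifier` (several rows per probeset and database allowed).
#' @return A tibble `database`, `n_compared`, `n_agree`, `agreement`.
#' @export
compare_annotations <- function(ours, theirs) {
  a <- ours |> distinct(.data$probeset_id, .data$database, .data$identifier)
  b <- theirs |> distinct(.data$probeset_id, .data$database,
                          .data$identifier)
  keys <- inner_join(a |> distinct(.data$probeset_id, .data$database),
                     b |> distinct(.data$probeset_id, .data$database),
                     by = c("probeset_id", "database"))
  if (nrow(keys) == 0)
    return(tibble(database = character(), n_compared = integer(),
                  n_agree = integer(), agreement = numeric()))
  agree <- keys |>
    left_join(a, by = c("probeset_id", "database"),
              relationship = "many-to-many") |>
    rename(id_a = "identifier") |>
    left_join(b, by = c("probeset_id", "database"),
              relationship = "many-to-many") |>
    rename(id_b = "identifier") |>
    group_by(.data$probeset_id, .data$database) |>
    summarise(agree = any(.data$id_a == .data$id_b), .groups = "drop")
  agree |>
    group_by(.data$database) |>
    summarise(n_compared = n(), n_agree = sum(.data$agree),
              .groups = "drop") |>
    mutate(agreement = .data$n_agree / .data$n_compared) |>
    arrange(.data$database)
}
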