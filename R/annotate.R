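#' Species-level 3' UTR extension policy
#'
#' Arrays are designed against transcript 3' ends, but many transcript
#' models have short or missing 3' UTRs, so footprints are extended
#' downstream before probes are counted.  The species extension length is
#' the greater of the mean and the median of all annotated 3' UTR lengths
#' (transcripts with no annotated UTR are excluded from the statistic),
#' rounded to the nearest integer with ties up.
#'
#' @param transcripts Transcript tibble (see [read_gene_models()]).
#' @param utr_multiplier Factor applied to an annotated 3' UTR (default 2:
#'   the annotated UTR plus an equally long extension beyond it).
#' @param clip_at_neighbor If `TRUE`, extensions are truncated before the
#'   nearest downstream gene span on either strand.
#' @param extension Optional explicit override of the species extension
#'   length in bases; required when no transcript has an annotated 3' UTR.
#' @return An `extension_policy` object.
#' @export
compute_extension_policy <- function(transcripts, utr_multiplier = 2,
                                     clip_at_neighbor = FALSE,
                                     extension = NULL) {
  if (is.null(extension)) {
    lens <- transcripts$utr3_length[transcripts$utr3_length > 0]
    if (!length(lens))
      abort_input(paste0("no transcript has an annotated 3' UTR; ",
                         "supply an explicit `extension` override"))
    extension <- round_half_up(max(mean(lens), median(lens)))
  }
  structure(list(extension_length = as.integer(extension),
                 utr_multiplier = utr_multiplier,
                 clip_at_neighbor = isTRUE(clip_at_neighbor)),
            class = "extension_policy")
}

#' @export
print.extension_policy <- function(x, ...) {
  cat(sprintf(paste0("<extension_policy> species extension %d bp, UTR x%g,",
                     " clip at neighbor: %s\n"),
              x$extension_length, x$utr_multiplier,
              if (x$clip_at_neighbor) "yes" else "no"))
  invisible(x)
}

#' Extend transcripts on their 3' side and build footprints
#'
#' A transcript with an annotated 3' UTR of length `u` is extended by
#' `(utr_multiplier - 1) * u` bases beyond its annotated end (the total UTR
#' considered is the multiplier times the annotated one); a transcript with
#' no annotated UTR is extended by the species extension length.  The
#' extension grows downstream in transcript orientation (higher coordinates
#' on `+`, lower on `-`), clipped to the chromosome, and, when the policy
#' requests it, truncated before the nearest downstream gene span.  The
#' footprint is the merged union of exons and extension.
#'
#' @param transcripts Transcript tibble.
#' @param policy An `extension_policy` from [compute_extension_policy()].
#' @param genome Genome reference (for chromosome lengths), or a tibble
#'   from [genome_lengths()].
#' @return The transcript tibble with `ext_start`, `ext_end` (NA when the
#'   extension is empty) and `footprint` (list of merged interval matrices)
#'   added.
#' @export
extend_transcripts <- function(transcripts, policy, genome) {
  gl <- if (is.data.frame(genome)) genome else genome_lengths(genome)
  spans <- transcripts |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), g_start = min(.data$tx_start),
              g_end = max(.data$tx_end), .groups = "drop")
  tx <- transcripts |> left_join(gl, by = "chrom")
  rows <- pmap(tx, function(transcript_id, gene_id, chrom, strand, exons,
                            tx_start, tx_end, utr3_length, length, ...) {
    ext_len <- if (utr3_length > 0)
      as.integer((policy$utr_multiplier - 1) * utr3_length)
    else policy$extension_length
    if (strand == "+") {
      es <- tx_end + 1L
      ee <- min(tx_end + ext_len, length)
    } else {
      ee <- tx_start - 1L
      es <- max(tx_start - ext_len, 1L)
    }
    if (policy$clip_at_neighbor && es <= ee) {
      nb <- spans[spans$chrom == chrom & spans$gene_id != gene_id, ]
      hit <- nb[nb$g_start <= ee & nb$g_end >= es, ]
      if (nrow(hit)) {
        if (strand == "+") ee <- min(hit$g_start) - 1L
        else es <- max(hit$g_end) + 1L
      }
    }
    empty <- es > ee
    ivs <- rbind(exons[order(exons[, 1]), , drop = FALSE],
                 if (!empty) c(es, ee))
    fp <- merge_intervals(ivs)
    tibble(ext_start = if (empty) NA_integer_ else as.integer(es),
           ext_end = if (empty) NA_integer_ else as.integer(ee),
           footprint = list(fp))
  })
  dplyr::bind_cols(transcripts, bind_rows(rows))
}

merge_intervals <- function(m) {
  m <- m[order(m[, 1]), , drop = FALSE]
  ir <- IRanges::reduce(IRanges::IRanges(m[, 1], m[, 2]))
  out <- cbind(start = IRanges::start(ir), end = IRanges::end(ir))
  out
}

#' Match probe placements against extended transcripts
#'
#' A placement matches a transcript when every alignment block lies within
#' the footprint and the alignment strand equals the transcript strand, or
#' when the placement was projected from a sense cDNA hit on that very
#' transcript.  Non-matching placements are classified for reporting:
#' `antisense` (footprint-contained, strand-opposed), `intronic`
#' (inside the extended transcript span but not footprint-contained),
#' `intergenic` otherwise.
#'
#' @param alignments Alignment tibble.
#' @param extended Output of [extend_transcripts()].
#' @return A tibble of (alignment, transcript) pairs restricted to
#'   transcripts whose extended span overlaps the placement, with columns of
#'   both plus `matched` and `reason`.
#' @export
match_probes_to_transcripts <- function(alignments, extended) {
  if (nrow(alignments) == 0)
    return(tibble(probe_name = character(), transcript_id = character(),
                  gene_id = character(), matched = logical(),
                  reason = character()))
  tx_span <- extended |>
    mutate(span_start = map_int(.data$footprint, ~ min(.x[, 1])),
           span_end = map_int(.data$footprint, ~ max(.x[, 2])))
  al <- alignments |> mutate(.aln = row_number())
  ov <- find_span_overlaps(al, tx_span)
  if (nrow(ov) == 0)
    return(tibble(probe_name = character(), transcript_id = character(),
                  gene_id = character(), matched = logical(),
                  reason = character()))
  ov$contained <- unlist(Map(function(b, fp) {
    blocks_within(parse_blocks(b)[[1]], fp)
  }, ov$blocks, ov$footprint), use.names = FALSE)
  ov$sense <- ov$strand == ov$tx_strand
  projected_here <- ov$source == "cdna_projected" &
    !is.na(ov$transcript_id.aln) & ov$transcript_id.aln == ov$transcript_id
  ov$matched <- (ov$contained | projected_here) & ov$sense
  ov$reason <- dplyr::case_when(
    ov$matched ~ "matched",
    ov$contained & !ov$sense ~ "antisense",
    TRUE ~ "intronic")
  ov |> select("probe_name", "transcript_id", "gene_id", "matched",
               "reason", ".aln")
}

find_span_overlaps <- function(al, tx_span) {
  q <- GenomicRanges::GRanges(al$chrom, IRanges::IRanges(al$start, al$end))
  s <- GenomicRanges::GRanges(tx_span$chrom,
                              IRanges::IRanges(tx_span$span_start,
                                               tx_span$span_end))
  h <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  tibble(
    probe_name = al$probe_name[qi], chrom = al$chrom[qi],
    strand = al$strand[qi], blocks = al$blocks[qi],
    source = al$source[qi], transcript_id.aln = al$transcript_id[qi],
    .aln = al$.aln[qi],
    transcript_id = tx_span$transcript_id[si],
    gene_id = tx_span$gene_id[si], tx_strand = tx_span$strand[si],
    footprint = tx_span$footprint[si]
  )
}

blocks_within <- function(blocks, footprint) {
  all(vapply(seq_len(nrow(blocks)), function(i) {
    any(footprint[, 1] <= blocks[i, 1] & blocks[i, 2] <= footprint[, 2])
  }, logical(1)))
}

#' Minimum matched probes required to annotate a probeset
#'
#' "At least half of the probes" with odd sizes resolved upward:
#' `ceiling(size / 2)` is the smallest integer count that is at least half.
#'
#' @param probeset_size Number of member probes.
#' @return Integer threshold.
#' @export
annotation_threshold <- function(probeset_size) {
  as.integer(ceiling(probeset_size / 2))
}

#' Annotate probesets to transcripts under the 50% rule
#'
#' For every (probeset, transcript) pair with at least one matched probe, a
#' record is emitted carrying the distinct matched-probe count, the dynamic
#' probeset size (member probes in the array design, including probes that
#' were discarded, unmapped or ambiguous -- they still count in the
#' denominator), and the verdict `annotated = n_matched >= ceiling(size/2)`.
#' Each probe contributes at most once per transcript regardless of how
#' many placements it has there.  Per-probe reasons record why a probe did
#' not support the annotation.
#'
#' @param probes Probe tibble.
#' @param alignments Merged alignment tibble.
#' @param extended Output of [extend_transcripts()].
#' @param dispositions Disposition tibble from the aligner (optional; used
#'   to distinguish unmapped / promiscuous / ambiguous probes in reasons).
#' @return Annotation tibble: `probeset_id`, `transcript_id`, `gene_id`,
#'   `n_matched`, `probeset_size`, `annotated`, `reasons` (list-column of
#'   per-probe reasons).
#' @export
annotate_probesets <- function(probes, alignments, extended,
                               dispositions = NULL) {
  if (nrow(probes) == 0) abort_input("probe table is empty")
  sizes <- probes |> count(.data$probeset_id, name = "probeset_size")
  pairs <- match_probes_to_transcripts(alignments, extended)
  membership <- probes |> select("probe_name", "probeset_id")
  hit_tx <- pairs |>
    inner_join(membership, by = "probe_name",
               relationship = "many-to-many") |>
    group_by(.data$probeset_id, .data$transcript_id, .data$gene_id)
  counts <- hit_tx |>
    summarise(n_matched = n_distinct(.data$probe_name[.data$matched]),
              .groups = "drop") |>
    filter(.data$n_matched > 0)
  if (nrow(counts) == 0) {
    return(tibble(probeset_id = character(), transcript_id = character(),
                  gene_id = character(), n_matched = integer(),
                  probeset_size = integer(), annotated = logical(),
                  reasons = list()))
  }
  reason_tbl <- probe_reason_table(probes, pairs, dispositions)
  counts |>
    left_join(sizes, by = "probeset_id") |>
    mutate(annotated = .data$n_matched >=
             annotation_threshold(.data$probeset_size)) |>
    mutate(reasons = map2(.data$probeset_id, .data$transcript_id,
                          function(ps, tx) {
      reason_tbl[[paste(ps, tx, sep = "\r")]]
    })) |>
    arrange(.data$probeset_id, .data$transcript_id) |>
    select("probeset_id", "transcript_id", "gene_id", "n_matched",
           "probeset_size", "annotated", "reasons")
}

# one reason per (probeset, transcript, probe): disposition-level failures
# first, then the best outcome among that probe's placements on the
# transcript, else intergenic
probe_reason_table <- function(probes, pairs, dispositions) {
  disp <- if (is.null(dispositions)) {
    tibble(probe_name = probes$probe_name, disposition = "mapped")
  } else dispositions
  disp_reason <- c(discarded_promiscuous = "promiscuous_discarded",
                   unmapped = "unmapped",
                   ambiguous_sequence = "ambiguous_sequence")
  rank <- c(matched = 1, antisense = 2, intronic = 3)
  best <- pairs |>
    group_by(.data$probe_name, .data$transcript_id) |>
    summarise(reason = names(rank)[min(rank[.data$reason])],
              .groups = "drop")
  keys <- pairs |>
    inner_join(probes |> select("probe_name", "probeset_id"),
               by = "probe_name", relationship = "many-to-many") |>
    distinct(.data$probeset_id, .data$transcript_id)
  member <- probes |> select("probe_name", "probeset_id") |>
    left_join(disp, by = "probe_name")
  out <- list()
  for (i in seq_len(nrow(keys))) {
    ps <- keys$probeset_id[i]; tx <- keys$transcript_id[i]
    mem <- member[member$probeset_id == ps, ]
    r <- best[best$transcript_id == tx, ]
    reasons <- tibble(probe_name = mem$probe_name) |>
      left_join(r |> select("probe_name", "reason"), by = "probe_name") |>
      mutate(reason = dplyr::coalesce(
        unname(disp_reason[mem$disposition]),
        .data$reason, "intergenic"))
    out[[paste(ps, tx, sep = "\r")]] <- reasons
  }
  out
}

#' Probesets left unannotated by the 50% rule
#'
#' @param probes Probe tibble.
#' @param annotations Output of [annotate_probesets()].
#' @return Character vector of probeset ids with no `annotated = TRUE` row.
#' @export
unannotated_probesets <- function(probes, annotations) {
  ok <- unique(annotations$probeset_id[annotations$annotated])
  setdiff(sort(unique(probes$probeset_id)), ok)
}
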