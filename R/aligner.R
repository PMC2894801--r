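#' Build a probe search index over a genome
#'
#' The search tolerates at most one substitution, so completeness follows
#' from the pigeonhole principle: any hit with <= 1 mismatch matches one of
#' the two probe halves exactly.  Each half is used as an exact trusted band
#' over the genome and candidates are verified by Hamming distance, which
#' makes the search exact and deterministic with no heuristic thresholds.
#' The reverse strand is handled at query time by searching the reverse
#' complement of the probe against the forward sequence.
#'
#' @param genome A [Biostrings::DNAStringSet] (uppercase).
#' @param probe_length Probe length in bases (>= 10).
#' @return A `probe_index` object.
#' @export
build_index <- function(genome, probe_length = 25) {
  if (length(genome) == 0) abort_input("cannot index an empty genome")
  if (probe_length < 10) abort_input("probe_length must be >= 10")
  structure(list(genome = genome, probe_length = as.integer(probe_length),
                 seed_break = as.integer(probe_length %/% 2)),
            class = "probe_index")
}

#' @export
print.probe_index <- function(x, ...) {
  cat(sprintf("<probe_index> %d sequence(s), %s bases, probe length %d (seeds %d+%d)\n",
              length(x$genome), format(sum(Biostrings::width(x$genome)),
                                       big.mark = ","),
              x$probe_length, x$seed_break, x$probe_length - x$seed_break))
  invisible(x)
}

# all Hamming<=max_mismatch placements of unique sequences on a subject set;
# returns tibble(sequence, chrom, start, strand, mismatch_count)
scan_sequences <- function(seqs, subjects, max_mismatch) {
  if (!max_mismatch %in% c(0L, 1L))
    abort_input("only 0 or 1 mismatches are supported (gaps are not modelled)")
  seqs <- unique(seqs)
  out <- vector("list", 0)
  for (w in sort(unique(nchar(seqs)))) {
    grp <- seqs[nchar(seqs) == w]
    fwd <- Biostrings::DNAStringSet(grp)
    for (strand in c("+", "-")) {
      pats <- if (strand == "+") fwd else Biostrings::reverseComplement(fwd)
      hits <- match_with_budget(pats, subjects, w, max_mismatch)
      if (nrow(hits)) {
        hits$sequence <- grp[hits$pat]
        hits$strand <- strand
        out[[length(out) + 1L]] <- hits[, c("sequence", "chrom", "start",
                                            "strand", "mismatch_count")]
      }
    }
  }
  if (!length(out))
    return(tibble(sequence = character(), chrom = character(),
                  start = integer(), strand = character(),
                  mismatch_count = integer()))
  bind_rows(out) |> distinct()
}

match_with_budget <- function(pats, subjects, w, max_mismatch) {
  h <- w %/% 2L
  dicts <- if (max_mismatch == 0L) {
    list(Biostrings::PDict(pats))
  } else {
    list(Biostrings::PDict(pats, tb.start = 1L, tb.end = h),
         Biostrings::PDict(pats, tb.start = h + 1L, tb.end = w))
  }
  res <- list()
  for (chrom in names(subjects)) {
    subj <- subjects[[chrom]]
    if (length(subj) < w) next
    starts <- lapply(dicts, function(d) {
      Biostrings::startIndex(
        Biostrings::matchPDict(d, subj, max.mismatch = max_mismatch))
    })
    for (i in seq_along(pats)) {
      st <- sort(unique(unlist(lapply(starts, `[[`, i))))
      if (!length(st)) next
      mm <- if (max_mismatch == 0L) integer(length(st)) else
        Biostrings::neditStartingAt(pats[[i]], subj, starting.at = st,
                                    with.indels = FALSE)
      res[[length(res) + 1L]] <- tibble(pat = i, chrom = chrom,
                                        start = as.integer(st),
                                        mismatch_count = as.integer(mm))
    }
  }
  if (!length(res))
    return(tibble(pat = integer(), chrom = character(), start = integer(),
                  mismatch_count = integer()))
  bind_rows(res)
}

#' Align probes to the genome with at most one mismatch
#'
#' Every distinct (chromosome, start, strand) placement with Hamming
#' distance <= `max_mismatch` is reported and labelled `full_match`
#' (0 mismatches) or `mismatch` (exactly 1).  Probes whose placement count
#' exceeds `max_hits` are discarded as promiscuous, even when all their
#' placements are full matches; their alignments are suppressed and the hit
#' count is recorded in the disposition table.  Probes containing `N` are
#' excluded with disposition `ambiguous_sequence` because mismatch counting
#' against an ambiguous base is undefined.
#'
#' @param probes Probe tibble (see [read_probe_table()]).
#' @param genome A [Biostrings::DNAStringSet] or a `probe_index`.
#' @param max_mismatch Maximum substitutions tolerated (0 or 1; default 1).
#' @param max_hits Promiscuity cap on distinct genomic placements
#'   (default 100).
#' @return A list of class `probe_map`: `alignments` (one row per placement:
#'   `probe_name`, `chrom`, `strand`, `start`, `end`, `blocks`, `n_blocks`,
#'   `mismatch_count`, `match_status`, `source`, `transcript_id`) and
#'   `dispositions` (`probe_name`, `disposition`, `n_hits`).
#' @export
align_probes_genomic <- function(probes, genome, max_mismatch = 1,
                                 max_hits = 100) {
  if (inherits(genome, "probe_index")) genome <- genome$genome
  has_n <- grepl("[^ACGT]", toupper(probes$sequence))
  clean <- probes[!has_n, , drop = FALSE]
  hits <- scan_sequences(clean$sequence, genome, as.integer(max_mismatch))
  per_seq <- hits |> count(.data$sequence, name = "n_hits")
  seq_tab <- tibble(sequence = unique(toupper(clean$sequence))) |>
    left_join(per_seq, by = "sequence") |>
    mutate(n_hits = tidyr::replace_na(.data$n_hits, 0L),
           disposition = dplyr::case_when(
             n_hits == 0L ~ "unmapped",
             n_hits > max_hits ~ "discarded_promiscuous",
             TRUE ~ "mapped"))
  kept <- hits |>
    inner_join(seq_tab |> filter(.data$disposition == "mapped") |>
                 select("sequence"), by = "sequence")
  aln <- probes |>
    mutate(sequence = toupper(.data$sequence)) |>
    select("probe_name", "sequence") |>
    inner_join(kept, by = "sequence", relationship = "many-to-many") |>
    mutate(end = .data$start + nchar(.data$sequence) - 1L,
           blocks = sprintf("%d-%d", .data$start, .data$end),
           n_blocks = 1L,
           match_status = if_else(.data$mismatch_count == 0L,
                                  "full_match", "mismatch"),
           source = "genomic", transcript_id = NA_character_) |>
    select("probe_name", "chrom", "strand", "start", "end", "blocks",
           "n_blocks", "mismatch_count", "match_status", "source",
           "transcript_id") |>
    arrange(.data$chrom, .data$start, .data$strand, .data$probe_name)
  disp <- probes |>
    mutate(sequence = toupper(.data$sequence)) |>
    left_join(seq_tab, by = "sequence") |>
    mutate(disposition = if_else(grepl("[^ACGT]", .data$sequence),
                                 "ambiguous_sequence", .data$disposition),
           n_hits = if_else(.data$disposition == "ambiguous_sequence",
                            0L, .data$n_hits)) |>
    select("probe_name", "disposition", "n_hits") |>
    arrange(.data$probe_name)
  structure(list(alignments = aln, dispositions = disp),
            class = "probe_map")
}

#' @export
print.probe_map <- function(x, ...) {
  tab <- table(x$dispositions$disposition)
  cat(sprintf("<probe_map> %d alignment(s) for %d probe(s)\n",
              nrow(x$alignments), nrow(x$dispositions)))
  for (d in names(tab)) cat(sprintf("  %-22s %d\n", d, tab[[d]]))
  invisible(x)
}

#' Spliced cDNA sequences of transcript models
#'
#' @param transcripts Transcript tibble (see [read_gene_models()]).
#' @param genome A [Biostrings::DNAStringSet].
#' @return A [Biostrings::DNAStringSet] named by `transcript_id`, sense
#'   strand of each transcript.
#' @export
get_cdna <- function(transcripts, genome) {
  seqs <- pmap(transcripts, function(transcript_id, chrom, strand, exons, ...) {
    chunks <- substring(as.character(genome[[chrom]]), exons[, 1], exons[, 2])
    if (strand == "-") chunks <- revcomp(chunks)
    paste(chunks, collapse = "")
  })
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- transcripts$transcript_id
  out
}

#' Align probes to spliced transcript (cDNA) sequences
#'
#' The same 0/1-mismatch search is run against each spliced transcript
#' sequence, in both orientations; antisense placements carry
#' `cdna_strand = "-"`.  This recovers probes that straddle exon-exon
#' junctions and are therefore invisible to the genomic search.
#'
#' @inheritParams align_probes_genomic
#' @param transcripts Transcript tibble.
#' @return A tibble `probe_name`, `transcript_id`, `cdna_start`,
#'   `cdna_strand`, `mismatch_count`.
#' @export
align_probes_cdna <- function(probes, transcripts, genome, max_mismatch = 1) {
  cdna <- get_cdna(transcripts, genome)
  clean <- probes[!grepl("[^ACGT]", toupper(probes$sequence)), , drop = FALSE]
  hits <- scan_sequences(clean$sequence, cdna, as.integer(max_mismatch))
  probes |>
    mutate(sequence = toupper(.data$sequence)) |>
    select("probe_name", "sequence") |>
    inner_join(hits, by = "sequence", relationship = "many-to-many") |>
    rename(transcript_id = "chrom", cdna_start = "start",
           cdna_strand = "strand") |>
    select("probe_name", "transcript_id", "cdna_start", "cdna_strand",
           "mismatch_count") |>
    arrange(.data$transcript_id, .data$cdna_start, .data$probe_name)
}

#' Project cDNA placements to genomic block coordinates
#'
#' A probe interval on the spliced transcript is clipped against the exon
#' chain, producing one genomic block per touched exon, reported in
#' ascending genomic order.  The genomic strand is the transcript strand
#' composed with the cDNA hit orientation.
#'
#' @param cdna_hits Output of [align_probes_cdna()] plus a `probe_length`
#'   attribute per row (taken from the probe table).
#' @param transcripts Transcript tibble.
#' @param probes Probe tibble (for probe lengths).
#' @return An alignment tibble with `source = "cdna_projected"`.
#' @export
project_to_genome <- function(cdna_hits, transcripts, probes) {
  if (nrow(cdna_hits) == 0) return(empty_alignments())
  tx <- transcripts |> select("transcript_id", "chrom", "strand", "exons",
                              "spliced_length")
  lens <- probes |> mutate(len = nchar(.data$sequence)) |>
    select("probe_name", "len")
  hits <- cdna_hits |>
    left_join(tx, by = "transcript_id") |>
    left_join(lens, by = "probe_name")
  rows <- pmap(hits, function(probe_name, transcript_id, cdna_start,
                              cdna_strand, mismatch_count, chrom, strand,
                              exons, spliced_length, len) {
    if (cdna_start < 1 || cdna_start + len - 1L > spliced_length)
      abort_input(paste0("cDNA offset out of range for ", transcript_id))
    b <- spliced_to_genomic(exons, strand, cdna_start, cdna_start + len - 1L)
    g_strand <- if (cdna_strand == "+") strand else flip_strand(strand)
    tibble(probe_name = probe_name, chrom = chrom, strand = g_strand,
           start = min(b[, 1]), end = max(b[, 2]),
           blocks = format_blocks(list(b)), n_blocks = nrow(b),
           mismatch_count = as.integer(mismatch_count),
           match_status = if (mismatch_count == 0) "full_match" else "mismatch",
           source = "cdna_projected", transcript_id = transcript_id)
  })
  bind_rows(rows) |>
    arrange(.data$chrom, .data$start, .data$strand, .data$probe_name)
}

# map a spliced interval [s5, e5] (transcript coordinates) through the exon
# chain; returns genomic blocks sorted ascending by start
spliced_to_genomic <- function(exons, strand, s5, e5) {
  lens <- exons[, 2] - exons[, 1] + 1L
  offs <- cumsum(c(0L, lens[-length(lens)]))
  out <- list()
  for (i in seq_len(nrow(exons))) {
    lo <- max(s5, offs[i] + 1L)
    hi <- min(e5, offs[i] + lens[i])
    if (lo > hi) next
    a <- lo - offs[i]  # 1-based offset within exon, transcript orientation
    b <- hi - offs[i]
    blk <- if (strand == "+") {
      c(exons[i, 1] + a - 1L, exons[i, 1] + b - 1L)
    } else {
      c(exons[i, 2] - b + 1L, exons[i, 2] - a + 1L)
    }
    out[[length(out) + 1L]] <- blk
  }
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  colnames(m) <- c("start", "end")
  m
}

empty_alignments <- function() {
  tibble(probe_name = character(), chrom = character(), strand = character(),
         start = integer(), end = integer(), blocks = character(),
         n_blocks = integer(), mismatch_count = integer(),
         match_status = character(), source = character(),
         transcript_id = character())
}

#' Merge genomic and cDNA-projected alignments
#'
#' A projected single-block placement identical in (chromosome, blocks,
#' strand) to a genomic placement is reported once, labelled genomic;
#' junction placements (>= 2 blocks) are always retained as
#' `cdna_projected`.  The promiscuity cap has already been applied to the
#' genomic route only.
#'
#' @param genomic Alignment tibble from [align_probes_genomic()].
#' @param projected Alignment tibble from [project_to_genome()].
#' @return The unified alignment tibble.
#' @export
merge_alignments <- function(genomic, projected) {
  if (nrow(projected) == 0) return(genomic)
  key <- function(d) paste(d$probe_name, d$chrom, d$strand, d$blocks)
  dup_single <- projected$n_blocks == 1L & key(projected) %in% key(genomic)
  kept <- projected[!dup_single, , drop = FALSE] |>
    distinct(.data$probe_name, .data$chrom, .data$strand, .data$blocks,
             .data$transcript_id, .keep_all = TRUE)
  bind_rows(genomic, kept) |>
    arrange(.data$chrom, .data$start, .data$strand, .data$probe_name)
}

#' Map probes end to end (collapse, genomic + cDNA search, merge)
#'
#' Convenience driver running [collapse_probes()] semantics implicitly:
#' alignment is computed once per unique sequence and fanned out to member
#' probes.
#'
#' @inheritParams align_probes_genomic
#' @param transcripts Optional transcript tibble; when given, the cDNA
#'   route is run and merged in.
#' @return A `probe_map` list: `alignments`, `dispositions`.
#' @export
map_probes <- function(probes, genome, transcripts = NULL, max_mismatch = 1,
                       max_hits = 100) {
  pm <- align_probes_genomic(probes, genome, max_mismatch, max_hits)
  if (!is.null(transcripts) && nrow(transcripts)) {
    # promiscuous probes stay suppressed on the cDNA route too: a discarded
    # probe must not resurface through a transcript copy of its repeat
    ok <- pm$dispositions$probe_name[
      pm$dispositions$disposition != "discarded_promiscuous"]
    cand <- probes[probes$probe_name %in% ok, , drop = FALSE]
    ch <- align_probes_cdna(cand, transcripts, genome, max_mismatch)
    pr <- project_to_genome(ch, transcripts, cand)
    pm$alignments <- merge_alignments(pm$alignments, pr)
  }
  pm
}
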