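#' Read a genome FASTA into a reference object
#'
#' Sequences are uppercased on read: soft-masking (lowercase) marks repeats
#' for heuristic aligners but is irrelevant to an exact 0/1-mismatch search,
#' so it is normalised away.  Only `A`, `C`, `G`, `T`, `N` are accepted.
#'
#' @param path Path to a (possibly soft-masked) FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort_input(paste0("genome FASTA not found: ", path))
  if (file.size(path) == 0) {
    warn("empty genome FASTA; returning an empty genome")
    return(Biostrings::DNAStringSet())
  }
  gn <- Biostrings::readDNAStringSet(path)
  names(gn) <- sub("\\s.*$", "", names(gn))
  if (anyDuplicated(names(gn)))
    abort_input(paste0("duplicate chromosome name in ", path, ": ",
                       names(gn)[duplicated(names(gn))][1]))
  gn <- Biostrings::DNAStringSet(toupper(as.character(gn)))
  # DNAStringSet already rejects non-IUPAC letters; restrict further to ACGTN
  freq <- Biostrings::alphabetFrequency(gn)
  extra <- rowSums(freq[, setdiff(colnames(freq), c("A", "C", "G", "T", "N")),
                        drop = FALSE])
  if (any(extra > 0))
    abort_input("genome contains characters outside {A,C,G,T,N}")
  gn
}

#' Write a genome reference to FASTA
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70)
  invisible(path)
}

#' Chromosome lengths of a genome reference
#' @param genome A [Biostrings::DNAStringSet].
#' @return A tibble with columns `chrom`, `length`.
#' @export
genome_lengths <- function(genome) {
  tibble(chrom = names(genome), length = Biostrings::width(genome))
}

#' Read gene models from a GTF file
#'
#' Exon features are grouped per transcript and ordered 5' to 3' in
#' transcript orientation.  The annotated 3' UTR length is computed as the
#' number of exonic bases strictly downstream (3'-ward) of the CDS end;
#' transcripts without CDS features get `utr3_length = 0`.
#'
#' @param path Path to a GTF with `gene_id`/`transcript_id` attributes.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `exons` (list of start/end matrices in transcript
#'   order), `n_exons`, `tx_start`, `tx_end`, `spliced_length`, `cds_start`,
#'   `cds_end`, `utr3_length`, `biotype`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort_input(paste0("GTF not found: ", path))
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS")]
  if (length(gr) == 0) abort_input(paste0("no exon/CDS features in ", path))
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    biotype = if ("gene_biotype" %in% names(S4Vectors::mcols(gr)))
      gr$gene_biotype else "protein_coding"
  )
  if (any(is.na(df$transcript_id) & df$type == "exon"))
    abort_input("exon feature without transcript_id")
  build_transcripts(df)
}

build_transcripts <- function(df) {
  ex <- df[df$type == "exon", ]
  cds <- df[df$type == "CDS", ]
  ex |>
    group_by(.data$transcript_id) |>
    group_modify_transcript(cds) |>
    ungroup() |>
    arrange(.data$chrom, .data$tx_start, .data$transcript_id)
}

# not a dplyr group_modify: plain split/apply keeps list-columns simple
group_modify_transcript <- function(grouped, cds) {
  pieces <- dplyr::group_split(grouped)
  cds_by_tx <- split(cds, cds$transcript_id)
  rows <- lapply(pieces, function(p) {
    tid <- p$transcript_id[1]
    strand <- p$strand[1]
    m <- as.matrix(p[order(p$start), c("start", "end")])
    if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2]))
      abort_input(paste0("overlapping exons within transcript ", tid))
    if (strand == "-") m <- m[nrow(m):1, , drop = FALSE]
    colnames(m) <- c("start", "end")
    cc <- cds_by_tx[[tid]]
    cds_start <- if (!is.null(cc) && nrow(cc)) min(cc$start) else NA_integer_
    cds_end <- if (!is.null(cc) && nrow(cc)) max(cc$end) else NA_integer_
    utr3 <- utr3_length_of(m, strand, cds_start, cds_end)
    tibble(
      transcript_id = tid, gene_id = p$gene_id[1], chrom = p$chrom[1],
      strand = strand, exons = list(m), n_exons = nrow(m),
      tx_start = min(m[, 1]), tx_end = max(m[, 2]),
      spliced_length = sum(m[, 2] - m[, 1] + 1L),
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      utr3_length = utr3, biotype = p$biotype[1]
    )
  })
  bind_rows(rows)
}

# exonic bases 3'-ward of the CDS end in transcript orientation
utr3_length_of <- function(exons, strand, cds_start, cds_end) {
  if (is.na(cds_start)) return(0L)
  if (strand == "+") {
    sum(pmax(0L, exons[, 2] - pmax(exons[, 1], cds_end + 1L) + 1L) *
          (exons[, 2] > cds_end))
  } else {
    sum(pmax(0L, pmin(exons[, 2], cds_start - 1L) - exons[, 1] + 1L) *
          (exons[, 1] < cds_start))
  }
}

#' Write gene models to GTF (exon and CDS features, Ensembl-style attributes)
#' @param transcripts Transcript tibble as from [read_gene_models()].
#' @param path Output path.
#' @export
write_gene_models <- function(transcripts, path) {
  rows <- pmap(transcripts, function(transcript_id, gene_id, chrom, strand,
                                     exons, cds_start, cds_end, biotype, ...) {
    ex <- tibble(chrom = chrom, start = exons[, 1], end = exons[, 2],
                 strand = strand, type = "exon")
    out <- ex
    if (!is.na(cds_start)) {
      cd <- ex |>
        mutate(start = pmax(.data$start, cds_start),
               end = pmin(.data$end, cds_end), type = "CDS") |>
        filter(.data$start <= .data$end)
      out <- bind_rows(ex, cd)
    }
    out$gene_id <- gene_id
    out$transcript_id <- transcript_id
    out$gene_biotype <- biotype
    out
  })
  df <- bind_rows(rows) |> arrange(.data$chrom, .data$start, .data$transcript_id,
                                   dplyr::desc(.data$type))
  gr <- GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
    type = df$type, gene_id = df$gene_id, transcript_id = df$transcript_id,
    gene_biotype = df$gene_biotype,
    phase = ifelse(df$type == "CDS", 0L, NA_integer_)
  )
  rtracklayer::export(gr, path, format = "gtf")
  # drop volatile comment lines so identical inputs give identical files
  ln <- readLines(path)
  keep <- !grepl("^##(source-version|date)", ln)
  writeLines(ln[keep], path)
  invisible(path)
}

#' Read a manufacturer-style probe table
#'
#' Expected tab-delimited columns: `probeset_id`, `x`, `y`, `sequence`, and
#' optionally `array_name`.  Probe names follow the manufacturer convention
#' `probeset:x:y`.
#'
#' @param path Path to the TSV.
#' @return A tibble with `probe_name`, `probeset_id`, `array_name`, `x`,
#'   `y`, `sequence`.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) abort_input(paste0("probe table not found: ", path))
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("probeset_id", "x", "y", "sequence")
  if (!all(need %in% names(tb)))
    abort_input(paste0("probe table must have columns ",
                       paste(need, collapse = ", ")))
  if (!"array_name" %in% names(tb)) tb$array_name <- "array1"
  bad <- which(is.na(tb$sequence) | nchar(tb$sequence) < 10)
  if (length(bad))
    abort_input(paste0("malformed probe row at line ", bad[1] + 1L,
                       ": sequence missing or shorter than 10 nt"))
  tb |>
    mutate(probe_name = paste(.data$probeset_id, .data$x, .data$y, sep = ":"),
           sequence = toupper(.data$sequence)) |>
    select("probe_name", "probeset_id", "array_name", "x", "y", "sequence")
}

#' Write a probe table TSV
#' @param probes Probe tibble.
#' @param path Output path.
#' @export
write_probe_table <- function(probes, path) {
  readr::write_tsv(probes[, c("probeset_id", "x", "y", "sequence",
                              "array_name")], path, progress = FALSE)
  invisible(path)
}

#' Write probe sequences as FASTA
#' @param probes Probe tibble with `probe_name` and `sequence`.
#' @param path Output path.
#' @export
write_probe_fasta <- function(probes, path) {
  ss <- Biostrings::DNAStringSet(probes$sequence)
  names(ss) <- probes$probe_name
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Read variants from a minimal VCF
#'
#' Only the first eight columns are used.  Positions are 1-based.
#'
#' @param path Path to an uncompressed VCF (>= 4.0).
#' @param genome Optional genome to validate positions against.
#' @return A tibble `chrom`, `pos`, `id`, `ref`, `alt`.
#' @export
read_variants <- function(path, genome = NULL) {
  if (!file.exists(path)) abort_input(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1,
                                     dimnames = list(NULL, names(fx)))
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  out <- tibble(
    chrom = fx$CHROM, pos = as.integer(fx$POS),
    id = dplyr::coalesce(fx$ID, "."), ref = fx$REF, alt = fx$ALT
  )
  if (any(is.na(out$pos)))
    abort_input(paste0("malformed VCF row at record ",
                       which(is.na(out$pos))[1]))
  if (!is.null(genome)) {
    gl <- genome_lengths(genome)
    chk <- left_join(out, gl, by = "chrom")
    if (any(is.na(chk$length) | chk$pos > chk$length | chk$pos < 1))
      abort_input("VCF position outside chromosome bounds")
  }
  out
}

#' Write variants as a minimal 8-column VCF
#' @param variants Tibble `chrom`, `pos`, `id`, `ref`, `alt`.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       variants$chrom, variants$pos,
                       dplyr::coalesce(variants$id, "."),
                       variants$ref, variants$alt), con)
  }
  invisible(path)
}

#' Write probe alignments as BED12
#'
#' Internal 1-based inclusive coordinates are converted to BED's 0-based
#' half-open convention at this boundary only.  Multi-block (exon junction)
#' alignments use blockCount/blockSizes/blockStarts.
#'
#' @param alignments Alignment tibble (see [align_probes_genomic()]).
#' @param path Output path.
#' @export
write_probe_features <- function(alignments, path) {
  if (nrow(alignments) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bl <- parse_blocks(alignments$blocks)
  blocks <- IRanges::IRangesList(lapply(seq_along(bl), function(i) {
    b <- bl[[i]]
    IRanges::IRanges(b[, 1] - alignments$start[i] + 1L,
                     b[, 2] - alignments$start[i] + 1L)
  }))
  gr <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(alignments$start, alignments$end),
    strand = alignments$strand,
    name = alignments$probe_name,
    score = alignments$mismatch_count,
    thick = IRanges::IRanges(alignments$start, alignments$end),
    blocks = blocks
  )
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write / read the full-fidelity alignment table
#'
#' BED12 is emitted for genome browsers; pipeline stages exchange this TSV
#' instead because BED cannot carry the match status, source and transcript
#' fields without lossy encoding.
#'
#' @param alignments Alignment tibble.
#' @param path TSV path.
#' @export
write_alignments <- function(alignments, path) {
  readr::write_tsv(alignments, path, progress = FALSE, na = "")
  invisible(path)
}

#' @rdname write_alignments
#' @export
read_alignments <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = character(),
                  col_types = readr::cols(
                    probe_name = "c", chrom = "c", strand = "c", start = "i",
                    end = "i", blocks = "c", n_blocks = "i",
                    mismatch_count = "i", match_status = "c", source = "c",
                    transcript_id = "c")) |>
    mutate(transcript_id = if_else(.data$transcript_id == "",
                                   NA_character_, .data$transcript_id))
}

#' Write / read the probeset annotation table
#'
#' One row per (probeset, transcript) with the matched-probe count, the
#' dynamic probeset size, the verdict, and the per-probe reasons serialised
#' as `probe=reason` pairs separated by `;`.
#'
#' @param annotations Annotation tibble from [annotate_probesets()].
#' @param path TSV path.
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations |>
    mutate(reasons = map_chr(.data$reasons, function(r) {
      paste(sprintf("%s=%s", r$probe_name, r$reason), collapse = ";")
    })) |>
    select("probeset_id", "transcript_id", "gene_id", "n_matched",
           "probeset_size", "annotated", "reasons")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          probeset_id = "c", transcript_id = "c",
                          gene_id = "c", n_matched = "i", probeset_size = "i",
                          annotated = "l", reasons = "c"))
  tb$reasons <- lapply(tb$reasons, function(s) {
    if (is.na(s) || s == "") return(tibble(probe_name = character(),
                                           reason = character()))
    kv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    tibble(probe_name = map_chr(kv, 1), reason = map_chr(kv, 2))
  })
  tb
}
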