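#' Genomic regions of a transcript in transcript order
#'
#' Exons are split into 5' UTR, coding exon and 3' UTR parts using the CDS
#' span (a transcript without CDS is all `exon`), introns are inserted
#' between exons, and every region carries its 5'-to-3' order so border
#' placements can be attributed to their most-5' region.
#'
#' @param exons Exon matrix in transcript orientation.
#' @param strand Transcript strand.
#' @param cds_start,cds_end Genomic CDS span (NA when absent).
#' @return A tibble `type`, `g_start`, `g_end`, `ord`.
#' @keywords internal
transcript_regions <- function(exons, strand, cds_start, cds_end) {
  regions <- list()
  ord <- 0L
  push <- function(type, gs, ge) {
    if (gs > ge) return()
    ord <<- ord + 1L
    regions[[ord]] <<- tibble(type = type, g_start = gs, g_end = ge,
                              ord = ord)
  }
  no_cds <- is.na(cds_start)
  for (i in seq_len(nrow(exons))) {
    s <- exons[i, 1]; e <- exons[i, 2]
    if (no_cds) {
      push("exon", s, e)
    } else if (strand == "+") {
      push("utr5", s, min(e, cds_start - 1L))
      push("exon", max(s, cds_start), min(e, cds_end))
      push("utr3", max(s, cds_end + 1L), e)
    } else {
      # transcript orientation: 5' portion has higher genomic coordinates
      push("utr5", max(s, cds_end + 1L), e)
      push("exon", max(s, cds_start), min(e, cds_end))
      push("utr3", s, min(e, cds_start - 1L))
    }
    if (i < nrow(exons)) {
      nxt <- exons[i + 1L, ]
      if (strand == "+") push("intron", e + 1L, nxt[1] - 1L)
      else push("intron", nxt[2] + 1L, s - 1L)
    }
  }
  bind_rows(regions)
}

#' Classify one probe placement relative to one transcript
#'
#' Placements falling entirely within a single region take that region's
#' category; placements spanning a region boundary (or running off the
#' transcript span) are `border`, sub-labelled by the most-5' region they
#' touch in transcript orientation (a probe across an exon-intron boundary
#' is an exon border; across an intron-exon boundary, an intron border).
#' Placements not overlapping the transcript span at all are `intergenic`.
#'
#' @param blocks Alignment block matrix.
#' @param regions Output of [transcript_regions()].
#' @param strand Transcript strand.
#' @return A list with `category` and `sublabel`.
#' @keywords internal
classify_location <- function(blocks, regions, strand) {
  span <- c(min(regions$g_start), max(regions$g_end))
  ov_any <- any(blocks[, 1] <= span[2] & blocks[, 2] >= span[1])
  if (!ov_any) return(list(category = "intergenic", sublabel = "intergenic"))
  covered <- character(0)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    hit <- regions$type[regions$g_start <= b[2] & regions$g_end >= b[1]]
    covered <- c(covered, hit)
    if (b[1] < span[1] || b[2] > span[2]) covered <- c(covered, "intergenic")
  }
  covered <- unique(covered)
  if (length(covered) == 1L)
    return(list(category = covered, sublabel = covered))
  # most-5' base of the placement in transcript orientation
  base5 <- if (strand == "+") min(blocks[, 1]) else max(blocks[, 2])
  at5 <- regions$type[regions$g_start <= base5 & regions$g_end >= base5]
  list(category = "border",
       sublabel = if (length(at5)) at5[1] else "intergenic")
}

profile_categories <- c("exon", "utr5", "utr3", "intron", "intergenic",
                        "border")
coding_categories <- c("exon", "utr5", "utr3")

#' Profile unannotated probesets by probe location
#'
#' Every probe placement of an unannotated probeset is classified against
#' every associated transcript (all transcripts whose gene span overlaps at
#' least one placement of the probeset; a single probe hit can be exonic on
#' one transcript and intronic on another).  Category counts are divided by
#' the number of associated transcripts and centred to sum one, then
#' collapsed to ternary coordinates: coding (exon + UTRs), border, and
#' non-coding (intron + intergenic).
#'
#' Flags follow the published conventions: `putative_coding` marks
#' probesets with under half their probes mapped but at least half of the
#' mapped ones in coding regions (probesets that would likely be annotated
#' had more probes mapped); `noncoding_gene` marks probesets whose mapped
#' probes fall mostly within gene models of non-protein-coding biotype.
#'
#' @param probes Probe tibble.
#' @param alignments Merged alignment tibble.
#' @param transcripts Transcript tibble to classify against.
#' @param annotations Output of [annotate_probesets()] (defines which
#'   probesets are unannotated).
#' @return A tibble with one row per unannotated probeset: `probeset_id`,
#'   `n_transcripts`, the six category ratios, `coding`, `noncoding`,
#'   `flag`.  (`border` is both a category ratio and the middle ternary
#'   coordinate.)
#' @export
profile_probesets <- function(probes, alignments, transcripts, annotations) {
  unann <- unannotated_probesets(probes, annotations)
  if (!length(unann)) return(empty_profile())
  member <- probes |> filter(.data$probeset_id %in% unann) |>
    select("probe_name", "probeset_id")
  sizes <- member |> count(.data$probeset_id, name = "size")
  al <- alignments |>
    inner_join(member, by = "probe_name", relationship = "many-to-many") |>
    distinct(.data$probeset_id, .data$probe_name, .data$chrom, .data$strand,
             .data$blocks, .keep_all = TRUE)
  spans <- transcripts |>
    group_by(.data$gene_id) |>
    mutate(g_start = min(.data$tx_start), g_end = max(.data$tx_end)) |>
    ungroup()
  regions_by_tx <- lapply(seq_len(nrow(spans)), function(i) {
    transcript_regions(spans$exons[[i]], spans$strand[i],
                       spans$cds_start[i], spans$cds_end[i])
  })
  names(regions_by_tx) <- spans$transcript_id
  noncoding_genes <- unique(spans$gene_id[spans$biotype != "protein_coding"])
  rows <- lapply(unann, function(ps) {
    pal <- al[al$probeset_id == ps, , drop = FALSE]
    size <- sizes$size[sizes$probeset_id == ps]
    if (nrow(pal) == 0) {
      message("probeset ", ps, " has no mapped probes; ",
              "profiled as fully non-coding by convention")
      return(profile_row(ps, 1L, stats::setNames(numeric(6),
                                                 profile_categories),
                         size, 0L, 0L, 0L))
    }
    hit_gene <- vapply(seq_len(nrow(spans)), function(i) {
      any(pal$chrom == spans$chrom[i] & pal$start <= spans$g_end[i] &
            pal$end >= spans$g_start[i])
    }, logical(1))
    assoc <- spans[hit_gene, , drop = FALSE]
    n_tx <- max(1L, nrow(assoc))
    cats <- character(0)
    per_probe <- list()
    for (j in seq_len(nrow(pal))) {
      blocks <- parse_blocks(pal$blocks[j])[[1]]
      pcats <- if (nrow(assoc) == 0) "intergenic" else
        vapply(seq_len(nrow(assoc)), function(k) {
          if (assoc$chrom[k] != pal$chrom[j]) return("intergenic")
          classify_location(blocks, regions_by_tx[[assoc$transcript_id[k]]],
                            assoc$strand[k])$category
        }, character(1))
      cats <- c(cats, pcats)
      pn <- pal$probe_name[j]
      per_probe[[pn]] <- c(per_probe[[pn]], pcats)
    }
    counts <- vapply(profile_categories, function(cc) sum(cats == cc),
                     numeric(1))
    n_mapped <- length(unique(pal$probe_name))
    n_coding_probes <- sum(vapply(per_probe, function(v) {
      mean(v %in% coding_categories) >= 0.5
    }, logical(1)))
    gene_hits <- al |>
      filter(.data$probeset_id == ps) |>
      inner_join(spans |> select("gene_id", "chrom", "g_start", "g_end") |>
                   distinct(),
                 by = "chrom", relationship = "many-to-many") |>
      filter(.data$start <= .data$g_end, .data$end >= .data$g_start)
    n_noncoding_probes <- gene_hits |>
      filter(.data$gene_id %in% noncoding_genes) |>
      pull("probe_name") |> unique() |> length()
    profile_row(ps, n_tx, counts, size, n_mapped, n_coding_probes,
                n_noncoding_probes)
  })
  bind_rows(rows)
}

profile_row <- function(ps, n_tx, counts, size, n_mapped, n_coding,
                        n_noncoding) {
  ratios <- counts / n_tx
  tot <- sum(ratios)
  centred <- if (tot > 0) ratios / tot else
    stats::setNames(c(0, 0, 0, 0, 1, 0), profile_categories)
  flag <- if (n_mapped > 0 && n_noncoding > n_mapped / 2) "noncoding_gene"
  else if (n_mapped > 0 && n_mapped < size / 2 &&
           n_coding >= n_mapped / 2) "putative_coding"
  else "plain"
  tibble(
    probeset_id = ps, n_transcripts = n_tx,
    exon = centred[["exon"]], utr5 = centred[["utr5"]],
    utr3 = centred[["utr3"]], intron = centred[["intron"]],
    intergenic = centred[["intergenic"]], border = centred[["border"]],
    coding = centred[["exon"]] + centred[["utr5"]] + centred[["utr3"]],
    noncoding = centred[["intron"]] + centred[["intergenic"]],
    flag = flag
  )
}

empty_profile <- function() {
  tibble(probeset_id = character(), n_transcripts = integer(),
         exon = numeric(), utr5 = numeric(), utr3 = numeric(),
         intron = numeric(), intergenic = numeric(), border = numeric(),
         coding = numeric(), noncoding = numeric(), flag = character())
}

#' Profile unannotated probesets against an alternative gene set
#'
#' Runs the identical location profiling against a second set of gene
#' models (for example EST-based predictions) while keeping the
#' unannotated set defined by the primary annotation, so the two profiles
#' can be compared side by side.
#'
#' @inheritParams profile_probesets
#' @param est_transcripts The alternative transcript tibble.
#' @return A profile tibble (see [profile_probesets()]).
#' @export
profile_against_second_geneset <- function(probes, alignments,
                                           est_transcripts, annotations) {
  if (nrow(est_transcripts) == 0) {
    # with no models every placement is intergenic
    unann <- unannotated_probesets(probes, annotations)
    sizes <- probes |> filter(.data$probeset_id %in% unann) |>
      count(.data$probeset_id, name = "size")
    member <- probes |> select("probe_name", "probeset_id")
    rows <- lapply(unann, function(ps) {
      pal <- alignments |>
        inner_join(member |> filter(.data$probeset_id == ps),
                   by = "probe_name")
      counts <- stats::setNames(numeric(6), profile_categories)
      counts[["intergenic"]] <- nrow(pal)
      profile_row(ps, 1L, counts, sizes$size[sizes$probeset_id == ps],
                  length(unique(pal$probe_name)), 0L, 0L)
    })
    return(bind_rows(rows))
  }
  profile_probesets(probes, alignments, est_transcripts, annotations)
}
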