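test_that("species extension is the larger of mean and median UTR length", {
  mk <- function(lens) {
    dplyr::bind_rows(lapply(seq_along(lens), function(i) {
      tx_row(paste0("T", i), paste0("G", i), "c1", "+",
             cbind(1L, 1000L))
    })) |> dplyr::mutate(utr3_length = as.integer(lens))
  }
  expect_equal(compute_extension_policy(mk(c(100, 200, 600)))$extension_length,
               300L)  # mean 300 beats median 200
  expect_equal(compute_extension_policy(mk(c(100, 100, 100)))$extension_length,
               100L)
  # transcripts without an annotated UTR are excluded from the statistic
  expect_equal(compute_extension_policy(mk(c(0, 0, 50)))$extension_length,
               50L)
  expect_error(compute_extension_policy(mk(c(0, 0))), "override")
  expect_equal(compute_extension_policy(mk(c(0, 0)),
                                        extension = 400)$extension_length,
               400L)
  # rounding is to the nearest integer, ties up
  expect_equal(compute_extension_policy(mk(c(100, 101)))$extension_length,
               101L)
})

test_that("extension intervals grow 3'-ward and clip at chromosome ends", {
  gl <- tibble::tibble(chrom = "c1", length = 5000L)
  pol <- structure(list(extension_length = 300L, utr_multiplier = 2,
                        clip_at_neighbor = FALSE),
                   class = "extension_policy")
  # '+' strand with an annotated 150 bp UTR: 150 new bases beyond the end
  tx <- tx_row("T1", "G1", "c1", "+", cbind(c(1L, 801L), c(500L, 1000L)),
               cds_start = 100L, cds_end = 850L)
  expect_equal(tx$utr3_length, 150L)
  et <- extend_transcripts(tx, pol, gl)
  expect_equal(c(et$ext_start, et$ext_end), c(1001L, 1150L))
  # '-' strand, no UTR: species extension below the 3' end
  tx2 <- tx_row("T2", "G2", "c1", "-", cbind(c(901L, 500L), c(1100L, 700L)))
  et2 <- extend_transcripts(tx2, pol, gl)
  expect_equal(c(et2$ext_start, et2$ext_end), c(200L, 499L))
  # 3' end at the chromosome end: empty extension
  tx3 <- tx_row("T3", "G3", "c1", "+", cbind(4001L, 5000L))
  et3 <- extend_transcripts(tx3, pol, gl)
  expect_true(is.na(et3$ext_start))
  expect_equal(et3$footprint[[1]], cbind(start = 4001L, end = 5000L),
               ignore_attr = TRUE)
  # 3' end at position 1 on '-': empty extension
  tx4 <- tx_row("T4", "G4", "c1", "-", cbind(1L, 300L))
  et4 <- extend_transcripts(tx4, pol, gl)
  expect_true(is.na(et4$ext_start))
})

test_that("clipping at a downstream neighbour truncates the extension", {
  gl <- tibble::tibble(chrom = "c1", length = 10000L)
  pol <- structure(list(extension_length = 2000L, utr_multiplier = 2,
                        clip_at_neighbor = TRUE),
                   class = "extension_policy")
  txs <- dplyr::bind_rows(
    tx_row("T1", "G1", "c1", "+", cbind(1000L, 2000L)),
    tx_row("T2", "G2", "c1", "+", cbind(3000L, 3500L)))
  et <- extend_transcripts(txs, pol, gl)
  expect_equal(et$ext_end[et$transcript_id == "T1"], 2999L)
})

test_that("probe placements are matched, antisense, intronic or intergenic", {
  gl <- tibble::tibble(chrom = "c1", length = 5000L)
  pol <- structure(list(extension_length = 200L, utr_multiplier = 2,
                        clip_at_neighbor = FALSE),
                   class = "extension_policy")
  tx <- tx_row("T1", "G1", "c1", "+", cbind(c(1001L, 1501L), c(1200L, 1700L)))
  et <- extend_transcripts(tx, pol, gl)
  mk_al <- function(name, start, end, strand, blocks = NULL) {
    tibble::tibble(probe_name = name, chrom = "c1", strand = strand,
                   start = start, end = end,
                   blocks = blocks %||% sprintf("%d-%d", start, end),
                   n_blocks = 1L, mismatch_count = 0L,
                   match_status = "full_match", source = "genomic",
                   transcript_id = NA_character_)
  }
  al <- dplyr::bind_rows(
    mk_al("sense_exon", 1520L, 1544L, "+"),
    mk_al("antisense_exon", 1520L, 1544L, "-"),
    mk_al("intron", 1301L, 1325L, "+"),
    mk_al("in_extension", 1750L, 1774L, "+"),
    mk_al("exon_intron_straddle", 1190L, 1214L, "+"))
  m <- match_probes_to_transcripts(al, et)
  res <- stats::setNames(m$reason, m$probe_name)
  expect_equal(res[["sense_exon"]], "matched")
  expect_equal(res[["antisense_exon"]], "antisense")
  expect_equal(res[["intron"]], "intronic")
  expect_equal(res[["in_extension"]], "matched")  # doubled-UTR territory
  expect_equal(res[["exon_intron_straddle"]], "intronic")
})

test_that("the 50% rule annotates at ceil(size/2) matched probes", {
  expect_equal(annotation_threshold(11), 6L)
  expect_equal(annotation_threshold(16), 8L)
  gl <- tibble::tibble(chrom = "c1", length = 100000L)
  pol <- structure(list(extension_length = 200L, utr_multiplier = 2,
                        clip_at_neighbor = FALSE),
                   class = "extension_policy")
  tx <- tx_row("T1", "G1", "c1", "+", cbind(1001L, 3000L))
  et <- extend_transcripts(tx, pol, gl)
  build_case <- function(size, m, ps) {
    probes <- dplyr::bind_rows(lapply(seq_len(size), function(i) {
      probe_row(ps, i, strrep("A", 25))
    }))
    al <- if (m > 0) tibble::tibble(
      probe_name = probes$probe_name[seq_len(m)], chrom = "c1",
      strand = "+", start = 1100L + seq_len(m) * 30L,
      end = 1124L + seq_len(m) * 30L,
      blocks = sprintf("%d-%d", 1100L + seq_len(m) * 30L,
                       1124L + seq_len(m) * 30L),
      n_blocks = 1L, mismatch_count = 0L, match_status = "full_match",
      source = "genomic", transcript_id = NA_character_)
    else probemapr:::empty_alignments()
    list(probes = probes, al = al)
  }
  cases <- list(list(11, 6, TRUE), list(11, 5, FALSE), list(16, 8, TRUE),
                list(16, 7, FALSE), list(12, 6, TRUE))
  for (cs in cases) {
    cc <- build_case(cs[[1]], cs[[2]], "ps")
    ann <- annotate_probesets(cc$probes, cc$al, et)
    if (cs[[2]] == 0 || nrow(ann) == 0) {
      expect_false(cs[[3]])
    } else {
      expect_equal(ann$annotated, cs[[3]],
                   label = sprintf("size %d matched %d", cs[[1]], cs[[2]]))
      expect_equal(ann$n_matched, cs[[2]])
      expect_equal(ann$probeset_size, cs[[1]])
    }
  }
})

test_that("a probe counts once per transcript however often it places", {
  gl <- tibble::tibble(chrom = "c1", length = 10000L)
  pol <- structure(list(extension_length = 100L, utr_multiplier = 2,
                        clip_at_neighbor = FALSE),
                   class = "extension_policy")
  tx <- tx_row("T1", "G1", "c1", "+", cbind(1001L, 3000L))
  et <- extend_transcripts(tx, pol, gl)
  probes <- dplyr::bind_rows(lapply(1:11, function(i)
    probe_row("ps", i, strrep("A", 25))))
  # one probe placed twice inside the same transcript
  al <- tibble::tibble(
    probe_name = rep(probes$probe_name[1], 2), chrom = "c1", strand = "+",
    start = c(1100L, 1400L), end = c(1124L, 1424L),
    blocks = c("1100-1124", "1400-1424"), n_blocks = 1L,
    mismatch_count = 0L, match_status = "full_match", source = "genomic",
    transcript_id = NA_character_)
  ann <- annotate_probesets(probes, al, et)
  expect_equal(ann$n_matched, 1L)
  expect_false(ann$annotated)
})

test_that("per-probe reasons cover disposition failures and placements", {
  run <- default_run()
  fx <- default_fixture()
  reasons <- run$annotations |>
    dplyr::select(probeset_id, transcript_id, reasons) |>
    tidyr::unnest(reasons)
  expect_true(all(reasons$reason %in%
                    c("matched", "intronic", "antisense", "intergenic",
                      "promiscuous_discarded", "unmapped",
                      "ambiguous_sequence")))
  # every member probe of an emitted record has exactly one reason
  n_by_rec <- reasons |> dplyr::count(probeset_id, transcript_id, probe_name)
  expect_true(all(n_by_rec$n == 1))
  sizes <- fx$probes |> dplyr::count(probeset_id, name = "size")
  rec_sizes <- reasons |>
    dplyr::count(probeset_id, transcript_id, name = "n_probes") |>
    dplyr::left_join(sizes, by = "probeset_id")
  expect_equal(rec_sizes$n_probes, rec_sizes$size)
})

test_that("stored matched counts survive an independent recount", {
  run <- default_run()
  fx <- default_fixture()
  tx <- read_gene_models(fx$paths[["gtf"]])
  gn <- read_genome(fx$paths[["genome"]])
  pol <- compute_extension_policy(tx)
  et <- extend_transcripts(tx, pol, gn)
  member <- fx$probes |> dplyr::select(probe_name, probeset_id)
  fp_by_tx <- stats::setNames(et$footprint, et$transcript_id)
  strand_by_tx <- stats::setNames(et$strand, et$transcript_id)
  chrom_by_tx <- stats::setNames(et$chrom, et$transcript_id)
  for (i in sample.int(nrow(run$annotations),
                       min(25, nrow(run$annotations)))) {
    rec <- run$annotations[i, ]
    fp <- fp_by_tx[[rec$transcript_id]]
    al <- run$alignments |>
      dplyr::inner_join(member[member$probeset_id == rec$probeset_id, ],
                        by = "probe_name")
    ok <- vapply(seq_len(nrow(al)), function(j) {
      if (al$chrom[j] != chrom_by_tx[[rec$transcript_id]]) return(FALSE)
      if (al$strand[j] != strand_by_tx[[rec$transcript_id]]) return(FALSE)
      b <- probemapr:::parse_blocks(al$blocks[j])[[1]]
      all(vapply(seq_len(nrow(b)), function(k) {
        any(fp[, 1] <= b[k, 1] & b[k, 2] <= fp[, 2])
      }, logical(1)))
    }, logical(1))
    expect_equal(length(unique(al$probe_name[ok])), rec$n_matched,
                 label = paste(rec$probeset_id, rec$transcript_id))
  }
})
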