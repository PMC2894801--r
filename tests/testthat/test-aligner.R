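test_that("planted probes are found with the right match status", {
  withr::local_seed(21)
  g <- random_dna(4000)
  probe_exact <- substr(g, 1001, 1025)
  probe_mm <- mutate_base_at(substr(g, 2001, 2025), 13)
  gn <- Biostrings::DNAStringSet(c(c1 = g))
  probes <- dplyr::bind_rows(probe_row("ps1", 1, probe_exact),
                             probe_row("ps1", 2, probe_mm))
  pm <- align_probes_genomic(probes, gn)
  a1 <- pm$alignments[pm$alignments$probe_name == "ps1:1:1", ]
  expect_equal(nrow(a1), 1)
  expect_equal(a1$start, 1001L)
  expect_equal(a1$match_status, "full_match")
  a2 <- pm$alignments[pm$alignments$probe_name == "ps1:2:1", ]
  expect_equal(nrow(a2), 1)
  expect_equal(a2$start, 2001L)
  expect_equal(a2$match_status, "mismatch")
  expect_equal(a2$mismatch_count, 1L)
})

test_that("probes with ambiguous bases are excluded, not aligned", {
  gn <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 100)))
  probes <- probe_row("ps1", 1, paste0(strrep("A", 12), "N",
                                       strrep("C", 12)))
  pm <- align_probes_genomic(probes, gn)
  expect_equal(pm$dispositions$disposition, "ambiguous_sequence")
  expect_equal(nrow(pm$alignments), 0)
})

test_that("the promiscuity cap discards by placement count", {
  withr::local_seed(22)
  unit <- random_dna(30)
  # 7 copies of one unit, 4 of another, separated by random sequence
  g <- paste0(random_dna(200),
              paste(replicate(7, paste0(unit, random_dna(20))),
                    collapse = ""),
              random_dna(200))
  unit2 <- random_dna(30)
  g <- paste0(g, paste(replicate(4, paste0(unit2, random_dna(20))),
                       collapse = ""), random_dna(100))
  gn <- Biostrings::DNAStringSet(c(c1 = g))
  probes <- dplyr::bind_rows(probe_row("ps1", 1, substr(unit, 1, 25)),
                             probe_row("ps1", 2, substr(unit2, 1, 25)))
  pm <- align_probes_genomic(probes, gn, max_hits = 5)
  d <- pm$dispositions
  expect_equal(d$disposition[d$probe_name == "ps1:1:1"],
               "discarded_promiscuous")
  expect_equal(d$n_hits[d$probe_name == "ps1:1:1"], 7L)
  expect_equal(d$disposition[d$probe_name == "ps1:2:1"], "mapped")
  expect_equal(sum(pm$alignments$probe_name == "ps1:1:1"), 0)
  expect_equal(sum(pm$alignments$probe_name == "ps1:2:1"), 4)
  # cap behaviour: hit count <= cap <=> not discarded
  expect_true(all((d$n_hits <= 5) != (d$disposition ==
                                        "discarded_promiscuous")))
})

test_that("genomic search equals the naive Hamming scan exactly", {
  withr::local_seed(23)
  gn <- Biostrings::DNAStringSet(c(c1 = random_dna(4000),
                                   c2 = random_dna(2500)))
  seqs <- as.character(gn)
  mk_probe <- function(i) {
    kind <- i %% 4
    if (kind == 0) random_dna(25)
    else if (kind == 1) substr(seqs[["c1"]], i * 30 + 1, i * 30 + 25)
    else if (kind == 2)
      mutate_base_at(substr(seqs[["c2"]], i * 17 + 1, i * 17 + 25),
                     (i %% 25) + 1)
    else as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(seqs[["c1"]], i * 23 + 1, i * 23 + 25))))
  }
  probes <- dplyr::bind_rows(lapply(1:40, function(i) {
    probe_row(paste0("ps", i), i, mk_probe(i))
  }))
  pm <- align_probes_genomic(probes, gn, max_hits = 1e6)
  got <- pm$alignments |>
    dplyr::select(probe_name, chrom, start, strand, mismatch_count) |>
    dplyr::arrange(probe_name, chrom, start, strand)
  want <- dplyr::bind_rows(lapply(seq_len(nrow(probes)), function(i) {
    h <- naive_scan(probes$sequence[i], gn)
    if (nrow(h)) h$probe_name <- probes$probe_name[i]
    h
  })) |>
    dplyr::select(probe_name, chrom, start, strand, mismatch_count) |>
    dplyr::arrange(probe_name, chrom, start, strand)
  expect_equal(got, want)
})

test_that("allowing one mismatch never loses exact placements", {
  withr::local_seed(24)
  gn <- Biostrings::DNAStringSet(c(c1 = random_dna(3000)))
  probes <- dplyr::bind_rows(lapply(1:12, function(i) {
    probe_row(paste0("ps", i), i,
              substr(as.character(gn[["c1"]]), i * 100, i * 100 + 24))
  }))
  h0 <- align_probes_genomic(probes, gn, max_mismatch = 0)$alignments
  h1 <- align_probes_genomic(probes, gn, max_mismatch = 1)$alignments
  key <- function(d) paste(d$probe_name, d$chrom, d$start, d$strand)
  expect_true(all(key(h0) %in% key(h1)))
  expect_gte(nrow(h1), nrow(h0))
})

test_that("cDNA placements project to exon-clipped genomic blocks", {
  exons <- cbind(c(1L, 201L), c(100L, 300L))
  tx <- tx_row("T1", "G1", "c1", "+", exons)
  probes <- probe_row("ps1", 1, strrep("A", 10))
  hits <- tibble::tibble(probe_name = "ps1:1:1", transcript_id = "T1",
                         cdna_start = 96L, cdna_strand = "+",
                         mismatch_count = 0L)
  al <- project_to_genome(hits, tx, probes)
  expect_equal(al$blocks, "96-100,201-205")
  expect_equal(al$n_blocks, 2L)
  expect_equal(al$strand, "+")

  hits$cdna_start <- 1L
  al2 <- project_to_genome(hits, tx, probes)
  expect_equal(al2$blocks, "1-10")

  hits$cdna_start <- 195L  # runs past the spliced end
  expect_error(project_to_genome(hits, tx, probes), "out of range")
})

test_that("minus-strand projection reproduces the probe on re-extraction", {
  withr::local_seed(25)
  g <- random_dna(600)
  gn <- Biostrings::DNAStringSet(c(c1 = g))
  exons <- cbind(c(301L, 51L), c(400L, 150L))  # transcript order on '-'
  tx <- tx_row("T1", "G1", "c1", "-", exons)
  cdna <- unname(as.character(get_cdna(tx, gn)))
  for (off in c(1L, 95L, 120L)) {
    probe <- substr(cdna, off, off + 24L)
    probes <- probe_row("ps1", 1, probe)
    hits <- tibble::tibble(probe_name = "ps1:1:1", transcript_id = "T1",
                           cdna_start = off, cdna_strand = "+",
                           mismatch_count = 0L)
    al <- project_to_genome(hits, tx, probes)
    expect_equal(al$strand, "-")
    bl <- probemapr:::parse_blocks(al$blocks)[[1]]
    # blocks ascend genomically even though the transcript runs backwards
    expect_true(all(diff(bl[, 1]) > 0))
    pieces <- substring(g, bl[, 1], bl[, 2])
    re <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(paste(pieces, collapse = ""))))
    expect_equal(re, probe)
  }
  # offset 1 on '-' lands at the 3'-most genomic end of the chain
  probes <- probe_row("ps1", 1, substr(cdna, 1, 25))
  hits <- tibble::tibble(probe_name = "ps1:1:1", transcript_id = "T1",
                         cdna_start = 1L, cdna_strand = "+",
                         mismatch_count = 0L)
  al <- project_to_genome(hits, tx, probes)
  expect_equal(al$blocks, "376-400")
})

test_that("junction probes are recovered only through the cDNA route", {
  fx <- default_fixture()
  run <- default_run()
  junction_ps <- fx$truth$probeset_id[fx$truth$intent == "junction_spanning"]
  member <- fx$probes[fx$probes$probeset_id %in% junction_ps, ]
  al <- run$alignments[run$alignments$probe_name %in% member$probe_name, ]
  multi <- al[al$n_blocks >= 2, ]
  expect_gt(nrow(multi), 0)
  expect_true(all(multi$source == "cdna_projected"))
  # junction probes have no genomic placement at all
  junction_names <- unique(multi$probe_name)
  expect_equal(sum(al$source == "genomic" &
                     al$probe_name %in% junction_names), 0)
  # a probe over the short middle exon spans three exons
  expect_true(any(multi$n_blocks == 3))
  b3 <- probemapr:::parse_blocks(multi$blocks[multi$n_blocks == 3][1])[[1]]
  expect_equal(sum(b3[, 2] - b3[, 1] + 1), fx$config$probe_length)
})

test_that("merging deduplicates exonic cDNA hits and keeps junction hits", {
  withr::local_seed(26)
  g <- random_dna(1000)
  gn <- Biostrings::DNAStringSet(c(c1 = g))
  exons <- cbind(c(101L, 401L), c(300L, 600L))
  tx <- tx_row("T1", "G1", "c1", "+", exons)
  cdna <- as.character(get_cdna(tx, gn))
  probes <- dplyr::bind_rows(
    probe_row("ps1", 1, substr(cdna, 50, 74)),    # inside exon 1
    probe_row("ps1", 2, substr(cdna, 188, 212)))  # across the junction
  pm <- map_probes(probes, gn, tx)
  a1 <- pm$alignments[pm$alignments$probe_name == "ps1:1:1", ]
  expect_equal(nrow(a1), 1)
  expect_equal(a1$source, "genomic")
  a2 <- pm$alignments[pm$alignments$probe_name == "ps1:2:1", ]
  expect_equal(nrow(a2), 1)
  expect_equal(a2$source, "cdna_projected")
  expect_equal(a2$n_blocks, 2L)
  # the merge added exactly the junction alignment
  genomic_only <- align_probes_genomic(probes, gn)
  expect_equal(nrow(pm$alignments) - nrow(genomic_only$alignments), 1L)
})

test_that("the seed index validates its inputs", {
  expect_error(build_index(Biostrings::DNAStringSet(), 25), "empty genome")
  gn <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 10)))
  expect_error(build_index(gn, 8), ">= 10")
  idx <- build_index(gn, 25)
  expect_s3_class(idx, "probe_index")
  expect_output(print(idx), "probe_index")
})
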