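test_that("planted multi-gene probesets get their expected verdicts", {
  run <- default_run()
  fx <- default_fixture()
  mg <- run$multi_gene
  truth <- fx$truth
  want <- c(multi_gene_paralog = "paralogous",
            multi_gene_overlap = "overlapping",
            multi_gene_unexplained = "unexplained")
  for (intent in names(want)) {
    ids <- truth$probeset_id[truth$intent == intent]
    got <- mg$verdict[mg$probeset_id %in% ids]
    expect_equal(got, rep(want[[intent]], length(ids)), ignore_attr = TRUE,
                 label = intent)
  }
  # every multi-gene probeset receives exactly one verdict
  expect_equal(anyDuplicated(mg$probeset_id), 0L)
  expect_true(all(mg$n_genes >= 2))
  expect_true(all(mg$verdict %in% c("paralogous", "overlapping", "both",
                                    "unexplained")))
  frac <- table(mg$verdict) / nrow(mg)
  expect_equal(sum(frac), 1)
})

test_that("three-gene probesets follow the pairwise verdict rules", {
  ext <- dplyr::bind_rows(
    tx_row("T1", "G1", "c1", "+", cbind(1000L, 2000L)),
    tx_row("T2", "G2", "c1", "+", cbind(1900L, 3000L)),  # overlaps G1
    tx_row("T3", "G3", "c2", "+", cbind(1000L, 2000L))) |>
    dplyr::mutate(ext_start = NA_integer_, ext_end = NA_integer_,
                  footprint = purrr::map(exons, identity))
  mk_ann <- function(ps, genes) {
    tibble::tibble(probeset_id = ps, transcript_id = paste0("T", 1:3),
                   gene_id = genes, n_matched = 6L, probeset_size = 11L,
                   annotated = TRUE, reasons = list(tibble::tibble()))
  }
  paralogs <- tibble::tibble(gene_a = c("G1", "G2"), gene_b = c("G3", "G3"))
  # all pairs explained, both relation types present -> both
  mg <- explain_multi_gene(mk_ann("ps1", c("G1", "G2", "G3")), paralogs,
                           ext)
  expect_equal(mg$verdict, "both")
  # one unexplained pair poisons the probeset
  mg2 <- explain_multi_gene(mk_ann("ps2", c("G1", "G2", "G3")),
                            tibble::tibble(gene_a = "G1", gene_b = "G3"),
                            ext)
  expect_equal(mg2$verdict, "unexplained")
  # a pair that is both paralogous and overlapping
  mg3 <- explain_multi_gene(
    mk_ann("ps3", c("G1", "G2", "G3"))[1:2, ],
    tibble::tibble(gene_a = "G2", gene_b = "G1"), ext)
  expect_equal(mg3$verdict, "both")
  # unknown gene is an error naming it
  expect_error(explain_multi_gene(mk_ann("ps4", c("G1", "G2", "G9")),
                                  paralogs, ext), "G9")
})

test_that("the paralog table is symmetric on load", {
  ext <- dplyr::bind_rows(
    tx_row("T1", "G1", "c1", "+", cbind(1000L, 2000L)),
    tx_row("T2", "G2", "c2", "+", cbind(1000L, 2000L))) |>
    dplyr::mutate(ext_start = NA_integer_, ext_end = NA_integer_,
                  footprint = purrr::map(exons, identity))
  ann <- tibble::tibble(probeset_id = "ps", transcript_id = c("T1", "T2"),
                        gene_id = c("G1", "G2"), n_matched = 6L,
                        probeset_size = 11L, annotated = TRUE,
                        reasons = list(tibble::tibble()))
  # stored in the reverse orientation only
  mg <- explain_multi_gene(ann, tibble::tibble(gene_a = "G2",
                                               gene_b = "G1"), ext)
  expect_equal(mg$verdict, "paralogous")
})

test_that("genes-per-probeset histogram counts annotated gene sets", {
  run <- default_run()
  fx <- default_fixture()
  h <- run$histogram
  expect_true(all(h$n_genes >= 1))
  n_multi <- sum(h$n_probesets[h$n_genes >= 2])
  expect_equal(n_multi, nrow(run$multi_gene))
  n_ann <- length(unique(
    run$annotations$probeset_id[run$annotations$annotated]))
  expect_equal(sum(h$n_probesets), n_ann)
})

test_that("SNP overlap respects block boundaries and intron gaps", {
  al <- tibble::tibble(
    probe_name = c("p1", "p2"), chrom = "c1", strand = "+",
    start = c(100L, 200L), end = c(124L, 260L),
    blocks = c("100-124", "200-210,250-260"),
    n_blocks = c(1L, 2L), mismatch_count = c(0L, 1L),
    match_status = c("full_match", "mismatch"), source = "genomic",
    transcript_id = NA_character_)
  v <- tibble::tibble(chrom = "c1", pos = c(100L, 230L, 255L),
                      id = c("v1", "v2", "v3"), ref = "A", alt = "G")
  rec <- snp_overlap(al, v)
  # first base of a block is inside; the intron gap is not
  expect_true(rec$has_snp[rec$probe_name == "p1"])
  expect_true(rec$has_snp[rec$probe_name == "p2"])  # v3 in second block
  rec2 <- snp_overlap(al, v[v$id == "v2", ])
  expect_false(rec2$has_snp[rec2$probe_name == "p2"])
  expect_equal(rec$group, c("perfect_match_snp", "mismatch_snp"))
})

test_that("indels and unknown chromosomes are skipped with warnings", {
  al <- tibble::tibble(
    probe_name = "p1", chrom = "c1", strand = "+", start = 100L,
    end = 124L, blocks = "100-124", n_blocks = 1L, mismatch_count = 0L,
    match_status = "full_match", source = "genomic",
    transcript_id = NA_character_)
  v <- tibble::tibble(chrom = c("c1", "c9"), pos = c(110L, 10L),
                      id = c("ins", "v"), ref = c("AT", "A"),
                      alt = c("A", "G"))
  gn <- Biostrings::DNAStringSet(c(c1 = strrep("A", 200)))
  expect_warning(expect_warning(rec <- snp_overlap(al, v, gn), "non-SNV"),
                 "unknown chromosome")
  expect_false(rec$has_snp)
})

test_that("the four SNP-by-match groups partition all placements", {
  run <- default_run()
  fx <- default_fixture()
  rec <- run$snp$records
  expect_equal(nrow(rec), nrow(run$alignments))
  expect_true(all(rec$group %in% c("perfect_match_no_snp",
                                   "perfect_match_snp", "mismatch_no_snp",
                                   "mismatch_snp")))
  # the fixture plants all four groups
  expect_setequal(unique(rec$group),
                  c("perfect_match_no_snp", "perfect_match_snp",
                    "mismatch_no_snp", "mismatch_snp"))
  # exactly the planted snp probes overlap SNPs: two per snp probeset
  snp_ps <- fx$truth$probeset_id[fx$truth$intent == "snp_overlapping"]
  member <- fx$probes[fx$probes$probeset_id %in% snp_ps, ]
  affected <- unique(rec$probe_name[rec$has_snp])
  expect_length(affected, 2 * length(snp_ps))
  expect_true(all(affected %in% member$probe_name))
  s <- run$snp$summary
  expect_equal(s$n_probes_snp, length(affected))
  expect_equal(s$n_probesets_snp, length(snp_ps))
  expect_equal(s$frac_probes_snp, s$n_probes_snp / s$n_probes_mapped)
})

test_that("annotation comparison honours the one-common-identifier rule", {
  ours <- tibble::tibble(
    probeset_id = c("ps1", "ps1", "ps2", "ps3"),
    database = c("EntrezGene", "EntrezGene", "EntrezGene", "RefSeq"),
    identifier = c("G1", "G2", "G5", "N1"))
  theirs <- tibble::tibble(
    probeset_id = c("ps1", "ps1", "ps2", "ps3"),
    database = c("EntrezGene", "EntrezGene", "EntrezGene", "RefSeq"),
    identifier = c("G2", "G9", "G7", "N1"))
  cmp <- compare_annotations(ours, theirs)
  eg <- cmp[cmp$database == "EntrezGene", ]
  expect_equal(eg$n_compared, 2L)
  expect_equal(eg$n_agree, 1L)  # {G1,G2} vs {G2,G9} agree; {G5} vs {G7} not
  expect_equal(eg$agreement, 0.5)
  expect_equal(cmp$agreement[cmp$database == "RefSeq"], 1)
  # identical tables agree fully; comparison is symmetric
  self <- compare_annotations(ours, ours)
  expect_true(all(self$agreement == 1))
  expect_equal(compare_annotations(ours, theirs),
               compare_annotations(theirs, ours))
  # probesets present in only one table are not compared
  extra <- dplyr::bind_rows(theirs,
                            tibble::tibble(probeset_id = "ps9",
                                           database = "EntrezGene",
                                           identifier = "G9"))
  expect_equal(compare_annotations(ours, extra), cmp)
})
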