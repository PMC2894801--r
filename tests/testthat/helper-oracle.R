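# Independent naive aligner oracle: O(G * L) Hamming scan over both strands.
# Deliberately shares no code with the package's seeded search.
naive_scan_one <- function(probe, chrom_name, chrom_seq, max_mm = 1) {
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") probe else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(probe)))
    pr <- charToRaw(pat)
    gr <- charToRaw(chrom_seq)
    L <- length(pr)
    n <- length(gr) - L + 1L
    if (n < 1) next
    mm <- integer(n)
    for (i in seq_len(L)) {
      mm <- mm + (gr[i:(n + i - 1L)] != pr[i])
    }
    hit <- which(mm <= max_mm)
    if (length(hit)) {
      out[[strand]] <- tibble::tibble(chrom = chrom_name, start = hit,
                                      strand = strand,
                                      mismatch_count = mm[hit])
    }
  }
  dplyr::bind_rows(out)
}

naive_scan <- function(probe, genome, max_mm = 1) {
  seqs <- as.character(genome)
  dplyr::bind_rows(lapply(names(seqs), function(cc) {
    naive_scan_one(probe, cc, seqs[[cc]], max_mm)
  }))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_base_at <- function(seq, pos) {
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  substr(seq, pos, pos) <- flip[[substr(seq, pos, pos)]]
  seq
}

# minimal transcript-table row in the package's gene-model layout
tx_row <- function(transcript_id, gene_id, chrom, strand, exons,
                   cds_start = NA_integer_, cds_end = NA_integer_,
                   biotype = "protein_coding") {
  colnames(exons) <- c("start", "end")
  ex <- exons
  utr3 <- probemapr:::utr3_length_of(ex, strand, cds_start, cds_end)
  tibble::tibble(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exons = list(ex), n_exons = nrow(ex),
    tx_start = min(ex[, 1]), tx_end = max(ex[, 2]),
    spliced_length = sum(ex[, 2] - ex[, 1] + 1L),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    utr3_length = utr3, biotype = biotype)
}

probe_row <- function(probeset_id, i, sequence, array_name = "A1") {
  tibble::tibble(probe_name = paste(probeset_id, i, 1, sep = ":"),
                 probeset_id = probeset_id, array_name = array_name,
                 x = i, y = 1L, sequence = sequence)
}

# the default fixture and its pipeline run are shared across test files
.fixture_cache <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    d <- file.path(tempdir(), "probemapr_default_fixture")
    .fixture_cache$fx <- simulate_fixture(fixture_config(seed = 1), dir = d)
  }
  .fixture_cache$fx
}

default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    fx <- default_fixture()
    cfg <- pipeline_config(
      genome = fx$paths[["genome"]], gtf = fx$paths[["gtf"]],
      probes = fx$paths[["probes"]], vcf = fx$paths[["vcf"]],
      paralogs = fx$paths[["paralogs"]],
      out_dir = file.path(tempdir(), "probemapr_default_run"))
    .fixture_cache$run <- suppressMessages(run_pipeline(cfg))
  }
  .fixture_cache$run
}

# annotated transcript sets per probeset, for truth comparison
annotated_tx_by_probeset <- function(annotations) {
  ann <- annotations[annotations$annotated, , drop = FALSE]
  split(ann$transcript_id, ann$probeset_id) |>
    lapply(function(v) sort(unique(v)))
}
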