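#' Probeset intents planted by the fixture simulator
#'
#' Each synthetic probeset is built to exercise one failure or success mode
#' of the mapping and annotation pipeline: clean single-target probesets,
#' probesets annotated to multiple genes (paralogous, overlapping after UTR
#' extension, or with no biological explanation), intronic and antisense
#' probesets, probesets with too few matching probes, probes drawn from a
#' high-copy repeat (promiscuous), exon-junction-spanning probes,
#' probesets recoverable only through the 3' UTR extension, and probes
#' overlapping SNPs.
#'
#' @export
probe_intents <- c(
  "clean_single_target", "multi_gene_paralog", "multi_gene_overlap",
  "multi_gene_unexplained", "intronic", "antisense", "sub_threshold",
  "promiscuous", "junction_spanning", "utr3_dependent", "snp_overlapping"
)

#' Configuration for the fixture simulator
#'
#' Defaults mirror commercial short-oligo expression arrays: 25-mer probes,
#' 11 probes per probeset (valid range 11-20).  Identical seed and
#' configuration reproduce byte-identical outputs; each component draws
#' from its own labelled RNG stream (see [derive_seed()]).
#'
#' @param seed Master seed.
#' @param n_chromosomes,chromosome_length Genome dimensions (>= 10 kb per
#'   chromosome).
#' @param n_genes Optional total gene count; at least the number required
#'   by the planted intents, extra genes become untargeted background.
#' @param fraction_without_utr3 Fraction of transcripts lacking an
#'   annotated 3' UTR.
#' @param probes_per_probeset Probes per probeset (11-20).
#' @param probe_length Probe length in bases (>= 12; default 25).
#' @param n_probesets_per_intent Probesets planted per intent.
#' @param variant_density Background SNVs per kilobase, placed away from
#'   every probe footprint so the planted SNP accounting stays exact.
#' @return A `fixture_config` object.
#' @export
fixture_config <- function(seed = 1, n_chromosomes = 2,
                           chromosome_length = 50000, n_genes = NULL,
                           fraction_without_utr3 = 0.25,
                           probes_per_probeset = 11, probe_length = 25,
                           n_probesets_per_intent = 2,
                           variant_density = 0.2) {
  if (chromosome_length < 10000)
    abort_input("chromosome_length must be >= 10000")
  if (n_chromosomes < 1) abort_input("n_chromosomes must be >= 1")
  if (probes_per_probeset < 11 || probes_per_probeset > 20)
    abort_input("probes_per_probeset must be within 11-20")
  if (probe_length < 12)
    abort_input("probe_length must be >= 12")
  structure(list(seed = seed, n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length = as.integer(chromosome_length),
                 n_genes = n_genes,
                 fraction_without_utr3 = fraction_without_utr3,
                 probes_per_probeset = as.integer(probes_per_probeset),
                 probe_length = as.integer(probe_length),
                 n_probesets_per_intent = as.integer(n_probesets_per_intent),
                 variant_density = variant_density),
            class = "fixture_config")
}

DNA_BASES <- c("A", "C", "G", "T")
# base flip guarantees a substitution wherever one is required
flip_base <- function(x) c(A = "C", C = "A", G = "T", T = "G")[x]

REPEAT_UNIT_LEN <- 60L
REPEAT_COPIES_HIGH <- 120L     # above the 100-location cap: discarded
REPEAT_COPIES_NEAR_CAP <- 99L  # below the cap: retained with 99 hits

#' Simulate a random genome with planted repeat families
#'
#' Two repeat families are embedded in reserved tail regions: a high-copy
#' unit (120 occurrences, above the promiscuity cap) and a near-cap unit
#' (99 occurrences, just under it).  Occurrence positions and reserved
#' regions are recorded in the object metadata so gene placement avoids
#' them.
#'
#' @param config A [fixture_config()].
#' @return A [Biostrings::DNAStringSet]; `S4Vectors::metadata()` carries
#'   `repeats` (units, occurrence tables) and `reserved` (regions genes
#'   must avoid).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  seqs <- withr::with_seed(derive_seed(config$seed, "genome"), {
    lapply(seq_len(config$n_chromosomes), function(i) {
      paste(sample(DNA_BASES, config$chromosome_length, TRUE), collapse = "")
    })
  })
  names(seqs) <- paste0("chr", seq_along(seqs))
  units <- withr::with_seed(derive_seed(config$seed, "repeats"), {
    list(unit_a = paste(sample(DNA_BASES, REPEAT_UNIT_LEN, TRUE),
                        collapse = ""),
         unit_b = paste(sample(DNA_BASES, REPEAT_UNIT_LEN, TRUE),
                        collapse = ""))
  })
  pitch <- REPEAT_UNIT_LEN + 2L
  plan <- c(rep("unit_a", REPEAT_COPIES_HIGH),
            rep("unit_b", REPEAT_COPIES_NEAR_CAP))
  need <- length(plan) * pitch + 100L
  # fill the tails of the chromosomes, last first, spilling if necessary
  occ <- list(); reserved <- list()
  ci <- config$n_chromosomes
  while (length(plan) && ci >= 1) {
    room <- config$chromosome_length - 400L  # keep a margin from genes
    fit <- min(length(plan), room %/% pitch)
    if (fit <= 0) abort_input("chromosomes too short to plant repeats")
    start <- config$chromosome_length - fit * pitch - 50L
    s <- seqs[[ci]]
    pos <- start
    for (u in plan[seq_len(fit)]) {
      substr(s, pos, pos + REPEAT_UNIT_LEN - 1L) <- units[[u]]
      occ[[length(occ) + 1L]] <- tibble(family = u, chrom = names(seqs)[ci],
                                        start = pos,
                                        end = pos + REPEAT_UNIT_LEN - 1L)
      pos <- pos + pitch
    }
    seqs[[ci]] <- s
    reserved[[length(reserved) + 1L]] <-
      tibble(chrom = names(seqs)[ci], start = start - 50L,
             end = config$chromosome_length)
    plan <- plan[-seq_len(fit)]
    ci <- ci - 1L
  }
  if (length(plan)) abort_input("genome too small to plant repeat families")
  gn <- Biostrings::DNAStringSet(unlist(seqs))
  S4Vectors::metadata(gn) <- list(repeats = list(units = units,
                                                 occurrences = bind_rows(occ)),
                                  reserved = bind_rows(reserved))
  gn
}

# ---- gene construction -----------------------------------------------------

# genomic layout of one gene from transcript-order exon/intron lengths
make_gene_coords <- function(slot_start, strand, exon_lens, intron_lens,
                             utr5, utr3) {
  pieces <- integer(0)
  for (i in seq_along(exon_lens)) {
    pieces <- c(pieces, exon_lens[i])
    if (i < length(exon_lens)) pieces <- c(pieces, intron_lens[i])
  }
  if (strand == "-") pieces <- rev(pieces)
  ends <- slot_start - 1L + cumsum(pieces)
  starts <- ends - pieces + 1L
  is_exon <- if (strand == "+") seq_along(pieces) %% 2L == 1L
  else rev(seq_along(pieces) %% 2L == 1L)
  ex_g <- cbind(start = starts[is_exon], end = ends[is_exon])
  if (strand == "-") ex_g <- ex_g[nrow(ex_g):1, , drop = FALSE]
  sl <- sum(exon_lens)
  cds <- spliced_to_genomic(ex_g, strand, utr5 + 1L, sl - utr3)
  list(exons = ex_g, tx_start = min(ex_g[, 1]), tx_end = max(ex_g[, 2]),
       spliced_length = sl, cds_start = min(cds[, 1]),
       cds_end = max(cds[, 2]),
       locus_len = sum(exon_lens) + sum(intron_lens))
}

gene_locus_len <- function(exon_lens, intron_lens)
  sum(exon_lens) + sum(intron_lens)

# per-role structural templates
gene_template <- function(role_type, probe_length) {
  me <- min(10L, probe_length - 4L)  # short middle exon for 3-exon probes
  switch(role_type,
    junction = list(exon_lens = c(400L, me, 350L),
                    intron_lens = c(150L, 150L)),
    intronic = list(exon_lens = c(400L, 250L, 350L),
                    intron_lens = c(300L, 150L)),
    list(exon_lens = c(400L, 250L, 350L), intron_lens = c(150L, 150L))
  )
}

# spec for every gene the fixture needs, in deterministic placement order;
# units keep genes that must sit next to each other together
build_gene_units <- function(config) {
  np <- config$n_probesets_per_intent
  units <- list()
  add <- function(kind, genes) {
    units[[length(units) + 1L]] <<- list(kind = kind, genes = genes)
  }
  g <- function(role, type = "default", strand = "+", utr3 = NA_integer_) {
    list(role = role, type = type, strand = strand, utr3 = utr3)
  }
  for (k in seq_len(np)) {
    s <- if (k %% 2L == 1L) "+" else "-"
    add("single", list(g(paste0("clean:", k), strand = s)))
    add("single", list(g(paste0("paralog_a:", k))))
    add("single", list(g(paste0("paralog_b:", k))))
    add("overlap_pair", list(g(paste0("overlap_a:", k), utr3 = 250L),
                             g(paste0("overlap_b:", k))))
    add("single", list(g(paste0("unexplained_a:", k))))
    add("single", list(g(paste0("intronic:", k), type = "intronic",
                         strand = s)))
    add("single", list(g(paste0("antisense:", k))))
    add("single", list(g(paste0("sub_threshold:", k))))
    add("single", list(g(paste0("junction:", k), type = "junction",
                         strand = s, utr3 = 150L)))
    utr_forced <- if (k %% 2L == 1L || config$fraction_without_utr3 == 0)
      250L else 0L
    add("single", list(g(paste0("utr3dep:", k),
                         strand = if (utr_forced > 0) "+" else "-",
                         utr3 = utr_forced)))
    add("single", list(g(paste0("snp:", k))))
  }
  add("t2t_pair", list(g("t2t_a:1"), g("t2t_b:1", strand = "-")))
  # partners of the unexplained pairs go last so they land far away
  for (k in seq_len(np)) {
    add("single", list(g(paste0("unexplained_b:", k))))
  }
  needed <- sum(vapply(units, function(u) length(u$genes), integer(1)))
  extra <- if (!is.null(config$n_genes)) max(0L, config$n_genes - needed)
  else 0L
  for (k in seq_len(extra)) {
    add("single", list(g(paste0("background:", k),
                         strand = if (k %% 2L) "+" else "-")))
  }
  units
}

#' Simulate gene models over a genome
#'
#' Places multi-exon genes on both strands with generous intergenic gaps,
#' including: a tail-to-tail pair (3' ends on opposite strands within
#' 500 bp), same-strand tandem pairs whose extended spans overlap,
#' paralogous duplicate pairs (locus copied, then lightly mutated outside
#' the probe windows) recorded in the emitted paralog table, distant gene
#' pairs sharing an exonic sequence block, genes with edited intron/exon
#' boundaries so junction-spanning probes cannot be matched contiguously,
#' and a configurable fraction of transcripts without an annotated 3' UTR.
#' The genome is edited in place (duplications, shared blocks, boundary
#' guards) and returned alongside the models.
#'
#' @param genome Output of [simulate_genome()].
#' @param config A [fixture_config()].
#' @return A list: `genome` (edited), `transcripts` (tibble in
#'   [read_gene_models()] layout), `paralogs` (`gene_a`, `gene_b`),
#'   `gene_plan` (role-to-gene map with slot coordinates).
#' @export
simulate_gene_models <- function(genome, config) {
  units <- build_gene_units(config)
  md <- S4Vectors::metadata(genome)
  reserved <- md$reserved %||% tibble(chrom = character(), start = integer(),
                                      end = integer())
  chroms <- names(genome)
  limits <- vapply(chroms, function(cc) {
    r <- reserved[reserved$chrom == cc, ]
    if (nrow(r)) min(r$start) - 400L else Biostrings::width(genome)[
      chroms == cc] - 300L
  }, integer(1))
  seqs <- stats::setNames(as.character(genome), chroms)

  # draw flexible 3' UTR lengths and the without-UTR assignment up front
  n_total <- sum(vapply(units, function(u) length(u$genes), integer(1)))
  draws <- withr::with_seed(derive_seed(config$seed, "genes"), {
    list(utr = sample(150:340, n_total, replace = TRUE),
         mut = sample.int(1e6, 64, replace = TRUE))
  })
  flex_roles <- character(0)
  all_specs <- unlist(lapply(units, `[[`, "genes"), recursive = FALSE)
  for (sp in all_specs) {
    if (is.na(sp$utr3) &&
        grepl("^(clean|intronic|antisense|sub_threshold|snp|background)",
              sp$role))
      flex_roles <- c(flex_roles, sp$role)
  }
  n_forced_zero <- sum(vapply(all_specs, function(sp)
    identical(sp$utr3, 0L), logical(1)))
  n_zero_target <- round(config$fraction_without_utr3 * n_total)
  zero_roles <- utils::head(flex_roles,
                            max(0L, n_zero_target - n_forced_zero))

  cursor <- stats::setNames(rep(200L, length(chroms)), chroms)
  rows <- list(); plan <- list(); paralogs <- list()
  gidx <- 0L
  place_gene <- function(sp, slot_start, chrom) {
    gidx <<- gidx + 1L
    tpl <- gene_template(sp$type, config$probe_length)
    utr3 <- if (!is.na(sp$utr3)) sp$utr3
    else if (sp$role %in% zero_roles) 0L
    else draws$utr[gidx]
    co <- make_gene_coords(slot_start, sp$strand, tpl$exon_lens,
                           tpl$intron_lens, 50L, utr3)
    gene_id <- sprintf("GENE%03d", gidx)
    tx_id <- sprintf("TX%03d", gidx)
    rows[[length(rows) + 1L]] <<- tibble(
      transcript_id = tx_id, gene_id = gene_id, chrom = chrom,
      strand = sp$strand, exons = list(co$exons),
      n_exons = nrow(co$exons), tx_start = co$tx_start,
      tx_end = co$tx_end, spliced_length = co$spliced_length,
      cds_start = co$cds_start, cds_end = co$cds_end,
      utr3_length = as.integer(utr3), biotype = "protein_coding")
    plan[[length(plan) + 1L]] <<- tibble(
      role = sp$role, gene_id = gene_id, transcript_id = tx_id,
      chrom = chrom, slot_start = slot_start,
      slot_end = slot_start + co$locus_len - 1L, strand = sp$strand,
      utr3 = as.integer(utr3))
    co
  }
  for (u in units) {
    glen <- vapply(u$genes, function(sp) {
      tpl <- gene_template(sp$type, config$probe_length)
      gene_locus_len(tpl$exon_lens, tpl$intron_lens)
    }, integer(1))
    internal_gap <- switch(u$kind, overlap_pair = 100L, t2t_pair = 120L, 0L)
    unit_len <- sum(glen) + internal_gap * (length(glen) - 1L)
    placed <- FALSE
    for (cc in chroms) {
      if (cursor[cc] + unit_len <= limits[cc]) {
        at <- cursor[cc]
        if (u$kind == "overlap_pair") {
          co_a <- place_gene(u$genes[[1]], at, cc)
          # downstream gene starts inside the first gene's extension
          place_gene(u$genes[[2]], co_a$tx_end + internal_gap + 1L, cc)
        } else if (u$kind == "t2t_pair") {
          co_a <- place_gene(u$genes[[1]], at, cc)
          place_gene(u$genes[[2]], co_a$tx_end + internal_gap + 1L, cc)
        } else {
          for (sp in u$genes) {
            place_gene(sp, at, cc)
            at <- at + glen[1] # single units hold one gene
          }
        }
        cursor[cc] <- cursor[cc] + unit_len + 1600L
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort_input("gene placement impossible at requested density")
  }
  transcripts <- bind_rows(rows)
  plan <- bind_rows(plan)

  # sequence edits ----------------------------------------------------------
  mut_i <- 0L
  next_mut <- function(n) {
    mut_i <<- mut_i + 1L
    draws$mut[mut_i] %% n + 1L
  }
  for (k in seq_len(config$n_probesets_per_intent)) {
    # paralogs: copy the whole locus, then mutate outside exon 1
    pa <- plan[plan$role == paste0("paralog_a:", k), ]
    pb <- plan[plan$role == paste0("paralog_b:", k), ]
    src <- substr(seqs[[pa$chrom]], pa$slot_start, pa$slot_end)
    substr(seqs[[pb$chrom]], pb$slot_start, pb$slot_end) <- src
    llen <- pb$slot_end - pb$slot_start + 1L
    for (off in c(450, 520, 640, 700, 820, 900, 1000, 1150)) {
      p <- pb$slot_start + min(off, llen - 2L)
      base <- substr(seqs[[pb$chrom]], p, p)
      substr(seqs[[pb$chrom]], p, p) <- flip_base(base)
    }
    paralogs[[length(paralogs) + 1L]] <-
      tibble(gene_a = pa$gene_id, gene_b = pb$gene_id)
    # unexplained pair: copy the probe window of A's first exon into B's
    # second exon; the genes stay unrelated otherwise
    ua <- plan[plan$role == paste0("unexplained_a:", k), ]
    ub <- plan[plan$role == paste0("unexplained_b:", k), ]
    ta <- transcripts[transcripts$transcript_id == ua$transcript_id, ]
    tb <- transcripts[transcripts$transcript_id == ub$transcript_id, ]
    win <- shared_window_genomic(ta)
    blk <- substr(seqs[[ua$chrom]], win[1], win[2])
    dst <- tb$exons[[1]][2, 1] + 49L
    substr(seqs[[ub$chrom]], dst, dst + (win[2] - win[1])) <- blk
  }
  # junction boundary guards: force >=2 sense mismatches at every junction
  for (jrole in plan$role[grepl("^junction:", plan$role)]) {
    pj <- plan[plan$role == jrole, ]
    tj <- transcripts[transcripts$transcript_id == pj$transcript_id, ]
    seqs[[pj$chrom]] <- guard_junctions(seqs[[pj$chrom]], tj$exons[[1]],
                                        tj$strand)
  }

  out <- Biostrings::DNAStringSet(unlist(seqs))
  S4Vectors::metadata(out) <- md
  list(genome = out, transcripts = transcripts,
       paralogs = bind_rows(paralogs), gene_plan = plan)
}

# the 150 bp exon-1 window shared between an unexplained pair, genomic
shared_window_genomic <- function(tx) {
  b <- spliced_to_genomic(tx$exons[[1]], tx$strand, 60L, 209L)
  c(min(b[, 1]), max(b[, 2]))
}

# edit the two intron bases adjacent to each junction so that any
# contiguous genomic window crossing the junction carries >= 2 mismatches
# against a spliced (junction-spanning) probe
guard_junctions <- function(seq, exons, strand) {
  n <- nrow(exons)
  for (i in seq_len(n - 1L)) {
    if (strand == "+") {
      bi <- exons[i, 2]; ai1 <- exons[i + 1L, 1]
      pairs <- rbind(c(bi + 1L, ai1), c(bi + 2L, ai1 + 1L),
                     c(ai1 - 1L, bi), c(ai1 - 2L, bi - 1L))
    } else {
      ai <- exons[i, 1]; bi1 <- exons[i + 1L, 2]
      pairs <- rbind(c(ai - 1L, bi1), c(ai - 2L, bi1 - 1L),
                     c(bi1 + 1L, ai), c(bi1 + 2L, ai + 1L))
    }
    for (r in seq_len(nrow(pairs))) {
      tgt <- substr(seq, pairs[r, 2], pairs[r, 2])
      substr(seq, pairs[r, 1], pairs[r, 1]) <- flip_base(tgt)
    }
  }
  seq
}

# ---- array design ----------------------------------------------------------

# n window start offsets within a region, overlapping when the region is
# tight; deterministic
spaced_offsets <- function(region_start, region_len, L, n) {
  sp <- max(1L, (region_len - L) %/% max(1L, n - 1L))
  region_start + (seq_len(n) - 1L) * sp
}

#' Simulate an array design with planted truth and variants
#'
#' Probe sequences are drawn from transcript cDNA (sense strand) and then
#' modified per intent: antisense probes are reverse complements, intronic
#' probes come from intron sequence, sub-threshold probesets have fewer
#' than half their probes drawn from the target, promiscuous probes come
#' from the planted high-copy repeat, junction probes straddle exon-exon
#' boundaries with at least three bases on each side, UTR-dependent probes
#' sit in the 3' extension region, and SNP probesets carry planted
#' variants and single-base probe mutations so all four SNP-by-match
#' groups are populated.  Background SNVs are placed away from every probe
#' footprint.
#'
#' @param models Output of [simulate_gene_models()].
#' @param config A [fixture_config()].
#' @return A list: `probes` (probe tibble), `truth` (planted truth),
#'   `variants` (variant tibble), `planted` (known genomic placements of
#'   clean probes, for self-consistency checks).
#' @export
simulate_array <- function(models, config) {
  transcripts <- models$transcripts
  genome <- models$genome
  plan <- models$gene_plan
  L <- config$probe_length
  n <- config$probes_per_probeset
  md <- S4Vectors::metadata(genome)
  policy <- compute_extension_policy(transcripts)
  S <- policy$extension_length
  seqs <- stats::setNames(as.character(genome), names(genome))
  cdna <- stats::setNames(as.character(get_cdna(transcripts, genome)),
                          transcripts$transcript_id)
  rand <- withr::with_seed(derive_seed(config$seed, "array"), {
    replicate(n * config$n_probesets_per_intent,
              paste(sample(DNA_BASES, L, TRUE), collapse = ""))
  })
  rand_i <- 0L
  probes <- list(); truth <- list(); variants <- list(); planted <- list()
  ps_idx <- 0L
  tx_of <- function(role) {
    tid <- plan$transcript_id[plan$role == role]
    transcripts[transcripts$transcript_id == tid, ]
  }
  exon1_len <- function(tx) {
    ex <- tx$exons[[1]]
    ex[1, 2] - ex[1, 1] + 1L
  }
  cdna_probe <- function(tx, off) substr(cdna[[tx$transcript_id]], off,
                                         off + L - 1L)
  add_ps <- function(intent, seqv, expected_tx, expected_ann) {
    ps_idx <<- ps_idx + 1L
    psid <- sprintf("%d_at", 1000L + ps_idx)
    probes[[ps_idx]] <<- tibble(
      probeset_id = psid, x = seq_along(seqv) * 3L, y = ps_idx * 5L,
      sequence = unname(seqv), array_name = "SYNTH1")
    truth[[ps_idx]] <<- tibble(
      probeset_id = psid, intent = intent,
      expected_transcripts = paste(expected_tx, collapse = ";"),
      expected_annotated = expected_ann)
    psid
  }
  probe_names_of <- function(psid) {
    p <- probes[[which(vapply(probes, function(x) x$probeset_id[1],
                              character(1)) == psid)]]
    paste(psid, p$x, p$y, sep = ":")
  }

  for (intent in probe_intents) {
    for (k in seq_len(config$n_probesets_per_intent)) {
      if (intent == "clean_single_target") {
        tx <- tx_of(paste0("clean:", k))
        offs <- spaced_offsets(60L, exon1_len(tx) - 70L, L, n)
        psid <- add_ps(intent, vapply(offs, function(o) cdna_probe(tx, o),
                                      character(1)),
                       tx$transcript_id, TRUE)
        bl <- lapply(offs, function(o)
          spliced_to_genomic(tx$exons[[1]], tx$strand, o, o + L - 1L))
        planted[[length(planted) + 1L]] <- tibble(
          probe_name = probe_names_of(psid), chrom = tx$chrom,
          start = map_int(bl, ~ min(.x[, 1])), strand = tx$strand)
      } else if (intent == "multi_gene_paralog") {
        ta <- tx_of(paste0("paralog_a:", k))
        tb <- tx_of(paste0("paralog_b:", k))
        offs <- spaced_offsets(60L, exon1_len(ta) - 70L, L, n)
        add_ps(intent, vapply(offs, function(o) cdna_probe(ta, o),
                              character(1)),
               c(ta$transcript_id, tb$transcript_id), TRUE)
      } else if (intent == "multi_gene_overlap") {
        ta <- tx_of(paste0("overlap_a:", k))
        tb <- tx_of(paste0("overlap_b:", k))
        # window where the first gene's doubled UTR covers the second
        # gene's first exon
        win_start <- tb$tx_start
        win_len <- ta$tx_end + ta$utr3_length - tb$tx_start + 1L
        offs <- spaced_offsets(win_start + 2L, win_len - 4L, L, n)
        add_ps(intent, vapply(offs, function(o)
          substr(seqs[[ta$chrom]], o, o + L - 1L), character(1)),
          c(ta$transcript_id, tb$transcript_id), TRUE)
      } else if (intent == "multi_gene_unexplained") {
        ta <- tx_of(paste0("unexplained_a:", k))
        tb <- tx_of(paste0("unexplained_b:", k))
        offs <- spaced_offsets(60L, 150L, L, n)
        add_ps(intent, vapply(offs, function(o) cdna_probe(ta, o),
                              character(1)),
               c(ta$transcript_id, tb$transcript_id), TRUE)
      } else if (intent == "intronic") {
        tx <- tx_of(paste0("intronic:", k))
        ex <- tx$exons[[1]]
        iv <- if (tx$strand == "+") c(ex[1, 2] + 1L, ex[2, 1] - 1L)
        else c(ex[2, 2] + 1L, ex[1, 1] - 1L)
        offs <- spaced_offsets(iv[1] + 4L, iv[2] - iv[1] - 8L, L, n)
        sv <- vapply(offs, function(o)
          substr(seqs[[tx$chrom]], o, o + L - 1L), character(1))
        if (tx$strand == "-") sv <- revcomp(sv)
        add_ps(intent, sv, character(0), FALSE)
      } else if (intent == "antisense") {
        tx <- tx_of(paste0("antisense:", k))
        offs <- spaced_offsets(60L, exon1_len(tx) - 70L, L, n)
        add_ps(intent, revcomp(vapply(offs, function(o) cdna_probe(tx, o),
                                      character(1))),
               character(0), FALSE)
      } else if (intent == "sub_threshold") {
        tx <- tx_of(paste0("sub_threshold:", k))
        m <- annotation_threshold(n) - 1L
        offs <- spaced_offsets(60L, exon1_len(tx) - 70L, L, m)
        sv <- vapply(offs, function(o) cdna_probe(tx, o), character(1))
        rnd <- rand[rand_i + seq_len(n - m)]
        rand_i <- rand_i + (n - m)
        add_ps(intent, c(sv, rnd), character(0), FALSE)
      } else if (intent == "promiscuous") {
        unit <- md$repeats$units$unit_a
        offs <- spaced_offsets(1L, nchar(unit), L, n)
        add_ps(intent, vapply(offs, function(o) substr(unit, o, o + L - 1L),
                              character(1)),
               character(0), FALSE)
      } else if (intent == "junction_spanning") {
        tx <- tx_of(paste0("junction:", k))
        ex <- tx$exons[[1]]
        e1 <- ex[1, 2] - ex[1, 1] + 1L
        me <- ex[2, 2] - ex[2, 1] + 1L
        n_j <- max(2L, round(n * 0.25))
        a <- (L - me) %/% 2L
        j_offs <- c(e1 - a + 1L,                      # across all 3 exons
                    e1 - (L - me) - seq_len(n_j - 1L) + 1L)
        ex_offs <- spaced_offsets(60L, e1 - 70L, L, n - n_j)
        sv <- vapply(c(ex_offs, j_offs), function(o) cdna_probe(tx, o),
                     character(1))
        add_ps(intent, sv, tx$transcript_id, TRUE)
      } else if (intent == "utr3_dependent") {
        tx <- tx_of(paste0("utr3dep:", k))
        R <- if (tx$utr3_length > 0) tx$utr3_length else S
        if (tx$strand == "+") {
          offs <- spaced_offsets(tx$tx_end + 5L, R - 8L, L, n)
          sv <- vapply(offs, function(o)
            substr(seqs[[tx$chrom]], o, o + L - 1L), character(1))
        } else {
          sp <- max(1L, (R - L - 8L) %/% max(1L, n - 1L))
          starts <- tx$tx_start - 4L - (seq_len(n) - 1L) * sp - L + 1L
          sv <- revcomp(vapply(starts, function(o)
            substr(seqs[[tx$chrom]], o, o + L - 1L), character(1)))
        }
        add_ps(intent, sv, tx$transcript_id, TRUE)
      } else if (intent == "snp_overlapping") {
        tx <- tx_of(paste0("snp:", k))
        e1 <- exon1_len(tx)
        g0 <- tx$exons[[1]][1, 1]  # '+' gene: cDNA offset o -> g0 + o - 1
        w <- c(60L, 60L + L + 5L, 60L + 2L * (L + 5L))
        rest <- spaced_offsets(60L + 3L * (L + 5L),
                               e1 - 10L - (60L + 3L * (L + 5L)), L, n - 3L)
        sv <- vapply(c(w, rest), function(o) cdna_probe(tx, o), character(1))
        mm_off <- min(L - 7L, L - 2L)
        substr(sv[2], mm_off, mm_off) <- flip_base(substr(sv[2], mm_off,
                                                          mm_off))
        substr(sv[3], 5L, 5L) <- flip_base(substr(sv[3], 5L, 5L))
        psid <- add_ps(intent, sv, tx$transcript_id, TRUE)
        snp_pos <- c(g0 + w[1] - 1L + L %/% 2L,
                     g0 + w[3] - 1L + L %/% 2L + 2L)
        variants[[length(variants) + 1L]] <- tibble(
          chrom = tx$chrom, pos = snp_pos,
          id = paste0("snp_", psid, "_", seq_along(snp_pos)),
          ref = substring(seqs[[tx$chrom]], snp_pos, snp_pos),
          alt = unname(flip_base(substring(seqs[[tx$chrom]], snp_pos,
                                           snp_pos))))
      }
    }
  }
  probe_tbl <- bind_rows(probes) |>
    mutate(probe_name = paste(.data$probeset_id, .data$x, .data$y,
                              sep = ":")) |>
    select("probe_name", "probeset_id", "array_name", "x", "y", "sequence")
  vr <- background_variants(models, config, bind_rows(variants))
  list(probes = probe_tbl, truth = bind_rows(truth), variants = vr,
       planted = bind_rows(planted))
}

# background SNVs in regions no probe can touch (gene slots padded by the
# maximum extension, plus the repeat reserves, are excluded)
background_variants <- function(models, config, planted_variants) {
  genome <- models$genome
  md <- S4Vectors::metadata(genome)
  seqs <- stats::setNames(as.character(genome), names(genome))
  total_kb <- sum(Biostrings::width(genome)) / 1000
  n_bg <- max(0L, round(config$variant_density * total_kb))
  avoid <- bind_rows(
    models$gene_plan |>
      mutate(start = .data$slot_start - 600L, end = .data$slot_end + 600L) |>
      select("chrom", "start", "end"),
    md$reserved %||% tibble(chrom = character(), start = integer(),
                            end = integer()))
  allowed <- list()
  for (cc in names(seqs)) {
    len <- nchar(seqs[[cc]])
    av <- avoid |> filter(.data$chrom == cc)
    ir <- IRanges::reduce(IRanges::IRanges(pmax(1L, av$start),
                                           pmin(len, av$end)))
    ok <- IRanges::setdiff(IRanges::IRanges(1L, len), ir)
    if (length(ok))
      allowed[[cc]] <- tibble(chrom = cc, start = IRanges::start(ok),
                              end = IRanges::end(ok))
  }
  allowed <- bind_rows(allowed) |> mutate(w = .data$end - .data$start + 1L)
  pos <- withr::with_seed(derive_seed(config$seed, "variants"), {
    offs <- sort(sample.int(sum(allowed$w), min(n_bg, sum(allowed$w))))
    cum <- cumsum(allowed$w)
    iv <- findInterval(offs - 1L, c(0L, cum), rightmost.closed = FALSE)
    tibble(chrom = allowed$chrom[iv],
           pos = allowed$start[iv] + (offs - c(0L, cum)[iv] - 1L))
  })
  bg <- pos |>
    mutate(id = sprintf("bg_%04d", row_number()),
           ref = substring(seqs[.data$chrom], .data$pos, .data$pos),
           alt = unname(flip_base(.data$ref)))
  bind_rows(planted_variants, bg) |>
    arrange(.data$chrom, .data$pos) |>
    select("chrom", "pos", "id", "ref", "alt")
}

#' Simulate a complete fixture (genome, models, array, variants, truth)
#'
#' @param config A [fixture_config()].
#' @param dir Optional directory; when given, all files are written
#'   (genome FASTA, models GTF, probe table TSV, probe FASTA, variants
#'   VCF, paralog TSV, truth TSV).
#' @return An `array_fixture` list: `config`, `genome`, `transcripts`,
#'   `paralogs`, `gene_plan`, `probes`, `truth`, `variants`, `planted`,
#'   and `paths` when `dir` was given.
#' @export
simulate_fixture <- function(config = fixture_config(), dir = NULL) {
  genome <- simulate_genome(config)
  models <- simulate_gene_models(genome, config)
  arr <- simulate_array(models, config)
  fx <- structure(list(config = config, genome = models$genome,
                       transcripts = models$transcripts,
                       paralogs = models$paralogs,
                       gene_plan = models$gene_plan, probes = arr$probes,
                       truth = arr$truth, variants = arr$variants,
                       planted = arr$planted),
                  class = "array_fixture")
  if (!is.null(dir)) fx$paths <- write_fixture(fx, dir)
  fx
}

#' Write all fixture files to a directory
#' @param fx An `array_fixture`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "models.gtf"),
    probes = file.path(dir, "probes.tsv"),
    probe_fasta = file.path(dir, "probes.fa"),
    vcf = file.path(dir, "variants.vcf"),
    paralogs = file.path(dir, "paralogs.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_genome(fx$genome, paths[["genome"]])
  write_gene_models(fx$transcripts, paths[["gtf"]])
  write_probe_table(fx$probes, paths[["probes"]])
  write_probe_fasta(fx$probes, paths[["probe_fasta"]])
  write_variants(fx$variants, paths[["vcf"]])
  readr::write_tsv(fx$paralogs, paths[["paralogs"]], progress = FALSE)
  readr::write_tsv(fx$truth, paths[["truth"]], progress = FALSE)
  paths
}

#' @export
print.array_fixture <- function(x, ...) {
  cat(sprintf(paste0("<array_fixture> %d chromosome(s), %d transcript(s), ",
                     "%d probeset(s), %d probe(s), %d variant(s)\n"),
              length(x$genome), nrow(x$transcripts),
              length(unique(x$probes$probeset_id)), nrow(x$probes),
              nrow(x$variants)))
  invisible(x)
}
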