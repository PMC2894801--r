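#' Collapse per-array probe lists into a non-redundant probe set
#'
#' A single probe sequence can be part of several array designs, so probes
#' from all arrays of a species are collapsed by sequence before alignment:
#' the search runs once per unique sequence and its hits are fanned out to
#' every member probe afterwards.  Comparison is case-insensitive and
#' strand-sensitive (a probe and its reverse complement are distinct).
#'
#' @param probes Probe tibble (see [read_probe_table()]); may span arrays.
#' @return A tibble with one row per distinct sequence: `sequence`,
#'   `n_members`, `members` (list-column of the member probe rows).
#' @export
collapse_probes <- function(probes) {
  dup <- probes |> count(.data$array_name, .data$probe_name) |> filter(n > 1)
  if (nrow(dup))
    abort_input(paste0("duplicate probe name within an array: ",
                       dup$array_name[1], "/", dup$probe_name[1]))
  probes |>
    mutate(sequence = toupper(.data$sequence)) |>
    group_by(.data$sequence) |>
    summarise(n_members = n(),
              members = list(dplyr::pick("probe_name", "probeset_id",
                                         "array_name")),
              .groups = "drop") |>
    arrange(.data$sequence)
}

#' Write the non-redundant probe sequences as FASTA
#'
#' Sequences are named `nr_<i>` in lexicographic sequence order so the file
#' is reproducible regardless of input order.
#'
#' @param collapsed Output of [collapse_probes()].
#' @param path Output path.
#' @export
write_nonredundant_fasta <- function(collapsed, path) {
  ss <- Biostrings::DNAStringSet(collapsed$sequence)
  names(ss) <- sprintf("nr_%05d", seq_len(nrow(collapsed)))
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

#' Expand sequence-level alignments back to per-probe alignments
#'
#' @param seq_hits Tibble of hits keyed by `sequence`.
#' @param collapsed Output of [collapse_probes()].
#' @return The hits with one row per member probe (`probe_name` added).
#' @export
expand_to_probes <- function(seq_hits, collapsed) {
  members <- collapsed |>
    select("sequence", "members") |>
    tidyr::unnest("members")
  inner_join(members, seq_hits, by = "sequence",
             relationship = "many-to-many") |>
    select(-"sequence")
}
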