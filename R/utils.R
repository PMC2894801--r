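#' Derive a reproducible sub-stream seed from a master seed and a label
#'
#' Each simulator component draws from its own RNG stream so that adding or
#' reordering components does not perturb the numbers drawn by the others.
#' The stream seed is a polynomial hash of the label folded into the master
#' seed, kept within the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed Integer master seed.
#' @param label Character scalar naming the component.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647
  h <- as.double(seed %% m)
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer(h)
}

# round half away from zero (base round() rounds halves to even)
round_half_up <- function(x) floor(x + 0.5)

# blocks are stored as a compact string "start1-end1,start2-end2" (1-based
# inclusive, ascending by start); these helpers convert to/from matrices
format_blocks <- function(blocks) {
  vapply(blocks, function(b) {
    paste(sprintf("%d-%d", b[, 1], b[, 2]), collapse = ",")
  }, character(1))
}

parse_blocks <- function(x) {
  lapply(strsplit(x, ",", fixed = TRUE), function(parts) {
    m <- matrix(as.integer(unlist(strsplit(parts, "-", fixed = TRUE))),
                ncol = 2, byrow = TRUE)
    colnames(m) <- c("start", "end")
    m
  })
}

block_span <- function(x) {
  b <- parse_blocks(x)
  tibble(
    start = map_int(b, ~ min(.x[, 1])),
    end = map_int(b, ~ max(.x[, 2])),
    n_blocks = map_int(b, nrow)
  )
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

flip_strand <- function(x) if_else(x == "+", "-", "+")

abort_input <- function(msg) abort(msg, class = "probemapr_input_error")
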