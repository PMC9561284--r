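# internal helpers

DNA_BASES <- c("A", "C", "G", "T")

# random DNA string of length n under the current RNG
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
}

# set substring [pos] of a string to a base
set_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

# vectorised per-position character access
char_at <- function(seq, pos) substring(seq, pos, pos)

new_log_line <- function(stage, n_in, n_out) {
  tibble::tibble(stage = stage, n_in = as.integer(n_in),
                 n_out = as.integer(n_out),
                 n_dropped = as.integer(n_in - n_out))
}

# attach a per-stage count log as an attribute (one line per stage call;
# subsetting drops attributes, so pipelines collect lines explicitly)
append_log <- function(x, line) {
  attr(x, "stage_log") <- line
  x
}

#' Per-stage read-count log of a processed read table
#'
#' Returns the conservation log (`stage`, `n_in`, `n_out`, `n_dropped`)
#' accumulated by [preprocess_reads()] and [align_reads()].
#'
#' @param x A tibble returned by a pipeline stage.
#' @return A tibble with one row per stage, or `NULL` if no log is attached.
#' @export
stage_log <- function(x) attr(x, "stage_log")
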