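#' Trim the 3' adapter from read sequences
#'
#' Removes, from each read, the longest 3' suffix that matches a prefix of
#' the adapter with at least `min_overlap` bases and a Hamming error rate of
#' at most `max_error_rate`. Reads with no qualifying suffix are returned
#' unchanged.
#'
#' @param reads Tibble with a `sequence` column (or a character vector).
#' @param adapter Adapter sequence in DNA space.
#' @param min_overlap Minimum adapter overlap in nt.
#' @param max_error_rate Maximum fraction of mismatches in the overlap.
#' @return The input with trimmed sequences; a `stage_log` attribute records
#'   read counts (trimming never drops reads).
#' @examples
#' trim_adapter(tibble::tibble(sequence = paste0("ACGTACGT", MICLIP_ADAPTER)))
#' @export
trim_adapter <- function(reads, adapter = MICLIP_ADAPTER, min_overlap = 3,
                         max_error_rate = 0.1) {
  assert_that(nchar(adapter) >= 1, "adapter must be non-empty")
  assert_that(min_overlap >= 1, "min_overlap must be >= 1")
  assert_that(max_error_rate >= 0 && max_error_rate < 0.5,
              "max_error_rate must be in [0, 0.5)")
  vec_in <- is.character(reads)
  seqs <- if (vec_in) reads else reads$sequence
  keep <- trim_adapter_cpp(seqs, adapter, as.integer(min_overlap),
                           max_error_rate)
  out_seq <- substr(seqs, 1L, keep)
  if (vec_in) return(out_seq)
  reads$sequence <- out_seq
  append_log(reads, new_log_line("trim_adapter", length(seqs), length(seqs)))
}

#' Extract the 5' UMI into the read identifier
#'
#' The first `umi_length` bases are removed from the sequence, stored in a
#' `umi` column and appended to the read id after an underscore. Reads not
#' longer than the UMI are dropped and counted.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param umi_length UMI length in nt; 0 is a no-op that adds an empty `umi`
#'   column.
#' @return Tibble with columns `read_id`, `umi`, `sequence`.
#' @export
extract_umi <- function(reads, umi_length = 10) {
  assert_that(umi_length >= 0, "umi_length must be >= 0")
  n_in <- nrow(reads)
  if (umi_length == 0) {
    out <- dplyr::mutate(reads, umi = "", .after = "read_id")
    return(append_log(out, new_log_line("extract_umi", n_in, n_in)))
  }
  keep <- nchar(reads$sequence) > umi_length
  out <- reads[keep, , drop = FALSE]
  out <- dplyr::mutate(
    out,
    umi = substr(.data$sequence, 1L, umi_length),
    sequence = substr(.data$sequence, umi_length + 1L,
                      nchar(.data$sequence)),
    read_id = paste0(.data$read_id, "_", .data$umi),
    .after = NULL)
  out <- dplyr::relocate(out, "umi", .after = "read_id")
  append_log(out, new_log_line("extract_umi", n_in, nrow(out)))
}

#' Discard reads shorter than the minimum insert length
#'
#' @param reads Tibble with a `sequence` column.
#' @param min_length Minimum insert length in nt (default 18).
#' @return The retained reads, with the retained/discarded counts in the
#'   `stage_log` attribute.
#' @export
filter_length <- function(reads, min_length = 18) {
  n_in <- nrow(reads)
  out <- reads[nchar(reads$sequence) >= min_length, , drop = FALSE]
  append_log(out, new_log_line("filter_length", n_in, nrow(out)))
}

#' Prepare raw reads: trim, extract UMI, length-filter
#'
#' The read-preparation contract of the miCLIP arm: 3' adapter trimming,
#' then UMI extraction into the read name, then discarding inserts shorter
#' than `min_length` (applied after UMI removal, since the UMI is not
#' biological sequence). Each stage appends an in/out/dropped line to the
#' `stage_log` attribute, so input count always equals output count plus
#' total dropped.
#'
#' @param reads Tibble with `read_id` and `sequence` (see [read_fastq()]).
#' @param adapter 3' adapter; `""` skips trimming.
#' @param umi_length UMI length in nt.
#' @param min_length Minimum insert length (nt) kept.
#' @param min_overlap,max_error_rate Adapter-matching parameters, see
#'   [trim_adapter()].
#' @return Tibble with `read_id`, `umi`, `sequence` and a `stage_log`
#'   attribute.
#' @export
preprocess_reads <- function(reads, adapter = MICLIP_ADAPTER,
                             umi_length = 10, min_length = 18,
                             min_overlap = 3, max_error_rate = 0.1) {
  logs <- list()
  out <- reads
  if (nzchar(adapter)) {
    out <- trim_adapter(out, adapter, min_overlap, max_error_rate)
    logs <- c(logs, list(stage_log(out)))
  }
  out <- extract_umi(out, umi_length)
  logs <- c(logs, list(stage_log(out)))
  out <- filter_length(out, min_length)
  logs <- c(logs, list(stage_log(out)))
  attr(out, "stage_log") <- dplyr::bind_rows(logs)
  out
}
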