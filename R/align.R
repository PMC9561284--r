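#' Default alignment scoring scheme
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores. A gap of length
#'   L costs `gap_open + (L - 1) * gap_extend` (the first gapped base pays
#'   the opening penalty).
#' @return Named list of scores.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                          gap_extend = -2L) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

#' Optimal local (Smith-Waterman) alignment of a query against a target
#'
#' Full dynamic-programming local alignment with affine gaps. Ties are
#' resolved deterministically (highest score, then the alignment ending
#' earliest on the target, with a diagonal-preferring traceback), which for
#' exact substring queries yields the leftmost occurrence.
#'
#' @param query,target Non-empty DNA strings.
#' @param scoring Scores from [align_scoring()].
#' @param bisulfite If `TRUE`, score in three-letter space (C collapsed onto
#'   T on both sequences).
#' @return A list with `score`, `target_start` (1-based), `target_end`,
#'   `query_start`, `query_end`, `cigar` (M/I/D, reference-consuming ops
#'   M and D).
#' @examples
#' t <- strrep("ACGT", 50)
#' local_align(substr(t, 101, 130), t)$score  # 30 matches x 2
#' @export
local_align <- function(query, target, scoring = align_scoring(),
                        bisulfite = FALSE) {
  assert_that(nchar(query) >= 1 && nchar(target) >= 1,
              "query and target must be non-empty")
  r <- sw_pair_cpp(query, target, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend, bisulfite)
  list(score = r$score,
       target_start = r$target_start + 1L, target_end = r$target_end + 1L,
       query_start = r$query_start + 1L, query_end = r$query_end + 1L,
       cigar = r$cigar)
}

#' Align processed reads to the reference set
#'
#' Seed-and-extend alignment: exact k-mer seeds over an index of the
#' references propose candidate loci, which are extended with a banded
#' affine-gap Smith-Waterman (band width `8 + ceiling(0.1 * read length)`).
#' In `bisulfite` mode both reads and references are collapsed C onto T for
#' seeding and scoring (three-letter alignment against the converted
#' reference), while the original read sequence is preserved for downstream
#' conversion counting. The best-scoring locus is reported when its score
#' reaches `min_score_frac` of the maximum attainable for the read; ties
#' break by reference name, then leftmost end. Reads are aligned sense-only:
#' CLIP and amplicon reads are sense to the RNA.
#'
#' @param reads Tibble from [preprocess_reads()] (`read_id`, `umi`,
#'   `sequence`).
#' @param refs A [ref_set()].
#' @param mode `"standard"` or `"bisulfite"`.
#' @param scoring Scores from [align_scoring()].
#' @param k Seed length (default 12).
#' @param min_score_frac Fraction of the maximum possible score required to
#'   report an alignment (default 0.66).
#' @return Tibble of alignment records: `read_id`, `umi`, `ref`, `start`
#'   (1-based leftmost aligned reference base), `strand`, `aligned_length`,
#'   `score`, `cigar`, `query_start`, `query_end`, `sequence` (original).
#'   Unmapped reads are counted in the `stage_log` attribute, not emitted.
#' @export
align_reads <- function(reads, refs, mode = c("standard", "bisulfite"),
                        scoring = align_scoring(), k = 12,
                        min_score_frac = 0.66) {
  mode <- match.arg(mode)
  if (!"umi" %in% names(reads)) reads$umi <- ""
  n_in <- nrow(reads)
  if (n_in == 0) return(append_log(empty_alignment(),
                                   new_log_line("align", 0, 0)))
  res <- align_batch_cpp(reads$sequence, names(refs$sequences),
                         unname(refs$sequences), as.integer(k),
                         scoring$match, scoring$mismatch, scoring$gap_open,
                         scoring$gap_extend, min_score_frac,
                         mode == "bisulfite", 8L, 0.1)
  mapped <- !is.na(res$ref_idx)
  out <- tibble::tibble(
    read_id = reads$read_id[mapped],
    umi = reads$umi[mapped],
    ref = names(refs$sequences)[res$ref_idx[mapped]],
    start = res$start0[mapped] + 1L,
    strand = "+",
    aligned_length = res$aligned_length[mapped],
    score = res$score[mapped],
    cigar = res$cigar[mapped],
    query_start = res$query_start0[mapped] + 1L,
    query_end = res$query_end0[mapped] + 1L,
    sequence = reads$sequence[mapped])
  append_log(out, new_log_line("align", n_in, nrow(out)))
}
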