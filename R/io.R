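#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (plain or gzip).
#' @return Tibble with columns `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = sub(" .*", "", names(ss)),
                 sequence = unname(as.character(ss)))
}

#' Write reads to FASTQ with constant quality
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param path Output path; a `.gz` suffix enables compression.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$read_id
  q <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(ss, filepath = path, format = "fastq",
                              qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

# cigar helpers ---------------------------------------------------------

cigar_ops <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1]]
  list(len = lens, op = ops)
}

cigar_ref_consumed <- function(cigar) {
  vapply(cigar, function(cg) {
    x <- cigar_ops(cg)
    sum(x$len[x$op %in% c("M", "D", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

#' Write alignment records as SAM
#'
#' Emits a plain-text SAM with `@SQ` headers from the reference set; the UMI
#' is stored in the `RX` tag and the alignment score in `AS`. Soft clips for
#' unaligned read ends are added to the CIGAR.
#'
#' @param records Alignment tibble from [align_reads()].
#' @param refs A [ref_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(records, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(refs$sequences),
                  "\tLN:", nchar(refs$sequences)),
           "@PG\tID:m5cmap\tPN:m5cmap")
  if (nrow(records) > 0) {
    lead <- records$query_start - 1L
    trail <- nchar(records$sequence) - records$query_end
    cig <- paste0(ifelse(lead > 0, paste0(lead, "S"), ""),
                  records$cigar,
                  ifelse(trail > 0, paste0(trail, "S"), ""))
    body <- paste(records$read_id, 0L, records$ref, records$start, 255L,
                  cig, "*", 0L, 0L, records$sequence, "*",
                  paste0("RX:Z:", records$umi),
                  paste0("AS:i:", records$score), sep = "\t")
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file written by [write_sam()] back into an alignment tibble
#'
#' A minimal reader for the plain-text SAM this package emits (single-end,
#' forward-strand records with `RX`/`AS` tags).
#'
#' @param path SAM path.
#' @return Alignment tibble in the [align_reads()] layout.
#' @export
read_sam <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (length(ln) == 0) return(empty_alignment())
  f <- strsplit(ln, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, "", i)
  tag <- function(prefix) {
    vapply(f, function(x) {
      hit <- x[startsWith(x, prefix)]
      if (length(hit)) sub(prefix, "", hit[[1]]) else NA_character_
    }, "")
  }
  cig_full <- get(6)
  lead <- ifelse(grepl("^[0-9]+S", cig_full),
                 as.integer(sub("S.*", "", cig_full)), 0L)
  cig <- sub("[0-9]+S$", "", sub("^[0-9]+S", "", cig_full))
  seqs <- get(10)
  trail <- integer(length(cig_full))
  has_trail <- grepl("[0-9]+S$", cig_full)
  trail[has_trail] <- as.integer(sub("S$", "",
                                     regmatches(cig_full,
                                                regexpr("[0-9]+S$", cig_full))))
  tibble::tibble(
    read_id = get(1), umi = tag("RX:Z:"), ref = get(3),
    start = as.integer(get(4)), strand = "+",
    aligned_length = cigar_ref_consumed(cig),
    score = as.integer(tag("AS:i:")), cigar = cig,
    query_start = lead + 1L,
    query_end = nchar(seqs) - trail,
    sequence = seqs)
}

empty_alignment <- function() {
  tibble::tibble(read_id = character(), umi = character(), ref = character(),
                 start = integer(), strand = character(),
                 aligned_length = integer(), score = integer(),
                 cigar = character(), query_start = integer(),
                 query_end = integer(), sequence = character())
}

#' Write a per-position track as bedGraph
#'
#' Positions are 1-based in the input tibble and written 0-based half-open.
#'
#' @param track Tibble with columns `ref`, `pos` and a value column.
#' @param path Output path.
#' @param value Name of the value column (default the third column).
#' @param refs A [ref_set()] supplying sequence lengths.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, refs, value = names(track)[[3]]) {
  gr <- GenomicRanges::GRanges(
    seqnames = track$ref,
    ranges = IRanges::IRanges(start = track$pos, width = 1),
    score = track[[value]],
    seqlengths = setNames(nchar(refs$sequences), names(refs$sequences)))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write intervals (sites or windows) as BED
#'
#' @param x Tibble with `ref`, `start`, `end` (1-based inclusive) and
#'   optionally `name` and `score` columns.
#' @param path Output path.
#' @param refs A [ref_set()].
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path, refs) {
  gr <- GenomicRanges::GRanges(
    seqnames = x$ref,
    ranges = IRanges::IRanges(start = x$start, end = x$end),
    seqlengths = setNames(nchar(refs$sequences), names(refs$sequences)))
  if ("name" %in% names(x)) gr$name <- x$name
  if ("score" %in% names(x)) gr$score <- x$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
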