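RRNA_REGIONS <- c("5ETS", "18S", "ITS1", "5.8S", "ITS2", "28S", "3ETS")
CLASS_LABELS <- c(RRNA_REGIONS, "snoRNA_CD", "snoRNA_HACA", "vtRNA", "decoy")

#' Reference layout for the synthetic study system
#'
#' Region lengths (nt) of the pre-rRNA mimic, in transcript order, plus the
#' number and size of accessory references. Defaults reproduce the coordinate
#' frame of the human 47S pre-rRNA, in which the mature 28S carries the
#' methylated cytosine at 28S-local position 4447, so that region-local
#' coordinates such as `28S:4447` are directly comparable.
#'
#' @param len_5ets,len_18s,len_its1,len_58s,len_its2,len_28s,len_3ets Region
#'   lengths in nt. `len_28s` must be at least 4447.
#' @param n_snord,n_snora Number of box C/D and H/ACA snoRNA mimics.
#' @param len_snorna Length of each snoRNA mimic (nt).
#' @param n_decoy Number of unrelated decoy references.
#' @param len_decoy Length of each decoy (nt).
#' @param len_vtrna Length of the vault RNA mimic (default 88, the length of
#'   vtRNA1.2).
#' @return A named list of layout parameters.
#' @export
ref_layout <- function(len_5ets = 3655, len_18s = 1869, len_its1 = 1077,
                       len_58s = 157, len_its2 = 1167, len_28s = 5070,
                       len_3ets = 361, n_snord = 3, n_snora = 1,
                       len_snorna = 130, n_decoy = 2, len_decoy = 500,
                       len_vtrna = 88) {
  layout <- list(
    region_lengths = c("5ETS" = len_5ets, "18S" = len_18s, "ITS1" = len_its1,
                       "5.8S" = len_58s, "ITS2" = len_its2, "28S" = len_28s,
                       "3ETS" = len_3ets),
    n_snord = n_snord, n_snora = n_snora, len_snorna = len_snorna,
    n_decoy = n_decoy, len_decoy = len_decoy, len_vtrna = len_vtrna)
  assert_that(all(layout$region_lengths >= 1) &&
                all(layout$region_lengths == floor(layout$region_lengths)),
              "all pre-rRNA region lengths must be positive integers")
  assert_that(len_28s >= 4447, "the 28S region must be at least 4447 nt")
  assert_that(len_vtrna >= 27, "the vtRNA mimic must be at least 27 nt")
  layout
}

#' Construct a reference set
#'
#' A reference set pairs named nucleotide sequences (DNA alphabet; reads are
#' reported in DNA space) with an interval annotation table in 1-based
#' inclusive coordinates.
#'
#' @param sequences Named character vector of ACGT sequences.
#' @param intervals Tibble with columns `name`, `ref`, `start`, `end`,
#'   `class`; `class` must be one of the supported labels (pre-rRNA regions,
#'   `snoRNA_CD`, `snoRNA_HACA`, `vtRNA`, `decoy`).
#' @return An object of class `ref_set`.
#' @export
ref_set <- function(sequences, intervals) {
  assert_that(length(sequences) > 0 && !is.null(names(sequences)),
              "sequences must be a named character vector")
  assert_that(all(nchar(sequences) > 0), "all sequences must be non-empty")
  assert_that(!any(grepl("[^ACGT]", sequences)),
              "sequences must use the DNA alphabet ACGT")
  intervals <- tibble::as_tibble(intervals)
  assert_that(all(c("name", "ref", "start", "end", "class") %in%
                    names(intervals)),
              "intervals needs columns name, ref, start, end, class")
  assert_that(all(intervals$ref %in% names(sequences)),
              "interval on unknown reference")
  assert_that(all(intervals$class %in% CLASS_LABELS),
              "unknown interval class label")
  lens <- nchar(sequences)[intervals$ref]
  assert_that(all(intervals$start >= 1 & intervals$end <= lens &
                    intervals$start <= intervals$end),
              "intervals must lie within reference bounds")
  structure(list(sequences = sequences, intervals = intervals),
            class = "ref_set")
}

#' @export
print.ref_set <- function(x, ...) {
  cat("<ref_set> ", length(x$sequences), " references, ",
      nrow(x$intervals), " intervals\n", sep = "")
  lens <- nchar(x$sequences)
  for (nm in names(x$sequences))
    cat("  ", nm, ": ", lens[[nm]], " nt\n", sep = "")
  invisible(x)
}

ref_length <- function(refs, ref) nchar(refs$sequences[[ref]])

#' Build the synthetic reference set
#'
#' Generates a seeded random reference set whose coordinate layout mimics the
#' 47S pre-rRNA precursor: one long reference tiled, in order, by the 5'ETS,
#' 18S, ITS1, 5.8S, ITS2, 28S and 3'ETS regions, plus vault RNA, box C/D and
#' H/ACA snoRNA mimics and unrelated decoys. Sequence content is uniform
#' random DNA; only the coordinates carry meaning. A cytosine is forced at
#' 28S-local position 4447 and at vtRNA-local position 27 so the canonical
#' m5C sites exist in every realization.
#'
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param layout A layout from [ref_layout()].
#' @return A [ref_set()] with references `pre_rRNA`, `vtRNA1.2`,
#'   `SNORD_1..n`, `SNORA_1..n`, `decoy_1..n`.
#' @examples
#' refs <- build_reference(seed = 1)
#' nchar(refs$sequences[["pre_rRNA"]])
#' @export
build_reference <- function(seed = 1L, layout = ref_layout()) {
  set.seed(seed)
  rl <- layout$region_lengths
  pre <- random_dna(sum(rl))
  ends <- cumsum(rl)
  starts <- ends - rl + 1
  ivs <- tibble::tibble(name = names(rl), ref = "pre_rRNA",
                        start = unname(starts), end = unname(ends),
                        class = names(rl))
  # canonical methylation site: 28S-local 4447
  pre <- set_base(pre, starts[["28S"]] + 4447 - 1, "C")

  seqs <- c(pre_rRNA = pre)
  vt <- set_base(random_dna(layout$len_vtrna), 27, "C")
  seqs[["vtRNA1.2"]] <- vt
  ivs <- dplyr::bind_rows(ivs, tibble::tibble(
    name = "vtRNA1.2", ref = "vtRNA1.2", start = 1L,
    end = layout$len_vtrna, class = "vtRNA"))

  add_refs <- function(seqs, ivs, n, len, prefix, class) {
    for (i in seq_len(n)) {
      nm <- paste0(prefix, "_", i)
      seqs[[nm]] <- random_dna(len)
      ivs <- dplyr::bind_rows(ivs, tibble::tibble(
        name = nm, ref = nm, start = 1L, end = len, class = class))
    }
    list(seqs = seqs, ivs = ivs)
  }
  x <- add_refs(seqs, ivs, layout$n_snord, layout$len_snorna, "SNORD",
                "snoRNA_CD")
  x <- add_refs(x$seqs, x$ivs, layout$n_snora, layout$len_snorna, "SNORA",
                "snoRNA_HACA")
  x <- add_refs(x$seqs, x$ivs, layout$n_decoy, layout$len_decoy, "decoy",
                "decoy")
  ref_set(x$seqs, x$ivs)
}

#' Convert an absolute reference position to its region-local label
#'
#' @param refs A [ref_set()].
#' @param ref Reference name(s).
#' @param pos 1-based absolute position(s) on `ref`.
#' @return Character label(s) such as `"28S:4447"`; positions outside any
#'   annotated interval are labelled `"<ref>:<pos>"`.
#' @export
local_coord <- function(refs, ref, pos) {
  if (length(ref) == 1 && length(pos) > 1) ref <- rep(ref, length(pos))
  iv <- refs$intervals
  out <- paste0(ref, ":", pos)
  done <- logical(length(pos))
  for (i in seq_len(nrow(iv))) {
    sel <- !done & ref == iv$ref[[i]] & pos >= iv$start[[i]] &
      pos <= iv$end[[i]]
    if (any(sel)) {
      out[sel] <- paste0(iv$name[[i]], ":", pos[sel] - iv$start[[i]] + 1)
      done[sel] <- TRUE
    }
  }
  out
}

#' Convert a region-local coordinate to the absolute reference position
#'
#' @param refs A [ref_set()].
#' @param interval Interval name, e.g. `"28S"`.
#' @param local_pos 1-based position within the interval.
#' @return A list with `ref` and `pos` (absolute 1-based).
#' @export
absolute_coord <- function(refs, interval, local_pos) {
  hit <- refs$intervals[refs$intervals$name == interval, ]
  assert_that(nrow(hit) == 1, paste0("unknown interval: ", interval))
  assert_that(local_pos >= 1 && local_pos <= hit$end - hit$start + 1,
              "local position outside interval")
  list(ref = hit$ref[[1]], pos = hit$start[[1]] + local_pos - 1)
}

#' Write a reference set to FASTA and BED
#'
#' The interval table is written as 0-based half-open BED with the class
#' label in the name column as `<name>|<class>`.
#'
#' @param refs A [ref_set()].
#' @param fasta,bed Output paths.
#' @return Invisibly, the paths written.
#' @export
write_reference <- function(refs, fasta, bed) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(refs$sequences), filepath = fasta)
  gr <- GenomicRanges::GRanges(
    seqnames = refs$intervals$ref,
    ranges = IRanges::IRanges(start = refs$intervals$start,
                              end = refs$intervals$end),
    name = paste0(refs$intervals$name, "|", refs$intervals$class),
    seqlengths = setNames(nchar(refs$sequences), names(refs$sequences)))
  rtracklayer::export(gr, bed, format = "BED")
  invisible(c(fasta = fasta, bed = bed))
}

#' Read a reference set from FASTA and BED written by [write_reference()]
#'
#' @param fasta,bed Input paths.
#' @return A [ref_set()].
#' @export
read_reference <- function(fasta, bed) {
  ss <- Biostrings::readDNAStringSet(fasta)
  seqs <- setNames(as.character(ss), names(ss))
  gr <- rtracklayer::import(bed, format = "BED")
  nm <- strsplit(as.character(gr$name), "|", fixed = TRUE)
  ivs <- tibble::tibble(
    name = vapply(nm, `[[`, "", 1),
    ref = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    class = vapply(nm, `[[`, "", 2))
  ref_set(seqs, ivs)
}
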