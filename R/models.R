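#' Crosslink ground-truth model
#'
#' Describes where a catalytically trapped methyltransferase mutant (such as
#' NOP2/NSUN1 C459A) crosslinks its substrate cytosines, and where the
#' protein binds without crosslinking. Truncation-prone sites make reads
#' start exactly at the crosslinked cytosine with probability
#' `truncation_prob`; binding windows multiply read-start density by
#' `relative_enrichment` in both WT and mutant IP libraries.
#'
#' @param sites Tibble with columns `ref`, `pos` (1-based), `truncation_prob`.
#' @param binding_windows Tibble with columns `ref`, `start`, `end`
#'   (1-based inclusive), `relative_enrichment` (>= 1).
#' @param refs A [ref_set()] used to validate that every site sits on a
#'   cytosine and every window is in bounds.
#' @return An object of class `crosslink_model`.
#' @export
crosslink_model <- function(sites, binding_windows, refs) {
  sites <- tibble::as_tibble(sites)
  binding_windows <- tibble::as_tibble(binding_windows)
  assert_that(all(c("ref", "pos", "truncation_prob") %in% names(sites)),
              "sites needs columns ref, pos, truncation_prob")
  assert_that(all(sites$ref %in% names(refs$sequences)),
              "crosslink site on reference absent from the reference set")
  assert_that(all(sites$truncation_prob >= 0 & sites$truncation_prob <= 1),
              "truncation_prob must be in [0, 1]")
  base <- char_at(refs$sequences[sites$ref], sites$pos)
  assert_that(all(base == "C"), "every crosslink site must carry base C")
  if (nrow(binding_windows) > 0) {
    assert_that(all(binding_windows$ref %in% names(refs$sequences)),
                "binding window on unknown reference")
    lens <- nchar(refs$sequences)[binding_windows$ref]
    assert_that(all(binding_windows$start >= 1 &
                      binding_windows$end <= lens &
                      binding_windows$start <= binding_windows$end),
                "binding windows must lie within reference bounds")
    assert_that(all(binding_windows$relative_enrichment >= 1),
                "relative_enrichment must be >= 1")
  }
  structure(list(sites = sites, binding_windows = binding_windows),
            class = "crosslink_model")
}

#' Default crosslink ground truth
#'
#' Two crosslink sites — the canonical 28S m5C position (`28S:4447`) and
#' vtRNA1.2 C27 — each with truncation probability 0.6, plus two 5'ETS
#' binding windows with five-fold enrichment, emulating the 5'ETS-restricted
#' binding footprint of the protein.
#'
#' @param refs A [ref_set()].
#' @param truncation_prob Truncation probability applied to both sites.
#' @return A [crosslink_model()].
#' @export
default_crosslink_model <- function(refs, truncation_prob = 0.6) {
  s1 <- absolute_coord(refs, "28S", 4447)
  s2 <- absolute_coord(refs, "vtRNA1.2", 27)
  ets <- refs$intervals[refs$intervals$name == "5ETS", ]
  L <- ets$end - ets$start + 1
  # two binding footprints at fixed fractions of the 5'ETS, around the
  # early (01/A') and late (A0/1) processing-site regions
  w1 <- ets$start - 1 + round(c(0.22, 0.38) * L)
  w2 <- ets$start - 1 + round(c(0.77, 0.93) * L)
  crosslink_model(
    sites = tibble::tibble(ref = c(s1$ref, s2$ref), pos = c(s1$pos, s2$pos),
                           truncation_prob = truncation_prob),
    binding_windows = tibble::tibble(
      ref = ets$ref, start = c(w1[1], w2[1]), end = c(w1[2], w2[2]),
      relative_enrichment = 5),
    refs = refs)
}

#' Bisulfite conversion ground-truth model
#'
#' Bisulfite treatment deaminates unmethylated cytosines to uracil (read as
#' T); methylated cytosines resist conversion. Every reference C converts
#' independently with `default_conversion_efficiency` unless a per-site,
#' per-condition override applies; a uniform sequencing error is superposed.
#'
#' @param default_conversion_efficiency Probability in `[0,1]` that an
#'   unprotected C reads as T.
#' @param site_overrides Tibble with columns `ref`, `pos`, `condition`,
#'   `conversion_prob` for protected (or partially protected) sites.
#' @param sequencing_error_rate Per-base substitution probability in `[0,1)`.
#' @param refs Optional [ref_set()]; when given, overrides are checked to sit
#'   on reference cytosines.
#' @return An object of class `bisulfite_model`.
#' @export
bisulfite_model <- function(default_conversion_efficiency = 0.97,
                            site_overrides = NULL,
                            sequencing_error_rate = 0.001,
                            refs = NULL) {
  assert_that(is_prob(default_conversion_efficiency),
              "default_conversion_efficiency must be in [0, 1]")
  assert_that(is.numeric(sequencing_error_rate) &&
                sequencing_error_rate >= 0 && sequencing_error_rate < 1,
              "sequencing_error_rate must be in [0, 1)")
  if (is.null(site_overrides))
    site_overrides <- tibble::tibble(ref = character(), pos = integer(),
                                     condition = character(),
                                     conversion_prob = double())
  site_overrides <- tibble::as_tibble(site_overrides)
  assert_that(all(c("ref", "pos", "condition", "conversion_prob") %in%
                    names(site_overrides)),
              "site_overrides needs columns ref, pos, condition, conversion_prob")
  assert_that(all(site_overrides$conversion_prob >= 0 &
                    site_overrides$conversion_prob <= 1),
              "override conversion probabilities must be in [0, 1]")
  if (!is.null(refs) && nrow(site_overrides) > 0) {
    base <- char_at(refs$sequences[site_overrides$ref], site_overrides$pos)
    assert_that(all(base == "C"),
                "site overrides must reference C positions")
  }
  structure(list(default_conversion_efficiency = default_conversion_efficiency,
                 site_overrides = site_overrides,
                 sequencing_error_rate = sequencing_error_rate),
            class = "bisulfite_model")
}

#' Default bisulfite ground truth
#'
#' The shipped study conditions: overall conversion efficiency 0.97 and a
#' partially protected site at `28S:4447` whose converted fraction is 0.16
#' in the control knockdown (`siC`; the unconverted remainder reports m5C,
#' with incomplete protection attributed to unmodified nascent pre-rRNA),
#' rising to 0.28 and 0.34 under the two NOP2/NSUN1 knockdowns.
#'
#' @param refs A [ref_set()].
#' @param efficiency Conversion efficiency for unprotected cytosines.
#' @return A [bisulfite_model()] with conditions `siC`, `siNOP2_1`,
#'   `siNOP2_2`.
#' @export
default_bisulfite_model <- function(refs, efficiency = 0.97) {
  s <- absolute_coord(refs, "28S", 4447)
  ov <- tibble::tibble(
    ref = s$ref, pos = s$pos,
    condition = c("siC", "siNOP2_1", "siNOP2_2"),
    conversion_prob = c(0.16, 0.28, 0.34))
  bisulfite_model(default_conversion_efficiency = efficiency,
                  site_overrides = ov, sequencing_error_rate = 0.001,
                  refs = refs)
}

SAMPLE_TYPES <- c("IP_WT", "IP_C459A", "SMInput", "BISULFITE")

#' Per-library simulation configuration
#'
#' @param n_reads Number of reads to generate.
#' @param sample_type One of `IP_WT`, `IP_C459A`, `SMInput`, `BISULFITE`.
#' @param read_length_range Insert length range (nt) after trimming, sampled
#'   uniformly; ignored for bisulfite libraries, which span the amplicon.
#' @param umi_length UMI length in nt placed at the 5' end of the read
#'   (default 10 for CLIP-style libraries, 0 for bisulfite amplicons).
#' @param adapter 3' adapter appended after the insert (DNA space).
#' @param seed Integer seed for this library.
#' @param condition Condition label (bisulfite arm: `siC`, `siNOP2_1`, ...).
#' @param replicate Replicate index.
#' @param class_weights Named sampling probabilities over reference classes
#'   `rRNA`, `snoRNA_CD`, `snoRNA_HACA`, `vtRNA`, `decoy`; must sum to 1.
#'   `NULL` selects the shipped default for the sample type.
#' @param duplication_rate Fraction of reads re-emitted as PCR duplicates
#'   (same insert and UMI) for deduplication testing.
#' @return An object of class `library_config`.
#' @export
library_config <- function(n_reads, sample_type,
                           read_length_range = c(50L, 110L),
                           umi_length = if (sample_type == "BISULFITE") 0L else 10L,
                           adapter = if (sample_type == "BISULFITE") "" else MICLIP_ADAPTER,
                           seed = 1L, condition = "none", replicate = 1L,
                           class_weights = NULL,
                           duplication_rate = if (sample_type == "BISULFITE") 0 else 0.1) {
  assert_that(is_count(n_reads), "n_reads must be a positive count")
  assert_that(sample_type %in% SAMPLE_TYPES,
              paste0("sample_type must be one of: ",
                     paste(SAMPLE_TYPES, collapse = ", ")))
  assert_that(umi_length >= 0, "umi_length must be >= 0")
  if (is.null(class_weights)) class_weights <- default_class_weights(sample_type)
  assert_that(abs(sum(class_weights) - 1) < 1e-8, "class_weights must sum to 1")
  structure(list(n_reads = as.integer(n_reads), sample_type = sample_type,
                 read_length_range = as.integer(read_length_range),
                 umi_length = as.integer(umi_length), adapter = adapter,
                 seed = as.integer(seed), condition = condition,
                 replicate = as.integer(replicate),
                 class_weights = class_weights,
                 duplication_rate = duplication_rate),
            class = "library_config")
}

#' The eCLIP-style 3' adapter in DNA space
#' @export
MICLIP_ADAPTER <- "AGATCGGAAGAGCACACGTC"

#' Shipped default class weights per sample type
#'
#' Read-class mixtures calibrated to the observed library compositions:
#' rRNA-dominant IP libraries (mutant ~97.8%, WT ~98.5% rRNA) with the
#' remainder mostly box C/D snoRNAs, and a flatter SMInput background.
#'
#' @param sample_type One of `IP_WT`, `IP_C459A`, `SMInput`.
#' @return Named numeric vector over classes summing to 1.
#' @export
default_class_weights <- function(sample_type) {
  switch(sample_type,
    IP_C459A = c(rRNA = 0.978, snoRNA_CD = 0.011, snoRNA_HACA = 0.002,
                 vtRNA = 0.004, decoy = 0.005),
    IP_WT = c(rRNA = 0.985, snoRNA_CD = 0.009, snoRNA_HACA = 0.002,
              vtRNA = 0.001, decoy = 0.003),
    SMInput = c(rRNA = 0.90, snoRNA_CD = 0.04, snoRNA_HACA = 0.01,
                vtRNA = 0.01, decoy = 0.04),
    BISULFITE = c(rRNA = 1, snoRNA_CD = 0, snoRNA_HACA = 0, vtRNA = 0,
                  decoy = 0),
    stop("unknown sample type"))
}
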