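# read simulation: miCLIP (IP / SMInput) and bisulfite amplicon libraries

# class of each reference: pre-rRNA regions collapse to "rRNA"
ref_class_table <- function(refs) {
  iv <- refs$intervals
  cls <- vapply(names(refs$sequences), function(r) {
    cl <- unique(iv$class[iv$ref == r])
    if (any(cl %in% RRNA_REGIONS)) "rRNA" else cl[[1]]
  }, "")
  tibble::tibble(ref = names(refs$sequences), class = unname(cls),
                 length = unname(nchar(refs$sequences)))
}

# sample a reference for each read: class by class_weights, reference within
# class proportional to length
sample_refs <- function(n, refs, class_weights) {
  rct <- ref_class_table(refs)
  w <- class_weights[class_weights > 0]
  assert_that(all(names(w) %in% rct$class),
              "class weight given for a class with no reference")
  cls <- sample(names(w), n, replace = TRUE, prob = w)
  out <- character(n)
  for (cl in unique(cls)) {
    sub <- rct[rct$class == cl, ]
    sel <- cls == cl
    out[sel] <- if (nrow(sub) == 1) sub$ref else
      sample(sub$ref, sum(sel), replace = TRUE, prob = sub$length)
  }
  out
}

# per-reference start-position weights (binding-window enrichment)
start_weights <- function(refs, model, enriched) {
  lapply(setNames(names(refs$sequences), names(refs$sequences)), function(r) {
    w <- rep(1, nchar(refs$sequences[[r]]))
    if (enriched && nrow(model$binding_windows) > 0) {
      bw <- model$binding_windows[model$binding_windows$ref == r, ]
      for (i in seq_len(nrow(bw)))
        w[bw$start[[i]]:bw$end[[i]]] <- w[bw$start[[i]]:bw$end[[i]]] *
          bw$relative_enrichment[[i]]
    }
    w
  })
}

random_umis <- function(n, len) {
  if (len == 0) return(rep("", n))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate a miCLIP IP or SMInput library
#'
#' Draws inserts from the reference set according to the library's class
#' weights; SMInput starts are uniform, IP starts are additionally weighted
#' by `relative_enrichment` inside binding windows, and for the
#' crosslink-trapping mutant (`IP_C459A`) an insert overlapping a crosslink
#' site is truncated — its 5' end moved exactly onto the site — with
#' probability `truncation_prob`, emulating reverse transcription arrest at
#' the covalent protein-RNA adduct. Each read is `UMI + insert + adapter`
#' with constant quality. A configurable fraction of reads is re-emitted as
#' exact PCR duplicates (same insert and UMI).
#'
#' @param refs A [ref_set()].
#' @param model A [crosslink_model()].
#' @param cfg A [library_config()] with `sample_type` one of `IP_WT`,
#'   `IP_C459A`, `SMInput`.
#' @param fastq,manifest Optional output paths; when given, the FASTQ and the
#'   TSV truth manifest are written.
#' @return A list with `reads` (tibble `read_id`, `sequence`) and `truth`
#'   (tibble `read_id`, `ref`, `start`, `end`, `class`, `truncated`, `umi`,
#'   `duplicate_of`), deterministic for a fixed `cfg$seed`.
#' @export
simulate_miclip_library <- function(refs, model, cfg, fastq = NULL,
                                    manifest = NULL) {
  assert_that(cfg$sample_type %in% c("IP_WT", "IP_C459A", "SMInput"),
              "cfg$sample_type must be IP_WT, IP_C459A or SMInput")
  assert_that(all(model$sites$ref %in% names(refs$sequences)),
              "crosslink site on reference absent from refs")
  set.seed(cfg$seed)
  n_dup <- floor(cfg$duplication_rate * cfg$n_reads)
  n_uni <- cfg$n_reads - n_dup
  assert_that(n_uni >= 1, "duplication_rate leaves no unique reads")

  is_ip <- cfg$sample_type != "SMInput"
  refsamp <- sample_refs(n_uni, refs, cfg$class_weights)
  sw <- start_weights(refs, model, enriched = is_ip)

  # insert lengths: uniform over the feasible range per reference — on a
  # short RNA the size selection yields fragments up to its length, not a
  # pile of full-length molecules
  lens <- integer(n_uni)
  start <- integer(n_uni)
  for (r in unique(refsamp)) {
    sel <- which(refsamp == r)
    L <- nchar(refs$sequences[[r]])
    lo <- min(cfg$read_length_range[[1]], L)
    hi <- min(cfg$read_length_range[[2]], L)
    lens[sel] <- if (lo == hi) lo else
      sample(seq(lo, hi), length(sel), replace = TRUE)
    w <- sw[[r]]
    st <- sample.int(L, length(sel), replace = TRUE, prob = w)
    # condition on the insert fitting: rejection-resample overhanging starts
    bad <- st > L - lens[sel] + 1
    while (any(bad)) {
      st[bad] <- sample.int(L, sum(bad), replace = TRUE, prob = w)
      bad <- st > L - lens[sel] + 1
    }
    start[sel] <- st
  }
  end <- start + lens - 1L
  truncated <- rep(FALSE, n_uni)

  if (cfg$sample_type == "IP_C459A" && nrow(model$sites) > 0) {
    for (i in seq_len(nrow(model$sites))) {
      s <- model$sites[i, ]
      ov <- which(refsamp == s$ref & start <= s$pos & end >= s$pos)
      if (length(ov) == 0) next
      hit <- ov[runif(length(ov)) < s$truncation_prob]
      if (length(hit) == 0) next
      L <- nchar(refs$sequences[[s$ref]])
      start[hit] <- s$pos
      end[hit] <- pmin(s$pos + lens[hit] - 1L, L)
      truncated[hit] <- TRUE
    }
  }

  inserts <- substring(refs$sequences[refsamp], start, end)
  umis <- random_umis(n_uni, cfg$umi_length)
  ids <- sprintf("%s_c%s_rep%d_%07d", cfg$sample_type, cfg$condition,
                 cfg$replicate, seq_len(n_uni))
  dup_of <- rep(NA_character_, n_uni)

  if (n_dup > 0) {
    src <- sample.int(n_uni, n_dup, replace = TRUE)
    refsamp <- c(refsamp, refsamp[src])
    start <- c(start, start[src]); end <- c(end, end[src])
    truncated <- c(truncated, truncated[src])
    inserts <- c(inserts, inserts[src]); umis <- c(umis, umis[src])
    dup_of <- c(dup_of, ids[src])
    ids <- c(ids, sprintf("%s_c%s_rep%d_%07d", cfg$sample_type,
                          cfg$condition, cfg$replicate,
                          n_uni + seq_len(n_dup)))
  }

  rct <- ref_class_table(refs)
  cls <- setNames(rct$class, rct$ref)[refsamp]
  reads <- tibble::tibble(read_id = ids,
                          sequence = paste0(umis, inserts, cfg$adapter))
  truth <- tibble::tibble(read_id = ids, ref = refsamp,
                          start = as.integer(start), end = as.integer(end),
                          class = unname(cls), truncated = truncated,
                          umi = umis, duplicate_of = dup_of)
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(manifest)) readr::write_tsv(truth, manifest)
  list(reads = reads, truth = truth)
}

#' Default bisulfite amplicon over the 28S m5C site
#'
#' The targeted amplicon spanning 28S-local positions 4178 to 4534, which
#' contains the methylated cytosine at 28S:4447.
#'
#' @param refs A [ref_set()].
#' @return A list with `ref`, `start`, `end` (absolute 1-based inclusive).
#' @export
default_amplicon <- function(refs) {
  a <- absolute_coord(refs, "28S", 4178)
  b <- absolute_coord(refs, "28S", 4534)
  list(ref = a$ref, start = a$pos, end = b$pos)
}

#' Simulate a bisulfite amplicon library
#'
#' Single-end reads spanning the full amplicon. Each reference cytosine in a
#' read converts to T independently with its per-site probability (a
#' condition-specific override where present, otherwise the model's default
#' conversion efficiency); a uniform substitution error is then applied at
#' `sequencing_error_rate`.
#'
#' @param refs A [ref_set()].
#' @param model A [bisulfite_model()].
#' @param amplicon List with `ref`, `start`, `end` (1-based inclusive); see
#'   [default_amplicon()].
#' @param cfg A [library_config()] with `sample_type = "BISULFITE"`; the
#'   `condition` label selects which site overrides apply.
#' @param fastq,manifest Optional output paths.
#' @return A list with `reads`, `truth` (per-read insert coordinates) and
#'   `site_truth` (per-read conversion outcome at each override site of this
#'   condition).
#' @export
simulate_bisulfite_library <- function(refs, model, amplicon, cfg,
                                       fastq = NULL, manifest = NULL) {
  assert_that(cfg$sample_type == "BISULFITE",
              "cfg$sample_type must be BISULFITE")
  assert_that(amplicon$ref %in% names(refs$sequences),
              "amplicon on unknown reference")
  L <- nchar(refs$sequences[[amplicon$ref]])
  assert_that(amplicon$start >= 1 && amplicon$end <= L &&
                amplicon$start <= amplicon$end,
              "amplicon outside reference bounds")
  insert <- substr(refs$sequences[[amplicon$ref]], amplicon$start,
                   amplicon$end)
  tmpl <- strsplit(insert, "", fixed = TRUE)[[1]]
  c_local <- which(tmpl == "C")
  assert_that(length(c_local) > 0, "amplicon contains no cytosine")
  c_abs <- amplicon$start + c_local - 1L

  ov <- model$site_overrides
  ov <- ov[ov$condition == cfg$condition & ov$ref == amplicon$ref, ]
  p <- rep(model$default_conversion_efficiency, length(c_abs))
  if (nrow(ov) > 0) {
    m <- match(ov$pos, c_abs)
    assert_that(!anyNA(m), "site override outside amplicon C positions")
    p[m] <- ov$conversion_prob
  }

  set.seed(cfg$seed)
  n <- cfg$n_reads
  nc <- length(c_abs)
  conv <- matrix(runif(n * nc) < rep(p, each = n), nrow = n)
  err <- model$sequencing_error_rate

  seqs <- character(n)
  for (i in seq_len(n)) {
    v <- tmpl
    v[c_local[conv[i, ]]] <- "T"
    if (err > 0) {
      ne <- rbinom(1, length(v), err)
      if (ne > 0) {
        at <- sample.int(length(v), ne)
        v[at] <- vapply(v[at],
                        function(b) sample(setdiff(DNA_BASES, b), 1), "")
      }
    }
    seqs[i] <- paste(v, collapse = "")
  }

  umis <- random_umis(n, cfg$umi_length)
  ids <- sprintf("BS_c%s_rep%d_%07d", cfg$condition, cfg$replicate,
                 seq_len(n))
  reads <- tibble::tibble(read_id = ids,
                          sequence = paste0(umis, seqs, cfg$adapter))
  truth <- tibble::tibble(read_id = ids, ref = amplicon$ref,
                          start = amplicon$start, end = amplicon$end,
                          condition = cfg$condition,
                          replicate = cfg$replicate)
  site_truth <- if (nrow(ov) > 0) {
    purrr::map_dfr(seq_len(nrow(ov)), function(i) {
      tibble::tibble(read_id = ids, ref = ov$ref[[i]], pos = ov$pos[[i]],
                     converted = conv[, match(ov$pos[[i]], c_abs)])
    })
  } else {
    tibble::tibble(read_id = character(), ref = character(),
                   pos = integer(), converted = logical())
  }
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(manifest)) readr::write_tsv(truth, manifest)
  list(reads = reads, truth = truth, site_truth = site_truth)
}
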