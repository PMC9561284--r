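#' Study design for the synthetic two-arm experiment
#'
#' The default design mirrors the study layout: a miCLIP arm with two
#' biological replicates of each of IP (WT and crosslink-trapping C459A
#' mutant) and their paired size-matched inputs, and a bisulfite arm with
#' three conditions (control `siC` and two knockdowns) of three replicates
#' each. Per-library seeds are derived deterministically from the global
#' seed.
#'
#' @param seed Global integer seed.
#' @param n_miclip_reads Reads per miCLIP library (default 20000).
#' @param n_bisulfite_reads Reads per bisulfite library (default 50000,
#'   scaled down from the study's ~130000 aligned reads per sample).
#' @param miclip_replicates Biological replicates per miCLIP sample type.
#' @param bisulfite_conditions Condition labels; the first is the control.
#' @param bisulfite_replicates Replicates per bisulfite condition.
#' @param truncation_prob Crosslink truncation probability (mutant IP).
#' @param conversion_efficiency Bisulfite conversion efficiency for
#'   unprotected cytosines.
#' @param amplicon 28S-local amplicon bounds `c(start, end)`.
#' @param read_length_range,umi_length,duplication_rate miCLIP library
#'   structure parameters, see [library_config()].
#' @return An object of class `study_design`.
#' @export
study_design <- function(seed = 1L, n_miclip_reads = 20000L,
                         n_bisulfite_reads = 50000L,
                         miclip_replicates = 2L,
                         bisulfite_conditions = c("siC", "siNOP2_1",
                                                  "siNOP2_2"),
                         bisulfite_replicates = 3L,
                         truncation_prob = 0.6,
                         conversion_efficiency = 0.97,
                         amplicon = c(4178L, 4534L),
                         read_length_range = c(50L, 110L),
                         umi_length = 10L, duplication_rate = 0.1) {
  assert_that(miclip_replicates >= 1, "need at least one miCLIP replicate")
  assert_that(bisulfite_replicates >= 2,
              "need at least 2 replicates per bisulfite condition")
  structure(list(seed = as.integer(seed),
                 n_miclip_reads = as.integer(n_miclip_reads),
                 n_bisulfite_reads = as.integer(n_bisulfite_reads),
                 miclip_replicates = as.integer(miclip_replicates),
                 bisulfite_conditions = bisulfite_conditions,
                 bisulfite_replicates = as.integer(bisulfite_replicates),
                 truncation_prob = truncation_prob,
                 conversion_efficiency = conversion_efficiency,
                 amplicon = as.integer(amplicon),
                 read_length_range = as.integer(read_length_range),
                 umi_length = as.integer(umi_length),
                 duplication_rate = duplication_rate),
            class = "study_design")
}

MICLIP_SAMPLES <- c("IP_WT", "IP_C459A", "SMInput_WT", "SMInput_C459A")

# deterministic per-library seed, kept within 32-bit integer range
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 97L + idx * 131L) %% 2147483587)
}

#' Generate the full synthetic study fixture on disk
#'
#' Writes references (FASTA + BED), a YAML run configuration, and every
#' library of the design: `miclip_replicates` x 4 miCLIP FASTQs (IP and
#' SMInput for WT and mutant) and `conditions x replicates` bisulfite
#' FASTQs, each with its TSV truth manifest. Deterministic for a fixed
#' design.
#'
#' @param design A [study_design()].
#' @param outdir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return Invisibly, a list with `refs`, `config` and the file tree root.
#' @export
make_fixture <- function(design, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force)
    stop("outdir exists and is non-empty; use force = TRUE", call. = FALSE)
  dir.create(file.path(outdir, "miclip"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outdir, "bisulfite"), showWarnings = FALSE)

  refs <- build_reference(seed = design$seed)
  write_reference(refs, file.path(outdir, "refs.fasta"),
                  file.path(outdir, "intervals.bed"))
  xl <- default_crosslink_model(refs, truncation_prob =
                                  design$truncation_prob)
  bs <- default_bisulfite_model(refs, efficiency =
                                  design$conversion_efficiency)
  amp <- list(ref = absolute_coord(refs, "28S", design$amplicon[[1]])$ref,
              start = absolute_coord(refs, "28S", design$amplicon[[1]])$pos,
              end = absolute_coord(refs, "28S", design$amplicon[[2]])$pos)

  idx <- 0L
  for (r in seq_len(design$miclip_replicates)) {
    for (st in MICLIP_SAMPLES) {
      idx <- idx + 1L
      stype <- if (startsWith(st, "SMInput")) "SMInput" else st
      cfg <- library_config(
        n_reads = design$n_miclip_reads, sample_type = stype,
        read_length_range = design$read_length_range,
        umi_length = design$umi_length,
        seed = derive_seed(design$seed, idx),
        condition = sub("^(IP_|SMInput_)", "", st), replicate = r,
        duplication_rate = design$duplication_rate)
      stem <- file.path(outdir, "miclip", paste0(st, "_rep", r))
      simulate_miclip_library(refs, xl, cfg,
                              fastq = paste0(stem, ".fastq"),
                              manifest = paste0(stem, ".manifest.tsv"))
    }
  }
  for (ci in seq_along(design$bisulfite_conditions)) {
    cond <- design$bisulfite_conditions[[ci]]
    for (r in seq_len(design$bisulfite_replicates)) {
      idx <- idx + 1L
      cfg <- library_config(
        n_reads = design$n_bisulfite_reads, sample_type = "BISULFITE",
        seed = derive_seed(design$seed, idx), condition = cond,
        replicate = r)
      stem <- file.path(outdir, "bisulfite", paste0(cond, "_rep", r))
      simulate_bisulfite_library(refs, bs, amp, cfg,
                                 fastq = paste0(stem, ".fastq"),
                                 manifest = paste0(stem, ".manifest.tsv"))
    }
  }

  config <- list(
    seed = design$seed,
    miclip = list(n_reads = design$n_miclip_reads,
                  replicates = design$miclip_replicates,
                  truncation_prob = design$truncation_prob,
                  umi_length = design$umi_length,
                  adapter = MICLIP_ADAPTER,
                  read_length_range = design$read_length_range),
    bisulfite = list(n_reads = design$n_bisulfite_reads,
                     replicates = design$bisulfite_replicates,
                     conditions = design$bisulfite_conditions,
                     efficiency = design$conversion_efficiency,
                     amplicon = list(interval = "28S",
                                     start = design$amplicon[[1]],
                                     end = design$amplicon[[2]])))
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  invisible(list(root = outdir, refs = refs, config = config))
}

read_fixture_config <- function(dir) {
  yaml::read_yaml(file.path(dir, "config.yaml"))
}

write_run_log <- function(lines, path) {
  writeLines(vapply(lines, function(x)
    jsonlite::toJSON(x, auto_unbox = TRUE), ""), path)
}

process_miclip_fastq <- function(path, refs, cfg) {
  raw <- read_fastq(path)
  pre <- preprocess_reads(raw, adapter = cfg$miclip$adapter,
                          umi_length = cfg$miclip$umi_length)
  pre_log <- stage_log(pre)
  aln <- align_reads(pre, refs, mode = "standard")
  aln_log <- stage_log(aln)
  ded <- deduplicate(aln)
  lg <- dplyr::bind_rows(pre_log, aln_log, stage_log(ded))
  list(records = ded, log = lg, n_raw = nrow(raw))
}

#' Run the miCLIP arm end to end on a fixture directory
#'
#' For every replicate: preprocess, align, deduplicate and profile each of
#' the four libraries; build depth-normalized RT-stop tracks and the
#' IP/SMInput coverage-ratio track; call crosslink sites from the
#' mutant-vs-WT stop contrast; test windowed IP enrichment over the paired
#' SMInput; summarize read classes. Writes bedGraph/BED/TSV outputs and a
#' JSON-lines run log under `<dir>/results_miclip`.
#'
#' @param dir Fixture directory from [make_fixture()].
#' @param refs Optional pre-loaded [ref_set()]; read from the fixture by
#'   default.
#' @param write_outputs Write track and table files (default `TRUE`).
#' @return An object of class `miclip_run`: `site_calls`, `windows`,
#'   `class_summary`, `ratio_track` (replicate mean), `stop_tracks`,
#'   `library_sizes`, `logs`.
#' @export
run_miclip <- function(dir, refs = NULL, write_outputs = TRUE) {
  cfg <- read_fixture_config(dir)
  if (is.null(refs))
    refs <- read_reference(file.path(dir, "refs.fasta"),
                           file.path(dir, "intervals.bed"))
  reps <- seq_len(cfg$miclip$replicates)
  fq <- function(st, r) file.path(dir, "miclip",
                                  paste0(st, "_rep", r, ".fastq"))
  for (r in reps) for (st in MICLIP_SAMPLES)
    assert_that(file.exists(fq(st, r)),
                paste0("missing miCLIP library: ", fq(st, r)))

  site_calls <- list(); windows <- list(); classes <- list()
  ratio_tracks <- list(); stop_tracks <- list(); logs <- list()
  libsizes <- list()
  for (r in reps) {
    lib <- lapply(setNames(MICLIP_SAMPLES, MICLIP_SAMPLES), function(st) {
      x <- process_miclip_fastq(fq(st, r), refs, cfg)
      logs[[paste0(st, "_rep", r)]] <<- dplyr::mutate(
        x$log, library = paste0(st, "_rep", r), .before = 1)
      x
    })
    prof <- lapply(lib, function(x) stop_profile(x$records, refs))
    for (st in MICLIP_SAMPLES)
      libsizes[[paste0(st, "_rep", r)]] <- library_size(prof[[st]])

    sc <- call_sites(prof$IP_C459A, prof$IP_WT, refs = refs)
    site_calls[[r]] <- dplyr::mutate(sc, replicate = r, .before = 1)
    we <- dplyr::bind_rows(
      IP_C459A = window_enrichment(prof$IP_C459A, prof$SMInput_C459A),
      IP_WT = window_enrichment(prof$IP_WT, prof$SMInput_WT),
      .id = "ip")
    windows[[r]] <- dplyr::mutate(we, replicate = r, .before = 1)
    cl <- dplyr::bind_rows(lapply(lib, function(x)
      class_summary(x$records, refs)), .id = "library")
    classes[[r]] <- dplyr::mutate(cl, replicate = r, .before = 1)
    ratio_tracks[[r]] <- enrichment_track(prof$IP_C459A,
                                          prof$SMInput_C459A)
    stop_tracks[[r]] <- dplyr::bind_rows(
      IP_C459A = normalize_rpm(prof$IP_C459A),
      IP_WT = normalize_rpm(prof$IP_WT), .id = "library") |>
      dplyr::mutate(replicate = r, .before = 1)
  }

  mean_ratio <- ratio_tracks[[1]]
  if (length(ratio_tracks) > 1) {
    m <- rowMeans(vapply(ratio_tracks, function(x) x$ratio,
                         double(nrow(mean_ratio))))
    mean_ratio$ratio <- m
  }
  res <- structure(list(
    site_calls = dplyr::bind_rows(site_calls),
    windows = dplyr::bind_rows(windows),
    class_summary = dplyr::bind_rows(classes),
    ratio_track = mean_ratio,
    stop_tracks = dplyr::bind_rows(stop_tracks),
    library_sizes = tibble::tibble(library = names(libsizes),
                                   n = unlist(libsizes)),
    logs = dplyr::bind_rows(logs)), class = "miclip_run")

  if (write_outputs) {
    out <- file.path(dir, "results_miclip")
    dir.create(out, showWarnings = FALSE)
    readr::write_tsv(res$site_calls, file.path(out, "site_calls.tsv"))
    readr::write_tsv(res$windows, file.path(out, "windows.tsv"))
    readr::write_tsv(res$class_summary, file.path(out, "class_summary.tsv"))
    write_bedgraph(res$ratio_track, file.path(out, "ip_over_smi.bedGraph"),
                   refs)
    tr <- res$stop_tracks[res$stop_tracks$replicate == 1 &
                            res$stop_tracks$library == "IP_C459A", ]
    write_bedgraph(tr[, c("ref", "pos", "stop_rpm")],
                   file.path(out, "stops_C459A_rep1.bedGraph"), refs)
    passed <- res$site_calls[res$site_calls$passed, ]
    if (nrow(passed) > 0)
      write_bed(dplyr::transmute(passed, ref = .data$ref,
                                 start = .data$pos, end = .data$pos,
                                 name = .data$label, score = .data$ratio),
                file.path(out, "passed_sites.bed"), refs)
    sig <- res$windows[res$windows$significant, ]
    if (nrow(sig) > 0)
      write_bed(sig, file.path(out, "significant_windows.bed"), refs)
    write_run_log(c(
      apply(res$library_sizes, 1, function(x)
        list(event = "library_size", library = x[["library"]],
             n = as.integer(x[["n"]]))),
      list(list(event = "top_sites",
                sites = head(res$site_calls$label[res$site_calls$passed],
                             5)))),
      file.path(out, "run_log.jsonl"))
  }
  res
}

#' Run the bisulfite arm end to end on a fixture directory
#'
#' For every condition and replicate: preprocess (no adapter/UMI by
#' default), align in bisulfite (three-letter) mode, and tabulate
#' per-cytosine conversion over the amplicon. Produces per-condition
#' replicate fractions at the override (target) sites, pooled and
#' per-replicate overall conversion rates excluding those sites, and
#' Student's t-tests of each non-control condition against the control.
#'
#' @param dir Fixture directory from [make_fixture()].
#' @param refs Optional pre-loaded [ref_set()].
#' @param target_sites Optional tibble (`ref`, `pos`) of methylation target
#'   sites; defaults to the shipped `28S:4447` site.
#' @param write_outputs Write TSV outputs under `<dir>/results_bisulfite`.
#' @return An object of class `bisulfite_run`: `tables` (per-library
#'   conversion tables, long), `site_fractions`, `condition_summary`,
#'   `comparisons`, `overall_rates`, `logs`.
#' @export
run_bisulfite <- function(dir, refs = NULL, target_sites = NULL,
                          write_outputs = TRUE) {
  cfg <- read_fixture_config(dir)
  assert_that(cfg$bisulfite$replicates >= 2,
              "need at least 2 replicates per condition")
  if (is.null(refs))
    refs <- read_reference(file.path(dir, "refs.fasta"),
                           file.path(dir, "intervals.bed"))
  amp <- list(
    ref = absolute_coord(refs, cfg$bisulfite$amplicon$interval,
                         cfg$bisulfite$amplicon$start)$ref,
    start = absolute_coord(refs, cfg$bisulfite$amplicon$interval,
                           cfg$bisulfite$amplicon$start)$pos,
    end = absolute_coord(refs, cfg$bisulfite$amplicon$interval,
                         cfg$bisulfite$amplicon$end)$pos)
  if (is.null(target_sites)) {
    s <- absolute_coord(refs, "28S", 4447)
    target_sites <- tibble::tibble(ref = s$ref, pos = s$pos)
  }

  tables <- list(); logs <- list(); rates <- list()
  for (cond in cfg$bisulfite$conditions) {
    for (r in seq_len(cfg$bisulfite$replicates)) {
      path <- file.path(dir, "bisulfite",
                        paste0(cond, "_rep", r, ".fastq"))
      assert_that(file.exists(path),
                  paste0("missing bisulfite library: ", path))
      raw <- read_fastq(path)
      pre <- preprocess_reads(raw, adapter = "", umi_length = 0)
      pre_log <- stage_log(pre)
      aln <- align_reads(pre, refs, mode = "bisulfite")
      lg <- dplyr::bind_rows(pre_log, stage_log(aln))
      tab <- conversion_table(aln, refs, amp)
      key <- paste0(cond, "_rep", r)
      tables[[key]] <- dplyr::mutate(tab, condition = cond, replicate = r,
                                     .before = 1)
      logs[[key]] <- dplyr::mutate(lg, library = key, .before = 1)
      rates[[key]] <- tibble::tibble(
        condition = cond, replicate = r,
        overall_rate = overall_conversion_rate(tab,
                                               exclude = target_sites))
    }
  }
  long <- dplyr::bind_rows(tables)
  site_fr <- long |>
    dplyr::semi_join(target_sites, by = c("ref", "pos")) |>
    dplyr::select("condition", "replicate", "ref", "pos", "label",
                  "converted_fraction")
  # per-replicate averaging is the headline statistic; the read-pooled
  # fraction across replicates is reported alongside
  cond_sum <- long |>
    dplyr::semi_join(target_sites, by = c("ref", "pos")) |>
    dplyr::group_by(.data$condition, .data$ref, .data$pos, .data$label) |>
    dplyr::summarise(mean_converted = mean(.data$converted_fraction),
                     sd_converted = stats::sd(.data$converted_fraction),
                     pooled_converted = sum(.data$n_converted) /
                       sum(.data$n_converted + .data$n_nonconverted),
                     n = dplyr::n(), .groups = "drop")
  control <- cfg$bisulfite$conditions[[1]]
  comparisons <- purrr::map_dfr(
    setdiff(cfg$bisulfite$conditions, control), function(cond) {
      purrr::map_dfr(seq_len(nrow(target_sites)), function(i) {
        sel <- site_fr$ref == target_sites$ref[[i]] &
          site_fr$pos == target_sites$pos[[i]]
        a <- site_fr$converted_fraction[sel & site_fr$condition == control]
        b <- site_fr$converted_fraction[sel & site_fr$condition == cond]
        compare_conditions(site_fr$label[sel][[1]], a, b,
                           labels = c(control, cond))
      })
    })
  res <- structure(list(
    tables = long, site_fractions = site_fr, condition_summary = cond_sum,
    comparisons = comparisons,
    overall_rates = dplyr::bind_rows(rates),
    logs = dplyr::bind_rows(logs)), class = "bisulfite_run")

  if (write_outputs) {
    out <- file.path(dir, "results_bisulfite")
    dir.create(out, showWarnings = FALSE)
    readr::write_tsv(long, file.path(out, "conversion_tables.tsv"))
    readr::write_tsv(site_fr, file.path(out, "site_fractions.tsv"))
    readr::write_tsv(cond_sum, file.path(out, "condition_summary.tsv"))
    readr::write_tsv(comparisons, file.path(out, "comparisons.tsv"))
    readr::write_tsv(res$overall_rates, file.path(out, "overall_rates.tsv"))
    write_run_log(list(list(
      event = "overall_rate",
      mean = mean(res$overall_rates$overall_rate))),
      file.path(out, "run_log.jsonl"))
  }
  res
}

#' @export
print.miclip_run <- function(x, ...) {
  cat("<miclip_run>\n")
  passed <- x$site_calls[x$site_calls$passed, ]
  cat("  passed site calls:", nrow(passed), "\n")
  if (nrow(passed) > 0)
    print(head(passed[, c("replicate", "label", "ratio", "stop_fraction")]))
  cat("  significant windows:", sum(x$windows$significant), "\n")
  invisible(x)
}

#' @export
print.bisulfite_run <- function(x, ...) {
  cat("<bisulfite_run>\n")
  cat("  overall conversion rate:",
      sprintf("%.3f", mean(x$overall_rates$overall_rate)), "\n")
  print(x$condition_summary)
  invisible(x)
}
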