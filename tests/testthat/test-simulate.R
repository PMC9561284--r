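refs <- small_refs()
xl <- default_crosslink_model(refs)

test_that("truncation probability 1 forces every site-overlapping read start", {
  cfg <- library_config(2000, "IP_C459A", seed = 5, duplication_rate = 0)
  xl1 <- crosslink_model(
    sites = dplyr::mutate(xl$sites, truncation_prob = 1),
    binding_windows = xl$binding_windows, refs = refs)
  sim <- simulate_miclip_library(refs, xl1, cfg)
  s <- absolute_coord(refs, "28S", 4447)
  ov <- sim$truth$ref == s$ref & sim$truth$start <= s$pos &
    sim$truth$end >= s$pos
  expect_true(all(sim$truth$start[ov & sim$truth$ref == s$ref &
                                    sim$truth$truncated] == s$pos))
  # every read overlapping the site must be truncated onto it
  expect_true(all(sim$truth$truncated[ov]))
})

test_that("empirical truncated fraction matches the binomial oracle", {
  cfg <- library_config(20000, "IP_C459A", seed = 7, duplication_rate = 0)
  sim <- simulate_miclip_library(refs, xl, cfg)  # truncation_prob 0.6
  s <- absolute_coord(refs, "28S", 4447)
  # overlap must be judged on pre-truncation geometry; truncated reads were
  # overlapping by construction, so count overlap among all reads on ref
  tr <- sim$truth[sim$truth$ref == s$ref, ]
  ov <- tr[tr$start <= s$pos & tr$end >= s$pos, ]
  n_ov <- nrow(ov)
  frac <- mean(ov$truncated)
  tol <- 3 * sqrt(0.6 * 0.4 / n_ov)
  expect_gt(n_ov, 100)
  expect_lt(abs(frac - 0.6), tol + 0.02) # +0.02: overlap set is post-hoc
})

test_that("FASTQ output is byte-identical for a fixed seed and conserves counts", {
  cfg <- library_config(500, "SMInput", seed = 11)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  s1 <- simulate_miclip_library(refs, xl, cfg, fastq = f1)
  s2 <- simulate_miclip_library(refs, xl, cfg, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(s1$reads), 500)
  expect_equal(nrow(s1$truth), 500)
  back <- read_fastq(f1)
  expect_equal(nrow(back), 500)
  expect_identical(back$sequence, s1$reads$sequence)
})

test_that("read structure is UMI + insert + adapter", {
  cfg <- library_config(200, "IP_WT", seed = 2, duplication_rate = 0)
  sim <- simulate_miclip_library(refs, xl, cfg)
  tr <- sim$truth
  ins <- substring(refs$sequences[tr$ref], tr$start, tr$end)
  expect_identical(sim$reads$sequence,
                   paste0(tr$umi, ins, MICLIP_ADAPTER))
  expect_true(all(nchar(tr$umi) == 10))
})

test_that("binding windows enrich read-start density by the configured factor", {
  w <- tibble::tibble(ref = "pre_rRNA", start = 1001L, end = 1600L,
                      relative_enrichment = 5)
  m <- crosslink_model(sites = xl$sites[0, ], binding_windows = w,
                       refs = refs)
  cfg <- library_config(50000, "IP_WT", seed = 3, duplication_rate = 0,
                        class_weights = c(rRNA = 1, snoRNA_CD = 0,
                                          snoRNA_HACA = 0, vtRNA = 0,
                                          decoy = 0),
                        read_length_range = c(30L, 30L))
  sim <- simulate_miclip_library(refs, m, cfg)
  st <- sim$truth$start
  L <- nchar(refs$sequences[["pre_rRNA"]])
  inside <- mean(st >= 1001 & st <= 1600) / (600 / L)
  outside <- mean(st < 1001 | st > 1600) / ((L - 600) / L)
  expect_lt(abs(inside / outside - 5), 0.5)
})

test_that("PCR duplicates share insert and UMI with their source read", {
  cfg <- library_config(1000, "SMInput", seed = 9, duplication_rate = 0.2)
  sim <- simulate_miclip_library(refs, xl, cfg)
  dups <- sim$truth[!is.na(sim$truth$duplicate_of), ]
  expect_equal(nrow(dups), 200)
  src <- sim$truth[match(dups$duplicate_of, sim$truth$read_id), ]
  expect_identical(dups$umi, src$umi)
  expect_identical(dups$start, src$start)
  expect_identical(dups$end, src$end)
})

test_that("bisulfite chemistry limits: full conversion and no conversion", {
  amp <- default_amplicon(refs)
  cfg <- library_config(50, "BISULFITE", seed = 1, condition = "none")
  full <- bisulfite_model(1, sequencing_error_rate = 0)
  sim <- simulate_bisulfite_library(refs, full, amp, cfg)
  expect_false(any(grepl("C", sim$reads$sequence)))
  none <- bisulfite_model(0, sequencing_error_rate = 0)
  sim0 <- simulate_bisulfite_library(refs, none, amp, cfg)
  ins <- substr(refs$sequences[[amp$ref]], amp$start, amp$end)
  expect_true(all(sim0$reads$sequence == ins))
})

test_that("per-C conversion rate matches the binomial oracle at 0.97", {
  amp <- default_amplicon(refs)
  m <- bisulfite_model(0.97, sequencing_error_rate = 0)
  cfg <- library_config(5000, "BISULFITE", seed = 3, condition = "siC")
  sim <- simulate_bisulfite_library(refs, m, amp, cfg)
  ins <- strsplit(substr(refs$sequences[[amp$ref]], amp$start, amp$end),
                  "")[[1]]
  cpos <- which(ins == "C")
  conv <- vapply(cpos, function(p)
    mean(substr(sim$reads$sequence, p, p) == "T"), double(1))
  # mean over all Cs concentrates tightly around the efficiency
  se <- sqrt(0.97 * 0.03 / (5000 * length(cpos)))
  expect_lt(abs(mean(conv) - 0.97), 4 * se + 0.001)
})

test_that("condition-specific site overrides apply only to their condition", {
  refs_f <- build_reference(seed = 2)
  bs <- default_bisulfite_model(refs_f)
  amp <- default_amplicon(refs_f)
  s <- absolute_coord(refs_f, "28S", 4447)
  off <- s$pos - amp$start + 1
  for (cond in c("siC", "siNOP2_1", "siNOP2_2")) {
    cfg <- library_config(4000, "BISULFITE", seed = 8, condition = cond)
    sim <- simulate_bisulfite_library(refs_f, bs, amp, cfg)
    frac <- mean(substr(sim$reads$sequence, off, off) == "T")
    want <- c(siC = 0.16, siNOP2_1 = 0.28, siNOP2_2 = 0.34)[[cond]]
    expect_lt(abs(frac - want), 3 * sqrt(want * (1 - want) / 4000) + 0.005)
    expect_equal(nrow(sim$site_truth), 4000)
    expect_lt(abs(mean(sim$site_truth$converted) - want), 0.05)
  }
})

test_that("degenerate inputs are rejected", {
  cfg <- library_config(10, "IP_C459A", seed = 1)
  bad <- xl
  bad$sites$ref <- "missing_ref"
  expect_error(simulate_miclip_library(refs, bad, cfg), "absent")
  amp_noC <- list(ref = "pre_rRNA", start = 1, end = 2)
  # engineered amplicon without C may still contain one; construct directly
  seq1 <- refs$sequences[["pre_rRNA"]]
  p <- regexpr("[AGT]{3}", seq1)
  amp2 <- list(ref = "pre_rRNA", start = as.integer(p),
               end = as.integer(p) + 2L)
  bcfg <- library_config(10, "BISULFITE", seed = 1)
  expect_error(
    simulate_bisulfite_library(refs, bisulfite_model(), amp2, bcfg),
    "cytosine")
  expect_error(library_config(10, "WHAT"), "sample_type")
})
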