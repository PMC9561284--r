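refs <- small_refs()

test_that("exact substring queries score match * length at the right offset", {
  t <- refs$sequences[["pre_rRNA"]]
  q <- substr(t, 101, 130)
  r <- local_align(q, t)
  expect_equal(r$score, 60)
  expect_equal(r$target_start, 101)
  expect_identical(r$cigar, "30M")
  # query equal to target
  full <- local_align(t, t)
  expect_equal(full$score, 2 * nchar(t))
  expect_error(local_align("", t), "non-empty")
})

test_that("seeded and full alignment agree with the brute-force SW oracle", {
  set.seed(99)
  for (i in 1:60) {
    q <- random_seq(sample(5:30, 1))
    t <- random_seq(sample(30:150, 1))
    r <- local_align(q, t)
    expect_equal(r$score, sw_oracle_score(q, t), info = paste("case", i))
  }
  # mutated substrings exercise mismatch/gap paths
  for (i in 1:20) {
    t <- random_seq(200)
    off <- sample(1:150, 1)
    q <- substr(t, off, off + 39)
    qc <- strsplit(q, "")[[1]]
    qc[sample(40, 3)] <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    q <- paste(c(qc[1:20], qc[22:40]), collapse = "") # plus one deletion
    expect_equal(local_align(q, t)$score, sw_oracle_score(q, t))
  }
})

test_that("bisulfite-mode score is invariant to the conversion pattern", {
  t <- refs$sequences[["pre_rRNA"]]
  amp <- default_amplicon(refs)
  q <- substr(t, amp$start, amp$start + 79)
  qs <- strsplit(q, "")[[1]]
  cpos <- which(qs == "C")
  set.seed(2)
  scores <- vapply(1:5, function(i) {
    conv <- qs
    flip <- cpos[runif(length(cpos)) < 0.7]
    conv[flip] <- "T"
    local_align(paste(conv, collapse = ""), t, bisulfite = TRUE)$score
  }, double(1))
  expect_true(all(scores == scores[[1]]))
  expect_equal(scores[[1]], 2 * 80)
  # in standard mode each converted C costs (match - mismatch)
  conv <- qs; conv[cpos] <- "T"
  std <- local_align(paste(conv, collapse = ""), t)$score
  expect_equal(std, 2 * 80 - length(cpos) * (2 - (-3)))
})

test_that("error-free reads map back to their true coordinates", {
  xl <- default_crosslink_model(refs)
  cfg <- library_config(3000, "SMInput", seed = 21, duplication_rate = 0)
  sim <- simulate_miclip_library(refs, xl, cfg)
  pre <- preprocess_reads(sim$reads)
  aln <- align_reads(pre, refs)
  truth <- sim$truth[match(sub("_[ACGT]+$", "", aln$read_id),
                           sim$truth$read_id), ]
  ok <- aln$ref == truth$ref & aln$start == truth$start
  expect_gte(mean(ok), 0.99)
  expect_gte(nrow(aln) / nrow(pre), 0.99)
  # alignment length never exceeds reference bounds
  expect_true(all(aln$start + aln$aligned_length - 1 <=
                    nchar(refs$sequences)[aln$ref]))
})

test_that("alignment output is deterministic including SAM bytes", {
  xl <- default_crosslink_model(refs)
  cfg <- library_config(300, "IP_WT", seed = 5)
  sim <- simulate_miclip_library(refs, xl, cfg)
  pre <- preprocess_reads(sim$reads)
  a1 <- align_reads(pre, refs)
  a2 <- align_reads(pre, refs)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(a1, refs, f1); write_sam(a2, refs, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_sam(f1)
  expect_equal(back$start, a1$start)
  expect_equal(back$score, a1$score)
  expect_identical(back$umi, a1$umi)
  expect_identical(back$sequence, a1$sequence)
  expect_equal(back$query_start, a1$query_start)
})

test_that("reads without a seed hit or below min_score are counted unmapped", {
  reads <- tibble::tibble(read_id = c("junk1", "junk2"),
                          umi = c("AAAA", "CCCC"),
                          sequence = c(strrep("AC", 15), strrep("GT", 15)))
  # random refs are unlikely to contain these dimers verbatim; verify count
  aln <- align_reads(reads, refs)
  lg <- stage_log(aln)
  expect_equal(lg$n_in, 2)
  expect_equal(lg$n_out + lg$n_dropped, 2)
})
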