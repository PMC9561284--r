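refs <- small_refs()

test_that("deduplication keys on position, UMI and read length", {
  r <- fake_records("pre_rRNA", c(10, 10, 10, 10, 50), aligned_length = 30,
                    umi = c("AAA", "AAA", "AAA", "CCC", "AAA"))
  out <- deduplicate(r)
  expect_equal(nrow(out), 3)  # {10,AAA}, {10,CCC}, {50,AAA}
  # differing length is a distinct key
  r2 <- fake_records("pre_rRNA", c(10, 10), aligned_length = c(30, 31),
                     umi = c("AAA", "AAA"))
  expect_equal(nrow(deduplicate(r2)), 2)
})

test_that("deduplication matches a distinct-key set oracle and is stable", {
  set.seed(8)
  n <- 200
  r <- fake_records("pre_rRNA",
                    start = sample(1:50, n, replace = TRUE),
                    aligned_length = sample(c(30L, 35L), n, replace = TRUE),
                    umi = sample(c("AA", "CC", "GG"), n, replace = TRUE))
  r$aligned_length <- sample(c(30L, 35L), n, replace = TRUE)
  r$cigar <- paste0(r$aligned_length, "M")
  out <- deduplicate(r)
  key <- paste(r$ref, r$start, r$strand, r$umi, r$aligned_length)
  expect_equal(nrow(out), length(unique(key)))
  # idempotent and order-independent
  expect_equal(nrow(deduplicate(out)), nrow(out))
  shuf <- r[sample(nrow(r)), ]
  expect_identical(dplyr::arrange(as.data.frame(deduplicate(shuf)), read_id),
                   dplyr::arrange(as.data.frame(out), read_id))
})

test_that("stop profiles count starts and overlaps with conservation", {
  r <- fake_records("pre_rRNA", c(10, 10, 11, 30, 30), aligned_length = 5)
  p <- stop_profile(r, refs)
  s <- function(pos) p$stops[p$ref == "pre_rRNA" & p$pos == pos]
  expect_equal(s(10), 2); expect_equal(s(11), 1); expect_equal(s(30), 2)
  expect_equal(sum(p$stops), library_size(p))
  cv <- function(pos) p$coverage[p$ref == "pre_rRNA" & p$pos == pos]
  expect_equal(cv(12), 3)  # covered by both reads at 10 and the one at 11
  expect_equal(cv(14), 3); expect_equal(cv(15), 1)
  expect_true(all(p$coverage >= p$stops))
  # empty record set
  p0 <- stop_profile(fake_records("pre_rRNA", integer(0)), refs)
  expect_equal(library_size(p0), 0)
  expect_true(all(p0$stops == 0) && all(p0$coverage == 0))
  # out-of-bounds records are corrupt input
  bad <- fake_records("pre_rRNA", nchar(refs$sequences[["pre_rRNA"]]),
                      aligned_length = 10)
  expect_error(stop_profile(bad, refs), "bounds")
})

test_that("RPM normalization is per-million and scale invariant", {
  r <- fake_records("pre_rRNA", rep(10, 5), umi = sprintf("U%d", 1:5))
  p <- stop_profile(r, refs)
  rpm <- normalize_rpm(p)
  expect_equal(rpm$stop_rpm[rpm$pos == 10 & rpm$ref == "pre_rRNA"],
               5 * 1e6 / 5)
  # arithmetic oracle: 2 stops at library size 200,000 -> 10 RPM
  p2 <- p
  attr(p2, "library_size") <- 200000L
  p2$stops[p2$ref == "pre_rRNA" & p2$pos == 10] <- 2L
  expect_equal(normalize_rpm(p2)$stop_rpm[p2$ref == "pre_rRNA" &
                                            p2$pos == 10], 10)
  # doubling all counts and the library size leaves the track unchanged
  p3 <- p
  p3$stops <- p3$stops * 2L
  p3$coverage <- p3$coverage * 2L
  attr(p3, "library_size") <- 2L * library_size(p)
  expect_equal(normalize_rpm(p3)$stop_rpm, rpm$stop_rpm)
  p0 <- stop_profile(fake_records("pre_rRNA", integer(0)), refs)
  expect_error(normalize_rpm(p0), "library_size")
})

test_that("enrichment track is 1 for identical profiles and follows arithmetic", {
  r <- fake_records("pre_rRNA", sample(1:100, 50, replace = TRUE))
  p <- stop_profile(r, refs)
  tr <- enrichment_track(p, p)
  expect_true(all(tr$ratio == 1))
  # c_ip = 199, c_smi = 99, equal library sizes -> ratio 2
  ip <- p; smi <- p
  ip$coverage[1] <- 199L; smi$coverage[1] <- 99L
  attr(ip, "library_size") <- 1000000L
  attr(smi, "library_size") <- 1000000L
  expect_equal(enrichment_track(ip, smi)$ratio[[1]], 2)
})

test_that("call_sites passes the plug-in arithmetic example", {
  p0 <- stop_profile(fake_records("pre_rRNA", integer(0)), refs)
  expect_equal(nrow(call_sites(p0, p0)), 0)
  mut <- p0; wt <- p0
  mut$stops[mut$pos == 500 & mut$ref == "pre_rRNA"] <- 50L
  mut$coverage[mut$pos == 500 & mut$ref == "pre_rRNA"] <- 100L
  attr(mut, "library_size") <- 100000L
  attr(wt, "library_size") <- 100000L
  sc <- call_sites(mut, wt, refs = refs)
  expect_equal(nrow(sc), 1)
  expect_equal(sc$stop_fraction, 0.5)
  expect_equal(sc$ratio, 50.5 / 0.5)
  expect_true(sc$passed)
  expect_identical(sc$label, local_coord(refs, "pre_rRNA", 500))
})

test_that("windowed Fisher enrichment matches the hypergeometric oracle", {
  # identical proportions: nothing significant
  set.seed(3)
  starts <- sample(1:2000, 2000, replace = TRUE)
  ip <- stop_profile(fake_records("pre_rRNA", starts,
                                  umi = sprintf("A%04d", 1:2000)), refs)
  smi <- stop_profile(fake_records("pre_rRNA", starts,
                                   umi = sprintf("B%04d", 1:2000)), refs)
  we <- window_enrichment(ip, smi)
  expect_false(any(we$significant))
  # direct 2x2 agreement with enumeration
  expect_equal(fisher.test(matrix(c(30, 970, 5, 995), 2))$p.value,
               fisher_oracle(30, 970, 5, 995), tolerance = 1e-12)
  for (tab in list(c(12, 88, 3, 97), c(2, 498, 9, 491), c(0, 50, 5, 45))) {
    expect_equal(
      fisher.test(matrix(tab, 2))$p.value,
      fisher_oracle(tab[1], tab[2], tab[3], tab[4]), tolerance = 1e-10)
  }
  expect_error(window_enrichment(ip, smi, window = 10, step = 25), "window")
})

test_that("BH adjustment is monotone and bounded on window p-values", {
  set.seed(5)
  ip <- stop_profile(fake_records("pre_rRNA",
                                  sample(1:5000, 3000, replace = TRUE),
                                  umi = sprintf("A%04d", 1:3000)), refs)
  smi <- stop_profile(fake_records("pre_rRNA",
                                   sample(1:5000, 3000, replace = TRUE),
                                   umi = sprintf("B%04d", 1:3000)), refs)
  we <- window_enrichment(ip, smi)
  expect_true(all(we$adjusted_p >= 0 & we$adjusted_p <= 1))
  o <- order(we$p_value)
  expect_true(all(diff(we$adjusted_p[o]) >= -1e-12))
  expect_equal(we$adjusted_p, p.adjust(we$p_value, "BH"))
})

test_that("no binding signal yields few significant windows under the null", {
  set.seed(6)
  frac <- replicate(10, {
    ip <- stop_profile(fake_records("pre_rRNA",
                                    sample(1:5000, 4000, replace = TRUE),
                                    umi = sprintf("A%04d", 1:4000)), refs)
    smi <- stop_profile(fake_records("pre_rRNA",
                                     sample(1:5000, 4000, replace = TRUE),
                                     umi = sprintf("B%04d", 1:4000)), refs)
    we <- window_enrichment(ip, smi)
    mean(we$significant)
  })
  expect_lte(mean(frac), 0.05)
})

test_that("class summary assigns intervals and sums to one", {
  r <- dplyr::bind_rows(
    fake_records("pre_rRNA", c(100, 2000, 4000), umi = c("A", "B", "C")),
    fake_records("SNORD_1", 5, umi = "D"),
    fake_records("vtRNA1.2", 10, umi = "E", aligned_length = 20))
  cs <- class_summary(r, refs)
  expect_equal(sum(cs$fraction), 1)
  expect_equal(cs$fraction[cs$class == "rRNA"], 0.6)
  expect_equal(cs$fraction[cs$class == "snoRNA_CD"], 0.2)
  expect_equal(cs$fraction[cs$class == "vtRNA"], 0.2)
})
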