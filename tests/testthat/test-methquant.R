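refs <- small_refs()
amp <- default_amplicon(refs)

# records that tile the amplicon exactly, with chosen bases at one C
amp_records <- function(n, at, base) {
  ins <- substr(refs$sequences[[amp$ref]], amp$start, amp$end)
  seqs <- rep(ins, n)
  off <- at - amp$start + 1
  substr(seqs, off, off) <- base
  tibble::tibble(read_id = sprintf("b%03d", seq_len(n)), umi = "",
                 ref = amp$ref, start = amp$start, strand = "+",
                 aligned_length = nchar(ins), score = 2L * nchar(ins),
                 cigar = paste0(nchar(ins), "M"), query_start = 1L,
                 query_end = nchar(ins), sequence = seqs)
}

site <- absolute_coord(refs, "28S", 4447)

test_that("conversion tallies count C/T/other per reference cytosine", {
  r <- amp_records(10, site$pos, "T")
  tab <- conversion_table(r, refs, amp)
  row <- tab[tab$pos == site$pos, ]
  expect_equal(row$n_converted, 10)
  expect_equal(row$converted_fraction, 1)
  mixed <- dplyr::bind_rows(amp_records(7, site$pos, "T"),
                            amp_records(3, site$pos, "C"))
  row2 <- conversion_table(mixed, refs, amp)[
    conversion_table(mixed, refs, amp)$pos == site$pos, ]
  expect_equal(row2$converted_fraction, 0.7)
  # sequencing errors land in n_other and leave the fraction denominator
  err <- dplyr::bind_rows(amp_records(12, site$pos, "T"),
                          amp_records(3, site$pos, "G"))
  tab3 <- conversion_table(err, refs, amp)
  row3 <- tab3[tab3$pos == site$pos, ]
  expect_equal(row3$n_other, 3)
  expect_equal(row3$coverage, 15)
  expect_equal(row3$converted_fraction, 1)
  # column conservation at every row
  expect_equal(tab3$n_converted + tab3$n_nonconverted + tab3$n_other,
               tab3$coverage)
  expect_error(conversion_table(r, refs,
                                list(ref = "nope", start = 1, end = 5)),
               "unknown")
})

test_that("gapped and clipped alignments tally through the cigar walk", {
  ins <- substr(refs$sequences[[amp$ref]], amp$start, amp$end)
  L <- nchar(ins)
  # a read with a 2-nt deletion upstream of the site column
  delpos <- 5L
  gap_seq <- paste0(substr(ins, 1, delpos), substr(ins, delpos + 3, L))
  rec <- tibble::tibble(
    read_id = "gap1", umi = "", ref = amp$ref, start = amp$start,
    strand = "+", aligned_length = L, score = 0L,
    cigar = paste0(delpos, "M2D", L - delpos - 2, "M"),
    query_start = 1L, query_end = nchar(gap_seq), sequence = gap_seq)
  tab <- conversion_table(rec, refs, amp, min_coverage = 1)
  row <- tab[tab$pos == site$pos, ]
  # the site base is read through the shifted query coordinates
  expect_equal(row$coverage, 1)
  expect_equal(row$n_nonconverted, 1)  # untouched reference base is C
})

test_that("overall conversion rate pools counts and honors exclusions", {
  tab <- tibble::tibble(ref = "x", pos = c(1, 2),
                        n_nonconverted = c(10, 20),
                        n_converted = c(90, 80), n_other = 0,
                        coverage = 100,
                        converted_fraction = c(0.9, 0.8))
  expect_equal(overall_conversion_rate(tab), 170 / 200)
  expect_equal(overall_conversion_rate(
    tab, exclude = tibble::tibble(ref = "x", pos = 2)), 0.9)
  expect_error(overall_conversion_rate(
    tab, exclude = tibble::tibble(ref = "x", pos = c(1, 2))), "no rows")
  full <- dplyr::mutate(tab, n_nonconverted = 0, n_converted = 100)
  expect_equal(overall_conversion_rate(full), 1)
})

test_that("the t-test matches the closed-form oracle to 1e-10", {
  a <- c(0.16, 0.15, 0.17)
  b <- c(0.28, 0.27, 0.29)
  cmp <- compare_conditions("28S:4447", a, b, labels = c("siC", "kd"))
  o <- t_oracle(a, b)
  expect_equal(cmp$t_statistic, o$t, tolerance = 1e-10)
  expect_equal(cmp$p_value, o$p, tolerance = 1e-10)
  expect_equal(cmp$df, 4)
  expect_equal(cmp$sd_a, stats::sd(a))
  # identical groups: t = 0, p = 1
  same <- compare_conditions("s", a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  # symmetry: swapped arguments negate t, keep p
  sw <- compare_conditions("s", b, a)
  expect_equal(sw$t_statistic, -cmp$t_statistic)
  expect_equal(sw$p_value, cmp$p_value)
  expect_error(compare_conditions("s", 0.5, b), "2 replicates")
  # randomized agreement including unequal group sizes
  set.seed(10)
  for (i in 1:25) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1), 0.3)
    cc <- compare_conditions("s", x, y)
    oo <- t_oracle(x, y)
    expect_equal(cc$t_statistic, oo$t, tolerance = 1e-10)
    expect_equal(cc$p_value, oo$p, tolerance = 1e-10)
  }
})

test_that("the t-test p-value is uniform under the null", {
  set.seed(11)
  ps <- replicate(1000, {
    x <- rnorm(3, 0.2, 0.01); y <- rnorm(3, 0.2, 0.01)
    compare_conditions("s", x, y)$p_value
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})
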