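# bisulfite conversion quantification

# cigar walk: per reference position of one record, the 1-based query index
# (NA across deletions)
ref_to_query_map <- function(cigar, start, query_start) {
  x <- cigar_ops(cigar)
  rp <- start; qp <- query_start
  out_pos <- integer(0); out_q <- integer(0)
  for (i in seq_along(x$op)) {
    l <- x$len[[i]]
    if (x$op[[i]] %in% c("M", "=", "X")) {
      out_pos <- c(out_pos, rp:(rp + l - 1))
      out_q <- c(out_q, qp:(qp + l - 1))
      rp <- rp + l; qp <- qp + l
    } else if (x$op[[i]] == "D") {
      out_pos <- c(out_pos, rp:(rp + l - 1))
      out_q <- c(out_q, rep(NA_integer_, l))
      rp <- rp + l
    } else if (x$op[[i]] == "I") {
      qp <- qp + l
    }
  }
  tibble::tibble(pos = out_pos, q = out_q)
}

#' Per-cytosine conversion table from bisulfite-mode alignments
#'
#' At every reference cytosine in the region, tallies the original
#' (unconverted) read base across aligned match columns: `C` reports a
#' non-converted (m5C-protected) cytosine, `T` a converted one, anything
#' else a sequencing error (`n_other`); deletion columns are skipped. The
#' converted fraction is `n_converted / (n_converted + n_nonconverted)`,
#' reported only where that denominator reaches `min_coverage`.
#'
#' @param records Bisulfite-mode alignment tibble (original sequences).
#' @param refs A [ref_set()].
#' @param region List with `ref`, `start`, `end` (1-based inclusive).
#' @param min_coverage Minimum informative depth to report a fraction.
#' @return Tibble with one row per reference C in the region: `ref`, `pos`,
#'   `label`, `n_nonconverted`, `n_converted`, `n_other`, `coverage`,
#'   `converted_fraction`.
#' @export
conversion_table <- function(records, refs, region, min_coverage = 10) {
  assert_that(region$ref %in% names(refs$sequences),
              "region on unknown reference")
  L <- nchar(refs$sequences[[region$ref]])
  assert_that(region$start >= 1 && region$end <= L &&
                region$start <= region$end,
              "region outside reference bounds")
  span <- substr(refs$sequences[[region$ref]], region$start, region$end)
  cpos <- region$start + which(strsplit(span, "")[[1]] == "C") - 1L

  n_C <- n_T <- n_other <- integer(length(cpos))
  recs <- records[records$ref == region$ref, , drop = FALSE]
  simple <- grepl("^[0-9]+M$", recs$cigar)
  rs <- recs[simple, , drop = FALSE]
  rg <- recs[!simple, , drop = FALSE]

  if (nrow(rs) > 0) {
    rend <- rs$start + rs$aligned_length - 1L
    for (j in seq_along(cpos)) {
      p <- cpos[[j]]
      sel <- rs$start <= p & rend >= p
      if (!any(sel)) next
      at <- rs$query_start[sel] + (p - rs$start[sel])
      base <- substr(rs$sequence[sel], at, at)
      n_C[[j]] <- n_C[[j]] + sum(base == "C")
      n_T[[j]] <- n_T[[j]] + sum(base == "T")
      n_other[[j]] <- n_other[[j]] + sum(base != "C" & base != "T")
    }
  }
  if (nrow(rg) > 0) {
    for (i in seq_len(nrow(rg))) {
      mp <- ref_to_query_map(rg$cigar[[i]], rg$start[[i]],
                             rg$query_start[[i]])
      mp <- mp[mp$pos %in% cpos & !is.na(mp$q), , drop = FALSE]
      if (nrow(mp) == 0) next
      base <- substr(rep(rg$sequence[[i]], nrow(mp)), mp$q, mp$q)
      j <- match(mp$pos, cpos)
      for (k in seq_along(j)) {
        if (base[[k]] == "C") n_C[[j[[k]]]] <- n_C[[j[[k]]]] + 1L
        else if (base[[k]] == "T") n_T[[j[[k]]]] <- n_T[[j[[k]]]] + 1L
        else n_other[[j[[k]]]] <- n_other[[j[[k]]]] + 1L
      }
    }
  }

  inf <- n_C + n_T
  tibble::tibble(
    ref = region$ref, pos = cpos,
    label = local_coord(refs, region$ref, cpos),
    n_nonconverted = n_C, n_converted = n_T, n_other = n_other,
    coverage = n_C + n_T + n_other,
    converted_fraction = ifelse(inf >= min_coverage, n_T / pmax(inf, 1L),
                                NA_real_))
}

#' Overall bisulfite conversion rate
#'
#' Pooled converted fraction `sum(n_converted) / sum(n_converted +
#' n_nonconverted)` over all rows of a conversion table except the excluded
#' sites — typically the methylated target site, so the rate measures
#' chemistry efficiency on unprotected cytosines.
#'
#' @param table A [conversion_table()].
#' @param exclude Optional tibble with `ref` and `pos` columns of sites to
#'   leave out.
#' @return The pooled conversion rate in `[0, 1]`.
#' @export
overall_conversion_rate <- function(table, exclude = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(exclude) && nrow(exclude) > 0)
    keep <- !(paste(table$ref, table$pos) %in%
                paste(exclude$ref, exclude$pos))
  tab <- table[keep, , drop = FALSE]
  assert_that(nrow(tab) > 0, "no rows left after exclusion")
  denom <- sum(tab$n_converted + tab$n_nonconverted)
  assert_that(denom > 0, "no informative bases in table")
  sum(tab$n_converted) / denom
}

#' Compare per-replicate conversion fractions between two conditions
#'
#' Two-sample Student's t-test (pooled variance; two-tailed) on the
#' replicate-level converted fractions of one site, the replicate being an
#' independent biological library. Welch's correction is available but off
#' by default.
#'
#' @param site Site label (e.g. `"28S:4447"`).
#' @param fractions_a,fractions_b Numeric vectors of per-replicate converted
#'   fractions (at least 2 each).
#' @param labels Length-2 character vector naming the conditions.
#' @param welch If `TRUE`, use Welch's unequal-variance t-test.
#' @return One-row tibble: `site`, `condition_a`, `condition_b`, `n_a`,
#'   `n_b`, `mean_a`, `mean_b`, `sd_a`, `sd_b` (sample SD), `t_statistic`,
#'   `df`, `p_value`.
#' @examples
#' compare_conditions("28S:4447", c(0.16, 0.15, 0.17), c(0.28, 0.27, 0.29))
#' @export
compare_conditions <- function(site, fractions_a, fractions_b,
                               labels = c("a", "b"), welch = FALSE) {
  assert_that(length(fractions_a) >= 2 && length(fractions_b) >= 2,
              "need at least 2 replicates per condition")
  tt <- t.test(fractions_a, fractions_b, var.equal = !welch)
  tibble::tibble(
    site = site, condition_a = labels[[1]], condition_b = labels[[2]],
    n_a = length(fractions_a), n_b = length(fractions_b),
    mean_a = mean(fractions_a), mean_b = mean(fractions_b),
    sd_a = stats::sd(fractions_a), sd_b = stats::sd(fractions_b),
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value)
}
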