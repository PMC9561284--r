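# broom-style methods for run objects

#' Tidy a miCLIP run into one row per evaluated site
#'
#' @param x A `miclip_run` from [run_miclip()].
#' @param ... Unused.
#' @return The site-call tibble (all evaluated positions with `passed`
#'   flags, per replicate).
#' @export
tidy.miclip_run <- function(x, ...) x$site_calls

#' One-row summary of a miCLIP run
#'
#' @param x A `miclip_run`.
#' @param ... Unused.
#' @return Tibble with replicate count, number of passed site calls,
#'   distinct passed site labels and significant-window count.
#' @export
glance.miclip_run <- function(x, ...) {
  passed <- x$site_calls[x$site_calls$passed, ]
  tibble::tibble(
    n_replicates = length(unique(x$site_calls$replicate)),
    n_passed_calls = nrow(passed),
    n_passed_sites = length(unique(passed$label)),
    n_significant_windows = sum(x$windows$significant),
    total_mapped = sum(x$library_sizes$n))
}

#' Tidy a bisulfite run into one row per condition comparison
#'
#' @param x A `bisulfite_run` from [run_bisulfite()].
#' @param ... Unused.
#' @return The comparison tibble (t-tests of each condition vs control).
#' @export
tidy.bisulfite_run <- function(x, ...) x$comparisons

#' One-row summary of a bisulfite run
#'
#' @param x A `bisulfite_run`.
#' @param ... Unused.
#' @return Tibble with the pooled overall conversion rate and the number of
#'   conditions, replicates and tested sites.
#' @export
glance.bisulfite_run <- function(x, ...) {
  tibble::tibble(
    overall_conversion_rate = mean(x$overall_rates$overall_rate),
    n_conditions = length(unique(x$tables$condition)),
    n_replicates = max(x$tables$replicate),
    n_sites_tested = nrow(unique(x$site_fractions[, c("ref", "pos")])))
}
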