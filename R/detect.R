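# Pooled ctDNA detection.
#
# Individual tracked positions are far too shallow to call ctDNA at
# fractions below 1%, so all of a patient's tracked sites are pooled
# and the pooled mutant fraction is tested against the background pool
# with a one-sided Fisher exact test (alternative: sample fraction
# greater than background).

#' Pool a sample's allele counts over its tracked sites
#'
#' @param site_counts per-site count data.frame from [count_alleles()].
#' @return named numeric vector `c(alt = ..., ref = ...)`.
#' @export
pool_counts <- function(site_counts) {
  if (nrow(site_counts) == 0L) stop("no tracked sites to pool")
  c(alt = sum(site_counts$n_alt), ref = sum(site_counts$n_ref))
}

#' One-sided Fisher exact test for an elevated mutant fraction
#'
#' Exact hypergeometric upper-tail probability of observing at least
#' `sample_alt` mutant reads given the margins of the 2x2 table
#' (sample vs background, mutant vs reference); identical to
#' `fisher.test(alternative = "greater")` and vectorized over tables.
#' A sample with zero mutant reads always gives p = 1.
#'
#' @param sample_alt,sample_ref mutant and reference read counts in the
#'   sample pool.
#' @param bg_alt,bg_ref mutant and reference read counts in the
#'   background pool.
#' @return p-value(s) in (0, 1].
#' @export
fisher_one_sided <- function(sample_alt, sample_ref, bg_alt, bg_ref) {
  if (any(c(sample_alt, sample_ref, bg_alt, bg_ref) < 0)) {
    stop("counts must be non-negative")
  }
  stats::phyper(sample_alt - 1, sample_alt + bg_alt,
                sample_ref + bg_ref, sample_alt + sample_ref,
                lower.tail = FALSE)
}

#' Detect ctDNA in a sample against a background pool
#'
#' Pools the sample's counts over its tracked sites, estimates the ctDNA
#' fraction as mutant/(mutant+reference), and tests it against the
#' background with [fisher_one_sided()]. The background must exclude the
#' sample itself and any sample whose tumor carries identical mutations.
#'
#' @param site_counts the sample's per-site counts ([count_alleles()]).
#' @param background list with `bg_alt` and `bg_ref`
#'   ([background_pool()]), or a numeric vector of the two counts.
#' @param sample_id label for the output row.
#' @param alpha significance level for the `detected` flag.
#' @return one-row data.frame: `sample_id`, `n_sites`, `sample_alt`,
#'   `sample_ref`, `bg_alt`, `bg_ref`, `ctdna_fraction`, `p_value`,
#'   `detected`.
#' @export
detect_ctdna <- function(site_counts, background, sample_id = NA,
                         alpha = 0.05) {
  if (is.numeric(background)) {
    background <- list(bg_alt = background[[1L]], bg_ref = background[[2L]])
  }
  if (background$bg_alt + background$bg_ref <= 0) {
    stop("background pool is empty")
  }
  pooled <- pool_counts(site_counts)
  tot <- pooled[["alt"]] + pooled[["ref"]]
  frac <- if (tot > 0) pooled[["alt"]] / tot else 0
  p <- fisher_one_sided(pooled[["alt"]], pooled[["ref"]],
                        background$bg_alt, background$bg_ref)
  data.frame(sample_id = sample_id, n_sites = nrow(site_counts),
             sample_alt = pooled[["alt"]], sample_ref = pooled[["ref"]],
             bg_alt = background$bg_alt, bg_ref = background$bg_ref,
             ctdna_fraction = frac, p_value = p, detected = p < alpha,
             stringsAsFactors = FALSE)
}
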