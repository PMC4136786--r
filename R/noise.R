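# Background noise-rate estimation and base-quality cutoff optimization.
#
# At every tracked variant position the pileup bases are classified as
# alternate, reference, other, or N. The noise rate of a background pool
# is mut/(mut+ref) at the tracked positions; sweeping the per-base
# quality cutoff trades data volume against noise, and the optimal
# cutoff minimizes the noise rate. Boosted qualities from merging and
# consensus calling enter only through this filter, never as calling
# evidence weights.

#' Extract per-base pileup observations at tracked sites
#'
#' One row per (site, covering fragment): the observed base, its
#' quality, and its class relative to the site's ref/alt alleles.
#' Computed once so that repeated cutoff sweeps are cheap.
#'
#' @param fragments aligned-fragments data.frame (any pipeline stage).
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return data.frame: `site` (row index into `sites`), `base`, `qual`,
#'   `class` in {"alt","ref","other","N"}.
#' @export
pileup_bases <- function(fragments, sites) {
  empty <- data.frame(site = integer(0), base = character(0),
                      qual = integer(0), class = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0L || nrow(fragments) == 0L) return(empty)
  fr <- GenomicRanges::GRanges(fragments$chrom,
                               IRanges::IRanges(fragments$start,
                                                fragments$end))
  si <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(si, fr)
  if (length(hits) == 0L) return(empty)
  s <- S4Vectors::queryHits(hits)
  f <- S4Vectors::subjectHits(hits)
  off <- sites$pos[s] - fragments$start[f] + 1L
  base <- substring(fragments$seq[f], off, off)
  qual <- as.integer(charToRaw(paste(substring(fragments$qual[f], off, off),
                                     collapse = ""))) - 33L
  class <- ifelse(base == "N", "N",
           ifelse(base == sites$alt[s], "alt",
           ifelse(base == sites$ref[s], "ref", "other")))
  data.frame(site = s, base = base, qual = qual, class = class,
             stringsAsFactors = FALSE)
}

#' Count alleles at tracked sites above a quality cutoff
#'
#' Bases with quality at or above `cutoff` are tallied as alternate,
#' reference or other; N bases are reported in `n_masked` and excluded
#' from rates. With `cutoff = 0` this is the unfiltered pileup.
#'
#' @param fragments aligned-fragments data.frame.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param cutoff minimum per-base quality (phred).
#' @param sample_id optional label carried into the output.
#' @return data.frame: one row per site with `sample_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `cutoff`, `n_alt`, `n_ref`, `n_other`,
#'   `n_masked`.
#' @export
count_alleles <- function(fragments, sites, cutoff = 0L, sample_id = NA) {
  pb <- pileup_bases(fragments, sites)
  tally_pileup(pb, sites, cutoff = cutoff, sample_id = sample_id)
}

#' Tally a precomputed pileup at a quality cutoff
#'
#' @param pb output of [pileup_bases()].
#' @param sites the site table the pileup was computed against.
#' @param cutoff minimum per-base quality.
#' @param sample_id optional label.
#' @return per-site count data.frame as in [count_alleles()].
#' @export
tally_pileup <- function(pb, sites, cutoff = 0L, sample_id = NA) {
  n <- nrow(sites)
  count_class <- function(cl) {
    keep <- pb$class == cl & pb$qual >= cutoff
    tabulate(pb$site[keep], nbins = n)
  }
  out <- data.frame(sample_id = sample_id,
                    chrom = sites$chrom, pos = sites$pos,
                    ref = sites$ref, alt = sites$alt,
                    cutoff = as.integer(cutoff),
                    n_alt = count_class("alt"),
                    n_ref = count_class("ref"),
                    n_other = count_class("other"),
                    n_masked = count_class("N"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pool background allele counts, leaving named samples out
#'
#' Sums alternate and reference counts over all samples except those
#' excluded — a sample's own counts, and any sample whose tumor carries
#' the identical mutation, must never enter its background.
#'
#' @param counts data.frame of per-site counts from [count_alleles()],
#'   stacked over samples (distinct `sample_id`s).
#' @param exclude_samples character vector of `sample_id`s to leave out.
#' @return list with `bg_alt`, `bg_ref` (pooled totals) and `per_site`
#'   (data.frame of per-position pooled counts).
#' @export
background_pool <- function(counts, exclude_samples = character(0)) {
  keep <- !(counts$sample_id %in% exclude_samples)
  k <- counts[keep, , drop = FALSE]
  if (nrow(k) == 0L) stop("background pool is empty after exclusions")
  per_site <- stats::aggregate(cbind(bg_alt = n_alt, bg_ref = n_ref) ~
                                 chrom + pos, data = k, FUN = sum)
  list(bg_alt = sum(k$n_alt), bg_ref = sum(k$n_ref), per_site = per_site)
}

#' Noise rate of a background pool
#'
#' mut / (mut + ref) over the pooled counts. A zero denominator has no
#' defined rate and is returned as `NA`.
#'
#' @param bg_alt,bg_ref pooled mutant and reference read counts, or a
#'   list with those fields in `bg_alt`.
#' @return the rate, or `NA_real_` when undefined.
#' @export
noise_rate <- function(bg_alt, bg_ref = NULL) {
  if (is.list(bg_alt)) {
    bg_ref <- bg_alt$bg_ref
    bg_alt <- bg_alt$bg_alt
  }
  den <- bg_alt + bg_ref
  if (den == 0) return(NA_real_)
  bg_alt / den
}

#' Sweep the base-quality cutoff over a background pileup
#'
#' For each cutoff: the noise rate, the fraction of reference reads
#' retained relative to the unfiltered pileup, and the log2 ratio of the
#' retained mutant proportion to the retained reference proportion
#' (negative when the filter removes mutant reads preferentially).
#'
#' @param fragments background aligned-fragments (pooled over samples),
#'   or a precomputed [pileup_bases()] data.frame.
#' @param sites tracked sites data.frame.
#' @param q_grid ascending integer cutoffs (default 0:50).
#' @return data.frame of class `cutoff_table`: `cutoff`, `n_alt`,
#'   `n_ref`, `noise_rate`, `fraction_data_left`, `log2_ratio`.
#' @export
sweep_cutoffs <- function(fragments, sites, q_grid = 0:50) {
  stopifnot(!is.unsorted(q_grid, strictly = TRUE))
  pb <- if (is.data.frame(fragments) && "class" %in% names(fragments) &&
            "site" %in% names(fragments)) fragments
        else pileup_bases(fragments, sites)
  alt0 <- sum(pb$class == "alt")
  ref0 <- sum(pb$class == "ref")
  rows <- lapply(q_grid, function(q) {
    alt <- sum(pb$class == "alt" & pb$qual >= q)
    ref <- sum(pb$class == "ref" & pb$qual >= q)
    data.frame(cutoff = q, n_alt = alt, n_ref = ref,
               noise_rate = if (alt + ref > 0) alt / (alt + ref) else NA_real_,
               fraction_data_left = if (ref0 > 0) ref / ref0 else NA_real_,
               log2_ratio = if (alt0 > 0 && ref0 > 0 && ref > 0 && alt > 0)
                 log2((alt / alt0) / (ref / ref0)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_table", "data.frame")
  out
}

#' Pick the optimal quality cutoff from a sweep table
#'
#' The optimum minimizes the noise rate; ties are broken toward the
#' larger fraction of data retained, then toward the smaller cutoff.
#'
#' @param table a `cutoff_table` from [sweep_cutoffs()].
#' @return the selected cutoff (integer).
#' @export
optimal_cutoff <- function(table) {
  ok <- !is.na(table$noise_rate)
  if (!any(ok)) stop("noise rate undefined at every cutoff")
  t <- table[ok, , drop = FALSE]
  o <- order(t$noise_rate, -t$fraction_data_left, t$cutoff)
  t$cutoff[o[1L]]
}
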