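# Genomic eligibility mask for ctDNA counting.
#
# Positions are only informative when the genome maps uniquely, the
# position is not a known germline variant and not inside a simple
# repeat. Low-mappability regions are additionally expanded by a flank
# (50 bp by default) so that sites merely near a poorly mapping region
# are also excluded. Interval arithmetic is done on the
# GenomicRanges/IRanges stack; BED tracks are read with rtracklayer.

#' Build the genomic eligibility mask
#'
#' The eligible territory is the complement, over the declared genome,
#' of the union of (i) low-mappability regions expanded by `flank` on
#' both sides, (ii) simple-repeat regions and (iii) germline variant
#' positions (population SNPs and cohort de-novo calls may be supplied
#' together or as separate `GRanges` concatenated by the caller).
#'
#' @param mappability_low `GRanges` of regions with mappability below 1,
#'   or `NULL`.
#' @param germline_sites `GRanges` of germline variant positions, or `NULL`.
#' @param repeat_track `GRanges` of simple-repeat regions, or `NULL`.
#' @param flank expansion of low-mappability regions, bp (default 50):
#'   a site within `flank` bases of such a region is excluded.
#' @param seqinfo a `Seqinfo` (or named vector of sequence lengths)
#'   declaring the genome over which the complement is taken.
#' @return an object of class `genomic_mask`: list with `eligible`
#'   (`GRanges`) and `sources` (named list of the exclusion `GRanges`
#'   as applied, i.e. low-mappability already flanked).
#' @export
build_mask <- function(mappability_low = NULL, germline_sites = NULL,
                       repeat_track = NULL, flank = 50L, seqinfo) {
  stopifnot(flank >= 0L)
  if (!methods::is(seqinfo, "Seqinfo")) {
    seqinfo <- GenomeInfoDb::Seqinfo(seqnames = names(seqinfo),
                                      seqlengths = as.integer(seqinfo))
  }
  check <- function(gr, what) {
    if (is.null(gr)) return(GenomicRanges::GRanges(seqinfo = seqinfo))
    if (any(BiocGenerics::width(gr) < 1L)) {
      stop(sprintf("malformed interval in %s track", what))
    }
    GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                           IRanges::ranges(gr), seqinfo = seqinfo)
  }
  lowmap <- check(mappability_low, "mappability")
  germ <- check(germline_sites, "germline")
  reps <- check(repeat_track, "repeat")
  lowmap_flanked <- GenomicRanges::trim(suppressWarnings(lowmap + flank))
  excl <- GenomicRanges::reduce(c(lowmap_flanked, germ, reps))
  genome <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(seqinfo),
    IRanges::IRanges(1L, GenomeInfoDb::seqlengths(seqinfo)),
    seqinfo = seqinfo)
  eligible <- GenomicRanges::setdiff(genome, excl)
  structure(list(eligible = eligible,
                 sources = list(mappability = lowmap_flanked,
                                germline = germ,
                                simple_repeat = reps)),
            class = "genomic_mask")
}

#' @export
print.genomic_mask <- function(x, ...) {
  tot <- sum(as.numeric(GenomeInfoDb::seqlengths(x$eligible)))
  elig <- sum(as.numeric(BiocGenerics::width(x$eligible)))
  cat(sprintf("genomic eligibility mask: %.0f / %.0f bp eligible (%.1f%%)\n",
              elig, tot, 100 * elig / tot))
  for (s in names(x$sources)) {
    cat(sprintf("  %s: %d intervals, %.0f bp\n", s,
                length(x$sources[[s]]),
                sum(as.numeric(BiocGenerics::width(x$sources[[s]])))))
  }
  invisible(x)
}

#' Filter variant sites against an eligibility mask
#'
#' @param sites data.frame with at least `chrom` and `pos` (1-based);
#'   a `patient` column, when present, is used for the per-patient
#'   removal report.
#' @param mask a `genomic_mask` from [build_mask()].
#' @return list with `retained` (subset of `sites`), `removed` (the
#'   complement) and `report` (data.frame with one row per exclusion
#'   source plus totals: source, n_sites removed; sites hitting several
#'   sources count once per source).
#' @export
filter_sites <- function(sites, mask) {
  stopifnot(inherits(mask, "genomic_mask"))
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1L))
  keep <- IRanges::overlapsAny(gr, mask$eligible)
  per_source <- vapply(mask$sources, function(src)
    sum(IRanges::overlapsAny(gr, src)), 0L)
  report <- data.frame(source = c(names(per_source), "total_removed",
                                  "total_retained"),
                       n_sites = c(per_source, sum(!keep), sum(keep)),
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(retained = sites[keep, , drop = FALSE],
       removed = sites[!keep, , drop = FALSE],
       report = report)
}

#' Read a BED track as GRanges
#'
#' Thin wrapper over [rtracklayer::import()] (BED is 0-based half-open
#' on disk; the returned `GRanges` is 1-based as usual in R).
#'
#' @param path BED file path.
#' @return `GRanges`.
#' @export
read_bed_track <- function(path) {
  rtracklayer::import(path, format = "BED")
}
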