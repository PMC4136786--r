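# PCR-duplicate identification and consensus for merged single-end reads.
#
# Standard single-end duplicate marking keys reads on the mapped start
# only, which collapses distinct molecules that happen to share a start.
# After overlap merging, every read's template length is known, so
# duplicate families are keyed on (chrom, strand, 5' start, template
# length): molecules of different lengths at the same start stay
# separate, and each family is collapsed into one consensus read whose
# per-column agreement both removes read-level sequencer errors and
# boosts the quality of multiply observed bases.

#' Duplicate key of aligned fragments
#'
#' Merged single-end reads are keyed by chromosome, strand, 5' start
#' (leftmost coordinate on `+`, rightmost on `-`) and template length.
#' Unmerged mates are keyed by both outer coordinates and orientation,
#' as in standard paired-end duplicate marking.
#'
#' @param fragments aligned-fragments data.frame ([place_reads()]).
#' @return character vector of keys, one per fragment.
#' @export
duplicate_key <- function(fragments) {
  if (nrow(fragments) > 0L && anyNA(fragments$start)) {
    stop("unaligned fragment: missing start coordinate")
  }
  five_prime <- ifelse(fragments$strand == "+", fragments$start, fragments$end)
  tlen <- fragments$end - fragments$start + 1L
  ifelse(fragments$merged,
         paste(fragments$chrom, fragments$strand, five_prime, tlen,
               sep = ":"),
         paste(fragments$chrom, "pair", fragments$start, fragments$end,
               fragments$strand, sep = ":"))
}

#' Start-only duplicate key (standard single-end behaviour)
#'
#' Ignores template length; used as the baseline for coverage
#' comparisons against the length-aware key.
#'
#' @inheritParams duplicate_key
#' @return character vector of keys.
#' @export
start_key <- function(fragments) {
  five_prime <- ifelse(fragments$strand == "+", fragments$start, fragments$end)
  paste(fragments$chrom, fragments$strand, five_prime, sep = ":")
}

#' Group coordinate-sorted fragments into duplicate families
#'
#' @param fragments aligned-fragments data.frame, coordinate-sorted
#'   (ascending start per chromosome); unsorted input is an error.
#' @return a list of data.frames, one per family, in coordinate order.
#' @export
group_duplicates <- function(fragments) {
  if (nrow(fragments) == 0L) return(list())
  o <- order(fragments$chrom, fragments$start)
  if (!identical(o, seq_len(nrow(fragments)))) {
    stop("input fragments must be coordinate-sorted")
  }
  key <- duplicate_key(fragments)
  idx <- split(seq_len(nrow(fragments)), key)
  first <- vapply(idx, `[[`, 0L, 1L)
  idx <- idx[order(fragments$chrom[first], fragments$start[first])]
  lapply(idx, function(i) fragments[i, , drop = FALSE])
}

#' Collapse one duplicate family into a consensus read
#'
#' Each column is voted on: if the modal base (N never counts) is carried
#' by at least 75% of the family, it is kept with quality equal to the
#' sum of the qualities of the reads carrying it, capped at `qual_cap`;
#' otherwise the column becomes N with quality 2. Singleton families pass
#' through unchanged. Boosted qualities are meant for quality filtering
#' downstream, not as calling evidence weights.
#'
#' @param family data.frame of fragments sharing one duplicate key.
#' @param qual_cap maximum consensus quality (50).
#' @return one-row data.frame: `id` (first member plus a family-size
#'   tag), `chrom`, `start`, `end`, `strand`, `merged`, `seq`, `qual`,
#'   `family_size`, `n_masked`.
#' @export
consensus <- function(family, qual_cap = 50L) {
  n <- nrow(family)
  stopifnot(n >= 1L)
  lens <- nchar(family$seq)
  if (length(unique(lens)) != 1L ||
      length(unique(family$start)) != 1L) {
    stop("mixed-length family: duplicate-key invariant violated")
  }
  out <- family[1L, c("chrom", "start", "end", "strand", "merged"),
                drop = FALSE]
  if (n == 1L) {
    out$id <- paste0(family$id[1L], ":fam1")
    out$seq <- family$seq[1L]
    out$qual <- family$qual[1L]
    out$family_size <- 1L
    out$n_masked <- 0L
    rownames(out) <- NULL
    return(out[, c("id", "chrom", "start", "end", "strand", "merged",
                   "seq", "qual", "family_size", "n_masked")])
  }
  L <- lens[1L]
  bases <- matrix(unlist(strsplit(family$seq, "")), nrow = n, byrow = TRUE)
  quals <- matrix(unlist(lapply(family$qual, phred_to_int)),
                  nrow = n, byrow = TRUE)
  cseq <- character(L)
  cqual <- integer(L)
  n_masked <- 0L
  for (j in seq_len(L)) {
    b <- bases[, j]
    real <- b != "N"
    if (any(real)) {
      tab <- table(b[real])
      modal <- names(tab)[which.max(tab)]
      # ">= 75% of bases in each position": inclusive, over family size
      if (max(tab) >= 0.75 * n - 1e-9) {
        cseq[j] <- modal
        cqual[j] <- min(sum(quals[b == modal, j]), qual_cap)
        next
      }
    }
    cseq[j] <- "N"
    cqual[j] <- 2L
    n_masked <- n_masked + 1L
  }
  out$id <- paste0(family$id[1L], ":fam", n)
  out$seq <- paste(cseq, collapse = "")
  out$qual <- int_to_phred(cqual)
  out$family_size <- n
  out$n_masked <- n_masked
  rownames(out) <- NULL
  out[, c("id", "chrom", "start", "end", "strand", "merged",
          "seq", "qual", "family_size", "n_masked")]
}

#' Deduplicate merged fragments by consensus calling
#'
#' Groups fragments by the length-aware duplicate key and collapses every
#' family with [consensus()].
#'
#' @param fragments coordinate-sorted aligned-fragments data.frame.
#' @param qual_cap maximum consensus quality (50).
#' @return coordinate-sorted data.frame of consensus reads.
#' @export
consensus_reads <- function(fragments, qual_cap = 50L) {
  fams <- group_duplicates(fragments)
  if (length(fams) == 0L) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), merged = logical(0),
                      seq = character(0), qual = character(0),
                      family_size = integer(0), n_masked = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(fams, consensus, qual_cap = qual_cap))
  rownames(out) <- NULL
  out
}

#' Start-only duplicate marking (keep one read per start)
#'
#' Mimics standard single-end duplicate removal, which ignores template
#' length: of all fragments sharing (chrom, strand, 5' start), only the
#' first survives. Used as the baseline in coverage comparisons with the
#' length-aware key.
#'
#' @param fragments coordinate-sorted aligned-fragments data.frame.
#' @return the surviving subset of `fragments`.
#' @export
mark_only <- function(fragments) {
  if (nrow(fragments) == 0L) return(fragments)
  keep <- !duplicated(start_key(fragments))
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
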