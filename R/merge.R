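# Overlap merging of paired-end mates.
#
# cfDNA fragments (~180 bp) sequenced 2x100 bp overlap in the middle.
# Merging turns each pair into one single-end read covering the whole
# template: concordant overlap bases get their qualities summed (capped
# at 45), discordant ones are masked to N with quality 2, so a sequencer
# error in either mate is either outvoted into a mask or never boosted.

#' Find the overlap offset between the mates of a read pair
#'
#' Mate 2 is reverse-complemented and slid along mate 1; the offset with
#' the most matching bases wins, provided the overlap is at least
#' `min_overlap` long and the mismatch fraction within it is at most
#' `max_mismatch_rate`. Ties are broken toward the longer overlap.
#' N in either mate counts as a mismatch.
#'
#' @param seq1,seq2 mate sequences (mate 2 in sequencing orientation).
#' @param min_overlap minimum acceptable overlap length, bp.
#' @param max_mismatch_rate maximum mismatch fraction within the overlap.
#' @return a list with `offset` (0-based start of reverse-complemented
#'   mate 2 within the merged read), `overlap`, `mismatches` and
#'   `template_length`, or `NULL` when no acceptable overlap exists.
#' @export
find_overlap <- function(seq1, seq2, min_overlap = 15L,
                         max_mismatch_rate = 0.1) {
  stopifnot(nchar(seq1) > 0L, nchar(seq2) > 0L)
  r1 <- charToRaw(seq1)
  r2 <- charToRaw(revcomp(seq2))
  n1 <- length(r1)
  n2 <- length(r2)
  rawN <- charToRaw("N")
  best <- NULL
  for (off in 0:(n1 - min_overlap)) {
    ov <- min(n1 - off, n2)
    a <- r1[(off + 1L):(off + ov)]
    b <- r2[1:ov]
    match <- sum(a == b & a != rawN)
    mm <- ov - match
    if (mm / ov <= max_mismatch_rate) {
      # maximize matches; earlier (longer-overlap) offsets win ties by order
      if (is.null(best) || match > best$matches) {
        best <- list(offset = off, overlap = ov, mismatches = mm,
                     matches = match, template_length = off + n2)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$matches <- NULL
  best
}

#' Merge one read pair at a given overlap offset
#'
#' Non-overlapping bases keep their original base and quality. In the
#' overlap, concordant bases are kept with quality `min(q1 + q2, 45)`;
#' discordant bases (including N in either mate) become N with quality 2.
#'
#' @param seq1,qual1 mate-1 sequence and phred+33 quality string.
#' @param seq2,qual2 mate-2 sequence and quality (sequencing orientation).
#' @param offset 0-based offset of reverse-complemented mate 2 within the
#'   merged read, as returned by [find_overlap()].
#' @param qual_cap maximum boosted quality (45).
#' @return a list with `seq`, `qual` (phred+33), `template_length` and
#'   `n_masked` (discordant overlap columns).
#' @export
merge_pair <- function(seq1, qual1, seq2, qual2, offset, qual_cap = 45L) {
  n1 <- nchar(seq1)
  n2 <- nchar(seq2)
  if (offset < 0L || offset > n1) stop("offset out of range")
  s2 <- strsplit(revcomp(seq2), "")[[1L]]
  q2 <- rev(phred_to_int(qual2))
  s1 <- strsplit(seq1, "")[[1L]]
  q1 <- phred_to_int(qual1)
  tlen <- offset + n2
  if (tlen < n1) stop("offset out of range")
  seq <- character(tlen)
  qual <- integer(tlen)
  if (offset > 0L) {
    seq[1:offset] <- s1[1:offset]
    qual[1:offset] <- q1[1:offset]
  }
  ov <- n1 - offset
  n_masked <- 0L
  if (ov > 0L) {
    for (k in seq_len(ov)) {
      i <- offset + k
      b1 <- s1[i]
      b2 <- s2[k]
      if (b1 == b2 && b1 != "N") {
        seq[i] <- b1
        qual[i] <- min(q1[i] + q2[k], qual_cap)
      } else {
        seq[i] <- "N"
        qual[i] <- 2L
        n_masked <- n_masked + 1L
      }
    }
  }
  if (tlen > n1) {
    seq[(n1 + 1L):tlen] <- s2[(ov + 1L):n2]
    qual[(n1 + 1L):tlen] <- q2[(ov + 1L):n2]
  }
  list(seq = paste(seq, collapse = ""), qual = int_to_phred(qual),
       template_length = tlen, n_masked = n_masked)
}

#' Merge all pairs of a read set
#'
#' Applies [find_overlap()] / [merge_pair()] to each pair. Pairs without
#' an acceptable overlap are passed through unmerged.
#'
#' @param reads data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (as produced by [simulate_library()] or [read_fastq_pair()]).
#' @param min_overlap,max_mismatch_rate see [find_overlap()].
#' @param qual_cap see [merge_pair()].
#' @return a list with `merged` (data.frame: `id`, `seq`, `qual`,
#'   `template_length`, `n_masked`) and `unmerged` (the pass-through
#'   subset of `reads`).
#' @export
merge_pairs <- function(reads, min_overlap = 15L, max_mismatch_rate = 0.1,
                        qual_cap = 45L) {
  n <- nrow(reads)
  merged <- vector("list", n)
  keep_unmerged <- logical(n)
  for (i in seq_len(n)) {
    hit <- find_overlap(reads$seq1[i], reads$seq2[i],
                        min_overlap = min_overlap,
                        max_mismatch_rate = max_mismatch_rate)
    if (is.null(hit)) {
      keep_unmerged[i] <- TRUE
    } else {
      m <- merge_pair(reads$seq1[i], reads$qual1[i],
                      reads$seq2[i], reads$qual2[i],
                      offset = hit$offset, qual_cap = qual_cap)
      merged[[i]] <- data.frame(id = reads$id[i], seq = m$seq, qual = m$qual,
                                template_length = m$template_length,
                                n_masked = m$n_masked,
                                stringsAsFactors = FALSE)
    }
  }
  merged <- do.call(rbind, merged[!vapply(merged, is.null, TRUE)])
  if (is.null(merged)) {
    merged <- data.frame(id = character(0), seq = character(0),
                         qual = character(0), template_length = integer(0),
                         n_masked = integer(0), stringsAsFactors = FALSE)
  }
  rownames(merged) <- NULL
  list(merged = merged, unmerged = reads[keep_unmerged, , drop = FALSE])
}
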