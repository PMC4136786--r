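# Placement of merged reads at their true coordinates and SAM round-trip.
#
# Read alignment is outside the scope of this package: the generator
# knows every molecule's coordinates, so merged reads are placed at the
# truth positions (what an aligner would recover for unique regions).
# Reads from minus-strand molecules are re-oriented to the reference.

#' Place merged reads at their true genomic coordinates
#'
#' @param merged data.frame from [merge_pairs()]`$merged`.
#' @param library the `cfdna_library` the reads came from (provides the
#'   truth coordinates and strands).
#' @return an `aligned fragments` data.frame: `id`, `chrom`, `start`,
#'   `end` (1-based, closed), `strand`, `merged`, `seq`, `qual`
#'   (reference orientation), sorted by coordinate.
#' @export
place_reads <- function(merged, library) {
  mol <- library$truth$molecules
  mid <- as.integer(sub("^M(\\d+)_R\\d+$", "\\1", merged$id))
  stopifnot(!anyNA(mid))
  strand <- mol$strand[mid]
  seq <- merged$seq
  qual <- merged$qual
  rev_idx <- which(strand == "-")
  for (i in rev_idx) {
    seq[i] <- revcomp(seq[i])
    qual[i] <- paste(rev(strsplit(qual[i], "")[[1L]]), collapse = "")
  }
  start <- mol$start[mid]
  out <- data.frame(id = merged$id, chrom = mol$chrom[mid],
                    start = start,
                    end = start + nchar(seq) - 1L,
                    strand = strand, merged = TRUE,
                    seq = seq, qual = qual, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Place raw (unmerged) mates individually at their true coordinates
#'
#' Emulates the standard pipeline in which each mate is an independent
#' alignment record; overlapping mates therefore cover the middle of the
#' fragment twice. Mate sequences from the reverse strand are re-oriented
#' to the reference.
#'
#' @param library a `cfdna_library`.
#' @return an aligned-fragments data.frame as in [place_reads()], with
#'   `merged = FALSE` and two records per pair, coordinate-sorted.
#' @export
place_raw_reads <- function(library) {
  r <- library$reads
  mol <- library$truth$molecules
  mid <- r$molecule_id
  len <- mol$end[mid] - mol$start[mid] + 1L
  rl1 <- nchar(r$seq1)
  rl2 <- nchar(r$seq2)
  plus <- mol$strand[mid] == "+"
  # mate 1 reads the left fragment end on + molecules, the right end on -
  s1 <- ifelse(plus, r$seq1, vapply(r$seq1, revcomp, "", USE.NAMES = FALSE))
  q1 <- ifelse(plus, r$qual1, vapply(r$qual1, function(q)
    paste(rev(strsplit(q, "")[[1L]]), collapse = ""), "", USE.NAMES = FALSE))
  st1 <- ifelse(plus, mol$start[mid], mol$end[mid] - rl1 + 1L)
  s2 <- ifelse(plus, vapply(r$seq2, revcomp, "", USE.NAMES = FALSE), r$seq2)
  q2 <- ifelse(plus, vapply(r$qual2, function(q)
    paste(rev(strsplit(q, "")[[1L]]), collapse = ""), "", USE.NAMES = FALSE),
    r$qual2)
  st2 <- ifelse(plus, mol$end[mid] - rl2 + 1L, mol$start[mid])
  out <- data.frame(
    id = c(paste0(r$id, "/1"), paste0(r$id, "/2")),
    chrom = mol$chrom[c(mid, mid)],
    start = c(st1, st2),
    end = c(st1 + rl1 - 1L, st2 + rl2 - 1L),
    strand = rep(mol$strand[mid], 2L),
    merged = FALSE,
    seq = c(s1, s2), qual = c(q1, q2), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$end, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write aligned fragments as a coordinate-sorted SAM file
#'
#' Merged reads are written as single-end records (FLAG 0/16 by strand)
#' with `XM` carrying the merged flag; the header declares the sort order
#' and reference length, so the file converts cleanly to BAM.
#'
#' @param fragments aligned-fragments data.frame ([place_reads()]).
#' @param path output SAM path.
#' @param genome_length reference length for the `@SQ` line.
#' @return `path`, invisibly.
#' @export
write_sam <- function(fragments, path, genome_length) {
  f <- fragments[order(fragments$chrom, fragments$start), , drop = FALSE]
  chroms <- unique(f$chrom)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(genome_length)))
  flag <- ifelse(f$strand == "-", 16L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tXM:i:%d",
                 f$id, flag, f$chrom, f$start, nchar(f$seq),
                 f$seq, f$qual, as.integer(f$merged))
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM file of single-end records into aligned fragments
#'
#' Minimal reader for the records [write_sam()] produces (single-end,
#' all-match CIGAR); alignment semantics are validated against
#' `Rsamtools` in the test suite.
#'
#' @param path SAM path.
#' @return aligned-fragments data.frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), merged = logical(0),
                      seq = character(0), qual = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(k) vapply(fields, `[[`, "", k)
  flag <- as.integer(get(2))
  start <- as.integer(get(4))
  seq <- get(10)
  merged <- vapply(fields, function(x) {
    xm <- grep("^XM:i:", x[-(1:11)], value = TRUE)
    length(xm) == 1L && xm == "XM:i:1"
  }, TRUE)
  data.frame(id = get(1), chrom = get(3), start = start,
             end = start + nchar(seq) - 1L,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             merged = merged, seq = seq, qual = get(11),
             stringsAsFactors = FALSE)
}

#' Write merged reads aligned at truth coordinates
#'
#' Convenience wrapper: merge the library's pairs, place the merged reads
#' at their true coordinates and write a coordinate-sorted SAM.
#'
#' @param library a `cfdna_library`.
#' @param merged optional pre-computed [merge_pairs()]`$merged`.
#' @param path output SAM path.
#' @return the aligned-fragments data.frame, invisibly.
#' @export
write_alignments <- function(library, path, merged = NULL) {
  if (is.null(merged)) merged <- merge_pairs(library$reads)$merged
  frags <- place_reads(merged, library)
  write_sam(frags, path, library$config$genome_length)
  invisible(frags)
}
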