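# Synthetic cfDNA library generation with ground-truth provenance.
#
# The generator emulates the salient structure of a cell-free DNA
# sequencing library: short fragments peaking around 180 bp, 2x100 bp
# paired-end reads whose mates overlap, PCR-duplicate families sharing
# family-level (PCR) errors, per-read sequencer errors, and somatic
# variants spiked at a known ctDNA fraction. Every molecule and read is
# recorded in a truth table so downstream stages can be checked against
# provenance rather than against themselves.

#' Configuration for the synthetic cfDNA generator
#'
#' @param genome_length length of the synthetic reference, bp.
#' @param n_variant_sites number of somatic variant positions to place.
#' @param ctdna_fraction probability that a molecule is tumor-derived
#'   (carries the alternate allele at every covered variant site).
#' @param fragment_size_mean,fragment_size_sd parameters of the truncated
#'   normal fragment-size distribution, bp. cfDNA peaks near 180 bp.
#' @param fragment_size_range truncation bounds, bp. The upper bound stays
#'   above \code{2 * read_length} so that a tail of fragments is too long
#'   for the mates to overlap.
#' @param read_length sequenced read length, bp (2 x read_length layout).
#' @param seq_error_rate per-base substitution rate of the sequencer.
#' @param pcr_error_rate per-base substitution rate introduced once per
#'   PCR-duplicate family (shared by all reads of the family).
#' @param duplicate_rate_mean mean number of reads per unique molecule;
#'   family sizes are 1 + Geometric, so 1 means no duplication.
#' @param n_molecules number of unique template molecules to draw.
#' @param base_quality_mean,base_quality_sd per-base quality distribution
#'   (normal, rounded, clipped to [2, 41]).
#' @param chrom name of the single synthetic chromosome.
#' @param seed optional RNG seed; with a fixed seed the whole generator is
#'   reproducible bit-for-bit.
#'
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(genome_length = 100000L,
                         n_variant_sites = 50L,
                         ctdna_fraction = 0.01,
                         fragment_size_mean = 180,
                         fragment_size_sd = 40,
                         fragment_size_range = c(50, 250),
                         read_length = 100L,
                         seq_error_rate = 0.0029,
                         pcr_error_rate = 1e-5,
                         duplicate_rate_mean = 5,
                         n_molecules = 2000L,
                         base_quality_mean = 36,
                         base_quality_sd = 3,
                         chrom = "synth1",
                         seed = NULL) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_variant_sites = as.integer(n_variant_sites),
    ctdna_fraction = ctdna_fraction,
    fragment_size_mean = fragment_size_mean,
    fragment_size_sd = fragment_size_sd,
    fragment_size_range = fragment_size_range,
    read_length = as.integer(read_length),
    seq_error_rate = seq_error_rate,
    pcr_error_rate = pcr_error_rate,
    duplicate_rate_mean = duplicate_rate_mean,
    n_molecules = as.integer(n_molecules),
    base_quality_mean = base_quality_mean,
    base_quality_sd = base_quality_sd,
    chrom = chrom,
    seed = seed
  )
  for (p in c("ctdna_fraction", "seq_error_rate", "pcr_error_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("%s must lie in [0, 1]", p))
    }
  }
  if (cfg$duplicate_rate_mean < 1) stop("duplicate_rate_mean must be >= 1")
  if (cfg$genome_length < 10 * cfg$fragment_size_mean) {
    stop("genome_length must be at least 10 x fragment_size_mean")
  }
  if (length(cfg$fragment_size_range) != 2L ||
      cfg$fragment_size_range[1] < 1 ||
      cfg$fragment_size_range[2] <= cfg$fragment_size_range[1]) {
    stop("fragment_size_range must be an increasing pair of positive bounds")
  }
  if (cfg$fragment_size_range[2] <= 2 * cfg$read_length &&
      cfg$fragment_size_range[2] < cfg$fragment_size_mean) {
    stop("fragment_size_range upper bound below fragment_size_mean")
  }
  class(cfg) <- "synth_config"
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic cfDNA library configuration\n")
  cat(sprintf("  genome: %d bp (%s), %d variant sites\n",
              x$genome_length, x$chrom, x$n_variant_sites))
  cat(sprintf("  fragments: %g +/- %g bp in [%g, %g]; reads 2 x %d bp\n",
              x$fragment_size_mean, x$fragment_size_sd,
              x$fragment_size_range[1], x$fragment_size_range[2],
              x$read_length))
  cat(sprintf("  molecules: %d, mean family size %g\n",
              x$n_molecules, x$duplicate_rate_mean))
  cat(sprintf("  ctDNA fraction: %g; errors: seq %g, PCR %g per base\n",
              x$ctdna_fraction, x$seq_error_rate, x$pcr_error_rate))
  invisible(x)
}

#' Generate a random reference sequence and variant-site list
#'
#' Variant sites are placed with pairwise spacing of at least one read
#' length so that no read covers two sites, and away from the sequence
#' ends. Each site gets the reference base found in the sequence and a
#' random alternate base.
#'
#' @param config a [synth_config()].
#' @return a list with `genome` (character scalar), `sites` (data.frame
#'   with `chrom`, `pos` (1-based), `ref`, `alt`) and `chrom`.
#' @export
make_reference <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$genome_length
  rl <- config$read_length
  genome <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
  n <- config$n_variant_sites
  if (n == 0L) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        stringsAsFactors = FALSE)
    return(list(genome = genome, sites = sites, chrom = config$chrom))
  }
  lo <- rl + 1L
  hi <- L - rl
  if (hi < lo || (hi - lo) %/% rl + 1L < n) {
    stop("cannot place variant sites at the requested spacing")
  }
  pos <- NULL
  for (try in seq_len(1000L)) {
    cand <- sort(sample(lo:hi, n))
    if (n == 1L || all(diff(cand) >= rl)) {
      pos <- cand
      break
    }
  }
  if (is.null(pos)) stop("cannot place variant sites at the requested spacing")
  ref <- substring(genome, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                "", USE.NAMES = FALSE)
  sites <- data.frame(chrom = config$chrom, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  list(genome = genome, sites = sites, chrom = config$chrom)
}

# substitute a base at string offset i, avoiding the current base
.substitute_base <- function(seq, i) {
  cur <- substring(seq, i, i)
  new <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
  substr(seq, i, i) <- new
  seq
}

.draw_quals <- function(n, mean, sd) {
  q <- round(stats::rnorm(n, mean, sd))
  pmin(pmax(q, 2L), 41L)
}

#' Simulate a paired-end cfDNA library with ground truth
#'
#' Molecules are drawn uniformly over the reference with truncated-normal
#' lengths. A molecule is tumor-derived with probability
#' `ctdna_fraction`; tumor molecules carry the alternate allele at every
#' variant site they cover. Each molecule is amplified into a
#' PCR-duplicate family (size 1 + Geometric with the configured mean);
#' PCR errors are injected once per family and shared by all of its reads,
#' sequencer errors independently per read. Mates are emitted with correct
#' reverse-complement geometry; fragments shorter than the read length are
#' sequenced to the template only (adapter read-through trimmed).
#'
#' @param config a [synth_config()].
#' @param reference output of [make_reference()].
#' @return an object of class `cfdna_library`: a list with
#'   \describe{
#'     \item{reads}{data.frame of read pairs: `id`, `molecule_id`, `seq1`,
#'       `qual1`, `seq2`, `qual2` (qualities as phred+33 strings).}
#'     \item{truth}{list of `molecules` (id, chrom, start, end, strand,
#'       tumor, family_size, pcr_errors as comma-separated genomic
#'       positions) and `reads` (read_id, molecule_id, seq_errors as
#'       comma-separated genomic positions of sequencer substitutions).}
#'     \item{sites, config}{the inputs, carried along.}
#'   }
#' @export
simulate_library <- function(config, reference) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  genome <- reference$genome
  sites <- reference$sites
  L <- config$genome_length
  rl <- config$read_length
  nmol <- config$n_molecules

  len <- round(rtruncnorm(nmol, config$fragment_size_mean,
                          config$fragment_size_sd,
                          config$fragment_size_range[1],
                          config$fragment_size_range[2]))
  start <- sample.int(L - max(len), nmol, replace = TRUE)
  end <- start + len - 1L
  strand <- sample(c("+", "-"), nmol, replace = TRUE)
  tumor <- stats::rbinom(nmol, 1L, config$ctdna_fraction) == 1L
  fam <- 1L + stats::rgeom(nmol, 1 / config$duplicate_rate_mean)

  mol_seq <- substring(genome, start, end)
  # spike alternate alleles into tumor molecules
  if (nrow(sites) > 0L && any(tumor)) {
    for (i in which(tumor)) {
      hit <- which(sites$pos >= start[i] & sites$pos <= end[i])
      for (j in hit) {
        off <- sites$pos[j] - start[i] + 1L
        substr(mol_seq[i], off, off) <- sites$alt[j]
      }
    }
  }

  # family-level (PCR) errors: injected once per molecule's amplicon
  pcr_errors <- character(nmol)
  amp_seq <- mol_seq
  n_perr <- stats::rbinom(nmol, len, config$pcr_error_rate)
  for (i in which(n_perr > 0L)) {
    perr <- sort(sample.int(len[i], min(n_perr[i], len[i])))
    for (o in perr) amp_seq[i] <- .substitute_base(amp_seq[i], o)
    pcr_errors[i] <- format_pos_list(start[i] + perr - 1L)
  }

  # expand molecules to reads: family member r of molecule i
  mid <- rep.int(seq_len(nmol), fam)
  nreads <- length(mid)
  ids <- sprintf("M%06d_R%d", mid, sequence(fam))
  end_len <- pmin(rl, len)      # sequenced length of each fragment end
  r1_len <- end_len[mid]        # left fragment end (forward)
  r2_len <- end_len[mid]        # right fragment end (forward)
  s1 <- substring(amp_seq[mid], 1L, r1_len)
  s2 <- substring(amp_seq[mid], len[mid] - r2_len + 1L, len[mid])

  # per-read sequencer errors on either fragment end
  seq_errors <- character(nreads)
  n_e1 <- stats::rbinom(nreads, r1_len, config$seq_error_rate)
  n_e2 <- stats::rbinom(nreads, r2_len, config$seq_error_rate)
  for (i in which(n_e1 + n_e2 > 0L)) {
    e1 <- if (n_e1[i] > 0L) sort(sample.int(r1_len[i], n_e1[i])) else integer(0)
    e2 <- if (n_e2[i] > 0L) sort(sample.int(r2_len[i], n_e2[i])) else integer(0)
    for (o in e1) s1[i] <- .substitute_base(s1[i], o)
    for (o in e2) s2[i] <- .substitute_base(s2[i], o)
    m <- mid[i]
    gpos <- sort(unique(c(start[m] + e1 - 1L,
                          start[m] + (len[m] - r2_len[i]) + e2 - 1L)))
    seq_errors[i] <- format_pos_list(gpos)
  }

  # mate geometry: read 1 sequences the left fragment end on + molecules
  # and the (reverse-complemented) right end on - molecules
  plus <- strand[mid] == "+"
  rc2 <- revcomp_many(s2)
  seq1 <- ifelse(plus, s1, rc2)
  seq2 <- ifelse(plus, rc2, s1)
  qm <- config$base_quality_mean
  qs <- config$base_quality_sd
  qual1 <- vapply(nchar(seq1), function(n) int_to_phred(.draw_quals(n, qm, qs)),
                  "", USE.NAMES = FALSE)
  qual2 <- vapply(nchar(seq2), function(n) int_to_phred(.draw_quals(n, qm, qs)),
                  "", USE.NAMES = FALSE)

  molecules <- data.frame(
    molecule_id = seq_len(nmol), chrom = config$chrom,
    start = start, end = end, strand = strand,
    tumor = tumor, family_size = fam, pcr_errors = pcr_errors,
    stringsAsFactors = FALSE)
  reads <- data.frame(id = ids, molecule_id = mid,
                      seq1 = seq1, qual1 = qual1,
                      seq2 = seq2, qual2 = qual2,
                      stringsAsFactors = FALSE)
  truth_reads <- data.frame(read_id = ids, molecule_id = mid,
                            seq_errors = seq_errors,
                            stringsAsFactors = FALSE)

  structure(list(reads = reads,
                 truth = list(molecules = molecules, reads = truth_reads),
                 sites = sites, config = config),
            class = "cfdna_library")
}

#' @export
print.cfdna_library <- function(x, ...) {
  m <- x$truth$molecules
  cat(sprintf("synthetic cfDNA library: %d molecules, %d read pairs\n",
              nrow(m), nrow(x$reads)))
  cat(sprintf("  fragment length mean %.1f bp; %d tumor-derived molecules\n",
              mean(m$end - m$start + 1), sum(m$tumor)))
  invisible(x)
}

#' Write a library's read pairs as a FASTQ pair
#'
#' @param library a `cfdna_library`.
#' @param prefix output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` (phred+33).
#' @return the two file paths, invisibly.
#' @export
write_fastq_pair <- function(library, prefix) {
  r <- library$reads
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (k in 1:2) {
    s <- Biostrings::DNAStringSet(r[[paste0("seq", k)]])
    names(s) <- r$id
    Biostrings::writeXStringSet(
      s, paths[k], format = "fastq",
      qualities = Biostrings::BStringSet(r[[paste0("qual", k)]]))
  }
  invisible(paths)
}

#' Read a FASTQ pair back into a read-pair data frame
#'
#' @param fq1,fq2 FASTQ paths (phred+33).
#' @return data.frame with `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_fastq_pair <- function(fq1, fq2) {
  a <- Biostrings::readDNAStringSet(fq1, format = "fastq", with.qualities = TRUE)
  b <- Biostrings::readDNAStringSet(fq2, format = "fastq", with.qualities = TRUE)
  stopifnot(identical(names(a), names(b)))
  data.frame(id = names(a),
             seq1 = as.character(a),
             qual1 = as.character(S4Vectors::mcols(a)$qualities),
             seq2 = as.character(b),
             qual2 = as.character(S4Vectors::mcols(b)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write the truth tables of a library as TSV
#'
#' @param library a `cfdna_library`.
#' @param prefix output path prefix; writes `<prefix>_molecules.tsv` and
#'   `<prefix>_reads.tsv`.
#' @return the two paths, invisibly.
#' @export
write_truth <- function(library, prefix) {
  paths <- paste0(prefix, c("_molecules.tsv", "_reads.tsv"))
  utils::write.table(library$truth$molecules, paths[1], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(library$truth$reads, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
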