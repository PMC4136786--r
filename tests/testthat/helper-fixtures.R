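# Shared fixture builders. All synthetic data is generated in code at
# test time; seeds are fixed so every run sees the same libraries.

# A small library plus its reference, with overridable generator knobs.
tiny_library <- function(seed = 1, genome_length = 20000, n_variant_sites = 10,
                         n_molecules = 200, ctdna_fraction = 0.05,
                         duplicate_rate_mean = 2, seq_error_rate = 0.0029,
                         pcr_error_rate = 1e-5, ...) {
  cfg <- synth_config(genome_length = genome_length,
                      n_variant_sites = n_variant_sites,
                      n_molecules = n_molecules,
                      ctdna_fraction = ctdna_fraction,
                      duplicate_rate_mean = duplicate_rate_mean,
                      seq_error_rate = seq_error_rate,
                      pcr_error_rate = pcr_error_rate,
                      seed = seed, ...)
  ref <- make_reference(cfg)
  lib <- simulate_library(cfg, ref)
  list(cfg = cfg, ref = ref, lib = lib)
}

# Reconstruct the true (pre-PCR) sequence of a molecule: reference plus
# spiked alternate alleles for tumor molecules.
molecule_truth_seq <- function(fx, molecule_id) {
  mol <- fx$lib$truth$molecules[molecule_id, ]
  seq <- substring(fx$ref$genome, mol$start, mol$end)
  if (mol$tumor && nrow(fx$lib$sites) > 0) {
    hit <- which(fx$lib$sites$pos >= mol$start & fx$lib$sites$pos <= mol$end)
    for (j in hit) {
      off <- fx$lib$sites$pos[j] - mol$start + 1L
      substr(seq, off, off) <- fx$lib$sites$alt[j]
    }
  }
  seq
}

# Build an error-free read pair from a fragment of the reference.
pair_from_fragment <- function(genome, start, frag_len, read_len = 100,
                               qual = 30) {
  frag <- substring(genome, start, start + frag_len - 1L)
  r1 <- substring(frag, 1L, min(read_len, frag_len))
  r2fwd <- substring(frag, max(1L, frag_len - read_len + 1L), frag_len)
  q <- function(s) rawToChar(rep(as.raw(qual + 33L), nchar(s)))
  list(seq1 = r1, qual1 = q(r1),
       seq2 = rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", r2fwd)))),
       qual2 = q(r2fwd))
}

# Brute-force one-sided Fisher p (hypergeometric upper tail by summation).
fisher_tail_oracle <- function(a, b, c, d) {
  K <- a + c       # mutant reads overall
  n <- a + b       # reads drawn into the sample margin
  N <- a + b + c + d
  ks <- a:min(n, K)
  sum(stats::dhyper(ks, K, N - K, n))
}

# Aligned-fragment rows built by hand for dedup/consensus unit tests.
frag_row <- function(id, start, len, seq, qual_int, strand = "+",
                     chrom = "c1", merged = TRUE) {
  data.frame(id = id, chrom = chrom, start = start, end = start + len - 1L,
             strand = strand, merged = merged, seq = seq,
             qual = rawToChar(as.raw(qual_int + 33L)),
             stringsAsFactors = FALSE)
}

# Constant-quality helper for hand-built fragments.
qvec <- function(q, n) rep(q, n)
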