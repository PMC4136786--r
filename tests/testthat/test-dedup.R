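test_that("duplicate key separates same-start molecules by length", {
  a <- frag_row("r1", 500, 166, strrep("A", 166), qvec(30, 166))
  b <- frag_row("r2", 500, 180, strrep("A", 180), qvec(30, 180))
  c_ <- frag_row("r3", 500, 166, strrep("A", 166), qvec(30, 166))
  expect_false(duplicate_key(a) == duplicate_key(b))
  expect_identical(duplicate_key(a), duplicate_key(c_))
  # start-only key collapses them
  expect_identical(start_key(a), start_key(b))
  # 5' start is the rightmost coordinate on the minus strand
  d1 <- frag_row("r4", 400, 101, strrep("A", 101), qvec(30, 101), strand = "-")
  d2 <- frag_row("r5", 450, 51, strrep("A", 51), qvec(30, 51), strand = "-")
  k1 <- strsplit(duplicate_key(d1), ":")[[1]]
  k2 <- strsplit(duplicate_key(d2), ":")[[1]]
  expect_equal(k1[3], "500")
  expect_equal(k2[3], "500")
  expect_false(duplicate_key(d1) == duplicate_key(d2))  # lengths differ
})

test_that("family grouping matches a brute-force key partition", {
  fx <- tiny_library(seed = 17, n_molecules = 250, duplicate_rate_mean = 3)
  fr <- place_reads(merge_pairs(fx$lib$reads)$merged, fx$lib)
  fams <- group_duplicates(fr)
  # brute force: hash every key independently
  brute <- split(fr$id, duplicate_key(fr))
  got <- lapply(fams, function(f) sort(f$id))
  expect_setequal(unname(got), unname(lapply(brute, sort)))
  # families stream out in coordinate order
  starts <- vapply(fams, function(f) f$start[1], 0)
  expect_true(!is.unsorted(starts))
  # unsorted input is rejected, empty input yields no families
  expect_error(group_duplicates(fr[rev(seq_len(nrow(fr))), ]), "sorted")
  expect_equal(group_duplicates(fr[0, ]), list())
})

test_that("truth family partition is recovered when keys are unambiguous", {
  fx <- tiny_library(seed = 23, n_molecules = 150, duplicate_rate_mean = 3,
                     genome_length = 50000, seq_error_rate = 0)
  fr <- place_reads(merge_pairs(fx$lib$reads)$merged, fx$lib)
  mid <- as.integer(sub("^M(\\d+)_R\\d+$", "\\1", fr$id))
  mol <- fx$lib$truth$molecules
  sig <- paste(mol$start[mid], mol$end[mid], mol$strand[mid])
  # molecules with a unique (start, end, strand) signature must map to
  # exactly one key that no other molecule's reads share
  key <- duplicate_key(fr)
  for (m in unique(mid)) {
    rows <- which(mid == m)
    others <- which(sig == sig[rows[1]] & mid != m)
    if (length(others) == 0) {
      expect_equal(length(unique(key[rows])), 1)
      expect_false(any(key[-rows] == key[rows[1]]))
    }
  }
})

test_that("consensus applies the 75% rule with summed capped qualities", {
  mk_fam <- function(seqs, quals) {
    do.call(rbind, lapply(seq_along(seqs), function(i)
      frag_row(paste0("r", i), 100, nchar(seqs[i]), seqs[i], quals[[i]])))
  }
  # column {A,A,A,C} at q30: 3/4 = 75% passes, quality min(90, 50) = 50
  fam <- mk_fam(c("A", "A", "A", "C"), rep(list(30), 4))
  cr <- consensus(fam)
  expect_equal(cr$seq, "A")
  expect_equal(as.integer(charToRaw(cr$qual)) - 33L, 50L)
  expect_equal(cr$family_size, 4)
  expect_equal(cr$n_masked, 0)
  # column {A,C}: 50% < 75% -> N with quality 2
  fam2 <- mk_fam(c("A", "C"), rep(list(30), 2))
  cr2 <- consensus(fam2)
  expect_equal(cr2$seq, "N")
  expect_equal(as.integer(charToRaw(cr2$qual)) - 33L, 2L)
  expect_equal(cr2$n_masked, 1)
  # {A,A,C}: 2/3 < 75% -> N; {A,A,A}: sum 36 below the cap
  expect_equal(consensus(mk_fam(c("A", "A", "C"), rep(list(30), 3)))$seq, "N")
  cr3 <- consensus(mk_fam(c("A", "A", "A"), rep(list(12), 3)))
  expect_equal(as.integer(charToRaw(cr3$qual)) - 33L, 36L)
  # only reads carrying the modal base contribute quality
  fam4 <- mk_fam(c("A", "A", "A", "C"), list(10, 10, 10, 40))
  expect_equal(as.integer(charToRaw(consensus(fam4)$qual)) - 33L, 30L)
  # N members count toward family size but never toward the modal base:
  # {A,A,A,N} -> 3/4 passes; {A,A,N,N} -> 2/4 fails
  famN <- mk_fam(c("A", "A", "A", "N"), rep(list(30), 4))
  expect_equal(consensus(famN)$seq, "A")
  famN2 <- mk_fam(c("A", "A", "N", "N"), rep(list(30), 4))
  expect_equal(consensus(famN2)$seq, "N")
})

test_that("singleton families pass through unchanged", {
  f <- frag_row("solo", 250, 5, "ACGTA", qvec(33, 5))
  cr <- consensus(f)
  expect_equal(cr$seq, "ACGTA")
  expect_equal(cr$qual, f$qual)
  expect_equal(cr$family_size, 1)
  expect_equal(cr$n_masked, 0)
})

test_that("mixed-length families violate the key invariant", {
  fam <- rbind(frag_row("a", 100, 4, "ACGT", qvec(30, 4)),
               frag_row("b", 100, 5, "ACGTA", qvec(30, 5)))
  expect_error(consensus(fam), "mixed-length")
})

test_that("consensus removes read-level errors but keeps family-level ones", {
  fx <- tiny_library(seed = 31, n_molecules = 200, duplicate_rate_mean = 5,
                     pcr_error_rate = 0.002, seq_error_rate = 0.003,
                     ctdna_fraction = 0)
  fr <- place_reads(merge_pairs(fx$lib$reads)$merged, fx$lib)
  crs <- consensus_reads(fr)
  mol <- fx$lib$truth$molecules
  mid <- as.integer(sub("^M(\\d+)_R\\d+.*$", "\\1", crs$id))
  n_pcr_kept <- 0
  for (i in seq_len(nrow(crs))) {
    m <- mid[i]
    truth <- molecule_truth_seq(fx, m)
    pcr_pos <- if (nzchar(mol$pcr_errors[m]))
      as.integer(strsplit(mol$pcr_errors[m], ",")[[1]]) else integer(0)
    cons <- strsplit(crs$seq[i], "")[[1]]
    tru <- strsplit(truth, "")[[1]]
    gpos <- crs$start[i]:crs$end[i]
    diff_pos <- gpos[cons != tru & cons != "N"]
    if (crs$family_size[i] >= 3) {
      # every surviving non-N difference from the true molecule sequence
      # must be a family-level (PCR) error; read-level errors are voted out
      expect_true(all(diff_pos %in% pcr_pos))
    }
    n_pcr_kept <- n_pcr_kept + sum(diff_pos %in% pcr_pos)
  }
  # PCR errors do survive consensus (they are shared by the whole family)
  expect_gt(n_pcr_kept, 0)
})

test_that("length-aware dedup retains more coverage than start-only", {
  fx <- tiny_library(seed = 19, n_molecules = 400, duplicate_rate_mean = 4,
                     genome_length = 4000)
  fr <- place_reads(merge_pairs(fx$lib$reads)$merged, fx$lib)
  n_length_aware <- nrow(consensus_reads(fr))
  n_start_only <- nrow(mark_only(fr))
  expect_gte(n_length_aware, n_start_only)     # key refinement, always
  expect_gt(n_length_aware, n_start_only)      # strict on variable lengths
  # two same-start different-length fragments: start-only keeps 1, the
  # length-aware key keeps both
  two <- rbind(frag_row("x", 100, 60, strrep("A", 60), qvec(30, 60)),
               frag_row("y", 100, 70, strrep("A", 70), qvec(30, 70)))
  expect_equal(nrow(mark_only(two)), 1)
  expect_equal(nrow(consensus_reads(two)), 2)
  # unique starts: identity
  uniq <- rbind(frag_row("u1", 100, 50, strrep("A", 50), qvec(30, 50)),
                frag_row("u2", 200, 50, strrep("A", 50), qvec(30, 50)))
  expect_equal(mark_only(uniq), uniq)
})
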