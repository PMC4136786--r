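test_that("allele counts match a truth recount on clean data", {
  fx <- tiny_library(seed = 41, seq_error_rate = 0, pcr_error_rate = 0,
                     n_molecules = 300, genome_length = 50000,
                     ctdna_fraction = 0.2, duplicate_rate_mean = 2)
  fr <- place_reads(merge_pairs(fx$lib$reads)$merged, fx$lib)
  crs <- consensus_reads(fr)
  counts <- count_alleles(crs, fx$lib$sites)
  # truth: one consensus read per unique (start, end, strand) molecule
  # signature; alt iff any contributing molecule is tumor (error-free
  # merge means every family is internally consistent when signatures
  # are unique, which this seed's library satisfies)
  mol <- fx$lib$truth$molecules
  # only fragments short enough for their mates to overlap get merged
  # (overlap = 2 x 100 - length >= 15) and reach the consensus stage
  mol <- mol[mol$end - mol$start + 1L <= 185L, ]
  sig <- paste(mol$start, mol$end, mol$strand)
  merged_mol <- mol[!duplicated(sig), ]
  for (j in seq_len(nrow(fx$lib$sites))) {
    p <- fx$lib$sites$pos[j]
    cov <- merged_mol$start <= p & merged_mol$end >= p
    expect_equal(counts$n_alt[j] + counts$n_ref[j], sum(cov))
    tum <- merged_mol$tumor & cov
    expect_equal(counts$n_alt[j], sum(tum))
  }
  expect_true(all(counts$n_other == 0))
  expect_true(all(counts$n_masked == 0))
})

test_that("quality cutoff 0 is the identity and high cutoffs empty counts", {
  fx <- tiny_library(seed = 43, n_molecules = 200)
  fr <- place_reads(merge_pairs(fx$lib$reads)$merged, fx$lib)
  crs <- consensus_reads(fr)
  c0 <- count_alleles(crs, fx$lib$sites, cutoff = 0)
  pb <- pileup_bases(crs, fx$lib$sites)
  expect_equal(sum(c0$n_alt + c0$n_ref + c0$n_other + c0$n_masked), nrow(pb))
  c99 <- count_alleles(crs, fx$lib$sites, cutoff = 99)
  expect_true(all(c99$n_alt + c99$n_ref + c99$n_other + c99$n_masked == 0))
})

test_that("noise rate is pooled mutant fraction, undefined on empty pools", {
  expect_equal(noise_rate(0, 10000), 0)
  expect_equal(noise_rate(3, 9997), 3e-4)
  expect_true(is.na(noise_rate(0, 0)))
  expect_equal(noise_rate(list(bg_alt = 3, bg_ref = 9997)), 3e-4)
})

test_that("cutoff sweep tracks retention and noise against a recount", {
  fx <- tiny_library(seed = 47, n_molecules = 400, duplicate_rate_mean = 3,
                     seq_error_rate = 0.01, ctdna_fraction = 0)
  fr <- place_reads(merge_pairs(fx$lib$reads)$merged, fx$lib)
  crs <- consensus_reads(fr)
  tab <- sweep_cutoffs(crs, fx$lib$sites, q_grid = seq(0, 50, by = 5))
  expect_true(all(diff(tab$fraction_data_left) <= 0))
  expect_equal(tab$fraction_data_left[1], 1)
  # each row equals a direct recount at that cutoff
  for (k in seq_len(nrow(tab))) {
    cc <- count_alleles(crs, fx$lib$sites, cutoff = tab$cutoff[k])
    expect_equal(tab$n_alt[k], sum(cc$n_alt))
    expect_equal(tab$n_ref[k], sum(cc$n_ref))
  }
})

test_that("log2 ratio falls when mutant reads carry lower qualities", {
  # constructed pileup: reference bases quality 20-50, mutant bases 10-25
  pb <- rbind(
    data.frame(site = 1L, base = "C", qual = rep(20:50, each = 20),
               class = "ref"),
    data.frame(site = 1L, base = "T", qual = rep(10:25, each = 5),
               class = "alt"))
  tab <- sweep_cutoffs(pb, data.frame(chrom = "c1", pos = 1, ref = "C",
                                      alt = "T"),
                       q_grid = c(0, 10, 15, 20, 25))
  ok <- !is.na(tab$log2_ratio)
  expect_true(all(diff(tab$log2_ratio[ok]) <= 0))
  expect_lt(tab$log2_ratio[ok][sum(ok)], 0)
})

test_that("optimal cutoff minimizes noise with the documented tie rules", {
  tab <- data.frame(cutoff = c(38, 43, 46, 50),
                    n_alt = c(5, 3, 1, 2), n_ref = c(100, 90, 80, 60),
                    noise_rate = c(5 / 105, 3 / 93, 1 / 81, 2 / 62),
                    fraction_data_left = c(1, .9, .8, .6),
                    log2_ratio = 0)
  expect_equal(optimal_cutoff(tab), 46)
  # strictly decreasing noise: the largest grid point wins
  tab2 <- transform(tab, noise_rate = c(.4, .3, .2, .1))
  expect_equal(optimal_cutoff(tab2), 50)
  # equal minima: higher retention wins, then the smaller cutoff
  tab3 <- transform(tab, noise_rate = c(.1, .2, .1, .3))
  expect_equal(optimal_cutoff(tab3), 38)
  tab4 <- transform(tab, noise_rate = .1, fraction_data_left = .5)
  expect_equal(optimal_cutoff(tab4), 38)
  tab5 <- transform(tab, noise_rate = NA_real_)
  expect_error(optimal_cutoff(tab5), "undefined")
})

test_that("error suppression orders the pipelines by noise rate", {
  # elevated sequencer errors, rare family-level errors, short fragments
  # so that most of each read is covered by its mate
  fx <- tiny_library(seed = 53, n_molecules = 2500, duplicate_rate_mean = 3,
                     genome_length = 20000, n_variant_sites = 30,
                     seq_error_rate = 0.05, pcr_error_rate = 1e-4,
                     ctdna_fraction = 0,
                     fragment_size_mean = 120, fragment_size_sd = 15,
                     fragment_size_range = c(50, 185))
  sites <- fx$lib$sites
  rate_of <- function(pipeline) {
    counts <- run_pipeline(fx$lib, pipeline, cutoff = 0)$counts
    noise_rate(sum(counts$n_alt), sum(counts$n_ref))
  }
  r_raw <- rate_of("raw")
  r_merge <- rate_of("merge")
  r_cons <- rate_of("consensus")
  expect_lte(r_merge, r_raw)
  expect_lte(r_cons, r_merge)
  expect_lt(r_cons, r_raw)
})

test_that("background pooling is leave-one-out", {
  counts <- rbind(
    data.frame(sample_id = "A", chrom = "c1", pos = 1:2, ref = "A",
               alt = "T", cutoff = 0, n_alt = c(1, 0), n_ref = c(10, 20),
               n_other = 0, n_masked = 0),
    data.frame(sample_id = "B", chrom = "c1", pos = 1:2, ref = "A",
               alt = "T", cutoff = 0, n_alt = c(0, 2), n_ref = c(30, 40),
               n_other = 0, n_masked = 0),
    data.frame(sample_id = "C", chrom = "c1", pos = 1:2, ref = "A",
               alt = "T", cutoff = 0, n_alt = c(1, 1), n_ref = c(5, 5),
               n_other = 0, n_masked = 0))
  pool <- background_pool(counts, exclude_samples = "A")
  expect_equal(pool$bg_alt, 4)
  expect_equal(pool$bg_ref, 80)
  # excluding a sample that shares the mutation as well
  pool2 <- background_pool(counts, exclude_samples = c("A", "C"))
  expect_equal(pool2$bg_alt, 2)
  expect_equal(pool2$bg_ref, 70)
  expect_error(background_pool(counts, exclude_samples = c("A", "B", "C")),
               "empty")
})
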