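# Monte-Carlo sensitivity of pooled ctDNA detection.
#
# For a grid of ctDNA fractions and DNA input masses, the pooled read
# depth reachable from the input is derived (haploid genome copies x
# capture efficiency x tracked variants x fraction of data kept by the
# quality filter, or fixed coverage in WGS mode), mutant reads are drawn
# binomially at the current fraction, and each draw is tested against a
# fixed background pool with the one-sided Fisher test. Sensitivity is
# the proportion of iterations passing the significance threshold; the
# detection limit is the smallest fraction reaching a target
# sensitivity.

#' Haploid genome copies in a DNA mass
#'
#' A haploid human genome weighs 3.218 pg, so `mass_pg / 3.218` copies
#' are available (10,000 pg = 3108 copies).
#'
#' @param mass_pg DNA mass in picograms (> 0).
#' @param pg_per_haploid_genome mass of one haploid genome copy, pg.
#' @return number of copies, rounded to the nearest integer.
#' @export
haploid_copies <- function(mass_pg, pg_per_haploid_genome = 3.218) {
  if (any(mass_pg <= 0)) stop("mass must be positive")
  round(mass_pg / pg_per_haploid_genome)
}

#' Expected number of mutant reads
#'
#' Product of per-site coverage, number of tracked variants, fraction of
#' data kept after quality filtering, and ctDNA fraction: at 30x over
#' 3000 variants with 61% of data kept, a 1/10,000 ctDNA fraction still
#' yields about 5.5 mutant reads on average.
#'
#' @param coverage per-site read depth.
#' @param n_variants number of tracked variant positions.
#' @param kept_fraction fraction of reads surviving the quality filter.
#' @param ctdna_fraction ctDNA fraction.
#' @return the expectation.
#' @export
expected_mutant_reads <- function(coverage, n_variants, kept_fraction,
                                  ctdna_fraction) {
  stopifnot(coverage >= 0, n_variants >= 0, kept_fraction >= 0,
            ctdna_fraction >= 0)
  coverage * n_variants * kept_fraction * ctdna_fraction
}

#' Configuration of the sensitivity simulation
#'
#' @param fractions ctDNA-fraction grid; default 40 log-spaced points
#'   over [1e-5, 0.05].
#' @param input_mass_ng DNA input masses to evaluate, ng (exome mode).
#' @param pg_per_haploid_genome mass of a haploid genome copy (3.218 pg).
#' @param capture_efficiency fraction of input molecules observable
#'   after library preparation and capture (default 0.047, the
#'   saturation estimate; the cohort-wide average was 0.038).
#' @param n_variants tracked variants pooled per test (50 for an exome,
#'   3000 for a whole genome).
#' @param coverage fixed per-site depth; setting it switches to WGS mode
#'   where depth does not derive from input mass.
#' @param kept_fraction fraction of data surviving the quality filter
#'   (0.61 for the consensus pipeline at its optimal cutoff).
#' @param bg_alt,bg_ref explicit background pool counts; when `NULL`
#'   they are derived as `round(pool_size * bg_noise_rate)` mutant reads
#'   out of `pool_size`.
#' @param pool_size total background pool reads (default 517973).
#' @param bg_noise_rate background mutant rate (default 1/35419, the
#'   consensus pipeline at cutoff 46).
#' @param iterations Monte-Carlo iterations per grid point.
#' @param alpha significance threshold.
#' @param mode `"binomial"` draws mutant reads Binomial(depth, fraction);
#'   `"empirical"` resamples from a finite read pool of `empirical_pool`
#'   reads in which `round(empirical_pool * fraction)` are mutant.
#' @param empirical_pool size of the finite read pool in empirical mode.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(fractions = exp(seq(log(1e-5), log(0.05),
                                           length.out = 40)),
                       input_mass_ng = 30,
                       pg_per_haploid_genome = 3.218,
                       capture_efficiency = 0.047,
                       n_variants = 50,
                       coverage = NULL,
                       kept_fraction = 0.61,
                       bg_alt = NULL, bg_ref = NULL,
                       pool_size = 517973,
                       bg_noise_rate = 1 / 35419,
                       iterations = 1000L,
                       alpha = 0.05,
                       mode = c("binomial", "empirical"),
                       empirical_pool = 4733L) {
  mode <- match.arg(mode)
  if (any(fractions <= 0 | fractions >= 1)) {
    stop("fractions must lie in (0, 1)")
  }
  if (capture_efficiency <= 0 || capture_efficiency > 1) {
    stop("capture_efficiency must lie in (0, 1]")
  }
  if (iterations < 1L) stop("iterations must be >= 1")
  if (is.null(bg_alt)) {
    bg_alt <- round(pool_size * bg_noise_rate)
    bg_ref <- pool_size - bg_alt
  }
  if (bg_alt < 0 || bg_ref <= 0) stop("invalid background pool")
  structure(list(fractions = sort(fractions),
                 input_mass_ng = input_mass_ng,
                 pg_per_haploid_genome = pg_per_haploid_genome,
                 capture_efficiency = capture_efficiency,
                 n_variants = n_variants, coverage = coverage,
                 kept_fraction = kept_fraction,
                 bg_alt = bg_alt, bg_ref = bg_ref,
                 iterations = as.integer(iterations), alpha = alpha,
                 mode = mode, empirical_pool = as.integer(empirical_pool)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ctDNA sensitivity simulation configuration\n")
  if (is.null(x$coverage)) {
    cat(sprintf("  exome mode: %g variants, efficiency %.3f, masses %s ng\n",
                x$n_variants, x$capture_efficiency,
                paste(x$input_mass_ng, collapse = ", ")))
  } else {
    cat(sprintf("  WGS mode: %g variants at %gx coverage\n",
                x$n_variants, x$coverage))
  }
  cat(sprintf("  kept fraction %.2f; background %d / %d (rate 1/%.0f)\n",
              x$kept_fraction, x$bg_alt, x$bg_ref,
              (x$bg_alt + x$bg_ref) / x$bg_alt))
  cat(sprintf("  %d fractions in [%.2g, %.2g], %d iterations, alpha %g, %s draws\n",
              length(x$fractions), min(x$fractions), max(x$fractions),
              x$iterations, x$alpha, x$mode))
  invisible(x)
}

#' Pooled read depth reachable from a DNA input mass
#'
#' Exome mode: haploid copies in the input times capture efficiency
#' gives the per-site depth; pooled depth multiplies by the number of
#' tracked variants and the kept fraction. WGS mode uses the fixed
#' coverage instead of input-derived depth.
#'
#' @param config a [sim_config()].
#' @param mass_ng input mass, ng (ignored in WGS mode).
#' @return pooled read count (rounded); zero depth is an error.
#' @export
sample_depth <- function(config, mass_ng = config$input_mass_ng[1L]) {
  if (is.null(config$coverage)) {
    copies <- mass_ng * 1000 / config$pg_per_haploid_genome
    pooled <- round(copies * config$capture_efficiency *
                    config$n_variants * config$kept_fraction)
  } else {
    pooled <- round(config$coverage * config$n_variants *
                    config$kept_fraction)
  }
  if (pooled <= 0) stop("pooled depth is zero; increase input or coverage")
  as.integer(pooled)
}

#' Simulate detection sensitivity over the fraction/mass grid
#'
#' For each (fraction, mass): draw mutant reads, test against the fixed
#' background pool with [fisher_one_sided()], and report the proportion
#' of iterations with p below `alpha`, with its Monte-Carlo standard
#' error. With `common_random = TRUE` one set of uniforms per mass is
#' reused across fractions (common random numbers), which makes the
#' sensitivity curve exactly monotone in the fraction.
#'
#' @param config a [sim_config()].
#' @param common_random reuse one uniform draw across fractions.
#' @return data.frame of class `sensitivity_curve`: `fraction`,
#'   `mass_ng`, `depth`, `sensitivity`, `se`; the config is attached as
#'   attribute `config`.
#' @export
simulate_sensitivity <- function(config, common_random = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  masses <- if (is.null(config$coverage)) config$input_mass_ng else NA_real_
  it <- config$iterations
  rows <- list()
  for (m in masses) {
    depth <- if (is.null(config$coverage)) sample_depth(config, m)
             else sample_depth(config)
    u <- if (common_random) stats::runif(it) else NULL
    for (f in config$fractions) {
      p_mut <- if (config$mode == "empirical") {
        round(config$empirical_pool * f) / config$empirical_pool
      } else f
      a <- if (common_random) stats::qbinom(u, depth, p_mut)
           else stats::rbinom(it, depth, p_mut)
      p <- fisher_one_sided(a, depth - a, config$bg_alt, config$bg_ref)
      s <- mean(p < config$alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, mass_ng = m, depth = depth, sensitivity = s,
        se = sqrt(s * (1 - s) / it))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("sensitivity_curve", "data.frame")
  out
}

#' Detection limit at a target sensitivity
#'
#' Per mass: the smallest grid fraction whose sensitivity reaches
#' `target`, refined by log-linear interpolation between the bracketing
#' grid points when the curve crosses between them. When no grid point
#' reaches the target the limit is beyond the simulated range and
#' reported as `NA`.
#'
#' @param curve a `sensitivity_curve` from [simulate_sensitivity()].
#' @param target target sensitivity (default 0.95).
#' @return data.frame: `mass_ng`, `limit_fraction`, `reciprocal`
#'   (`1 / limit_fraction`), `beyond_range`.
#' @export
detection_limit <- function(curve, target = 0.95) {
  one <- function(d) {
    d <- d[order(d$fraction), , drop = FALSE]
    i <- which(d$sensitivity >= target)[1L]
    if (is.na(i)) {
      return(data.frame(mass_ng = d$mass_ng[1L], limit_fraction = NA_real_,
                        reciprocal = NA_real_, beyond_range = TRUE))
    }
    f <- if (i == 1L || d$sensitivity[i - 1L] >= target) {
      d$fraction[i]
    } else {
      s0 <- d$sensitivity[i - 1L]
      s1 <- d$sensitivity[i]
      lf <- log(d$fraction[i - 1L]) +
        (target - s0) / (s1 - s0) * (log(d$fraction[i]) -
                                     log(d$fraction[i - 1L]))
      exp(lf)
    }
    data.frame(mass_ng = d$mass_ng[1L], limit_fraction = f,
               reciprocal = 1 / f, beyond_range = FALSE)
  }
  grp <- factor(curve$mass_ng, exclude = NULL)  # keep the NA mass of WGS mode
  out <- do.call(rbind, lapply(split(curve, grp), one))
  rownames(out) <- NULL
  out
}
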