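# Sequencing noise model: negative-binomial depth, binomial read
# sampling, a minimum-detectable-frequency filter, and an exact binomial
# test that calls a mutation "fixed" when the observed read counts are
# consistent with a true allele frequency of 0.5.

#' Sequencing model
#'
#' Parameters of the read-level observation model.  In `"perfect"` mode
#' true allele frequencies are observed directly (a mutation is fixed iff
#' its frequency is exactly 0.5) and the detection threshold is applied
#' to the true frequency.  In `"reads"` mode sequencing depth at each
#' locus is drawn from a negative binomial with mean `m` and variance
#' `v`, alternative-allele reads are binomial in the true frequency, the
#' detection threshold is applied to the observed frequency, and
#' fixation is decided by an exact binomial test of `q = 0.5` at level
#' `test_level`.
#'
#' @param mode `"perfect"` or `"reads"`.
#' @param m Mean sequencing depth (reads); required in reads mode.
#' @param v Depth variance; defaults to `1.1 * m`.  Must exceed `m`
#'   (the negative binomial is overdispersed relative to Poisson).
#' @param f_min Minimum detectable allele frequency in `[0, 0.5)`;
#'   records below it are dropped.
#' @param test_level Significance level of the fixation test.
#' @return A `seq_model` object.
#' @examples
#' seq_model("reads", m = 20)
#' seq_model("perfect", f_min = 0.05)
#' @export
seq_model <- function(mode = c("perfect", "reads"), m = NULL, v = NULL,
                      f_min = 0, test_level = 0.05) {
  mode <- match.arg(mode)
  stopifnot(f_min >= 0, f_min < 0.5, test_level > 0, test_level < 1)
  if (mode == "reads") {
    stopifnot(!is.null(m), m > 0)
    if (is.null(v)) v <- 1.1 * m
    if (v <= m) stop("depth variance v must exceed the mean m")
  } else {
    m <- NA_real_; v <- NA_real_
  }
  structure(list(mode = mode, m = m, v = v, f_min = f_min,
                 test_level = test_level),
            class = "seq_model")
}

#' @export
print.seq_model <- function(x, ...) {
  cat(sprintf("Sequencing model: %s mode", x$mode))
  if (x$mode == "reads")
    cat(sprintf(" (depth mean %g, variance %g)", x$m, x$v))
  cat(sprintf("\n  detection threshold: %g, fixation-test level: %g\n",
              x$f_min, x$test_level))
  invisible(x)
}

#' Negative-binomial depth parameters from mean and variance
#'
#' Solves the moment constraints of the negative binomial depth
#' distribution (number of successes `k` with success probability `p`
#' before the `t`-th failure; mean `p t / (1 - p)`, variance
#' `p t / (1 - p)^2`) for `(p, t)` given the mean `m` and variance `v`:
#' `p = 1 - m / v` and `t = m v / (v - m) - m`.
#'
#' @param m Mean depth, `0 < m < v`.
#' @param v Depth variance.
#' @return A named list with `p` and `t`.
#' @examples
#' depth_params_from_moments(20, 22)   # p = 1/11, t = 200
#' @export
depth_params_from_moments <- function(m, v) {
  stopifnot(m > 0)
  if (v <= m)
    stop("negative-binomial depth requires v > m (overdispersion)")
  list(p = 1 - m / v, t = m * v / (v - m) - m)
}

#' Draw sequencing depths
#'
#' Samples locus depths `k` from the negative binomial with pmf
#' `C(k + t - 1, k) p^k (1 - p)^t`.
#'
#' @param n Number of loci.
#' @param p,t Parameters from [depth_params_from_moments()].
#' @return Integer vector of depths.
#' @export
sample_depth <- function(n, p, t) {
  stopifnot(p > 0, p < 1, t > 0)
  stats::rnbinom(n, size = t, prob = 1 - p)
}

#' Draw alternative-allele read counts
#'
#' `n_a ~ Binomial(k, q)` reads support the mutated allele; the remaining
#' `k - n_a` reads carry the reference allele.
#'
#' @param k Depths (non-negative integers).
#' @param q True allele frequencies in `[0, 1]` (recycled against `k`).
#' @return Integer vector of alternative read counts.
#' @export
sample_reads <- function(k, q) {
  stopifnot(all(k >= 0), all(q >= 0 & q <= 1))
  stats::rbinom(length(k), size = k, prob = q)
}

# Vectorised two-sided exact binomial p-value for H0: q = q0, using the
# minimum-likelihood convention (sum of all outcome probabilities not
# exceeding that of the observed count), as in stats::binom.test.
binom_pvalue <- function(n_a, k, q0 = 0.5) {
  if (q0 == 0.5) {
    # symmetric null: two equal tails
    lo <- pmin(n_a, k - n_a)
    p <- stats::pbinom(lo, k, 0.5) +
      stats::pbinom(k - lo - 1L, k, 0.5, lower.tail = FALSE)
    pmin(1, p)
  } else {
    mapply(function(x, n) stats::binom.test(x, n, p = q0)$p.value,
           n_a, k)
  }
}

#' Exact binomial fixation call
#'
#' Tests `H0: q = 0.5` (one mutated allele in every diploid cell) with a
#' two-sided exact binomial test.  The mutation is called (potentially)
#' fixed when the test fails to reject at `test_level`.  Type II errors
#' deliberately pass through: frequencies near 0.5 are usually called
#' fixed, and the identical calling procedure is applied to simulated and
#' observed data so this introduces no bias in inference.
#'
#' @param n_a Alternative-allele read counts.
#' @param k Depths (>= 1).
#' @param test_level Significance level.
#' @return Logical vector: `TRUE` where the mutation is called fixed.
#' @examples
#' call_fixed(20, 40)   # perfectly balanced: fixed
#' call_fixed(2, 40)    # strongly unbalanced: not fixed
#' @export
call_fixed <- function(n_a, k, test_level = 0.05) {
  if (any(k < 1)) stop("fixation call undefined at zero depth")
  binom_pvalue(n_a, k, 0.5) >= test_level
}

#' Minimum-detectable-frequency filter
#'
#' Removes allele-frequency records below `f_min`, emulating the
#' inability of a variant caller to distinguish very low-frequency
#' mutations from sequencing error.
#'
#' @param freq Numeric vector of allele frequencies.
#' @param f_min Threshold in `[0, 0.5)`.
#' @return Logical vector: `TRUE` where the record is retained.
#' @export
detectable <- function(freq, f_min) {
  stopifnot(f_min >= 0, f_min < 0.5)
  freq >= f_min
}

#' Apply the sequencing model to a tumor sample
#'
#' Converts exact per-gland allele frequencies into the observation table
#' that the summary statistics operate on.  In perfect mode frequencies
#' pass through unchanged and a record is fixed iff its frequency is
#' exactly 0.5.  In reads mode each (gland, mutation) record receives an
#' independent depth `k`, alternative count `n_a ~ Binomial(k, freq)`,
#' observed frequency `n_a / k`, the detection filter (records with
#' `n_a = 0` or observed frequency below `f_min` are dropped, as a caller
#' cannot emit them), and an exact binomial fixation call.  The same
#' procedure is used for reference-table simulations and for observed
#' data.
#'
#' @param sample A `tumor_sample`.
#' @param model A [seq_model()].
#' @param seed Optional integer seed.
#' @return A `gland_obs` object: list with `records` (data frame
#'   `gland_id`, `half`, `mutation_id`, `obs_freq`, `fixed`, plus
#'   `depth`, `alt_reads` in reads mode) and `glands`.
#' @examples
#' s <- simulate_tumor(growth_params(2, 0.1, 0.8, n_fission_gens = 5, t3 = 5),
#'                     glands_per_half = 2, seed = 3)
#' obs <- sequence_sample(s, seq_model("reads", m = 20), seed = 4)
#' head(obs$records)
#' @export
sequence_sample <- function(sample, model, seed = NULL) {
  stopifnot(inherits(sample, "tumor_sample"), inherits(model, "seq_model"))
  if (!is.null(seed)) set.seed(seed)
  rec <- sample$records
  if (model$mode == "perfect") {
    keep <- detectable(rec$allele_freq, model$f_min)
    out <- data.frame(gland_id = rec$gland_id[keep],
                      half = rec$half[keep],
                      mutation_id = rec$mutation_id[keep],
                      obs_freq = rec$allele_freq[keep],
                      fixed = rec$allele_freq[keep] == 0.5,
                      stringsAsFactors = FALSE)
  } else {
    dp <- depth_params_from_moments(model$m, model$v)
    k <- sample_depth(nrow(rec), dp$p, dp$t)
    n_a <- sample_reads(k, rec$allele_freq)
    q_hat <- ifelse(k > 0, n_a / k, 0)
    keep <- n_a > 0 & detectable(q_hat, model$f_min)
    out <- data.frame(gland_id = rec$gland_id[keep],
                      half = rec$half[keep],
                      mutation_id = rec$mutation_id[keep],
                      obs_freq = q_hat[keep],
                      fixed = call_fixed(n_a[keep], k[keep],
                                         model$test_level),
                      depth = k[keep],
                      alt_reads = n_a[keep],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  new_gland_obs(out, sample$glands, model)
}

new_gland_obs <- function(records, glands, model = NULL) {
  structure(list(records = records, glands = glands, model = model),
            class = "gland_obs")
}

#' @export
print.gland_obs <- function(x, ...) {
  cat(sprintf("Gland observations: %d glands, %d records (%s mode)\n",
              nrow(x$glands), nrow(x$records),
              if (is.null(x$model)) "external" else x$model$mode))
  invisible(x)
}
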