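#' Growth-model parameters
#'
#' Bundle and validate the generative parameters of the three-phase tumor
#' growth model: formation of the first gland from a single transformed
#' cell, exponential doubling of gland number by fission, and a
#' constant-size phase in which each gland is maintained by cancer
#' stem cell (CSC) division.
#'
#' Mutation rates are expected numbers of new point mutations per daughter
#' cell per division (exome scale).  `alpha` applies to divisions before
#' the first gland has reached `n_csc` CSCs; `beta` applies to every
#' division thereafter (gland fission regrowth and the constant-size
#' phase).  `r` is the probability that a CSC divides asymmetrically
#' (one CSC daughter, one differentiating daughter); with probability
#' `(1 - r) / 2` it divides into two CSCs and with probability
#' `(1 - r) / 2` into two non-CSCs, which keeps the expected CSC count
#' constant.
#'
#' @param alpha Mutation rate before first-gland formation (>= 0).
#' @param beta Mutation rate after first-gland formation (>= 0).
#' @param r Probability of asymmetric CSC division, in `[0, 1]`
#'   (biologically plausible values lie in `[0.5, 1]`).
#' @param n_csc Number of CSCs per gland (integer >= 1).
#' @param t3 Number of generations in the constant-size phase (>= 0).
#' @param n_fission_gens Number of exponential-phase generations during
#'   which glands double in number (>= 0).
#' @param gland_cells Nominal total cells per gland.  Reporting metadata
#'   only: allele frequencies are computed over the CSC pool, the
#'   differentiated compartment being assumed to mirror it.
#' @param fission_mode How CSCs are apportioned when a gland splits.
#'   `"bottleneck"` (default): each daughter gland is founded by a single
#'   CSC drawn without replacement from the parent pool and regrown
#'   clonally to `n_csc` CSCs.  `"split"`: every parent CSC divides once
#'   and the `2 * n_csc` daughters are partitioned at random into the two
#'   glands.
#'
#' @return An object of class `"growth_params"` (a named list).
#' @examples
#' p <- growth_params(alpha = 2, beta = 0.1, r = 0.8)
#' p$n_csc
#' @export
growth_params <- function(alpha, beta, r, n_csc = 32L, t3 = 100L,
                          n_fission_gens = 19L, gland_cells = 10000L,
                          fission_mode = c("bottleneck", "split")) {
  fission_mode <- match.arg(fission_mode)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha >= 0,
    is.numeric(beta), length(beta) == 1L, is.finite(beta), beta >= 0,
    is.numeric(r), length(r) == 1L, r >= 0, r <= 1,
    is.numeric(n_csc), length(n_csc) == 1L, n_csc >= 1,
    n_csc == as.integer(n_csc),
    is.numeric(t3), length(t3) == 1L, t3 >= 0, t3 == as.integer(t3),
    is.numeric(n_fission_gens), length(n_fission_gens) == 1L,
    n_fission_gens >= 0, n_fission_gens == as.integer(n_fission_gens)
  )
  structure(
    list(alpha = alpha, beta = beta, r = r,
         n_csc = as.integer(n_csc), t3 = as.integer(t3),
         n_fission_gens = as.integer(n_fission_gens),
         gland_cells = as.integer(gland_cells),
         fission_mode = fission_mode),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Tumor growth parameters\n")
  cat(sprintf("  alpha (pre-gland rate):  %g\n", x$alpha))
  cat(sprintf("  beta  (post-gland rate): %g\n", x$beta))
  cat(sprintf("  r (asymmetric division): %g\n", x$r))
  cat(sprintf("  CSCs per gland:          %d\n", x$n_csc))
  cat(sprintf("  fission generations:     %d\n", x$n_fission_gens))
  cat(sprintf("  constant-phase length:   %d\n", x$t3))
  cat(sprintf("  fission mode:            %s\n", x$fission_mode))
  invisible(x)
}

#' Tumor size bookkeeping
#'
#' Deterministic size accounting for the exponential gland-fission phase:
#' starting from a single gland, glands double every generation, so after
#' `n_fission_gens` generations the tumor holds `2^n_fission_gens` glands
#' and `2^n_fission_gens * gland_cells` cells.  With the defaults
#' (19 generations, 10,000 cells per gland) this is ~5e5 glands and
#' ~4e9 cells, the size of a roughly 4 cm^3 colon tumor.
#'
#' @param params A [growth_params()] object.
#' @return A named list with `n_glands` and `n_cells`.
#' @examples
#' tumor_size(growth_params(1, 0.1, 0.8))
#' @export
tumor_size <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  n_glands <- 2^params$n_fission_gens
  list(n_glands = n_glands, n_cells = n_glands * params$gland_cells)
}

#' Expected whole-genome mutations per cell division
#'
#' Converts a per-base per-division mutation rate into the expected
#' number of new mutations per daughter cell per division over a genome
#' (or exome) of a given size.  The normal spontaneous rate of 1e-10 to
#' 1e-9 per base per division corresponds to 0.3--3 mutations per
#' division genome-wide (3e9 bases), or 0.003--0.03 per exome (3e7
#' bases).
#'
#' @param per_base_rate Mutation rate per base per cell division.
#' @param n_bases Number of bases considered (default: human genome,
#'   3e9).
#' @return Expected number of mutations per daughter cell per division.
#' @examples
#' mutations_per_division(1e-10)            # 0.3, genome-wide lower bound
#' mutations_per_division(1e-9, n_bases = 3e7)  # exome scale
#' @export
mutations_per_division <- function(per_base_rate, n_bases = 3e9) {
  stopifnot(per_base_rate >= 0, n_bases > 0)
  per_base_rate * n_bases
}

#' Minimum detectable allele frequency at a given sequencing depth
#'
#' A variant supported by fewer than one read cannot be observed, so at
#' depth `k` the smallest observable allele frequency is `1/k` (e.g. 0.05
#' at depth 20).
#'
#' @param depth Sequencing depth (reads), > 0.
#' @return The minimum detectable allele frequency `1/depth`.
#' @examples
#' min_detectable_af(20)
#' @export
min_detectable_af <- function(depth) {
  stopifnot(depth > 0)
  1 / depth
}

# Deterministic 32-bit substream seed derived from a master seed and an
# index, so that per-tumor simulations are reproducible and independent
# of evaluation order.
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) * 48271 + index * 16807) %% 2147483629) + 1L
}
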