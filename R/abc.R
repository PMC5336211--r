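# Rejection ABC with weighted summary statistics: prior sampling,
# reference-table construction, the three statistic-weighting schemes
# (equal, local linear regression, global linear regression), rejection,
# and posterior summaries.

#' Prior specification
#'
#' Independent uniform priors on the three inferred growth parameters.
#' Defaults: `alpha ~ Unif(0, 5)`, `beta ~ Unif(0, 1)`,
#' `r ~ Unif(0.5, 1)` — ranges chosen to comfortably cover mutation
#' rates reported for tumors (0.015--0.15 per division per exome) and
#' the biologically meaningful asymmetric-division regime.
#'
#' @param alpha,beta,r Numeric length-2 vectors `c(lower, upper)`.
#' @return A `prior_spec` object.
#' @examples
#' prior_spec()
#' @export
prior_spec <- function(alpha = c(0, 5), beta = c(0, 1), r = c(0.5, 1)) {
  p <- list(alpha = alpha, beta = beta, r = r)
  for (nm in names(p)) {
    b <- p[[nm]]
    stopifnot(length(b) == 2L, b[1] <= b[2])
  }
  structure(p, class = "prior_spec")
}

#' Draw parameters from the prior
#'
#' @param priors A [prior_spec()].
#' @param n Number of independent draws.
#' @param seed Optional integer seed.
#' @return An `n x 3` numeric matrix with columns `alpha`, `beta`, `r`.
#' @export
sample_prior <- function(priors, n, seed = NULL) {
  stopifnot(inherits(priors, "prior_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(priors, function(b) stats::runif(n, b[1], b[2]),
                numeric(n))
  if (n == 1L) out <- matrix(out, nrow = 1L,
                             dimnames = list(NULL, names(priors)))
  out
}

# Robust per-statistic scale for standardisation: median absolute
# deviation, falling back to the standard deviation when the MAD is 0
# (e.g. a statistic that is 0 in most simulations), and to 1 when both
# vanish.
stat_scale <- function(stats_mat) {
  apply(stats_mat, 2, function(x) {
    s <- stats::mad(x)
    if (s == 0) s <- stats::sd(x)
    if (is.na(s) || s == 0) s <- 1
    s
  })
}

#' Build an ABC reference table
#'
#' Draws `n` parameter vectors from the prior and, for each, simulates a
#' tumor, applies the sequencing model, and computes the nine summary
#' statistics.  Row `i` of `stats` was generated by row `i` of `theta`.
#' Also records the per-statistic robust scale used to standardise
#' distances.  Each row runs on a deterministic substream of `seed`, so
#' a rerun with the same arguments reproduces the table exactly.
#'
#' @param priors A [prior_spec()].
#' @param n Number of simulations (rows).
#' @param glands_per_half Glands sampled per tumor half.
#' @param model A [seq_model()].
#' @param base_params A [growth_params()] supplying the fixed constants
#'   (`n_csc`, `t3`, `n_fission_gens`, `fission_mode`); its `alpha`,
#'   `beta`, `r` are overwritten by the prior draws.
#' @param seed Integer master seed.
#' @return A `ref_table`: list with `theta` (n x 3), `stats` (n x 9),
#'   `scale`, and the generating configuration.
#' @export
build_reference_table <- function(priors, n, glands_per_half, model,
                                  base_params = growth_params(0, 0, 0.5),
                                  seed = 1L) {
  stopifnot(inherits(priors, "prior_spec"), n >= 1,
            inherits(model, "seq_model"),
            inherits(base_params, "growth_params"))
  theta <- sample_prior(priors, n, seed = derive_seed(seed, 0L))
  stats_mat <- matrix(NA_real_, n, 9,
                      dimnames = list(NULL, summary_stat_names()))
  for (i in seq_len(n)) {
    p <- base_params
    p$alpha <- theta[i, "alpha"]
    p$beta <- theta[i, "beta"]
    p$r <- theta[i, "r"]
    s <- simulate_tumor(p, glands_per_half, seed = derive_seed(seed, i))
    obs <- sequence_sample(s, model)
    stats_mat[i, ] <- summarize_sample(obs)
  }
  new_ref_table(theta, stats_mat, priors, model, base_params,
                glands_per_half, seed)
}

new_ref_table <- function(theta, stats_mat, priors, model, base_params,
                          glands_per_half, seed) {
  structure(list(theta = theta, stats = stats_mat,
                 scale = stat_scale(stats_mat),
                 priors = priors, model = model,
                 base_params = base_params,
                 glands_per_half = glands_per_half, seed = seed),
            class = "ref_table")
}

#' @export
print.ref_table <- function(x, ...) {
  cat(sprintf("ABC reference table: %d simulations, %d parameters, %d statistics\n",
              nrow(x$theta), ncol(x$theta), ncol(x$stats)))
  invisible(x)
}

#' Weighted Euclidean distance between summary vectors
#'
#' `d(S', S) = || (S' - S) W^T ||_2` computed on standardised
#' statistics:
#' `sqrt( sum_m ( w_m * (s'_m - s_m) / scale_m )^2 )`.
#'
#' @param s_obs,s_sim Numeric summary vectors of equal length (or a
#'   matrix of simulated summaries, one row per simulation, for
#'   `s_sim`).
#' @param w Non-negative weights, one per statistic.
#' @param scale Positive per-statistic scales (default 1: raw
#'   differences).
#' @return A non-negative scalar (or vector, one per row of `s_sim`).
#' @examples
#' weighted_distance(rep(0, 9), c(3, 4, rep(0, 7)), rep(1/9, 9))  # 5/9
#' @export
weighted_distance <- function(s_obs, s_sim, w, scale = 1) {
  if (is.matrix(s_sim)) {
    if (ncol(s_sim) != length(s_obs)) stop("summary length mismatch")
    z <- sweep(s_sim, 2, s_obs, "-")
    z <- sweep(z, 2, w / scale, "*")
    sqrt(rowSums(z^2))
  } else {
    if (length(s_sim) != length(s_obs)) stop("summary length mismatch")
    sqrt(sum((w * (s_sim - s_obs) / scale)^2))
  }
}

new_weight_vector <- function(w, scheme, r_squared = NULL, eta = NA_real_) {
  w <- w / sum(w)
  structure(list(w = w, scheme = scheme, r_squared = r_squared,
                 eta = eta), class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("Summary-statistic weights (%s scheme)\n", x$scheme))
  print(round(x$w, 4))
  invisible(x)
}

#' Equal statistic weights
#'
#' The baseline weighting: each of the `M` statistics receives weight
#' `1/M`.
#'
#' @param m Number of statistics.
#' @return A `weight_vector`.
#' @export
equal_weights <- function(m = 9L) {
  stopifnot(m >= 1)
  new_weight_vector(stats::setNames(rep(1 / m, m),
                                    if (m == 9L) summary_stat_names()
                                    else NULL),
                    scheme = "equal")
}

# R^2 of the simple linear regression of y on x; 0 when x (or y) has no
# variance, so uninformative statistics receive no weight.
r_squared <- function(x, y) {
  if (length(x) < 3L) return(0)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (is.na(sx) || is.na(sy) || sx == 0 || sy == 0) return(0)
  stats::cor(x, y)^2
}

normalize_r2 <- function(r2) {
  if (sum(r2) == 0) rep(1 / length(r2), length(r2)) else r2 / sum(r2)
}

#' Global-regression statistic weights
#'
#' For the target parameter, regresses the generating parameter values on
#' each summary statistic over the full reference table; the R-squared of
#' each simple regression measures how informative that statistic is for
#' the parameter.  The nine R-squared values are normalised to sum to 1
#' and used as the statistic weights.  When every R-squared is 0 the
#' weights fall back to equal.
#'
#' @param table A `ref_table`.
#' @param param Target parameter: `"alpha"`, `"beta"` or `"r"` (or a
#'   column index).
#' @return A `weight_vector` carrying the raw `r_squared` values.
#' @export
global_regression_weights <- function(table, param) {
  stopifnot(inherits(table, "ref_table"), nrow(table$theta) >= 3L)
  theta_l <- table$theta[, param]
  r2 <- apply(table$stats, 2, r_squared, y = theta_l)
  new_weight_vector(normalize_r2(r2), scheme = "global", r_squared = r2)
}

#' Local-regression statistic weights
#'
#' As [global_regression_weights()], but each statistic's regression is
#' fit only in the neighbourhood of the observed data: the
#' `ceil(eta * N)` reference rows whose value of that statistic is
#' closest (1-D absolute distance, ties broken by row index) to the
#' observed value.  Local fits track parameter-statistic relationships
#' near the data but are noisier than the global fit.
#'
#' @inheritParams global_regression_weights
#' @param s_obs Observed summary vector.
#' @param eta Neighbourhood fraction in `(0, 1]`; `eta = 1` reproduces
#'   the global weights.
#' @return A `weight_vector`.
#' @export
local_regression_weights <- function(table, param, s_obs, eta = 0.1) {
  stopifnot(inherits(table, "ref_table"), eta > 0, eta <= 1,
            length(s_obs) == ncol(table$stats))
  n <- nrow(table$theta)
  k <- ceiling(eta * n)
  if (k < 3L) stop("local neighbourhood must contain at least 3 rows")
  theta_l <- table$theta[, param]
  r2 <- vapply(seq_len(ncol(table$stats)), function(m) {
    d <- abs(table$stats[, m] - s_obs[m])
    nb <- order(d, seq_along(d))[seq_len(k)]
    r_squared(table$stats[nb, m], theta_l[nb])
  }, numeric(1))
  names(r2) <- colnames(table$stats)
  new_weight_vector(normalize_r2(r2), scheme = "local", r_squared = r2,
                    eta = eta)
}

#' Statistic weights for a scheme
#'
#' Dispatcher over the three weighting schemes.
#'
#' @inheritParams local_regression_weights
#' @param scheme `"equal"`, `"global"` or `"local"`.
#' @return A `weight_vector`.
#' @export
scheme_weights <- function(table, param, s_obs = NULL,
                           scheme = c("equal", "global", "local"),
                           eta = 0.1) {
  scheme <- match.arg(scheme)
  switch(scheme,
         equal = equal_weights(ncol(table$stats)),
         global = global_regression_weights(table, param),
         local = local_regression_weights(table, param, s_obs, eta))
}

#' Rejection ABC
#'
#' Computes the weighted distance between the observed summaries and
#' every reference-table row, and accepts the `floor(accept_fraction * N)`
#' rows with the smallest distance (equivalently, the threshold epsilon
#' is that order statistic of the distances).
#'
#' @param table A `ref_table`.
#' @param s_obs Observed summary vector.
#' @param w A `weight_vector` (or bare numeric weights).
#' @param accept_fraction Fraction of rows to accept, in `(0, 1]`.
#' @return A `posterior_sample`: list with `theta` (accepted parameter
#'   rows), `epsilon`, `distances`, and the acceptance settings.
#' @export
abc_reject <- function(table, s_obs, w, accept_fraction = 0.01) {
  stopifnot(inherits(table, "ref_table"),
            accept_fraction > 0, accept_fraction <= 1)
  wv <- if (inherits(w, "weight_vector")) w$w else w
  d <- weighted_distance(s_obs, table$stats, wv, table$scale)
  n_acc <- max(1L, floor(accept_fraction * nrow(table$theta)))
  idx <- order(d)[seq_len(n_acc)]
  structure(list(theta = table$theta[idx, , drop = FALSE],
                 index = idx,
                 epsilon = max(d[idx]),
                 distances = d,
                 accept_fraction = accept_fraction,
                 weights = wv,
                 priors = table$priors),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("ABC posterior sample: %d accepted draws (epsilon = %.4g)\n",
              nrow(x$theta), x$epsilon))
  invisible(x)
}

#' Posterior mean, standard deviation and mode
#'
#' Summarises the accepted draws of one parameter.  The mode is the
#' argmax of a Gaussian kernel density estimate (Silverman's rule,
#' 512-point grid over the prior support).  With fewer than 2 draws the
#' standard deviation is `NA`; with fewer than 5 the mode is `NA`.
#'
#' @param post A `posterior_sample` from [abc_reject()].
#' @param param Parameter name or column index.
#' @return Named numeric vector `mean`, `sd`, `mode`.
#' @export
posterior_summary <- function(post, param) {
  stopifnot(inherits(post, "posterior_sample"))
  x <- post$theta[, param]
  out <- c(mean = mean(x), sd = NA_real_, mode = NA_real_)
  if (length(x) >= 2L) out["sd"] <- stats::sd(x)
  if (length(x) >= 5L && out["sd"] > 0) {
    support <- if (!is.null(post$priors) && is.character(param))
      post$priors[[param]] else range(x)
    dens <- stats::density(x, bw = "nrd0", n = 512,
                           from = support[1], to = support[2])
    out["mode"] <- dens$x[which.max(dens$y)]
  } else if (length(x) >= 5L) {
    out["mode"] <- x[1]
  }
  out
}
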