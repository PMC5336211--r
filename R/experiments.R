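# Scripted parameter-recovery studies: simulate test tumors with known
# generating parameters, run ABC against a reference table, and tabulate
# posterior mean/sd against the truth under different observation
# conditions (weighting scheme, detection threshold, glands sampled per
# half, sequencing depth).
#
# All conditions of a study share one pool of simulated tumors: a tumor
# is simulated once at the largest glands-per-half requested, and each
# condition then applies its own gland subset and sequencing model.
# This is valid because conditions differ only in the observation layer,
# and it keeps the study tractable on a single core.

#' Observation condition for a recovery study
#'
#' @param model A [seq_model()].
#' @param glands_per_half Glands used per half under this condition
#'   (must not exceed the number simulated).
#' @return A named list.
#' @export
study_condition <- function(model, glands_per_half = 6L) {
  stopifnot(inherits(model, "seq_model"), glands_per_half >= 1)
  list(model = model, glands_per_half = as.integer(glands_per_half))
}

#' Condition sets for the four simulation-study designs
#'
#' * `"weights"`: perfect data, 6 glands/half — the weighting-scheme
#'   comparison.
#' * `"threshold"`: perfect data at minimum detectable allele
#'   frequencies 0.001 and 0.05.
#' * `"glands"`: perfect data with 1 vs 6 glands sampled per half.
#' * `"depth"`: read-level data at mean depths 20 and 80
#'   (variance `1.1 m`).
#'
#' @param design Study design name.
#' @return Named list of [study_condition()]s.
#' @export
study_conditions <- function(design = c("weights", "threshold", "glands",
                                        "depth")) {
  design <- match.arg(design)
  switch(design,
    weights = list(
      perfect = study_condition(seq_model("perfect"), 6L)),
    threshold = list(
      fmin_0.001 = study_condition(seq_model("perfect", f_min = 0.001), 6L),
      fmin_0.05 = study_condition(seq_model("perfect", f_min = 0.05), 6L)),
    glands = list(
      gph_1 = study_condition(seq_model("perfect"), 1L),
      gph_6 = study_condition(seq_model("perfect"), 6L)),
    depth = list(
      depth_20 = study_condition(seq_model("reads", m = 20), 6L),
      depth_80 = study_condition(seq_model("reads", m = 80), 6L))
  )
}

# Keep the first g glands of each half (sampled glands are exchangeable,
# so any fixed subset is a uniform subsample).
subset_glands <- function(sample, g) {
  keep <- unlist(lapply(split(sample$glands$gland_id, sample$glands$half),
                        utils::head, g), use.names = FALSE)
  out <- sample
  out$glands <- sample$glands[sample$glands$gland_id %in% keep, ,
                              drop = FALSE]
  out$records <- sample$records[sample$records$gland_id %in% keep, ,
                                drop = FALSE]
  out$glands_per_half <- as.integer(g)
  out
}

#' All observation conditions of the desk-scale simulation study
#'
#' The union of the four designs, sharing one simulated tumor pool:
#' perfect data at 6 glands/half, the two detection thresholds, the
#' 1-gland/half subsample, and the two read-depth conditions.
#'
#' @return Named list of [study_condition()]s.
#' @export
desk_recovery_conditions <- function() {
  c(list(perfect = study_condition(seq_model("perfect"), 6L)),
    study_conditions("threshold"),
    list(gph_1 = study_condition(seq_model("perfect"), 1L)),
    study_conditions("depth"))
}

#' Run a parameter-recovery study
#'
#' Draws `n_ref + n_test` parameter vectors from the prior, simulates one
#' tumor per vector, and computes the nine summary statistics under every
#' condition.  The first `n_ref` tumors form the per-condition reference
#' tables; the remaining `n_test` act as test tumors with known
#' generating parameters.  For each condition, test tumor, weighting
#' scheme, and parameter, rejection ABC yields a posterior sample whose
#' mean and standard deviation are tabulated against the truth.
#'
#' @param conditions Named list of [study_condition()]s (see
#'   [study_conditions()]).
#' @param n_ref Reference-table size.
#' @param n_test Number of test tumors.
#' @param priors A [prior_spec()].
#' @param base_params [growth_params()] carrying the fixed constants
#'   (CSC count, phase lengths, fission mode).
#' @param schemes Weighting schemes to evaluate.
#' @param eta Local-regression neighbourhood fraction.
#' @param accept_fraction ABC acceptance fraction.
#' @param seed Master seed; every tumor runs on a derived substream.
#' @return A `recovery_result`: list with `results` (long data frame:
#'   `condition`, `scheme`, `param`, `tumor`, `true`, `post_mean`,
#'   `post_sd`), `theta_test`, and the settings.
#' @examples
#' \donttest{
#' st <- recovery_study(study_conditions("weights"), n_ref = 200,
#'                      n_test = 5, seed = 1)
#' recovery_metrics(st)
#' }
#' @export
recovery_study <- function(conditions, n_ref = 5000L, n_test = 50L,
                           priors = prior_spec(),
                           base_params = growth_params(0, 0, 0.5),
                           schemes = c("equal", "local", "global"),
                           eta = 0.1, accept_fraction = 0.02,
                           seed = 1L) {
  stopifnot(length(conditions) >= 1L, n_ref >= 3L, n_test >= 1L)
  schemes <- match.arg(schemes, several.ok = TRUE)
  n_all <- n_ref + n_test
  max_gph <- max(vapply(conditions, `[[`, integer(1), "glands_per_half"))
  theta <- sample_prior(priors, n_all, seed = derive_seed(seed, 0L))

  stat_arr <- array(NA_real_, c(n_all, length(conditions), 9),
                    dimnames = list(NULL, names(conditions),
                                    summary_stat_names()))
  for (i in seq_len(n_all)) {
    p <- base_params
    p$alpha <- theta[i, "alpha"]
    p$beta <- theta[i, "beta"]
    p$r <- theta[i, "r"]
    set.seed(derive_seed(seed, i))
    sim <- simulate_tumor(p, max_gph)
    for (ci in seq_along(conditions)) {
      cond <- conditions[[ci]]
      s <- if (cond$glands_per_half < max_gph)
        subset_glands(sim, cond$glands_per_half) else sim
      stat_arr[i, ci, ] <- summarize_sample(sequence_sample(s, cond$model))
    }
  }

  params <- colnames(theta)
  rows <- list()
  for (ci in seq_along(conditions)) {
    cond_name <- names(conditions)[ci]
    tab <- new_ref_table(theta[seq_len(n_ref), , drop = FALSE],
                         stat_arr[seq_len(n_ref), ci, ],
                         priors, conditions[[ci]]$model, base_params,
                         conditions[[ci]]$glands_per_half, seed)
    w_global <- lapply(params, function(pp) global_regression_weights(tab, pp))
    names(w_global) <- params
    w_equal <- equal_weights(9L)
    for (t in seq_len(n_test)) {
      i <- n_ref + t
      s_obs <- stat_arr[i, ci, ]
      post_equal <- if ("equal" %in% schemes)
        abc_reject(tab, s_obs, w_equal, accept_fraction)
      for (pp in params) {
        for (sch in schemes) {
          post <- switch(sch,
            equal = post_equal,
            global = abc_reject(tab, s_obs, w_global[[pp]], accept_fraction),
            local = abc_reject(tab, s_obs,
                               local_regression_weights(tab, pp, s_obs, eta),
                               accept_fraction))
          ps <- posterior_summary(post, pp)
          rows[[length(rows) + 1L]] <- data.frame(
            condition = cond_name, scheme = sch, param = pp, tumor = t,
            true = theta[i, pp], post_mean = ps[["mean"]],
            post_sd = ps[["sd"]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(results = do.call(rbind, rows),
                 theta_test = theta[n_ref + seq_len(n_test), , drop = FALSE],
                 conditions = conditions, n_ref = n_ref, n_test = n_test,
                 schemes = schemes, eta = eta,
                 accept_fraction = accept_fraction, seed = seed),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "Recovery study: %d conditions, %d test tumors, %d-row reference table\n",
    length(x$conditions), x$n_test, x$n_ref))
  print(recovery_metrics(x))
  invisible(x)
}

#' Aggregate recovery metrics
#'
#' Per condition, scheme and parameter: the Spearman rank correlation
#' between posterior mean and generating value, the mean absolute bias
#' of the posterior mean, and the mean posterior standard deviation.
#'
#' @param study A `recovery_result` from [recovery_study()].
#' @return A data frame, one row per condition x scheme x parameter.
#' @export
recovery_metrics <- function(study) {
  stopifnot(inherits(study, "recovery_result"))
  res <- study$results
  grp <- interaction(res$condition, res$scheme, res$param, drop = TRUE)
  out <- do.call(rbind, lapply(split(res, grp), function(d) {
    data.frame(condition = d$condition[1], scheme = d$scheme[1],
               param = d$param[1],
               rank_cor = if (nrow(d) >= 3L)
                 stats::cor(d$post_mean, d$true, method = "spearman")
               else NA_real_,
               mean_abs_bias = mean(abs(d$post_mean - d$true)),
               mean_post_sd = mean(d$post_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Paired comparison of posterior summaries between two conditions
#'
#' For one parameter (and scheme), computes the per-tumor paired
#' differences in posterior standard deviation between two conditions of
#' the same study, with the mean difference and its Monte-Carlo standard
#' error.  Tumors are identical across conditions, so pairing removes
#' the between-tumor variance.
#'
#' @param study A `recovery_result`.
#' @param cond_a,cond_b Condition names.
#' @param param Parameter name.
#' @param scheme Scheme name.
#' @param what Column to compare (`"post_sd"` or `"post_mean"`).
#' @return Named list: `mean_diff` (a - b), `se` and the per-tumor
#'   differences.
#' @export
condition_contrast <- function(study, cond_a, cond_b, param,
                               scheme = "global", what = "post_sd") {
  res <- study$results
  pick <- function(cc) {
    d <- res[res$condition == cc & res$param == param &
               res$scheme == scheme, ]
    d[order(d$tumor), what]
  }
  da <- pick(cond_a); db <- pick(cond_b)
  stopifnot(length(da) == length(db), length(da) >= 2L)
  diffs <- da - db
  list(mean_diff = mean(diffs),
       se = stats::sd(diffs) / sqrt(length(diffs)),
       diffs = diffs)
}

#' Write deterministic test fixtures
#'
#' Generates the small fixture bundle used by the test suite: the toy
#' two-gland observation table, a 200-row reference table built from a
#' reduced simulator configuration, and a synthetic pair of
#' MuTect-call-stats-style files (one per tumor half).  Byte-stable for
#' a given seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the paths written.
#' @export
make_fixtures <- function(dir = tempfile("fixtures"), seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  toy <- toy_gland_obs()
  p_toy <- file.path(dir, "toy_sample.tsv")
  utils::write.table(toy$records, p_toy, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p_toy)

  base <- growth_params(0, 0, 0.5, n_csc = 16L, t3 = 10L,
                        n_fission_gens = 6L)
  tab <- build_reference_table(prior_spec(), n = 200L,
                               glands_per_half = 2L,
                               model = seq_model("perfect"),
                               base_params = base, seed = seed)
  p_tab <- file.path(dir, "ref_table_200.tsv")
  utils::write.table(
    data.frame(tab$theta, tab$stats, check.names = FALSE),
    p_tab, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p_tab)

  sim <- simulate_tumor(growth_params(2, 0.1, 0.8, n_csc = 16L, t3 = 10L,
                                      n_fission_gens = 6L),
                        glands_per_half = 1L, seed = derive_seed(seed, 7L))
  obs <- sequence_sample(sim, seq_model("reads", m = 40),
                         seed = derive_seed(seed, 8L))
  for (h in c("A", "B")) {
    p_mu <- file.path(dir, sprintf("synthetic_mutect_half%s.call_stats.txt", h))
    write_mutect_like(obs, half = h, path = p_mu)
    paths <- c(paths, p_mu)
  }
  invisible(paths)
}
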