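# ABC machinery tests: priors, weighted distances, the three weighting
# schemes, rejection, and posterior summaries, each against brute-force
# or closed-form oracles.

make_synthetic_table <- function(theta, stats_mat,
                                 priors = prior_spec()) {
  glandabc:::new_ref_table(theta, stats_mat, priors, seq_model("perfect"),
                           growth_params(0, 0, 0.5), 6L, 1L)
}

test_that("prior draws respect their supports and moments", {
  th <- sample_prior(prior_spec(), 1e5, seed = 99)
  expect_true(all(th[, "alpha"] >= 0 & th[, "alpha"] <= 5))
  expect_true(all(th[, "beta"] >= 0 & th[, "beta"] <= 1))
  expect_true(all(th[, "r"] >= 0.5 & th[, "r"] <= 1))
  se <- sqrt(1 / 12 / 1e5)
  expect_lt(abs(mean(th[, "beta"]) - 0.5), 3 * se)
})

test_that("the weighted distance matches hand and brute-force
           computations", {
  w9 <- rep(1 / 9, 9)
  expect_equal(weighted_distance(rep(0, 9), rep(0, 9), w9), 0)
  expect_equal(weighted_distance(rep(0, 9), c(3, 4, rep(0, 7)), w9), 5 / 9)

  set.seed(5)
  s_obs <- rnorm(9); s_sim <- rnorm(9)
  w <- runif(9); w <- w / sum(w)
  sc <- runif(9, 0.5, 2)
  brute <- sqrt(sum((w * (s_sim - s_obs) / sc)^2))
  expect_equal(weighted_distance(s_obs, s_sim, w, sc), brute)

  # doubling one weight doubles that component's contribution
  w2 <- w; w2[3] <- 2 * w[3]
  comp <- function(wv) (wv[3] * (s_sim[3] - s_obs[3]) / sc[3])^2
  expect_equal(weighted_distance(s_obs, s_sim, w2, sc)^2 -
                 weighted_distance(s_obs, s_sim, w, sc)^2,
               comp(w2) - comp(w))

  # scale equivariance: scaling a statistic and its scale together is a
  # no-op
  s_obs2 <- s_obs; s_sim2 <- s_sim; sc2 <- sc
  s_obs2[4] <- 10 * s_obs2[4]; s_sim2[4] <- 10 * s_sim2[4]
  sc2[4] <- 10 * sc2[4]
  expect_equal(weighted_distance(s_obs2, s_sim2, w, sc2),
               weighted_distance(s_obs, s_sim, w, sc))

  # symmetry and the matrix form
  expect_equal(weighted_distance(s_sim, s_obs, w, sc),
               weighted_distance(s_obs, s_sim, w, sc))
  mat <- rbind(s_sim, s_obs)
  expect_equal(weighted_distance(s_obs, mat, w, sc),
               c(brute, 0), ignore_attr = TRUE)
  expect_error(weighted_distance(s_obs, s_sim[1:5], w), "mismatch")
})

test_that("equal weights are uniform and normalized", {
  w <- equal_weights(9)
  expect_equal(unname(w$w), rep(1 / 9, 9))
  expect_equal(sum(w$w), 1)
  expect_identical(w$scheme, "equal")
})

test_that("global regression weights concentrate on the informative
           statistic", {
  set.seed(6)
  n <- 2000
  s3 <- runif(n)
  stats_mat <- cbind(matrix(rnorm(n * 2), n), s3,
                     matrix(rnorm(n * 6), n))
  colnames(stats_mat) <- glandabc:::summary_stat_names()
  theta <- cbind(alpha = 2 * s3 + rnorm(n, sd = 1e-4),
                 beta = runif(n), r = runif(n, 0.5, 1))
  tab <- make_synthetic_table(theta, stats_mat)
  w <- global_regression_weights(tab, "alpha")
  expect_gt(w$w[["s3"]], 0.95)
  expect_equal(sum(w$w), 1)

  # a parameter unrelated to every statistic: near-uniform weights
  w_null <- global_regression_weights(tab, "beta")
  expect_true(all(w_null$w < 0.4))
  expect_equal(sum(w_null$w), 1)
})

test_that("local regression weights reduce to global at eta = 1 and see
           local structure", {
  set.seed(7)
  n <- 1000
  stats_mat <- matrix(runif(n * 9), n)
  colnames(stats_mat) <- glandabc:::summary_stat_names()
  theta <- cbind(alpha = runif(n, 0, 5), beta = runif(n),
                 r = runif(n, 0.5, 1))
  tab <- make_synthetic_table(theta, stats_mat)
  s_obs <- stats_mat[1, ]
  wl <- local_regression_weights(tab, "alpha", s_obs, eta = 1)
  wg <- global_regression_weights(tab, "alpha")
  expect_equal(wl$w, wg$w)

  # theta depends on s2 only near the observed value (piecewise flat
  # elsewhere): the local weight on s2 must exceed the global one
  s2 <- stats_mat[, 2]
  near <- abs(s2 - 0.5) < 0.05
  theta2 <- theta
  theta2[, "alpha"] <- ifelse(near, 50 * s2, 2.5) + rnorm(n, sd = 1e-3)
  tab2 <- make_synthetic_table(theta2, stats_mat)
  s_obs2 <- s_obs; s_obs2[2] <- 0.5
  w_loc <- local_regression_weights(tab2, "alpha", s_obs2, eta = 0.08)
  w_glo <- global_regression_weights(tab2, "alpha")
  expect_gt(w_loc$w[["s2"]], w_glo$w[["s2"]])
  expect_equal(sum(w_loc$w), 1)
  expect_error(local_regression_weights(tab2, "alpha", s_obs2,
                                        eta = 0.001), "at least 3")
})

test_that("rejection ABC equals the brute-force nearest-neighbour
           selection", {
  set.seed(8)
  n <- 500
  stats_mat <- matrix(rnorm(n * 9), n)
  colnames(stats_mat) <- glandabc:::summary_stat_names()
  theta <- cbind(alpha = runif(n, 0, 5), beta = runif(n),
                 r = runif(n, 0.5, 1))
  tab <- make_synthetic_table(theta, stats_mat)

  # accept_fraction = 1 returns the whole prior sample
  post_all <- abc_reject(tab, stats_mat[3, ], equal_weights(9), 1)
  expect_equal(nrow(post_all$theta), n)

  # the observed row itself is always accepted at distance 0
  post <- abc_reject(tab, stats_mat[3, ], equal_weights(9), 0.02)
  expect_true(3L %in% post$index)
  expect_equal(min(post$distances), 0)

  # weight concentrated on one statistic: acceptance = 1-D nearest
  # neighbours on that statistic
  w1 <- c(1, rep(0, 8))
  post1 <- abc_reject(tab, stats_mat[3, ], w1, 0.05)
  brute <- order(abs(stats_mat[, 1] - stats_mat[3, 1]))[1:25]
  expect_setequal(post1$index, brute)
})

test_that("posterior summaries match closed forms", {
  mk_post <- function(x) {
    structure(list(theta = cbind(alpha = x), priors = prior_spec()),
              class = "posterior_sample")
  }
  ps <- posterior_summary(mk_post(c(0.2, 0.4)), "alpha")
  expect_equal(ps[["mean"]], 0.3)
  expect_equal(ps[["sd"]], sd(c(0.2, 0.4)))
  expect_true(is.na(ps[["mode"]]))

  ps_const <- posterior_summary(mk_post(rep(2, 10)), "alpha")
  expect_equal(ps_const[["mean"]], 2)
  expect_equal(ps_const[["sd"]], 0)
  expect_equal(ps_const[["mode"]], 2)

  set.seed(9)
  x <- runif(1e4)
  ps_unif <- posterior_summary(mk_post(x), "alpha")
  expect_lt(abs(ps_unif[["mean"]] - 0.5), 3 * sqrt(1 / 12 / 1e4))
  expect_lt(abs(ps_unif[["sd"]] - sqrt(1 / 12)), 0.01)
})

test_that("reference tables are deterministic and within prior support", {
  base <- growth_params(0, 0, 0.5, n_csc = 8L, t3 = 3L,
                        n_fission_gens = 4L)
  tab1 <- build_reference_table(prior_spec(), 10, 2, seq_model("perfect"),
                                base_params = base, seed = 123)
  tab2 <- build_reference_table(prior_spec(), 10, 2, seq_model("perfect"),
                                base_params = base, seed = 123)
  expect_identical(tab1$theta, tab2$theta)
  expect_identical(tab1$stats, tab2$stats)
  expect_true(all(tab1$theta[, "alpha"] >= 0 & tab1$theta[, "alpha"] <= 5))
  expect_true(all(tab1$theta[, "r"] >= 0.5 & tab1$theta[, "r"] <= 1))
  expect_true(all(tab1$scale > 0))

  # degenerate point priors at zero mutation rates: all-zero summaries
  tab0 <- build_reference_table(
    prior_spec(alpha = c(0, 0), beta = c(0, 0)), 5, 2,
    seq_model("perfect"), base_params = base, seed = 5)
  expect_true(all(tab0$stats == 0))
})

test_that("accepted posterior draws always stay inside the prior
           support", {
  set.seed(10)
  n <- 300
  stats_mat <- matrix(rnorm(n * 9), n)
  colnames(stats_mat) <- glandabc:::summary_stat_names()
  theta <- sample_prior(prior_spec(), n)
  tab <- make_synthetic_table(theta, stats_mat)
  for (scheme in c("equal", "global")) {
    w <- scheme_weights(tab, "r", stats_mat[5, ], scheme)
    post <- abc_reject(tab, stats_mat[5, ], w, 0.1)
    expect_true(all(post$theta[, "r"] >= 0.5 & post$theta[, "r"] <= 1))
  }
})
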