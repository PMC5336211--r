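# Growth-model unit tests.  Monte-Carlo checks compare empirical moments
# against closed-form oracles (binary-tree daughter counts, Poisson
# additivity, hypergeometric founder draws, critical branching-process
# moments) within 3 standard errors.

test_that("first-gland formation produces n_csc genotypes and the right
           mutation load", {
  p0 <- growth_params(alpha = 0, beta = 0, r = 0.8)
  g <- form_first_gland(p0)
  expect_length(g$csc, 32L)
  expect_true(all(lengths(g$csc) == 0L))

  # a single-cell gland involves no divisions at all
  g1 <- form_first_gland(growth_params(5, 0, 0.8, n_csc = 1L))
  expect_length(g1$csc, 1L)
  expect_length(g1$csc[[1]], 0L)

  # binary expansion to 32 leaves creates 62 daughter cells, each with
  # Poisson(alpha) new mutations: expected distinct mutations
  # = 5 * 62 = 310
  set.seed(101)
  p <- growth_params(alpha = 5, beta = 0, r = 0.8)
  n_runs <- 1000L
  totals <- vapply(seq_len(n_runs), function(i) {
    length(unique(unlist(form_first_gland(p)$csc)))
  }, numeric(1))
  expected <- 5 * 62
  se <- sqrt(expected / n_runs)   # Poisson variance = mean
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("non-power-of-two CSC counts expand to the exact target", {
  for (n in c(3L, 24L, 33L)) {
    g <- form_first_gland(growth_params(1, 0, 0.8, n_csc = n))
    expect_length(g$csc, n)
  }
})

test_that("carrier-count spectrum of the balanced expansion is geometric", {
  # a mutation arising in a round-k daughter (k = 1..5 for 32 cells) is
  # carried by 32 / 2^k final cells; each round creates 2^k daughters
  set.seed(77)
  p <- growth_params(alpha = 5, beta = 0, r = 0.8)
  counts <- unlist(lapply(1:300, function(i) {
    tab <- table(unlist(form_first_gland(p)$csc))
    as.integer(tab)
  }))
  expect_setequal(unique(counts), c(1L, 2L, 4L, 8L, 16L))
  # expected number of mutations per run with c carriers: 5 * 32 / c / c...
  # round k creates alpha * 2^k mutations at c = 32 / 2^k carriers
  obs16 <- sum(counts == 16) / 300
  expect_lt(abs(obs16 - 10), 3 * sqrt(10 / 300))
  obs1 <- sum(counts == 1) / 300
  expect_lt(abs(obs1 - 160), 3 * sqrt(160 / 300))
})

test_that("bottleneck fission founder draws follow the hypergeometric
           oracle", {
  # parent with mutation X in 1 of 32 CSCs: each daughter carries X with
  # probability 1/32; over many fissions the carrier fraction ~ 1/16
  # across both daughters
  set.seed(303)
  p <- growth_params(alpha = 0, beta = 0, r = 0.8)
  base <- form_first_gland(p)
  base$csc[[7]] <- 999999L   # plant mutation X in one CSC
  n_runs <- 2000L
  carried <- 0L
  for (i in seq_len(n_runs)) {
    d <- fission(base, p)
    carried <- carried + sum(vapply(d, function(x) 999999L %in% x$fixed,
                                    logical(1)))
  }
  frac <- carried / (2 * n_runs)
  se <- sqrt((1 / 32) * (31 / 32) / (2 * n_runs))
  expect_lt(abs(frac - 1 / 32), 3 * se)
})

test_that("fission inherits fixation and adds Poisson regrowth load", {
  p <- growth_params(alpha = 0, beta = 0, r = 0.8)
  g <- form_first_gland(p)
  g$fixed <- c(g$fixed, 1234L)   # mutation Y fixed in the parent
  set.seed(11)
  d <- fission(g, p)
  expect_true(all(vapply(d, function(x) 1234L %in% x$fixed, logical(1))))
  expect_true(all(lengths(d[[1]]$csc) == 0L))

  # beta = 0.5: expected distinct new mutations per daughter gland
  # = 0.5 * 62 regrowth daughters = 31
  set.seed(12)
  pb <- growth_params(alpha = 0, beta = 0.5, r = 0.8)
  n_runs <- 400L
  loads <- unlist(lapply(seq_len(n_runs), function(i) {
    vapply(fission(g, pb), function(x) length(unique(unlist(x$csc))),
           numeric(1))
  }))
  se <- sqrt(31 / length(loads))
  expect_lt(abs(mean(loads) - 31), 3 * se)
})

test_that("split-mode fission partitions all daughter cells", {
  set.seed(21)
  p <- growth_params(alpha = 2, beta = 0, r = 0.8, fission_mode = "split")
  g <- form_first_gland(p)
  d <- fission(g, p)
  expect_length(d[[1]]$csc, 32L)
  expect_length(d[[2]]$csc, 32L)
  # every parent mutation survives in the union of the two daughters
  # (beta = 0, cells only reshuffled)
  parent_muts <- sort(unique(unlist(g$csc)))
  child_muts <- sort(unique(c(unlist(d[[1]]$csc), unlist(d[[2]]$csc))))
  expect_identical(parent_muts, child_muts)
})

test_that("constant-phase step matches critical branching-process
           moments", {
  p1 <- growth_params(0, 0, r = 1)
  g <- form_first_gland(p1)
  expect_length(constant_phase_step(g, p1)$csc, 32L)   # r = 1: invariant

  # r = 0.5: offspring mean 1, variance (1 - r) = 0.5
  set.seed(55)
  p5 <- growth_params(0, 0, r = 0.5)
  n_runs <- 5000L
  sizes <- vapply(seq_len(n_runs), function(i)
    length(constant_phase_step(g, p5)$csc), numeric(1))
  se_mean <- sqrt(32 * 0.5 / n_runs)   # Var(pool) = n * offspring var
  expect_lt(abs(mean(sizes) - 32), 3 * se_mean)
  expect_lt(abs(var(sizes) - 16), 4 * 16 * sqrt(2 / n_runs))

  # beta = 0.1, r = 1: one retained daughter per CSC, so expected new
  # mutations per step = 0.1 * 32
  set.seed(56)
  pm <- growth_params(0, beta = 0.1, r = 1)
  new_muts <- vapply(seq_len(2000), function(i)
    sum(lengths(constant_phase_step(g, pm)$csc)), numeric(1))
  se <- sqrt(3.2 / 2000)
  expect_lt(abs(mean(new_muts) - 3.2), 3 * se)
})

test_that("constant-phase extinction is reported, not thrown", {
  set.seed(9)
  p <- growth_params(0, 0, r = 0)   # symmetric only: dies fast
  g <- form_first_gland(growth_params(0, 0, r = 0, n_csc = 2L))
  extinct <- FALSE
  for (i in 1:200) {
    g2 <- constant_phase_step(g, p)
    if (isTRUE(attr(g2, "extinct"))) { extinct <- TRUE; break }
  }
  expect_true(extinct)
  expect_error(constant_phase_step(g2, p), "extinct")
})

test_that("gland allele frequencies use the diploid CSC-pool convention", {
  g <- new_gland_state_for_test(fixed = 7L, carriers = list(`8` = 16L,
                                                            `9` = 1L),
                                pool = 32L)
  f <- gland_allele_frequencies(g)
  expect_identical(f[["7"]], 0.5)        # fixed: exactly one half
  expect_identical(f[["8"]], 0.25)       # 16 of 32 carriers
  expect_identical(f[["9"]], 1 / 64)     # single carrier
  expect_error(gland_allele_frequencies(
    new_gland_state_for_test(integer(0), list(), 0L)), "empty")
})

test_that("simulated tumors obey the fixation and bookkeeping
           invariants", {
  p <- growth_params(2, 0, 0.8, n_fission_gens = 8, t3 = 10)
  s <- simulate_tumor(p, glands_per_half = 3, seed = 42)
  # beta = 0: every mutation is pre-gland and fixed at exactly 0.5
  expect_true(all(s$records$origin_phase == "pre_gland"))
  expect_true(all(s$records$allele_freq == 0.5))
  expect_identical(nrow(s$glands), 6L)
  expect_setequal(unique(s$glands$half), c("A", "B"))

  # no mutation source at all
  s0 <- simulate_tumor(growth_params(0, 0, 0.8, n_fission_gens = 5, t3 = 5),
                       2, seed = 1)
  expect_identical(nrow(s0$records), 0L)

  # infinite sites: no frequency above 0.5, ids unique within gland
  sb <- simulate_tumor(growth_params(2, 0.5, 0.7, n_fission_gens = 6,
                                     t3 = 20), 3, seed = 7)
  expect_true(all(sb$records$allele_freq <= 0.5))
  expect_false(any(duplicated(
    sb$records[, c("gland_id", "mutation_id")])))

  # parameter validation
  expect_error(simulate_tumor(growth_params(1, 0, 0.8,
                                            n_fission_gens = 2), 3),
               "glands_per_half")
})

test_that("with r = 1 and beta = 0 the constant phase is a no-op", {
  p_none <- growth_params(2, 0, r = 1, n_fission_gens = 6, t3 = 0)
  p_long <- growth_params(2, 0, r = 1, n_fission_gens = 6, t3 = 100)
  a <- simulate_tumor(p_none, 2, seed = 31)
  b <- simulate_tumor(p_long, 2, seed = 31)
  expect_identical(a$records, b$records)
  expect_identical(a$glands, b$glands)
})

test_that("tumor samples round-trip through the TSV format", {
  s <- simulate_tumor(growth_params(1, 0.2, 0.8, n_fission_gens = 5,
                                    t3 = 5), 2, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_tumor_sample(s, path)
  back <- read_tumor_sample(path)
  expect_equal(back$records, s$records)
  expect_equal(back$glands[, c("gland_id", "half")],
               s$glands[, c("gland_id", "half")])
})

test_that("pruned simulation matches exhaustive simulation in
           distribution", {
  # 4 fission generations: sampling all 8 leaves per half is the full
  # tree; compare per-gland mutation load and mean frequency of a
  # 2-gland subsample against a directly pruned 1-gland-per-half run
  p <- growth_params(1, 0.3, 0.8, n_fission_gens = 4, t3 = 5)
  n_runs <- 300L
  stat_full <- matrix(NA_real_, n_runs, 2)
  stat_pruned <- matrix(NA_real_, n_runs, 2)
  for (i in seq_len(n_runs)) {
    full <- simulate_tumor(p, glands_per_half = 8, seed = 1000 + i)
    keep <- c(sample(full$glands$gland_id[full$glands$half == "A"], 1),
              sample(full$glands$gland_id[full$glands$half == "B"], 1))
    rec <- full$records[full$records$gland_id %in% keep, ]
    stat_full[i, ] <- c(nrow(rec) / 2, mean(rec$allele_freq))
    pr <- simulate_tumor(p, glands_per_half = 1, seed = 5000 + i)
    stat_pruned[i, ] <- c(nrow(pr$records) / 2, mean(pr$records$allele_freq))
  }
  for (j in 1:2) {
    se <- sqrt(var(stat_full[, j]) / n_runs + var(stat_pruned[, j]) / n_runs)
    expect_lt(abs(mean(stat_full[, j]) - mean(stat_pruned[, j])), 3.5 * se)
  }
})
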