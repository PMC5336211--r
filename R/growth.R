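# Tumor growth engine: first-gland formation, gland fission, constant-size
# phase.  Genotypes are tracked per cancer stem cell (CSC) as integer sets
# of mutation ids under an infinite-sites assumption.  Mutations carried by
# every CSC of a gland are factored into a shared `fixed` vector so that
# per-cell sets only hold segregating mutations.

PHASE_LEVELS <- c("pre_gland", "fission", "constant")

# Mutation registry: allocates globally unique integer ids and records
# the growth phase each mutation arose in.  Ids are sequential and phases
# arrive in long contiguous runs, so the phase map is stored run-length
# encoded (`run_ends[j]` is the last id of the j-th run).
new_mut_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$run_ends <- integer(0)
  e$run_codes <- integer(0)
  e
}

alloc_mutations <- function(reg, n, phase_code) {
  if (n == 0L) return(integer(0))
  ids <- reg$n + seq_len(n)
  reg$n <- reg$n + as.integer(n)
  j <- length(reg$run_codes)
  if (j > 0L && reg$run_codes[j] == phase_code) {
    reg$run_ends[j] <- reg$n
  } else {
    reg$run_ends <- c(reg$run_ends, reg$n)
    reg$run_codes <- c(reg$run_codes, as.integer(phase_code))
  }
  ids
}

# Phase code for each mutation id.
registry_phase <- function(reg, ids) {
  reg$run_codes[findInterval(ids - 1L, reg$run_ends) + 1L]
}

new_gland <- function(fixed, csc, half = "unassigned", gland_id = NA_integer_) {
  structure(list(fixed = fixed, csc = csc, half = half, gland_id = gland_id),
            class = "gland_state")
}

#' @export
print.gland_state <- function(x, ...) {
  cat(sprintf("Gland %s (half %s): %d CSCs, %d fixed mutations\n",
              x$gland_id, x$half, length(x$csc), length(x$fixed)))
  invisible(x)
}

gland_alive <- function(gland) length(gland$csc) >= 1L

# Regrow many bottleneck-founded glands at once: every gland starts from
# a single founder cell (whose mutations have moved to the gland's fixed
# set, so cells start with empty segregating sets) and expands to
# `n_csc` cells on the same balanced binary schedule.  Returns a list of
# per-gland cell lists.
joint_expand <- function(n_glands, n_csc, rate, reg, phase_code = 2L) {
  res <- cpp_joint_expand(n_glands, n_csc, rate, reg$n + 1L)
  alloc_mutations(reg, res$n_new, phase_code)
  res$glands
}

# Clonal expansion of a set of cells to `n_target` cells by balanced
# binary doubling.  Every round all current cells divide; when a full
# round would overshoot, only the first (left-to-right) cells needed to
# reach the target divide.  Each daughter cell receives an independent
# Poisson(rate) number of new mutation ids.  `cells` is a list of
# segregating-mutation id vectors; returns the expanded list.
clonal_expand <- function(cells, n_target, rate, reg, phase_code) {
  res <- cpp_grow(cells, n_target, rate, reg$n + 1L)
  alloc_mutations(reg, res$n_new, phase_code)
  res$cells
}

#' Form the first tumor gland
#'
#' Repeated division of the first transformed cell until the cell count
#' reaches the gland's CSC number, under the pre-gland mutation rate
#' `alpha`.  The expansion follows a balanced binary schedule: each round
#' every cell divides, and a final partial round (left-to-right) tops the
#' count up to `n_csc` when it is not a power of two.  Each daughter cell
#' created receives an independent Poisson(`alpha`) number of new
#' mutations, so a binary expansion to `n_csc` leaves creates
#' `2 * (n_csc - 1)` daughter cells and `alpha * 2 * (n_csc - 1)` expected
#' mutations.
#'
#' @param params A [growth_params()] object.
#' @param reg Internal mutation registry; supplied by [simulate_tumor()],
#'   created fresh when the function is used standalone.
#' @return A `gland_state` with exactly `n_csc` CSC genotypes.
#' @examples
#' set.seed(1)
#' g <- form_first_gland(growth_params(alpha = 5, beta = 0.1, r = 0.8))
#' length(g$csc)
#' @export
form_first_gland <- function(params, reg = new_mut_registry()) {
  stopifnot(inherits(params, "growth_params"))
  cells <- clonal_expand(list(integer(0)), params$n_csc, params$alpha,
                         reg, 1L)
  new_gland(fixed = integer(0), csc = cells, gland_id = 1L)
}

# One-daughter fission (used when only one branch of the gland genealogy
# is ancestral to a sampled gland; the marginal law of a single daughter
# is identical to drawing both and discarding one).
fission_daughters <- function(gland, params, reg, n_daughters = 2L) {
  if (!gland_alive(gland)) stop("cannot fission a dead gland")
  n <- length(gland$csc)
  if (params$fission_mode == "bottleneck") {
    founders <- sample.int(n, n_daughters)
    lapply(founders, function(f) {
      fixed <- c(gland$fixed, gland$csc[[f]])
      seg <- clonal_expand(list(integer(0)), params$n_csc, params$beta,
                           reg, 2L)
      new_gland(fixed = fixed, csc = seg, half = gland$half)
    })
  } else {
    daughters <- clonal_expand(gland$csc, 2L * n, params$beta, reg, 2L)
    ord <- sample.int(2L * n)
    out <- vector("list", n_daughters)
    for (d in seq_len(n_daughters)) {
      take <- ord[((d - 1L) * n + 1L):(d * n)]
      out[[d]] <- new_gland(fixed = gland$fixed, csc = daughters[take],
                            half = gland$half)
    }
    out
  }
}

#' Gland fission
#'
#' Splits one gland into two.  In the default `"bottleneck"` mode each
#' daughter gland is founded by a single CSC drawn without replacement
#' from the parent pool and regrown clonally to `n_csc` CSCs (each
#' regrowth daughter cell gaining Poisson(`beta`) new mutations); every
#' mutation carried by the founder is consequently present in every CSC
#' of its daughter gland.  In `"split"` mode every parent CSC divides
#' once and the `2 * n_csc` daughter cells are partitioned uniformly at
#' random into the two glands.
#'
#' @inheritParams form_first_gland
#' @param gland A living `gland_state`.
#' @return A list of two `gland_state` daughters.
#' @examples
#' set.seed(1)
#' p <- growth_params(alpha = 1, beta = 0.1, r = 0.8)
#' g <- form_first_gland(p)
#' pair <- fission(g, p)
#' length(pair[[1]]$csc)
#' @export
fission <- function(gland, params, reg = new_mut_registry()) {
  stopifnot(inherits(params, "growth_params"))
  fission_daughters(gland, params, reg, n_daughters = 2L)
}

# Run `t3` generations of the constant-size CSC division process on a
# joint pool of cells labelled by gland.  Each CSC divides
# asymmetrically with probability r (one CSC daughter), symmetrically
# into two CSCs with probability (1 - r) / 2, or into two
# differentiating non-CSCs with probability (1 - r) / 2 (its lineage
# leaves the pool).  Retained CSC daughters each gain Poisson(beta) new
# mutations; mutations in discarded non-CSC daughters can never persist
# and are not generated.
run_constant_phase <- function(cells, gid, t3, params, reg) {
  res <- cpp_constant_phase(cells, gid, params$r, params$beta, t3,
                            reg$n + 1L)
  alloc_mutations(reg, res$n_new, 3L)
  res
}

#' One generation of the constant-size phase
#'
#' Applies the CSC division rules to every stem cell of the gland for one
#' synchronous generation.  The CSC count follows a critical branching
#' process (offspring mean 1, variance `1 - r`) and may hit zero; an
#' empty pool is reported as extinction via the `"extinct"` attribute,
#' not as an error.
#'
#' @inheritParams fission
#' @return The updated `gland_state`; `attr(, "extinct")` is `TRUE` when
#'   the CSC pool died out.
#' @export
constant_phase_step <- function(gland, params, reg = new_mut_registry()) {
  stopifnot(inherits(params, "growth_params"))
  if (!gland_alive(gland)) stop("gland is already extinct")
  res <- run_constant_phase(gland$csc, rep(1L, length(gland$csc)), 1L,
                            params, reg)
  gland$csc <- res$cells
  attr(gland, "extinct") <- length(gland$csc) == 0L
  gland
}

# Frequency table of a gland: one row per mutation present in >= 1 CSC.
# Diploid convention: carriers / pool size / 2, so a mutation carried by
# every CSC sits at exactly 0.5.
gland_freq_rows <- function(gland) {
  pool <- length(gland$csc)
  if (pool == 0L) stop("gland has an empty CSC pool")
  seg <- unlist(gland$csc, use.names = FALSE)
  if (length(seg)) {
    seg <- sort.int(seg, method = "radix")
    runs <- rle(seg)
    keep <- runs$lengths < pool     # carried by all -> effectively fixed
    promoted <- runs$values[!keep]
    ids <- c(gland$fixed, promoted, runs$values[keep])
    counts <- c(rep.int(pool, length(gland$fixed) + length(promoted)),
                runs$lengths[keep])
  } else {
    ids <- gland$fixed
    counts <- rep.int(pool, length(gland$fixed))
  }
  list(ids = ids, freq = counts / pool / 2)
}

#' Exact allele frequencies of one gland
#'
#' Computes, for every mutation present in the gland, its diploid allele
#' frequency `carriers / pool_size / 2` over the CSC pool.  A mutation
#' carried by all CSCs maps to exactly 0.5.
#'
#' @param gland A living `gland_state`.
#' @return A named numeric vector of allele frequencies; names are
#'   mutation ids.
#' @export
gland_allele_frequencies <- function(gland) {
  ft <- gland_freq_rows(gland)
  stats::setNames(ft$freq, as.character(ft$ids))
}

#' Simulate a tumor and sample glands from its two halves
#'
#' Runs the full three-phase growth model: formation of the first gland
#' at mutation rate `alpha`; one fission of the first gland, whose two
#' daughters seed tumor halves A and B; continued gland fission for the
#' remaining `n_fission_gens - 1` generations (glands double each
#' generation); then `t3` generations of the constant-size phase for each
#' sampled gland.  `glands_per_half` glands are drawn uniformly without
#' replacement from each half's final glands.
#'
#' Only lineages ancestral to the sampled glands are simulated: glands
#' evolve independently after fission, so pruning unsampled branches
#' leaves the joint distribution of the sampled glands unchanged.
#' Sampled glands whose CSC pool goes extinct during the constant-size
#' phase have that phase resimulated from its start (conditioning on
#' survival); the number of restarts is recorded.
#'
#' @inheritParams form_first_gland
#' @param glands_per_half Number of glands sampled from each tumor half
#'   (requires `2^n_fission_gens >= 2 * glands_per_half`).
#' @param seed Optional integer seed set before simulation.
#' @return A `tumor_sample`: a list with `records` (data frame with
#'   columns `gland_id`, `half`, `mutation_id`, `origin_phase`,
#'   `allele_freq`, one row per mutation present in a sampled gland),
#'   `glands` (data frame of `gland_id`, `half`, `pool_size`), the
#'   `params`, and `n_restarts`.
#' @examples
#' s <- simulate_tumor(growth_params(2, 0.1, 0.8, n_fission_gens = 6, t3 = 5),
#'                     glands_per_half = 2, seed = 7)
#' head(s$records)
#' @export
simulate_tumor <- function(params, glands_per_half, seed = NULL) {
  stopifnot(inherits(params, "growth_params"),
            glands_per_half >= 1,
            params$n_fission_gens >= 1)
  if (2^params$n_fission_gens < 2 * glands_per_half)
    stop("glands_per_half exceeds the number of glands per half (",
         2^(params$n_fission_gens - 1), ")")
  if (!is.null(seed)) set.seed(seed)

  reg <- new_mut_registry()
  first <- form_first_gland(params, reg)
  seeds <- fission_daughters(first, params, reg, 2L)
  seeds[[1]]$half <- "A"
  seeds[[2]]$half <- "B"

  depth <- params$n_fission_gens - 1L   # fissions remaining per half
  leaves_per_half <- 2^depth

  # Pruned descent along the fission genealogy: `paths` are the 0-based
  # indices of sampled leaf glands below a branch, read as binary
  # left/right choices over the remaining generations.  Only branches
  # ancestral to a sampled leaf are simulated.
  descend <- function(gland, paths, depth) {
    # recursive form, used for "split" fission mode
    if (depth == 0L) return(list(gland))
    half_size <- 2^(depth - 1L)
    left <- paths[paths < half_size]
    right <- paths[paths >= half_size] - half_size
    if (length(left) && length(right)) {
      d <- fission_daughters(gland, params, reg, 2L)
      c(descend(d[[1]], left, depth - 1L),
        descend(d[[2]], right, depth - 1L))
    } else {
      d <- fission_daughters(gland, params, reg, 1L)
      descend(d[[1]], if (length(left)) left else right, depth - 1L)
    }
  }

  start_paths <- lapply(1:2, function(s) {
    if (depth == 0L) 0 else
      sort(sample.int(leaves_per_half, glands_per_half)) - 1
  })

  if (params$fission_mode == "split") {
    sampled <- c(descend(seeds[[1]], start_paths[[1]], depth),
                 descend(seeds[[2]], start_paths[[2]], depth))
  } else {
    # bottleneck mode, generation by generation: draw the founders of
    # every ancestral daughter gland of this generation, then regrow all
    # of them in one joint balanced expansion.
    branches <- list(list(fixed = seeds[[1]]$fixed, cells = seeds[[1]]$csc,
                          half = "A", paths = start_paths[[1]]),
                     list(fixed = seeds[[2]]$fixed, cells = seeds[[2]]$csc,
                          half = "B", paths = start_paths[[2]]))
    d <- depth
    while (d > 0L) {
      half_size <- 2^(d - 1L)
      nxt <- list()
      for (b in branches) {
        left <- b$paths[b$paths < half_size]
        right <- b$paths[b$paths >= half_size] - half_size
        sides <- Filter(length, list(left, right))
        f <- sample.int(length(b$cells), length(sides))
        for (k in seq_along(sides)) {
          nxt[[length(nxt) + 1L]] <- list(
            fixed = c(b$fixed, b$cells[[f[k]]]),
            cells = NULL, half = b$half, paths = sides[[k]])
        }
      }
      regrown <- joint_expand(length(nxt), params$n_csc, params$beta, reg)
      for (j in seq_along(nxt)) nxt[[j]]$cells <- regrown[[j]]
      branches <- nxt
      d <- d - 1L
    }
    sampled <- lapply(branches, function(b)
      new_gland(fixed = b$fixed, csc = b$cells, half = b$half))
  }

  # Constant-size phase, conditioned on CSC survival.  Glands evolve
  # independently, so all sampled glands are stepped jointly (one
  # vectorised draw per generation) with a per-cell gland label; glands
  # that go extinct are resimulated individually from the phase start.
  n_restarts <- 0L
  if (params$t3 > 0L) {
    start_pools <- lapply(sampled, `[[`, "csc")
    gid <- rep.int(seq_along(sampled),
                   vapply(start_pools, length, integer(1)))
    res <- run_constant_phase(do.call(c, start_pools), gid, params$t3,
                              params, reg)
    for (i in seq_along(sampled)) {
      pool <- res$cells[res$gid == i]
      while (length(pool) == 0L) {
        n_restarts <- n_restarts + 1L
        if (n_restarts > 10000L)
          stop("constant-size phase extinction resimulation limit reached")
        retry <- run_constant_phase(start_pools[[i]],
                                    rep(1L, length(start_pools[[i]])),
                                    params$t3, params, reg)
        pool <- retry$cells
      }
      sampled[[i]]$csc <- pool
    }
  }

  per_gland <- lapply(seq_along(sampled), function(i) {
    g <- sampled[[i]]
    ft <- gland_freq_rows(g)
    data.frame(gland_id = rep.int(i, length(ft$ids)),
               half = rep.int(g$half, length(ft$ids)),
               mutation_id = ft$ids,
               allele_freq = ft$freq,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, per_gland)
  records$origin_phase <- factor(
    PHASE_LEVELS[registry_phase(reg, records$mutation_id)],
    levels = PHASE_LEVELS)
  records <- records[, c("gland_id", "half", "mutation_id", "origin_phase",
                         "allele_freq")]
  rownames(records) <- NULL

  glands <- data.frame(
    gland_id = seq_along(sampled),
    half = vapply(sampled, function(g) g$half, character(1)),
    pool_size = vapply(sampled, function(g) length(g$csc), integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, glands = glands, params = params,
                 glands_per_half = as.integer(glands_per_half),
                 n_restarts = n_restarts),
            class = "tumor_sample")
}

#' @export
print.tumor_sample <- function(x, ...) {
  cat(sprintf("Tumor sample: %d glands (%d per half), %d mutation records\n",
              nrow(x$glands), x$glands_per_half, nrow(x$records)))
  if (x$n_restarts > 0)
    cat(sprintf("  constant-phase extinction restarts: %d\n", x$n_restarts))
  invisible(x)
}

#' Write / read a tumor sample as a TSV table
#'
#' The on-disk form is the long mutation table (`gland_id`, `half`,
#' `mutation_id`, `origin_phase`, `allele_freq`), with one extra row per
#' mutation-free gland (`mutation_id = NA`) so that glands carrying no
#' detected mutations survive the round trip.
#'
#' @param x A `tumor_sample`.
#' @param path File path.
#' @return `write_tumor_sample` returns `path` invisibly;
#'   `read_tumor_sample` returns a `tumor_sample` (without `params`).
#' @export
write_tumor_sample <- function(x, path) {
  stopifnot(inherits(x, "tumor_sample"))
  rec <- x$records
  empty <- x$glands[!(x$glands$gland_id %in% rec$gland_id), , drop = FALSE]
  if (nrow(empty)) {
    pad <- data.frame(gland_id = empty$gland_id, half = empty$half,
                      mutation_id = NA_integer_,
                      origin_phase = factor(NA, levels = PHASE_LEVELS),
                      allele_freq = NA_real_)
    rec <- rbind(rec, pad)
  }
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tumor_sample
#' @export
read_tumor_sample <- function(path) {
  rec <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gland_id", "half", "mutation_id", "origin_phase", "allele_freq")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  glands <- unique(rec[, c("gland_id", "half")])
  glands <- glands[order(glands$gland_id), , drop = FALSE]
  rownames(glands) <- NULL
  rec <- rec[!is.na(rec$mutation_id), need, drop = FALSE]
  rec$origin_phase <- factor(rec$origin_phase, levels = PHASE_LEVELS)
  rownames(rec) <- NULL
  structure(list(records = rec, glands = glands, params = NULL,
                 glands_per_half = sum(glands$half == "A"),
                 n_restarts = NA_integer_),
            class = "tumor_sample")
}
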