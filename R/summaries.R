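# Mutation classification and the nine summary statistics used by the
# ABC analysis.

# Sample variance with the degenerate-set conventions used throughout:
# empty set -> 0, single value -> 0, otherwise denominator n - 1.
safe_var <- function(x) if (length(x) < 2L) 0 else stats::var(x)
safe_mean <- function(x) if (length(x) == 0L) 0 else mean(x)

#' Classify mutations across a multi-gland sample
#'
#' Assigns each distinct detected mutation a sample-level fixed status
#' and a gland-specific/shared label.  A mutation is *gland-specific*
#' when it is present (after detection filtering) in exactly one gland
#' and *shared* when present in more than one.  Per-gland fixed flags
#' come from the upstream observation step (frequency exactly 0.5 in
#' perfect mode; the exact binomial test in reads mode); the sample-level
#' status is *fixed* only when the mutation is called fixed in every
#' gland where it is present — any segregating observation contradicts
#' fixation.
#'
#' Duplicate (gland, mutation) records are collapsed before
#' classification, so listing a gland's records twice changes nothing.
#'
#' @param obs A `gland_obs` object from [sequence_sample()] or
#'   [mutect_to_sample()].
#' @return A data frame with one row per distinct mutation: columns
#'   `mutation_id`, `n_glands`, `gland_specific`, `fixed`.
#' @export
classify_mutations <- function(obs) {
  stopifnot(inherits(obs, "gland_obs"))
  if (nrow(obs$glands) < 1L) stop("sample contains no glands")
  rec <- dedupe_records(obs$records)
  if (nrow(rec) == 0L)
    return(data.frame(mutation_id = rec$mutation_id, n_glands = integer(0),
                      gland_specific = logical(0), fixed = logical(0)))
  grp <- factor(rec$mutation_id)
  code <- as.integer(grp)
  n_glands <- tabulate(code, nbins = nlevels(grp))
  n_segregating <- tabulate(code[!rec$fixed], nbins = nlevels(grp))
  out <- data.frame(mutation_id = utils::type.convert(levels(grp),
                                                      as.is = TRUE),
                    n_glands = n_glands,
                    gland_specific = n_glands == 1L,
                    fixed = n_segregating == 0L)
  rownames(out) <- NULL
  out
}

dedupe_records <- function(rec) {
  if (nrow(rec) == 0L) return(rec)
  key <- if (is.numeric(rec$mutation_id))
    rec$gland_id * (max(rec$mutation_id) + 1) + rec$mutation_id
  else paste(rec$gland_id, rec$mutation_id)
  if (anyDuplicated(key)) rec <- rec[!duplicated(key), , drop = FALSE]
  rec
}

summary_stat_names <- function() paste0("s", 1:9)

#' The nine summary statistics
#'
#' Computes the summary vector `S = (s1, ..., s9)` of a multi-gland
#' observation table:
#' \describe{
#'   \item{s1}{mean allele frequency over all (gland, mutation) records
#'     of non-fixed mutations;}
#'   \item{s2}{variance of those allele frequencies;}
#'   \item{s3}{number of gland-specific mutations among non-fixed
#'     mutations;}
#'   \item{s4}{number of gland-specific mutations among fixed mutations;}
#'   \item{s5}{number of shared mutations among non-fixed mutations;}
#'   \item{s6}{number of shared mutations among fixed mutations;}
#'   \item{s7}{variance across glands of the per-gland count of distinct
#'     non-fixed mutations;}
#'   \item{s8}{variance across glands of the per-gland count of distinct
#'     fixed mutations;}
#'   \item{s9}{variance between the two tumor halves of the half-level
#'     mean allele frequency of non-fixed records.}
#' }
#' Fixed/non-fixed is the sample-level status from
#' [classify_mutations()]; s1/s2/s9 pool every (gland, mutation) record
#' rather than collapsing to one value per mutation, preserving per-gland
#' heterogeneity.  Empty categories give mean/variance 0; variances use
#' denominator `n - 1` and are 0 for a single value.  Glands with no
#' detected mutations contribute zero counts to s7/s8.
#'
#' @param obs A `gland_obs` object.
#' @param classification Optional precomputed [classify_mutations()]
#'   result.
#' @return Named numeric vector `s1` ... `s9`.
#' @examples
#' toy <- toy_gland_obs()
#' summarize_sample(toy)
#' @export
summarize_sample <- function(obs, classification = classify_mutations(obs)) {
  stopifnot(inherits(obs, "gland_obs"))
  rec <- dedupe_records(obs$records)
  cls <- classification
  s <- stats::setNames(numeric(9), summary_stat_names())

  glands <- obs$glands
  if (nrow(rec) == 0L || nrow(cls) == 0L) {
    return(s)  # no detected mutations: all statistics at their conventions
  }

  rec_fixed <- cls$fixed[match(rec$mutation_id, cls$mutation_id)]
  nf <- rec[!rec_fixed, , drop = FALSE]       # records of non-fixed mutations

  s["s1"] <- safe_mean(nf$obs_freq)
  s["s2"] <- safe_var(nf$obs_freq)
  s["s3"] <- sum(cls$gland_specific & !cls$fixed)
  s["s4"] <- sum(cls$gland_specific & cls$fixed)
  s["s5"] <- sum(!cls$gland_specific & !cls$fixed)
  s["s6"] <- sum(!cls$gland_specific & cls$fixed)

  gl <- factor(rec$gland_id, levels = glands$gland_id)
  counts_nf <- tabulate(gl[!rec_fixed], nbins = nrow(glands))
  counts_fx <- tabulate(gl[rec_fixed], nbins = nrow(glands))
  s["s7"] <- safe_var(counts_nf)
  s["s8"] <- safe_var(counts_fx)

  if (nrow(nf) > 0L) {
    half_means <- tapply(nf$obs_freq, nf$half, mean)
    s["s9"] <- safe_var(as.numeric(half_means))
  }
  s
}

#' Hand-checkable toy observation table
#'
#' Two glands, one per tumor half.  Gland 1 carries mutation A at 0.5 and
#' B at 0.25; gland 2 carries A at 0.5 and C at 0.125.  A is shared and
#' fixed; B and C are gland-specific and non-fixed.  Used in examples and
#' as a worked check of [summarize_sample()].
#'
#' @return A `gland_obs` object.
#' @export
toy_gland_obs <- function() {
  records <- data.frame(
    gland_id = c(1L, 1L, 2L, 2L),
    half = c("A", "A", "B", "B"),
    mutation_id = c("A", "B", "A", "C"),
    obs_freq = c(0.5, 0.25, 0.5, 0.125),
    fixed = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  glands <- data.frame(gland_id = 1:2, half = c("A", "B"),
                       stringsAsFactors = FALSE)
  new_gland_obs(records, glands)
}
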