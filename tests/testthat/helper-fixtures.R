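# Shared helpers for building small in-memory states and observation
# tables.

new_gland_state_for_test <- function(fixed, carriers, pool) {
  csc <- rep(list(integer(0)), pool)
  for (id in names(carriers)) {
    n <- carriers[[id]]
    for (i in seq_len(n)) csc[[i]] <- c(csc[[i]], as.integer(id))
  }
  glandabc:::new_gland(fixed = as.integer(fixed), csc = csc)
}

# Observation table from a compact description: a list of per-gland
# named frequency vectors, plus the half of each gland.  Fixed status
# follows the perfect-data rule (frequency exactly 0.5).
obs_from_freqs <- function(freqs_by_gland, halves) {
  rows <- do.call(rbind, lapply(seq_along(freqs_by_gland), function(g) {
    f <- freqs_by_gland[[g]]
    if (length(f) == 0L) return(NULL)
    data.frame(gland_id = g, half = halves[g], mutation_id = names(f),
               obs_freq = as.numeric(f), fixed = as.numeric(f) == 0.5,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(gland_id = integer(0), half = character(0),
                       mutation_id = character(0), obs_freq = numeric(0),
                       fixed = logical(0))
  glands <- data.frame(gland_id = seq_along(freqs_by_gland),
                       half = halves, stringsAsFactors = FALSE)
  glandabc:::new_gland_obs(rows, glands)
}
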