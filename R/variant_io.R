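# Real-data front end: MuTect call-stats ingestion, copy-number-adjusted
# allele frequencies, and conversion into the observation table consumed
# by the summary-statistic and ABC machinery.

mutect_required_cols <- c("contig", "position", "ref_allele", "alt_allele",
                          "t_ref_count", "t_alt_count", "judgement")

#' Read a MuTect call-stats file
#'
#' Parses the tab-delimited call-stats output of MuTect (any column
#' order; columns are located by name, never by position).  Lines
#' starting with `#` (the `## muTector` preamble) are skipped.  Only
#' records with `judgement == "KEEP"` are retained, and records with no
#' covering reads are dropped.
#'
#' @param path Path to a call-stats file.
#' @return A data frame with the columns
#'   `contig, position, ref_allele, alt_allele, t_ref_count,
#'   t_alt_count, judgement` (KEEP records only).
#' @export
read_mutect_callstats <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) == 0L && ncol(tab) == 0L)
    stop("empty call-stats file: ", path)
  miss <- setdiff(mutect_required_cols, names(tab))
  if (length(miss))
    stop("call-stats file ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab <- tab[tab$judgement == "KEEP", mutect_required_cols, drop = FALSE]
  tab <- tab[tab$t_ref_count + tab$t_alt_count >= 1L, , drop = FALSE]
  tab$contig <- as.character(tab$contig)
  rownames(tab) <- NULL
  tab
}

#' Read an integer copy-number segment table
#'
#' Tab-delimited, 1-based closed intervals, columns `contig`, `start`,
#' `end`, `copy_number`.  Segments must be non-overlapping within a
#' contig and have `copy_number >= 1`.
#'
#' @param path Path to the segment table.
#' @return A data frame of segments.
#' @export
read_cn_segments <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("contig", "start", "end", "copy_number"), names(seg))
  if (length(miss))
    stop("segment table is missing column(s): ",
         paste(miss, collapse = ", "))
  stopifnot(all(seg$copy_number >= 1), all(seg$start <= seg$end))
  seg$contig <- as.character(seg$contig)
  for (ctg in unique(seg$contig)) {
    s <- seg[seg$contig == ctg, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)]))
      stop("overlapping copy-number segments on contig ", ctg)
  }
  seg
}

# Copy number covering each (contig, position); NA where no segment
# covers the position.
lookup_copy_number <- function(contig, position, segments) {
  cn <- rep(NA_real_, length(contig))
  if (is.null(segments)) return(cn)
  for (ctg in unique(contig)) {
    idx <- which(contig == ctg)
    s <- segments[segments$contig == ctg, , drop = FALSE]
    if (nrow(s) == 0L) next
    s <- s[order(s$start), , drop = FALSE]
    j <- findInterval(position[idx], s$start)
    ok <- j >= 1L & position[idx] <= s$end[pmax(j, 1L)]
    cn[idx[ok]] <- s$copy_number[j[ok]]
  }
  cn
}

#' Copy-number-adjusted allele frequency and fixation call
#'
#' A mutation present on one copy in every cell of a region with integer
#' copy number `c` has expected allele frequency `1/c` (e.g. 0.33 at
#' copy number 3).  The fixation call therefore tests `H0: q = 1/c` with
#' an exact binomial test on the read counts and declares the mutation
#' fixed when the test fails to reject.  The diploid-equivalent adjusted
#' frequency `min(0.5, q_hat * c / 2)` puts real-data records on the
#' simulator's diploid frequency scale (capped at 0.5, the simulator's
#' maximum).
#'
#' By default only the single-mutated-copy hypothesis is tested;
#' `multi_copy = TRUE` additionally tests `q = j/c` for
#' `j = 2, ..., c - 1` and calls the mutation fixed if any hypothesis is
#' retained.
#'
#' @param t_alt_count,t_ref_count Alternative/reference read counts.
#' @param copy_number Integer copy numbers (`NA` falls back to diploid).
#' @param test_level Significance level of the exact test.
#' @param multi_copy Also test multi-copy mutant configurations.
#' @return A data frame with columns `adj_freq` and `fixed`.
#' @examples
#' cn_adjust(33, 67, 3)    # the 0.33 / copy-number-3 case: fixed
#' cn_adjust(25, 75, 2)    # 0.25 at diploid: segregating
#' @export
cn_adjust <- function(t_alt_count, t_ref_count, copy_number,
                      test_level = 0.05, multi_copy = FALSE) {
  n <- length(t_alt_count)
  copy_number <- rep_len(ifelse(is.na(copy_number), 2, copy_number), n)
  t_ref_count <- rep_len(t_ref_count, n)
  k <- t_alt_count + t_ref_count
  stopifnot(all(k >= 1))
  q_hat <- t_alt_count / k
  adj <- pmin(0.5, q_hat * copy_number / 2)
  fixed <- logical(n)
  for (i in seq_len(n)) {
    cc <- copy_number[i]
    js <- if (multi_copy && cc > 2) seq_len(cc - 1L) else 1L
    fixed[i] <- any(vapply(js, function(j)
      binom_pvalue(t_alt_count[i], k[i], j / cc) >= test_level,
      logical(1)))
  }
  data.frame(adj_freq = adj, fixed = fixed)
}

#' Build an observation table from per-gland MuTect files
#'
#' Reads one call-stats file per sequenced gland, groups the glands into
#' tumor halves A and B, keys mutations by
#' `contig:position:ref>alt`, applies the copy-number adjustment and
#' fixation test, and filters by the minimum detectable allele
#' frequency.  The result satisfies the same contract as
#' [sequence_sample()] output, so [summarize_sample()] and the ABC
#' machinery run on it unchanged.
#'
#' Records falling outside every copy-number segment are treated as
#' diploid with a warning (set `strict_cn = TRUE` to make this an
#' error).
#'
#' @param files_half_a,files_half_b Character vectors of call-stats file
#'   paths, one file per gland.
#' @param cn_segments Optional segment table from [read_cn_segments()];
#'   `NULL` means all-diploid.
#' @param f_min Minimum detectable (adjusted) allele frequency.
#' @param test_level Fixation-test significance level.
#' @param strict_cn Error instead of warning on uncovered records.
#' @return A `gland_obs` object.
#' @export
mutect_to_sample <- function(files_half_a, files_half_b,
                             cn_segments = NULL, f_min = 0,
                             test_level = 0.05, strict_cn = FALSE) {
  stopifnot(length(files_half_a) >= 1L, length(files_half_b) >= 1L)
  files <- c(files_half_a, files_half_b)
  halves <- rep(c("A", "B"), c(length(files_half_a), length(files_half_b)))
  recs <- vector("list", length(files))
  for (i in seq_along(files)) {
    v <- read_mutect_callstats(files[i])
    key <- paste0(v$contig, ":", v$position, ":", v$ref_allele, ">",
                  v$alt_allele)
    if (anyDuplicated(key))
      stop("duplicate variant rows in ", files[i], ": ",
           key[duplicated(key)][1])
    cn <- lookup_copy_number(v$contig, v$position, cn_segments)
    if (!is.null(cn_segments) && anyNA(cn)) {
      msg <- sprintf("%d record(s) in %s outside all CN segments",
                     sum(is.na(cn)), basename(files[i]))
      if (strict_cn) stop(msg)
      warning(msg, "; treated as diploid", call. = FALSE)
    }
    adj <- cn_adjust(v$t_alt_count, v$t_ref_count, cn, test_level)
    recs[[i]] <- data.frame(gland_id = i, half = halves[i],
                            mutation_id = key,
                            obs_freq = adj$adj_freq, fixed = adj$fixed,
                            depth = v$t_alt_count + v$t_ref_count,
                            alt_reads = v$t_alt_count,
                            stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, recs)
  rec <- rec[detectable(rec$obs_freq, f_min), , drop = FALSE]
  rownames(rec) <- NULL
  glands <- data.frame(gland_id = seq_along(files), half = halves,
                       stringsAsFactors = FALSE)
  new_gland_obs(rec, glands)
}

#' Export one half of a read-level observation table in MuTect style
#'
#' Writes a synthetic call-stats-like file (tab-delimited, `##` preamble,
#' named columns, `judgement = KEEP`) for the glands of one tumor half of
#' a reads-mode [sequence_sample()] result.  Mutation ids become
#' positions on a synthetic contig.  Intended for fixtures and round-trip
#' testing of the parser.
#'
#' @param obs A reads-mode `gland_obs` (must carry `depth` and
#'   `alt_reads`).
#' @param half `"A"` or `"B"`.
#' @param path Output file.
#' @param gland_id Which gland of that half to export (default: the
#'   first); call-stats files describe a single sequenced gland.
#' @return `path`, invisibly.
#' @export
write_mutect_like <- function(obs, half, path, gland_id = NULL) {
  stopifnot(inherits(obs, "gland_obs"),
            all(c("depth", "alt_reads") %in% names(obs$records)))
  if (is.null(gland_id))
    gland_id <- obs$glands$gland_id[obs$glands$half == half][1]
  rec <- obs$records[obs$records$half == half &
                       obs$records$gland_id == gland_id, , drop = FALSE]
  out <- data.frame(
    contig = "1",
    position = as.integer(rec$mutation_id),
    context = "NNN",
    ref_allele = "A",
    alt_allele = "T",
    t_ref_count = rec$depth - rec$alt_reads,
    t_alt_count = rec$alt_reads,
    judgement = "KEEP",
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("## muTector v1.1.4 (synthetic export)", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
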