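# Detection of phi29/MDA chimeric reads in four steps: (1) exact internal
# repeats (forward or reverse direction, >= 25 bases), (2) single-pass
# propagation of flags across strong similarity links, (3) classification
# of pairwise match geometries into the two chimeric rearrangement classes
# (inverted, transposed direct), (4) neighbourhood voting. The method
# assumes chimeric reads are a small fraction of the total; a warning is
# raised when more than 30% get flagged.

#' Search a read for exact internal repeats
#'
#' A read is flagged when an exact substring of at least `min_len` bases
#' occurs at two distinct start positions (forward repeat) or when such a
#' substring equals the reverse complement of another substring of the
#' same read (reverse-direction repeat; with `mode = "plain"` the plain
#' reversed string is used instead). Evidence records the longest such
#' block.
#'
#' @param seq one nucleotide sequence.
#' @param min_len minimum repeat length in bases (default 25).
#' @param mode interpretation of "reverse direction": `"revcomp"`
#'   (inverted repeat, the MDA branch-migration geometry, default) or
#'   `"plain"`.
#' @return `list(flagged, orientation, block_length)`; orientation is
#'   `"forward"`, `"reverse"` or `NA`.
#' @export
find_internal_repeats <- function(seq, min_len = 25L,
                                  mode = c("revcomp", "plain")) {
  mode <- match.arg(mode)
  k <- as.integer(min_len)
  L <- nchar(seq)
  none <- list(flagged = FALSE, orientation = NA_character_,
               block_length = NA_integer_)
  if (L < k) return(none)
  starts <- seq_len(L - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  fwd_dup <- duplicated(kmers)
  rev_seq <- if (mode == "revcomp") revcomp(seq) else {
    paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
  }
  rkmers <- substring(rev_seq, starts, starts + k - 1L)
  # map reverse-sequence k-mer index back to forward start position
  rk_fwd_start <- L - (starts + k - 1L) + 1L
  shared <- intersect(kmers, rkmers)
  rev_hit <- FALSE
  if (length(shared) > 0) {
    for (km in shared) {
      fpos <- starts[kmers == km]
      rpos <- rk_fwd_start[rkmers == km]
      # exclude the self-match of a palindromic k-mer at the same interval
      if (any(outer(fpos, rpos, function(a, b) a != b))) {
        rev_hit <- TRUE
        break
      }
    }
  }
  if (!any(fwd_dup) && !rev_hit) return(none)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  best_len <- 0L
  best_orient <- NA_character_
  if (any(fwd_dup)) {
    # longest run per offset between duplicate k-mer occurrences
    dup_idx <- which(fwd_dup)
    offs <- unique(unlist(lapply(dup_idx, function(i) {
      j <- starts[kmers == kmers[i]]
      (i - j)[j < i]
    })))
    for (d in offs) {
      eq <- chars[seq_len(L - d)] == chars[(d + 1L):L]
      run <- max_run(eq)
      if (run >= k && run > best_len) {
        best_len <- run
        best_orient <- "forward"
      }
    }
  }
  if (rev_hit) {
    rchars <- strsplit(rev_seq, "", fixed = TRUE)[[1]]
    # equal k-mers of seq and rev_seq extend along a fixed offset d = j - i
    offs <- unlist(lapply(shared, function(km) {
      as.vector(outer(starts[kmers == km], which(rkmers == km),
                      function(a, b) b - a))
    }))
    for (d in unique(offs)) {
      i <- max(1L, 1L - d):min(L, L - d)
      eq <- chars[i] == rchars[i + d]
      run <- max_run(eq)
      if (run >= k && run > best_len) {
        best_len <- run
        best_orient <- "reverse"
      }
    }
    if (is.na(best_orient)) best_orient <- "reverse"
  }
  if (best_len < k) {
    # duplicate k-mer guarantees a block of at least k
    best_len <- k
    if (is.na(best_orient)) best_orient <- "forward"
  }
  list(flagged = TRUE, orientation = best_orient, block_length = best_len)
}

max_run <- function(x) {
  if (length(x) == 0L || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Propagate chimera flags across strong similarity links
#'
#' A single pass (no transitive chaining): an unflagged read becomes
#' `flagged_propagated` iff some hit links it to a seed-flagged read with
#' identity strictly above `min_identity` percent over strictly more than
#' `min_cov` percent of the unflagged read's own length.
#'
#' @param reads a read set.
#' @param seed_flags ids of reads flagged by the internal-repeat rule.
#' @param hits an all-vs-all hit table.
#' @param min_identity,min_cov strict thresholds (percent), defaults 90/95.
#' @return data.frame of newly flagged reads with their evidence
#'   (`read_id`, `seed_id`, `pct_identity`, `coverage_pct`).
#' @export
propagate_similarity_flags <- function(reads, seed_flags, hits,
                                       min_identity = 90, min_cov = 95) {
  if (length(seed_flags) == 0L || nrow(hits) == 0L) {
    return(data.frame(read_id = character(0), seed_id = character(0),
                      pct_identity = numeric(0), coverage_pct = numeric(0)))
  }
  len <- stats::setNames(reads$length, reads$id)
  # candidate side = unflagged read of a hit touching a flagged read
  qf <- hits$query_id %in% seed_flags
  sf <- hits$subject_id %in% seed_flags
  cand <- rbind(
    data.frame(read_id = hits$subject_id[qf & !sf],
               seed_id = hits$query_id[qf & !sf],
               pct_identity = hits$pct_identity[qf & !sf],
               span = hits$s_end[qf & !sf] - hits$s_start[qf & !sf] + 1L),
    data.frame(read_id = hits$query_id[sf & !qf],
               seed_id = hits$subject_id[sf & !qf],
               pct_identity = hits$pct_identity[sf & !qf],
               span = hits$q_end[sf & !qf] - hits$q_start[sf & !qf] + 1L))
  if (nrow(cand) == 0L) {
    return(data.frame(read_id = character(0), seed_id = character(0),
                      pct_identity = numeric(0), coverage_pct = numeric(0)))
  }
  cand$coverage_pct <- 100 * cand$span / len[cand$read_id]
  ok <- cand$pct_identity > min_identity & cand$coverage_pct > min_cov
  cand <- cand[ok, c("read_id", "seed_id", "pct_identity", "coverage_pct")]
  cand <- cand[!duplicated(cand$read_id), ]
  rownames(cand) <- NULL
  cand
}

#' Classify the match geometry between two reads
#'
#' Hits are filtered to `aln_length >= min_len` and `evalue <= max_evalue`,
#' then the two highest-bitscore hits with non-overlapping query intervals
#' are examined: *transposed direct* iff both are plus strand and the
#' query-interval order is the reverse of the subject-interval order;
#' *inverted* iff the strands differ and the two subject intervals overlap
#' or lie within `overlap_tol` bases of each other; *collinear* iff order
#' and strand are consistent (a single usable hit is collinear);
#' *ambiguous* otherwise.
#'
#' @param hits hit records between one pair of reads.
#' @param min_len,max_evalue,overlap_tol filter and geometry parameters.
#' @return `list(pattern, hits)` with pattern one of `inverted`,
#'   `transposed_direct`, `collinear`, `ambiguous`.
#' @export
classify_pair_pattern <- function(hits, min_len = 25L, max_evalue = 1e-5,
                                  overlap_tol = 100L) {
  h <- hits[hits$aln_length >= min_len & hits$evalue <= max_evalue, ]
  if (nrow(h) == 0L) return(list(pattern = "ambiguous", hits = h))
  if (nrow(h) == 1L) return(list(pattern = "collinear", hits = h))
  h <- h[order(-h$bitscore), ]
  top <- h[1, ]
  second <- NULL
  for (r in seq(2L, nrow(h))) {
    if (h$q_end[r] < top$q_start || h$q_start[r] > top$q_end) {
      second <- h[r, ]
      break
    }
  }
  if (is.null(second)) return(list(pattern = "collinear", hits = top))
  pair <- rbind(top, second)
  pair <- pair[order(pair$q_start), ]
  q_order_asc <- TRUE                       # after sorting by q_start
  s_asc <- pair$s_start[1] < pair$s_start[2]
  same_strand <- pair$strand[1] == pair$strand[2]
  pattern <- if (!same_strand) {
    gap <- max(pair$s_start) - min(pair$s_end)
    if (gap <= overlap_tol) "inverted" else "ambiguous"
  } else if (all(pair$strand == "plus")) {
    if (!s_asc) "transposed_direct" else "collinear"
  } else {
    # both minus: consistent collinear order is subject-descending
    if (!s_asc) "collinear" else "ambiguous"
  }
  list(pattern = pattern, hits = pair)
}

#' Flag reads whose similarity neighbourhood is dominated by chimeric patterns
#'
#' For each read not already flagged, neighbours are the reads it shares at
#' least one filtered hit with; the read is flagged iff strictly more
#' neighbours show a chimeric pair pattern (`inverted` or
#' `transposed_direct`) than not (strict majority; ties are not flagged).
#'
#' @param pair_patterns data.frame (`read_a`, `read_b`, `pattern`) from
#'   [classify_pair_pattern()] applied to every read pair with hits.
#' @param exclude ids already flagged (not re-voted).
#' @return data.frame (`read_id`, `n_pattern`, `n_plain`) of newly flagged
#'   reads.
#' @export
vote_chimeras <- function(pair_patterns, exclude = character(0)) {
  if (nrow(pair_patterns) == 0L) {
    return(data.frame(read_id = character(0), n_pattern = integer(0),
                      n_plain = integer(0)))
  }
  long <- rbind(
    data.frame(read_id = pair_patterns$read_a, pattern = pair_patterns$pattern),
    data.frame(read_id = pair_patterns$read_b, pattern = pair_patterns$pattern))
  long$chimeric <- long$pattern %in% c("inverted", "transposed_direct")
  agg <- stats::aggregate(chimeric ~ read_id, data = long,
                          FUN = function(x) c(sum(x), sum(!x)))
  out <- data.frame(read_id = agg$read_id,
                    n_pattern = agg$chimeric[, 1],
                    n_plain = agg$chimeric[, 2],
                    stringsAsFactors = FALSE)
  out <- out[!(out$read_id %in% exclude) & out$n_pattern > out$n_plain, ]
  rownames(out) <- NULL
  out
}

#' Run the full chimera-identification stage
#'
#' Applies the rules in order — internal repeats, similarity propagation,
#' pair-pattern voting — removes flagged reads and returns per-read
#' verdicts. The first triggering rule determines a read's status.
#'
#' @param reads a QC-passed read set.
#' @param hits all-vs-all hit table; when `NULL` an error explains how to
#'   generate one with [all_vs_all_hits()].
#' @param config a [pipeline_config()].
#' @return `list(kept, verdicts, summary)`; `verdicts` has one row per
#'   read with `status` in `clean` / `flagged_repeat` /
#'   `flagged_propagated` / `flagged_vote` plus evidence columns.
#' @export
run_chimera_stage <- function(reads, hits = NULL,
                              config = pipeline_config()) {
  if (is.null(hits)) {
    stop("run_chimera_stage needs an all-vs-all hit table; generate one ",
         "with all_vs_all_hits(reads) or supply external aligner output ",
         "via read_hit_table()", call. = FALSE)
  }
  verdicts <- data.frame(read_id = reads$id, status = "clean",
                         evidence = NA_character_,
                         stringsAsFactors = FALSE)
  rep_res <- lapply(reads$seq, find_internal_repeats,
                    min_len = config$min_repeat_len,
                    mode = config$reverse_repeat_mode)
  flagged1 <- vapply(rep_res, `[[`, logical(1), "flagged")
  verdicts$status[flagged1] <- "flagged_repeat"
  verdicts$evidence[flagged1] <- vapply(rep_res[flagged1], function(x) {
    sprintf("repeat:%s:%d", x$orientation, x$block_length)
  }, character(1))
  seed_ids <- reads$id[flagged1]
  prop <- propagate_similarity_flags(reads, seed_ids, hits,
                                     config$propagate_min_identity,
                                     config$propagate_min_cov)
  prop <- prop[!(prop$read_id %in% seed_ids), ]
  idx <- match(prop$read_id, verdicts$read_id)
  verdicts$status[idx] <- "flagged_propagated"
  verdicts$evidence[idx] <- sprintf("seed:%s:id=%.1f:cov=%.1f",
                                    prop$seed_id, prop$pct_identity,
                                    prop$coverage_pct)
  # pair patterns over every read pair sharing filtered hits
  key <- paste(pmin(hits$query_id, hits$subject_id),
               pmax(hits$query_id, hits$subject_id), sep = "\r")
  pp <- lapply(split(hits, key), function(h) {
    classify_pair_pattern(h, config$pair_min_hit_len, config$pair_evalue,
                          config$pair_overlap_tol)$pattern
  })
  pairs <- unique(data.frame(
    read_a = pmin(hits$query_id, hits$subject_id),
    read_b = pmax(hits$query_id, hits$subject_id),
    stringsAsFactors = FALSE))
  pairs$pattern <- unlist(pp[paste(pairs$read_a, pairs$read_b, sep = "\r")])
  voted <- vote_chimeras(pairs,
                         exclude = verdicts$read_id[verdicts$status != "clean"])
  idx <- match(voted$read_id, verdicts$read_id)
  verdicts$status[idx] <- "flagged_vote"
  verdicts$evidence[idx] <- sprintf("vote:%d:%d", voted$n_pattern,
                                    voted$n_plain)
  n_flagged <- sum(verdicts$status != "clean")
  if (n_flagged > 0.3 * nrow(reads)) {
    warning(sprintf(paste0("%d of %d reads flagged as chimeric (>30%%); the ",
                           "method assumes chimeras are a small fraction of ",
                           "the reads"), n_flagged, nrow(reads)),
            call. = FALSE)
  }
  kept <- reads[verdicts$status == "clean", ]
  rownames(kept) <- NULL
  list(kept = kept, verdicts = verdicts,
       summary = as.list(table(verdicts$status)))
}
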