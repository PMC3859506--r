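# Initial read processing: artificial-replicate collapsing, DUST-style
# low-complexity masking, repeat-coverage filtering. A read is excluded
# when strictly more than half of its length is masked.

#' Group artificial replicates and pick one representative per group
#'
#' Pyrosequencing artifacts: two reads are replicates iff their first three
#' bases are identical, the length difference is at most 10% of the longer
#' read and the shorter read matches the prefix of the longer at >= 90%
#' identity (ungapped, position by position). Groups are transitive
#' closures of this relation; the longest read survives (ties broken by
#' lexicographically smallest id). Grouping is symmetric and independent of
#' input order.
#'
#' @param reads a read set (one sample).
#' @param min_identity prefix-identity floor (fraction, default 0.9).
#' @param max_len_diff maximum length difference as a fraction of the
#'   longer read (default 0.1).
#' @return `list(groups, keep)`: `groups` is a data.frame (`read_id`,
#'   `group`, `representative`); `keep` the surviving read ids.
#' @export
flag_artificial_replicates <- function(reads, min_identity = 0.9,
                                       max_len_diff = 0.1) {
  n <- nrow(reads)
  if (n == 0L) {
    return(list(groups = data.frame(read_id = character(0), group = integer(0),
                                    representative = logical(0)),
                keep = character(0)))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  prefix3 <- substr(reads$seq, 1L, 3L)
  buckets <- split(seq_len(n), prefix3)
  for (idx in buckets) {
    if (length(idx) < 2L) next
    for (ai in seq_len(length(idx) - 1L)) {
      for (bi in seq(ai + 1L, length(idx))) {
        i <- idx[ai]; j <- idx[bi]
        li <- reads$length[i]; lj <- reads$length[j]
        longer <- max(li, lj); shorter <- min(li, lj)
        if ((longer - shorter) > max_len_diff * longer) next
        a <- substr(reads$seq[if (li <= lj) i else j], 1L, shorter)
        b <- substr(reads$seq[if (li <= lj) j else i], 1L, shorter)
        ident <- prefix_identity(a, b)
        if (ident >= min_identity) unite(i, j)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  group <- match(root, unique(root))
  rep_flag <- logical(n)
  for (g in split(seq_len(n), group)) {
    best <- g[order(-reads$length[g], reads$id[g])][1]
    rep_flag[best] <- TRUE
  }
  list(groups = data.frame(read_id = reads$id, group = group,
                           representative = rep_flag,
                           stringsAsFactors = FALSE),
       keep = reads$id[rep_flag])
}

# ungapped identity of two equal-length strings
prefix_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  mean(ca == cb)
}

# ---- DUST-style low-complexity masking ------------------------------------

# integer codes of overlapping triplets (1..64), NA where any base is N
triplet_codes <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T")) - 1L
  L <- length(code)
  if (L < 3L) return(integer(0))
  16L * code[1:(L - 2L)] + 4L * code[2:(L - 1L)] + code[3:L] + 1L
}

#' Low-complexity masking by triplet (DUST-style) scoring
#'
#' Windows of `window` bases are scored as `sum c_t (c_t - 1) / 2 / (k - 1)`
#' over triplet counts `c_t` (`k` = number of triplets in the window); a
#' window scoring above `level / 10` is masked. Overlapping masked windows
#' are merged. With the defaults (window 64, level 20) a random ACGT
#' sequence is essentially never masked while tandem repeats of short
#' motifs are fully masked.
#'
#' @param seq one nucleotide sequence.
#' @param window window length in bases.
#' @param level DUST score level; the masking threshold is `level / 10`.
#' @return data.frame of 0-based half-open `start`/`end` mask intervals.
#' @export
low_complexity_mask <- function(seq, window = 64L, level = 20) {
  L <- nchar(seq)
  ab_assert(L > 0L, "low_complexity_mask: empty read")
  threshold <- level / 10
  trip <- triplet_codes(seq)
  nt <- length(trip)
  if (nt == 0L) return(data.frame(start = integer(0), end = integer(0)))
  w <- min(window, L)
  kw <- w - 2L                      # triplets per window
  if (kw < 2L) return(data.frame(start = integer(0), end = integer(0)))
  counts <- integer(64L)
  # N-containing triplets get a shared dummy bin that never accumulates
  trip[is.na(trip)] <- 0L
  pairsum <- 0                      # sum over bins of c*(c-1)/2
  masked_from <- integer(0)
  nwin <- nt - kw + 1L
  win_masked <- logical(max(nwin, 0L))
  for (t in seq_len(nt)) {
    tc <- trip[t]
    if (tc > 0L) {
      pairsum <- pairsum + counts[tc]
      counts[tc] <- counts[tc] + 1L
    }
    if (t >= kw) {
      widx <- t - kw + 1L
      if (pairsum / (kw - 1L) > threshold) win_masked[widx] <- TRUE
      drop <- trip[widx]
      if (drop > 0L) {
        counts[drop] <- counts[drop] - 1L
        pairsum <- pairsum - counts[drop]
      }
    }
  }
  if (!any(win_masked)) return(data.frame(start = integer(0), end = integer(0)))
  starts <- which(win_masked)                    # triplet-window index
  merge_intervals(starts - 1L, starts - 1L + w)  # window covers w bases
}

#' Drop a read when masked coverage exceeds half its length
#'
#' The union of mask intervals is measured against the read length; the
#' read is dropped iff the masked fraction strictly exceeds
#' `drop_fraction` (default 0.5 — a read masked over exactly half its
#' length is kept).
#'
#' @param read one-row read set.
#' @param masks data.frame of 0-based half-open `start`/`end` intervals.
#' @param which `"lowcomplexity"` or `"repeat"` (controls the verdict
#'   label).
#' @param drop_fraction strict threshold on the masked fraction.
#' @return one-row data.frame: `read_id`, `verdict`,
#'   `masked_fraction_lowcomp`, `masked_fraction_repeat`.
#' @export
apply_fraction_filter <- function(read, masks,
                                  which = c("lowcomplexity", "repeat"),
                                  drop_fraction = 0.5) {
  which <- match.arg(which)
  L <- read$length[1]
  if (nrow(masks) > 0) {
    ab_assert(all(masks$start >= 0L & masks$end <= L & masks$start < masks$end),
              "mask interval out of read bounds for %s", read$id[1])
  }
  frac <- interval_union_length(masks$start, masks$end) / L
  dropped <- frac > drop_fraction
  verdict <- if (!dropped) "kept" else if (which == "lowcomplexity") {
    "dropped_lowcomplexity"
  } else {
    "dropped_repeat"
  }
  data.frame(read_id = read$id[1], verdict = verdict,
             masked_fraction_lowcomp =
               if (which == "lowcomplexity") frac else 0,
             masked_fraction_repeat = if (which == "repeat") frac else 0,
             stringsAsFactors = FALSE)
}

#' Screen a read against a repeat library
#'
#' Exact 15-mer seeds against the library elements (both strands), extended
#' without gaps; matches of at least `min_len` bases at `min_identity` or
#' better become mask intervals on the read. This is a declared stand-in
#' for an external repeat-masking tool, not a claim of equivalence to it.
#'
#' @param read one-row read set.
#' @param repeat_library a read set holding the library elements.
#' @param k seed length.
#' @param min_len minimum match length in bases (default 50).
#' @param min_identity identity floor as a fraction (default 0.8).
#' @return data.frame of 0-based half-open `start`/`end` mask intervals.
#' @export
screen_repeat_library <- function(read, repeat_library, k = 15L,
                                  min_len = 50L, min_identity = 0.8) {
  ab_assert(nrow(repeat_library) > 0, "repeat library is empty")
  rq <- strsplit(read$seq[1], "", fixed = TRUE)[[1]]
  qpos <- kmer_positions(read$seq[1], k)
  if (is.null(qpos)) return(data.frame(start = integer(0), end = integer(0)))
  hits <- list()
  for (i in seq_len(nrow(repeat_library))) {
    for (lib_seq in c(repeat_library$seq[i], revcomp(repeat_library$seq[i]))) {
      lpos <- kmer_positions(lib_seq, k)
      if (is.null(lpos)) next
      m <- merge(qpos, lpos, by = "kmer", suffixes = c("_q", "_l"))
      if (nrow(m) == 0L) next
      m$diag <- m$pos_l - m$pos_q
      m <- m[!duplicated(m$diag), ]
      lb <- strsplit(lib_seq, "", fixed = TRUE)[[1]]
      for (r in seq_len(nrow(m))) {
        ext <- extend_diagonal(rq, lb, m$pos_q[r], m$pos_l[r], k, min_identity)
        if (!is.null(ext) && ext$len >= min_len) {
          hits[[length(hits) + 1L]] <- c(ext$qs - 1L, ext$qe)
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  iv <- do.call(rbind, hits)
  merge_intervals(iv[, 1], iv[, 2])
}

#' Run the full QC stage
#'
#' Stages run in order: artificial-replicate collapsing, low-complexity
#' filtering, repeat filtering. Precomputed repeat masks (BED intervals)
#' take precedence over the built-in repeat-library screen when both are
#' supplied. Filters are per read and idempotent: re-running QC on the
#' kept reads drops nothing.
#'
#' @param reads a read set.
#' @param repeat_masks optional data.frame (`read_id`, `start`, `end`) of
#'   precomputed repeat masks, e.g. from [read_mask_bed()].
#' @param repeat_library optional read set of repeat elements for the
#'   built-in screen.
#' @param config a [pipeline_config()].
#' @return `list(kept, outcomes, summary)`: the surviving reads, one
#'   QC outcome row per input read, and verdict counts.
#' @export
run_qc_stage <- function(reads, repeat_masks = NULL, repeat_library = NULL,
                         config = pipeline_config()) {
  drop_frac <- config$mask_drop_fraction / 100
  repl <- flag_artificial_replicates(reads,
                                     config$replicate_min_identity,
                                     config$replicate_max_len_diff)
  outcomes <- data.frame(read_id = reads$id,
                         verdict = ifelse(reads$id %in% repl$keep,
                                          "kept", "dropped_replicate"),
                         masked_fraction_lowcomp = 0,
                         masked_fraction_repeat = 0,
                         stringsAsFactors = FALSE)
  for (i in which(outcomes$verdict == "kept")) {
    masks <- low_complexity_mask(reads$seq[i], config$dust_window,
                                 config$dust_level)
    oc <- apply_fraction_filter(reads[i, ], masks, "lowcomplexity", drop_frac)
    outcomes$masked_fraction_lowcomp[i] <- oc$masked_fraction_lowcomp
    if (oc$verdict != "kept") {
      outcomes$verdict[i] <- oc$verdict
      next
    }
    rmask <- NULL
    if (!is.null(repeat_masks)) {
      rmask <- repeat_masks[repeat_masks$read_id == reads$id[i],
                            c("start", "end")]
    } else if (!is.null(repeat_library)) {
      rmask <- screen_repeat_library(reads[i, ], repeat_library)
    }
    if (!is.null(rmask)) {
      oc <- apply_fraction_filter(reads[i, ], rmask, "repeat", drop_frac)
      outcomes$masked_fraction_repeat[i] <- oc$masked_fraction_repeat
      if (oc$verdict != "kept") outcomes$verdict[i] <- oc$verdict
    }
  }
  kept <- reads[reads$id %in% outcomes$read_id[outcomes$verdict == "kept"], ]
  rownames(kept) <- NULL
  list(kept = kept, outcomes = outcomes,
       summary = as.list(table(outcomes$verdict)))
}
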