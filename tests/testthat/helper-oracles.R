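# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check: plain nested loops and direct
# evaluation of the rule definitions.

# Brute force internal-repeat search: compare every substring pair of
# length k directly. O(n^2 * k); only for short reads.
brute_internal_repeat <- function(seq, k = 25) {
  n <- nchar(seq)
  if (n < k) return(FALSE)
  subs <- substring(seq, 1:(n - k + 1), k:n)
  # forward: identical substrings at two distinct starts
  if (anyDuplicated(subs) > 0) return(TRUE)
  comp <- chartr("ACGT", "TGCA", seq)
  rcsubs <- sapply(1:(n - k + 1), function(i) {
    paste(rev(strsplit(substring(comp, i, i + k - 1), "")[[1]]), collapse = "")
  })
  for (i in seq_along(subs)) {
    for (j in seq_along(rcsubs)) {
      if (i != j && subs[i] == rcsubs[j]) return(TRUE)
    }
  }
  FALSE
}

# Brute-force four-rule chimera caller over a read set and a hit table;
# follows the rule text directly with no shared helpers.
brute_chimera_flags <- function(reads, hits,
                                min_repeat = 25,
                                prop_ident = 90, prop_cov = 95,
                                pair_min_len = 25, pair_eval = 1e-5,
                                overlap_tol = 100) {
  status <- setNames(rep("clean", nrow(reads)), reads$id)
  # rule 1
  for (i in seq_len(nrow(reads))) {
    if (brute_internal_repeat(reads$seq[i], min_repeat)) {
      status[reads$id[i]] <- "flagged_repeat"
    }
  }
  seeds <- names(status)[status == "flagged_repeat"]
  # rule 2: single pass
  lens <- setNames(reads$length, reads$id)
  newly <- character(0)
  for (r in seq_len(nrow(hits))) {
    q <- hits$query_id[r]; s <- hits$subject_id[r]
    if (q %in% seeds && !(s %in% seeds) && status[s] == "clean") {
      cov <- 100 * (hits$s_end[r] - hits$s_start[r] + 1) / lens[s]
      if (hits$pct_identity[r] > prop_ident && cov > prop_cov) {
        newly <- union(newly, s)
      }
    }
    if (s %in% seeds && !(q %in% seeds) && status[q] == "clean") {
      cov <- 100 * (hits$q_end[r] - hits$q_start[r] + 1) / lens[q]
      if (hits$pct_identity[r] > prop_ident && cov > prop_cov) {
        newly <- union(newly, q)
      }
    }
  }
  status[newly] <- "flagged_propagated"
  # rules 3+4: classify each pair, then vote
  pair_key <- paste(pmin(hits$query_id, hits$subject_id),
                    pmax(hits$query_id, hits$subject_id), sep = "|")
  patterns <- list()
  for (key in unique(pair_key)) {
    h <- hits[pair_key == key, ]
    h <- h[h$aln_length >= pair_min_len & h$evalue <= pair_eval, ]
    pat <- "ambiguous"
    if (nrow(h) == 1) pat <- "collinear"
    if (nrow(h) >= 2) {
      h <- h[order(-h$bitscore), ]
      top <- h[1, ]; second <- NULL
      for (r in 2:nrow(h)) {
        if (h$q_end[r] < top$q_start || h$q_start[r] > top$q_end) {
          second <- h[r, ]; break
        }
      }
      if (is.null(second))

        pat <- "collinear"
      else {
        two <- rbind(top, second)
        two <- two[order(two$q_start), ]
        if (two$strand[1] != two$strand[2]) {
          gap <- max(two$s_start) - min(two$s_end)
          pat <- if (gap <= overlap_tol) "inverted" else "ambiguous"
        } else if (all(two$strand == "plus")) {
          pat <- if (two$s_start[1] > two$s_start[2]) "transposed_direct"
                 else "collinear"
        } else {
          pat <- if (two$s_start[1] > two$s_start[2]) "collinear"
                 else "ambiguous"
        }
      }
    }
    patterns[[key]] <- pat
  }
  for (id in reads$id) {
    if (status[id] != "clean") next
    keys <- unique(pair_key[hits$query_id == id | hits$subject_id == id])
    if (length(keys) == 0) next
    pats <- unlist(patterns[keys])
    n_chim <- sum(pats %in% c("inverted", "transposed_direct"))
    if (n_chim > length(pats) - n_chim) status[id] <- "flagged_vote"
  }
  status
}

# PCA oracle: eigendecomposition of the sample covariance of the centered
# matrix, done by hand.
eigen_pca_oracle <- function(mat) {
  x <- scale(mat, center = TRUE, scale = FALSE)
  cv <- crossprod(x) / (nrow(x) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  list(var_explained = ev$values / sum(ev$values),
       values = ev$values)
}
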