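# Built-in exact-seed / ungapped-extension matcher. Provides the all-vs-all
# hit table the chimera stage consumes when no external aligner output is
# supplied, and the seed machinery reused by the repeat-library screen.
# This is a declared stand-in for an external local aligner: ungapped,
# k-mer-seeded, with an approximate bit score and e-value that are adequate
# for the downstream e-value/length filters.

# enumerate k-mers of one sequence: data.table(kmer, pos)
kmer_positions <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(NULL)
  starts <- seq_len(L - k + 1L)
  data.table::data.table(kmer = substring(seq, starts, starts + k - 1L),
                         pos = starts)
}

# integer-encoded k-mers (2 bits per base, requires k <= 15) for a whole
# read set in one pass; windows containing N are dropped.
# Returns data.table(kmer, pos, read).
kmer_table <- function(seqs, k) {
  lens <- nchar(seqs)
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T")) - 1L
  n <- length(code)
  if (n < k) return(NULL)
  nw <- n - k + 1L
  val <- numeric(nw)
  for (j in 0:(k - 1L)) {
    val <- val * 4 + code[(1L + j):(nw + j)]
  }
  read <- rep.int(seq_along(seqs), lens)
  offset <- c(0L, cumsum(lens))[read]
  pos <- seq_len(n) - offset
  keep_start <- seq_len(nw)
  # window must not cross a read boundary: its end belongs to the same read
  ok <- !is.na(val) &
    read[keep_start] == read[pmin(keep_start + k - 1L, n)]
  keep_start <- keep_start[ok]
  if (length(keep_start) == 0L) return(NULL)
  data.table::data.table(kmer = val[ok], pos = pos[keep_start],
                         read = read[keep_start])
}

# Ungapped extension of a seed on a fixed diagonal. a/b are character
# vectors (the split sequences); returns NULL or list(qs, qe, ss, se,
# matches, len) in the coordinates of a and b (both forward).
extend_diagonal <- function(a, b, pos_a, pos_b, k, min_identity) {
  off <- pos_b - pos_a
  lo <- max(1L, 1L - off)           # range of positions i in a with i+off in b
  hi <- min(length(a), length(b) - off)
  if (hi - lo + 1L < k) return(NULL)
  eq <- a[lo:hi] == b[(lo + off):(hi + off)]
  i0 <- pos_a - lo + 1L             # seed start within eq
  n <- length(eq)
  # extend right from seed end while running identity of the added suffix
  # stays above min_identity
  right <- i0 + k - 1L
  mism <- 0L
  best_right <- right
  j <- right
  while (j < n) {
    j <- j + 1L
    if (!eq[j]) mism <- mism + 1L
    if ((j - right) > 0 && mism / (j - right) <= (1 - min_identity)) {
      if (eq[j]) best_right <- j
    }
    if (mism > (1 - min_identity) * n + 2L) break
  }
  # extend left from seed start symmetrically
  left <- i0
  mism <- 0L
  best_left <- left
  j <- left
  while (j > 1L) {
    j <- j - 1L
    if (!eq[j]) mism <- mism + 1L
    if ((left - j) > 0 && mism / (left - j) <= (1 - min_identity)) {
      if (eq[j]) best_left <- j
    }
    if (mism > (1 - min_identity) * n + 2L) break
  }
  seg <- eq[best_left:best_right]
  len <- length(seg)
  matches <- sum(seg)
  if (matches / len < min_identity) return(NULL)
  qs <- lo + best_left - 1L
  list(qs = qs, qe = qs + len - 1L,
       ss = qs + off, se = qs + off + len - 1L,
       matches = matches, len = len)
}

approx_bitscore <- function(matches, len) 2 * matches - 3 * (len - matches)

approx_evalue <- function(bitscore, m, n) {
  e <- as.numeric(m) * as.numeric(n) * 2^(-bitscore)
  pmax(e, 1e-180)
}

#' All-vs-all similarity search over a read set
#'
#' Exact 15-mer seeds (forward and reverse-complement) grouped per read
#' pair and diagonal, extended without gaps while the running identity
#' stays at or above `min_identity`. Emits hits in the twelve-column
#' dialect (plus `strand`), suitable for [run_chimera_stage()].
#'
#' @param reads a read set.
#' @param k seed length (default 15).
#' @param min_len minimum reported alignment length (default 25).
#' @param min_identity minimum identity fraction of a reported hit.
#' @param max_kmer_occurrence seeds occurring in more reads than this are
#'   skipped (guards against low-complexity seed blowup).
#' @return a hit table `data.frame`.
#' @export
all_vs_all_hits <- function(reads, k = 15L, min_len = 25L,
                            min_identity = 0.9, max_kmer_occurrence = 50L) {
  n <- nrow(reads)
  if (n < 2L) return(empty_hit_table())
  ab_assert(k <= 15L, "seed length k must be <= 15")
  pos <- kmer_table(reads$seq, k)
  if (is.null(pos)) return(empty_hit_table())
  # reverse-complement k-mer values at their forward start positions
  rcpos <- kmer_table(revcomp(reads$seq), k)
  rcpos[, pos := reads$length[read] - pos - k + 2L]
  # candidate seed pairs: forward-vs-forward (plus) and forward-vs-rc (minus)
  cand <- rbind(
    seed_pairs(pos, pos, "plus", max_kmer_occurrence),
    seed_pairs(pos, rcpos, "minus", max_kmer_occurrence)
  )
  if (is.null(cand) || nrow(cand) == 0L) return(empty_hit_table())
  # one seed per (pair, strand, diagonal)
  cand[, diag := ifelse(strand == "plus", pos_b - pos_a, pos_a + pos_b)]
  cand <- cand[, .SD[1], by = .(read_a, read_b, strand, diag)]
  split_seqs <- lapply(reads$seq, function(s) strsplit(s, "")[[1]])
  rc_seqs <- lapply(revcomp(reads$seq), function(s) strsplit(s, "")[[1]])
  out <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$read_a[r]; j <- cand$read_b[r]
    if (cand$strand[r] == "plus") {
      ext <- extend_diagonal(split_seqs[[i]], split_seqs[[j]],
                             cand$pos_a[r], cand$pos_b[r], k, min_identity)
    } else {
      # pos_b is the k-mer start on the forward subject; convert to its
      # start within revcomp(read_j)
      pos_b_rc <- reads$length[j] - cand$pos_b[r] - k + 2L
      ext <- extend_diagonal(split_seqs[[i]], rc_seqs[[j]],
                             cand$pos_a[r], pos_b_rc, k, min_identity)
    }
    if (is.null(ext) || ext$len < min_len) next
    Lj <- reads$length[j]
    if (cand$strand[r] == "plus") {
      s_start <- ext$ss; s_end <- ext$se
    } else {
      s_start <- Lj - ext$se + 1L; s_end <- Lj - ext$ss + 1L
    }
    bs <- approx_bitscore(ext$matches, ext$len)
    out[[r]] <- data.frame(
      query_id = reads$id[i], subject_id = reads$id[j],
      pct_identity = 100 * ext$matches / ext$len,
      aln_length = ext$len, mismatches = ext$len - ext$matches,
      gap_opens = 0L, q_start = ext$qs, q_end = ext$qe,
      s_start = s_start, s_end = s_end,
      evalue = approx_evalue(bs, reads$length[i], Lj), bitscore = bs,
      strand = ifelse(cand$strand[r] == "plus", "plus", "minus"),
      stringsAsFactors = FALSE)
  }
  hits <- data.table::rbindlist(out)
  if (nrow(hits) == 0L) return(empty_hit_table())
  # drop duplicate identical intervals arising from adjacent seeds
  hits <- unique(hits)
  as.data.frame(hits)
}

seed_pairs <- function(tab_a, tab_b, strand_label, max_occ) {
  counts <- unique(tab_b[, c("kmer", "read")])[, .N, by = kmer]
  keep <- counts[N <= max_occ, kmer]
  a <- tab_a[kmer %in% keep]
  b <- tab_b[kmer %in% keep]
  m <- merge(a, b, by = "kmer", allow.cartesian = TRUE,
             suffixes = c("_a", "_b"))
  m <- m[read_a < read_b]
  if (nrow(m) == 0L) return(NULL)
  m[, strand := strand_label]
  m[, .(read_a, read_b, pos_a, pos_b, strand)]
}
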