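# Functional profiling: KO/COG abundances from peptide annotations with
# read-length and gene-length accounting, rollup to functional categories,
# pairwise profile correlations, PCA ordination with top-loading
# extraction, and the stringent resistance/virulence match filter.

#' KO (or COG) abundance matrix per sample
#'
#' In `raw` mode each annotated peptide contributes a count of 1. In
#' `length_normalized` mode each peptide contributes weight
#' `1 / (L_gene_nt + mean_read_len - 1)` — the number of read start
#' positions that can overlap the gene — where `L_gene_nt` is 3x the
#' subject gene length in residues and `mean_read_len` is the sample's
#' mean read length in bases; per-sample weights are then divided by the
#' sample total, so each row is a relative-abundance vector summing to 1.
#'
#' @param annotations data.frame with columns `sample`, `peptide_id`,
#'   `ko` (feature id; `NA` rows are ignored), and in normalized mode
#'   `gene_len_aa`.
#' @param read_lengths data.frame (`sample`, `mean_read_len`) giving each
#'   sample's mean read length in bases (required in normalized mode).
#' @param mode `"length_normalized"` (default) or `"raw"`.
#' @param feature column of `annotations` holding the feature id
#'   (default `"ko"`; use `"cog"` for COG profiles).
#' @return a samples x features matrix with attributes `mode` and
#'   `mean_read_len`.
#' @export
ko_abundance <- function(annotations, read_lengths = NULL,
                         mode = c("length_normalized", "raw"),
                         feature = "ko") {
  mode <- match.arg(mode)
  ann <- annotations[!is.na(annotations[[feature]]), ]
  ab_assert(nrow(ann) > 0, "no %s-annotated peptides", feature)
  if (mode == "length_normalized") {
    ab_assert(!is.null(read_lengths),
              "read_lengths is required in length_normalized mode")
    no_len <- is.na(ann$gene_len_aa)
    ab_assert(!any(no_len),
              "missing gene length for subjects of peptides: %s",
              paste(utils::head(ann$peptide_id[no_len], 5), collapse = ", "))
    mrl <- stats::setNames(read_lengths$mean_read_len, read_lengths$sample)
    ab_assert(all(ann$sample %in% names(mrl)),
              "read_lengths missing samples: %s",
              paste(setdiff(unique(ann$sample), names(mrl)), collapse = ", "))
    w <- 1 / (3 * ann$gene_len_aa + mrl[ann$sample] - 1)
  } else {
    w <- rep(1, nrow(ann))
  }
  samples <- sort(unique(ann$sample))
  features <- sort(unique(ann[[feature]]))
  m <- matrix(0, nrow = length(samples), ncol = length(features),
              dimnames = list(samples, features))
  agg <- tapply(w, list(ann$sample, ann[[feature]]), sum)
  agg[is.na(agg)] <- 0
  m[rownames(agg), colnames(agg)] <- agg
  if (mode == "length_normalized") {
    rs <- rowSums(m)
    empty <- rs == 0
    if (any(empty)) {
      ab_log("samples with no annotated peptides: %s",
             paste(samples[empty], collapse = ", "))
    }
    m[!empty, ] <- m[!empty, , drop = FALSE] / rs[!empty]
  }
  attr(m, "mode") <- mode
  if (!is.null(read_lengths)) {
    attr(m, "mean_read_len") <- read_lengths
  }
  m
}

#' Roll KO abundances up to functional categories
#'
#' Category abundance is the sum over member KOs; a KO mapping to several
#' categories contributes once to each. KOs absent from the map accumulate
#' under `"unmapped"`. Rows are renormalized to sum to 1.
#'
#' @param mat samples x KO abundance matrix.
#' @param map data.frame (`ko`, `category`); a KO may appear in several
#'   rows.
#' @return samples x categories matrix with rows summing to 1.
#' @export
category_rollup <- function(mat, map) {
  kos <- colnames(mat)
  unmapped <- setdiff(kos, map$ko)
  if (length(unmapped) > 0) {
    ab_log("%d features not in the category map -> 'unmapped'",
           length(unmapped))
    map <- rbind(map, data.frame(ko = unmapped, category = "unmapped"))
  }
  map <- map[map$ko %in% kos, ]
  cats <- sort(unique(map$category))
  out <- matrix(0, nrow = nrow(mat), ncol = length(cats),
                dimnames = list(rownames(mat), cats))
  for (cc in cats) {
    members <- map$ko[map$category == cc]
    out[, cc] <- rowSums(mat[, kos %in% members, drop = FALSE])
  }
  rs <- rowSums(out)
  out[rs > 0, ] <- out[rs > 0, , drop = FALSE] / rs[rs > 0]
  out
}

#' Pairwise Pearson correlations between sample profiles
#'
#' Correlates the feature-abundance vectors of each unordered sample pair
#' and reports the matrix together with the mean over all pairs. Pairs
#' involving a constant profile (undefined correlation) are excluded from
#' the mean and logged.
#'
#' @param mat samples x features abundance matrix (>= 2 samples).
#' @return `list(matrix, mean_pairwise)`.
#' @export
profile_correlation <- function(mat) {
  ab_assert(nrow(mat) >= 2, "need at least two samples")
  cm <- suppressWarnings(stats::cor(t(mat)))
  off <- cm[upper.tri(cm)]
  if (anyNA(off)) {
    ab_log("excluding %d sample pairs with undefined correlation",
           sum(is.na(off)))
  }
  list(matrix = cm, mean_pairwise = mean(off, na.rm = TRUE))
}

#' PCA ordination of samples from an abundance matrix
#'
#' Column-centered (not variance-scaled) principal component analysis.
#' Loadings follow a deterministic sign convention (the largest-magnitude
#' loading of each component is positive) so top-loading lists are stable.
#'
#' @param mat samples x features matrix (>= 3 samples, >= 2 features).
#' @param n_top number of top-|loading| features reported per component.
#' @return an `ordination_result`: list with `scores`, `var_explained`,
#'   `top_loadings` (one data.frame per component: feature, loading).
#' @export
pca_ordination <- function(mat, n_top = 10L) {
  ab_assert(nrow(mat) >= 3, "PCA ordination needs at least 3 samples")
  ab_assert(ncol(mat) >= 2, "PCA ordination needs at least 2 features")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  var_explained <- pc$sdev^2 / sum(pc$sdev^2)
  for (j in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  top <- lapply(seq_len(ncol(pc$rotation)), function(j) {
    ld <- pc$rotation[, j]
    ord <- order(-abs(ld))[seq_len(min(n_top, length(ld)))]
    data.frame(feature = names(ld)[ord], loading = unname(ld[ord]),
               stringsAsFactors = FALSE)
  })
  names(top) <- colnames(pc$rotation)
  structure(list(scores = pc$x, var_explained = var_explained,
                 top_loadings = top),
            class = "ordination_result")
}

#' Stringent identity/coverage filter for resistance and virulence hits
#'
#' Retains matches with identity >= `min_identity` percent AND coverage of
#' the peptide length >= `min_cov` percent (both inclusive). Used for
#' antibiotic-resistance and virulence-factor searches, where only
#' near-exact matches are trusted.
#'
#' @param hits data.frame with `pct_identity` and `pct_coverage` columns;
#'   an empty input yields an empty result.
#' @param min_identity,min_cov inclusive thresholds (default 90/90).
#' @return the retained subset of `hits`.
#' @export
stringent_match_filter <- function(hits, min_identity = 90, min_cov = 90) {
  keep <- hits$pct_identity >= min_identity & hits$pct_coverage >= min_cov
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
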