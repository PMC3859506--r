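# Two-component GC mixture decomposition. The unclassified reads' binned
# %(G+C) distribution U is modelled as X = p*E + (1-p)*PV, with E and PV
# the distributions of the eukaryotic and prokaryotic/viral reads; p is
# the grid value minimizing the symmetric Kullback-Leibler distance
# between X and U.

#' Bin GC values into a percent-scale histogram
#'
#' 101 integer-percent bins: bin i covers `[i, i+1)` percent for
#' i = 0..99, with the last bin `[100, 100]` closed. `NA` values (all-N
#' reads) are excluded and counted in the `n_excluded` field.
#'
#' @param gc numeric vector of GC fractions in `[0, 1]` (NAs allowed).
#' @return a `gc_distribution`: list with `prob` (length 101, sums to 1),
#'   `n`, `n_excluded`.
#' @export
gc_histogram <- function(gc) {
  usable <- gc[!is.na(gc)]
  ab_assert(length(usable) > 0, "no usable GC values")
  ab_assert(all(usable >= 0 & usable <= 1), "GC values must lie in [0,1]")
  bin <- pmin(floor(usable * 100), 100)
  counts <- tabulate(bin + 1L, nbins = 101L)
  structure(list(prob = counts / sum(counts), n = length(usable),
                 n_excluded = sum(is.na(gc))),
            class = "gc_distribution")
}

#' Symmetric Kullback-Leibler distance between two binned distributions
#'
#' `D(P, Q) = sum_i (p_i - q_i) * ln(p_i / q_i)` (natural log), computed
#' after adding a pseudocount of 1e-9 to every bin and renormalizing, so
#' empty bins never produce infinities. Symmetric, non-negative, and zero
#' iff the smoothed distributions coincide.
#'
#' @param p,q `gc_distribution` objects or plain probability vectors on
#'   identical bins.
#' @param eps pseudocount added to every bin before renormalization.
#' @return a non-negative number.
#' @export
symmetric_kl <- function(p, q, eps = 1e-9) {
  pv <- if (inherits(p, "gc_distribution")) p$prob else p
  qv <- if (inherits(q, "gc_distribution")) q$prob else q
  ab_assert(length(pv) == length(qv),
            "distributions are binned differently (%d vs %d bins)",
            length(pv), length(qv))
  pv <- (pv + eps) / sum(pv + eps)
  qv <- (qv + eps) / sum(qv + eps)
  sum((pv - qv) * log(pv / qv))
}

#' Fit the mixing proportion p of a two-component GC mixture
#'
#' Grid search over p in {0, 0.001, ..., 1}: for each p the mixture
#' `X = p*E + (1-p)*PV` is compared to `U` by [symmetric_kl()]; the argmin
#' is returned (ties resolved to the smallest p) together with the full
#' objective curve. A warning is emitted when E and PV are nearly
#' identical (symmetric KL < 0.05), in which case p is not identifiable.
#'
#' @param u,e,pv `gc_distribution` objects on identical bins: the target
#'   (unclassified) distribution and the two components.
#' @param grid_step resolution of the p grid (default 0.001).
#' @return a `mixture_fit`: list with `p`, `kl`, and `curve`
#'   (data.frame `p`, `kl`).
#' @export
fit_mixture_p <- function(u, e, pv, grid_step = 0.001) {
  uv <- if (inherits(u, "gc_distribution")) u$prob else u
  ev <- if (inherits(e, "gc_distribution")) e$prob else e
  pvv <- if (inherits(pv, "gc_distribution")) pv$prob else pv
  ab_assert(length(uv) == length(ev) && length(ev) == length(pvv),
            "u, e and pv must share one binning")
  if (symmetric_kl(ev, pvv) < 0.05) {
    warning("components E and PV are nearly identical (symmetric KL < ",
            "0.05); the fitted p is not meaningful", call. = FALSE)
  }
  grid <- seq(0, 1, by = grid_step)
  eps <- 1e-9
  us <- (uv + eps) / sum(uv + eps)
  mix <- outer(grid, ev) + outer(1 - grid, pvv)   # rows: p, cols: bins
  mix <- mix + eps
  mix <- mix / rowSums(mix)
  lu <- log(us)
  kl <- rowSums((mix - rep(us, each = length(grid))) *
                  (log(mix) - rep(lu, each = length(grid))))
  best <- which.min(kl)                            # first = smallest p on ties
  structure(list(p = grid[best], kl = kl[best],
                 curve = data.frame(p = grid, kl = kl)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("GC mixture fit: p = %.3f (symmetric KL = %.5f)\n", x$p, x$kl))
  invisible(x)
}
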