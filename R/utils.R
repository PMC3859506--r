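# Small shared helpers: reverse complement, rounding, seeded evaluation,
# logging. Everything downstream assumes sequences are uppercase ACGTN.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of nucleotide strings
#'
#' Vectorised over a character vector of uppercase ACGTN sequences.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(COMPLEMENT[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Unlike [base::round()] (banker's rounding), ties go up: 0.5 -> 1,
#' 73.5 -> 74. Used wherever percentages are rendered at printed precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG seed, restoring RNG state afterwards.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Package-level logging: quiet by default, enabled with
# options(aerobiome.verbose = TRUE).
ab_log <- function(...) {
  if (isTRUE(getOption("aerobiome.verbose", FALSE))) {
    message("[aerobiome] ", sprintf(...))
  }
  invisible(NULL)
}

# stopifnot() with a formatted message
ab_assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# union length of 0-based half-open intervals (data.frame with start/end)
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  sum(IRanges::width(ir))
}

# merge overlapping/adjacent 0-based half-open intervals
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = start + 1L, end = end))
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}
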