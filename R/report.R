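# Results arithmetic over kingdom count tables: assignment percentages,
# kingdom shares of the assigned fraction, cross-sample totals and
# percentage rendering at printed precision (half-up).

#' Kingdom classification counts for the six airborne metagenome samples
#'
#' The published per-sample read counts over the seven taxonomic
#' categories for six air samples (NYC indoor/outdoor office building,
#' San Diego indoor/outdoor hospital, house, pier), shipped as package
#' data. Used by the worked examples and the acceptance script.
#'
#' @return a `kingdom_count_table` with six samples.
#' @export
air_sample_kingdom_counts <- function() {
  path <- system.file("extdata", "air_sample_kingdom_counts.tsv",
                      package = "aerobiome")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  kingdom_count_table(df)
}

#' 16S amplicon chimera counts for the NYC samples
#'
#' Sequence totals and ChimeraSlayer-flagged counts for the two NYC 16S
#' amplicon datasets; input to [chimera_percent()].
#'
#' @return data.frame (`sample`, `n_sequences`, `n_chimeras`).
#' @export
air_sample_16s_counts <- function() {
  path <- system.file("extdata", "air_sample_16s_counts.tsv",
                      package = "aerobiome")
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Assignment summary of a kingdom count table
#'
#' Per sample: `assigned = Total - Unclassified` (Mixed and Other count as
#' assigned), `assigned_pct = 100 * assigned / Total`, and each kingdom's
#' percentage of the assigned reads. The mean assignment percentage is the
#' unweighted mean of the per-sample percentages. Raw unrounded values are
#' always reported; `*_rounded` columns render them half-up at integer
#' precision.
#'
#' @param table a `kingdom_count_table`.
#' @return an `assignment_summary`: list with `per_sample` (data.frame),
#'   `kingdom_pct_of_assigned` (matrix), `mean_assigned_pct`,
#'   `grand_total`.
#' @export
assignment_summary <- function(table) {
  ab_assert(all(table$Total > 0), "sample with zero total reads")
  assigned <- table$Total - table$Unclassified
  assigned_pct <- 100 * assigned / table$Total
  kingdoms <- setdiff(KINGDOM_LEVELS, "Unclassified")
  share <- 100 * as.matrix(table[kingdoms]) / assigned
  rownames(share) <- table$sample
  per_sample <- data.frame(
    sample = table$sample, total = table$Total, assigned = assigned,
    assigned_pct = assigned_pct,
    assigned_pct_rounded = round_half_up(assigned_pct),
    stringsAsFactors = FALSE)
  structure(list(per_sample = per_sample,
                 kingdom_pct_of_assigned = share,
                 kingdom_pct_of_assigned_rounded = round_half_up(share),
                 mean_assigned_pct = mean(assigned_pct),
                 grand_total = sum(table$Total)),
            class = "assignment_summary")
}

#' @export
print.assignment_summary <- function(x, ...) {
  cat("Assignment summary over", nrow(x$per_sample), "samples\n")
  cat(sprintf("  grand total reads: %s\n",
              format(x$grand_total, big.mark = ",")))
  cat(sprintf("  mean assigned: %.1f%% (rounded %d%%)\n",
              x$mean_assigned_pct, round_half_up(x$mean_assigned_pct)))
  for (i in seq_len(nrow(x$per_sample))) {
    cat(sprintf("  %-12s total %9d assigned %5.1f%%\n",
                x$per_sample$sample[i], x$per_sample$total[i],
                x$per_sample$assigned_pct[i]))
  }
  invisible(x)
}

#' Total reads across one or more kingdom count tables
#'
#' @param tables a `kingdom_count_table` or a list of them; an empty list
#'   gives 0.
#' @return integer sum of all sample totals.
#' @export
grand_total <- function(tables) {
  if (inherits(tables, "kingdom_count_table")) tables <- list(tables)
  sum(vapply(tables, function(t) sum(t$Total), numeric(1)))
}

#' Percentage of flagged chimeric sequences
#'
#' `100 * flagged / total`, rendered to one decimal half-up; the raw value
#' is attached as attribute `"raw"`.
#'
#' @param flagged,total non-negative integers with
#'   `0 <= flagged <= total`, `total > 0`.
#' @return the rendered percentage.
#' @export
chimera_percent <- function(flagged, total) {
  ab_assert(total > 0, "total must be positive")
  ab_assert(flagged >= 0 && flagged <= total,
            "flagged must lie in [0, total]")
  raw <- 100 * flagged / total
  structure(round_half_up(raw, 1), raw = raw)
}
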