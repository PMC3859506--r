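# End-to-end driver over a synthetic community: simulate -> QC -> chimera
# removal -> taxonomy -> GC mixture -> functional profile -> report.
# Every stage appends to a read-count ledger (reads_in = reads_out +
# reads_dropped) and the run manifest records spec, seed and thresholds,
# so a rerun with the same configuration is byte-identical.

#' Run the full pipeline on a synthetic community
#'
#' Generates a community and its reads, injects artifacts at the given
#' rates, then runs every analysis stage and (optionally) writes the
#' stage outputs as TSV/JSON under `out_dir`. No timestamps are written,
#' so reruns with identical arguments produce byte-identical files.
#'
#' @param spec a [community_spec()].
#' @param n_reads number of reads to simulate.
#' @param replicate_rate,chimera_rate,lowcomp_rate artifact rates.
#' @param hit_fraction,noise_fraction parameters of
#'   [fabricate_hit_tables()].
#' @param config a [pipeline_config()]; its `seed` drives all randomness.
#' @param out_dir optional output directory.
#' @return list with `reads`, `truth`, `qc`, `chimera`, `categories`,
#'   `kingdom_table`, `summary`, `gc_fit`, `ko_matrix`, `ledger`,
#'   `manifest`.
#' @export
run_pipeline <- function(spec, n_reads = 2000L,
                         replicate_rate = 0, chimera_rate = 0,
                         lowcomp_rate = 0, hit_fraction = 0.9,
                         noise_fraction = 0,
                         config = pipeline_config(), out_dir = NULL) {
  seed <- config$seed
  genomes <- generate_genomes(spec, seed = seed)
  sim <- simulate_reads(genomes, spec, n_reads, seed = seed + 1L)
  sim <- inject_artifacts(sim$reads, sim$truth, genomes,
                          replicate_rate = replicate_rate,
                          chimera_rate = chimera_rate,
                          lowcomp_rate = lowcomp_rate, seed = seed + 2L)
  reads <- sim$reads
  truth <- sim$truth
  ledger <- data.frame(stage = "input", reads_in = nrow(reads),
                       reads_out = nrow(reads), reads_dropped = 0L,
                       stringsAsFactors = FALSE)
  qc <- run_qc_stage(reads, config = config)
  ledger <- rbind(ledger, data.frame(
    stage = "qc", reads_in = nrow(reads), reads_out = nrow(qc$kept),
    reads_dropped = nrow(reads) - nrow(qc$kept)))
  hits <- all_vs_all_hits(qc$kept)
  chim <- run_chimera_stage(qc$kept, hits, config)
  ledger <- rbind(ledger, data.frame(
    stage = "chimera", reads_in = nrow(qc$kept),
    reads_out = nrow(chim$kept),
    reads_dropped = nrow(qc$kept) - nrow(chim$kept)))
  fab <- fabricate_hit_tables(chim$kept, truth, spec,
                              hit_fraction = hit_fraction,
                              noise_fraction = noise_fraction,
                              seed = seed + 3L)
  categories <- assign_read_taxonomy(chim$kept, fab$nt_hits, fab$peptides,
                                     fab$taxon_map, config)
  ktab <- tabulate_kingdoms(categories)
  summ <- assignment_summary(ktab)
  # GC mixture of the unclassified group against the classified components
  gc <- gc_fraction(chim$kept$seq)
  grp <- categories$category[match(chim$kept$id, categories$read_id)]
  is_euk <- grp == "Eukaryota"
  is_pv <- grp %in% c("Archaea", "Bacteria", "Viruses")
  is_un <- grp == "Unclassified"
  gc_fit <- NULL
  if (sum(is_un) > 0 && sum(is_euk) > 0 && sum(is_pv) > 0) {
    gc_fit <- fit_mixture_p(gc_histogram(gc[is_un]),
                            gc_histogram(gc[is_euk]),
                            gc_histogram(gc[is_pv]))
  }
  ko_matrix <- NULL
  bact <- fab$peptides[fab$peptides$kingdom == "Bacteria" &
                         fab$peptides$read_id %in% chim$kept$id, ]
  if (nrow(bact) > 0) {
    mrl <- stats::aggregate(length ~ sample, data = chim$kept, FUN = mean)
    names(mrl) <- c("sample", "mean_read_len")
    ko_matrix <- ko_abundance(bact, mrl)
  }
  manifest <- list(
    tool = "aerobiome", version = "0.1.0", seed = seed,
    thresholds = unclass(config),
    community = as.data.frame(spec),
    n_reads = n_reads,
    rates = list(replicate = replicate_rate, chimera = chimera_rate,
                 lowcomp = lowcomp_rate),
    ledger = ledger)
  res <- list(reads = reads, truth = truth, qc = qc, chimera = chim,
              categories = categories, kingdom_table = ktab,
              summary = summ, gc_fit = gc_fit, ko_matrix = ko_matrix,
              ledger = ledger, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_sequences(res$chimera$kept, file.path(out_dir, "reads_clean.fasta"))
  tsv(res$qc$outcomes, "qc_outcomes.tsv")
  tsv(res$chimera$verdicts, "chimera_verdicts.tsv")
  tsv(res$categories, "read_categories.tsv")
  tsv(as.data.frame(res$kingdom_table), "kingdom_counts.tsv")
  tsv(res$ledger, "ledger.tsv")
  if (!is.null(res$gc_fit)) {
    tsv(res$gc_fit$curve, "gc_mixture_curve.tsv")
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
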