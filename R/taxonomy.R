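# Two-tier kingdom assignment: a nucleotide prescreen that classifies a
# read as eukaryotic only when every retained nucleotide hit is eukaryotic,
# then transfer of peptide-level taxonomy (best protein hit) onto the read,
# tabulated over the seven categories Archaea / Bacteria / Eukaryota /
# Mixed / Viruses / Other / Unclassified.

#' Nucleotide prescreen of a read
#'
#' Retains the top `max_hits` nucleotide hits by bit score with e-value
#' strictly below `evalue_cutoff`; the read is classified `Eukaryota` iff
#' the retained set is non-empty and every subject is eukaryotic,
#' otherwise `undetermined` (it then falls through to the peptide path).
#'
#' @param hits nucleotide hit records for one read.
#' @param taxon_map subject taxonomy from [read_taxon_map()].
#' @param max_hits maximum hits retained (default 10).
#' @param evalue_cutoff strict e-value cutoff (default 1e-5).
#' @return `"Eukaryota"` or `"undetermined"`.
#' @export
nucleotide_prescreen <- function(hits, taxon_map, max_hits = 10L,
                                 evalue_cutoff = 1e-5) {
  h <- hits[hits$evalue < evalue_cutoff, ]
  if (nrow(h) == 0L) return("undetermined")
  h <- h[order(-h$bitscore), ]
  h <- utils::head(h, max_hits)
  missing <- setdiff(h$subject_id, taxon_map$subject_id)
  ab_assert(length(missing) == 0L,
            "subjects missing from taxon map: %s",
            paste(unique(missing), collapse = ", "))
  kingdoms <- taxon_map$kingdom[match(h$subject_id, taxon_map$subject_id)]
  if (all(kingdoms == "Eukaryota")) "Eukaryota" else "undetermined"
}

#' Predict peptides on a read (stand-in ORF caller)
#'
#' Six-frame translation; within each frame the longest open stretch
#' between stop codons of at least `min_aa` residues is reported. This is
#' a declared stand-in for a frameshift-aware gene caller, adequate for
#' synthetic data without indel errors. Deterministic; a read and its
#' reverse complement yield the same peptide set.
#'
#' @param read one-row read set (or a list with `id` and `seq`).
#' @param min_aa minimum peptide length in residues (default 60).
#' @return data.frame (`peptide_id`, `read_id`, `frame`, `aa_seq`,
#'   `aa_len`); zero rows when no frame has an ORF of `min_aa`.
#' @export
predict_peptides <- function(read, min_aa = 60L) {
  seqs <- c(read$seq[1], revcomp(read$seq[1]))
  frames <- expand.grid(off = 0:2, strand = c("+", "-"),
                        stringsAsFactors = FALSE)
  out <- list()
  for (f in seq_len(nrow(frames))) {
    s <- seqs[if (frames$strand[f] == "+") 1L else 2L]
    sub <- substr(s, 1L + frames$off[f], nchar(s))
    sub <- substr(sub, 1L, nchar(sub) - nchar(sub) %% 3L)
    if (nchar(sub) < 3L) next
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                             if.fuzzy.codon = "X"))
    pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
    if (length(pieces) == 0L) next
    longest <- pieces[which.max(nchar(pieces))]
    if (nchar(longest) >= min_aa) {
      out[[length(out) + 1L]] <- data.frame(
        read_id = read$id[1],
        frame = paste0(frames$strand[f], frames$off[f] + 1L),
        aa_seq = longest, aa_len = nchar(longest),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(peptide_id = character(0), read_id = character(0),
                      frame = character(0), aa_seq = character(0),
                      aa_len = integer(0)))
  }
  df <- do.call(rbind, out)
  df$peptide_id <- paste0(df$read_id, "_orf", seq_len(nrow(df)))
  df[c("peptide_id", "read_id", "frame", "aa_seq", "aa_len")]
}

#' Kingdom of a peptide from its best protein hit
#'
#' The kingdom of the highest-bitscore hit with e-value strictly below the
#' cutoff; equal bit scores are broken deterministically by
#' lexicographically smallest subject id (order-invariant). `unclassified`
#' when no hit qualifies.
#'
#' @param hits protein hit records for one peptide.
#' @param taxon_map subject taxonomy.
#' @param evalue_cutoff strict e-value cutoff (default 1e-5).
#' @return a kingdom string or `"unclassified"`.
#' @export
assign_peptide_taxonomy <- function(hits, taxon_map, evalue_cutoff = 1e-5) {
  h <- hits[hits$evalue < evalue_cutoff, ]
  if (nrow(h) == 0L) return("unclassified")
  h <- h[order(-h$bitscore, h$subject_id), ]
  missing <- setdiff(h$subject_id[1], taxon_map$subject_id)
  ab_assert(length(missing) == 0L,
            "subjects missing from taxon map: %s",
            paste(missing, collapse = ", "))
  taxon_map$kingdom[match(h$subject_id[1], taxon_map$subject_id)]
}

#' Transfer peptide kingdoms onto their read
#'
#' All classified peptides agreeing on one kingdom transfer it to the read
#' (unclassified peptides do not block the transfer); two or more distinct
#' kingdoms among the classified peptides give `Mixed`; no classified
#' peptide gives `Unclassified`.
#'
#' @param peptide_kingdoms character vector of per-peptide kingdoms
#'   (possibly including `"unclassified"`; possibly empty).
#' @return one of the seven category labels.
#' @export
transfer_to_read <- function(peptide_kingdoms) {
  cls <- setdiff(unique(peptide_kingdoms), "unclassified")
  if (length(cls) == 0L) return("Unclassified")
  if (length(cls) >= 2L) return("Mixed")
  cls
}

#' Assign kingdoms to all reads
#'
#' Orchestrates the two tiers: reads whose nucleotide prescreen returns
#' `Eukaryota` are finalized there and never reach the peptide path; all
#' other reads take the category given by [transfer_to_read()] over their
#' peptide kingdoms. Peptide kingdoms are supplied either precomputed in a
#' peptide annotation table (column `kingdom`) or derived from protein
#' hits via [assign_peptide_taxonomy()].
#'
#' @param reads a read set.
#' @param nt_hits nucleotide hit table (may be empty).
#' @param peptides peptide annotation table with columns `read_id`,
#'   `kingdom` (and optionally `genus`).
#' @param taxon_map subject taxonomy.
#' @param config a [pipeline_config()].
#' @return data.frame (`read_id`, `sample`, `category`).
#' @export
assign_read_taxonomy <- function(reads, nt_hits, peptides, taxon_map,
                                 config = pipeline_config()) {
  nt_by_read <- split(seq_len(nrow(nt_hits)), nt_hits$query_id)
  pep_by_read <- split(peptides$kingdom, peptides$read_id)
  category <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    id <- reads$id[i]
    rows <- nt_by_read[[id]]
    pre <- if (is.null(rows)) "undetermined" else {
      nucleotide_prescreen(nt_hits[rows, ], taxon_map,
                           config$max_nt_hits, config$nt_evalue_cutoff)
    }
    category[i] <- if (pre == "Eukaryota") "Eukaryota" else {
      transfer_to_read(pep_by_read[[id]] %||% character(0))
    }
  }
  data.frame(read_id = reads$id, sample = reads$sample,
             category = category, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate per-read categories into a kingdom count table
#'
#' One row per sample with integer counts over the seven categories and a
#' `Total` column equal to the number of reads in the sample.
#'
#' @param categories data.frame (`read_id`, `sample`, `category`).
#' @return a `kingdom_count_table` data.frame.
#' @export
tabulate_kingdoms <- function(categories) {
  ab_assert(all(categories$category %in% KINGDOM_LEVELS),
            "unknown category: %s",
            paste(setdiff(unique(categories$category), KINGDOM_LEVELS),
                  collapse = ", "))
  tab <- table(factor(categories$sample),
               factor(categories$category, levels = KINGDOM_LEVELS))
  df <- as.data.frame.matrix(tab)
  df <- cbind(sample = rownames(df), df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df$Total <- rowSums(df[KINGDOM_LEVELS])
  kingdom_count_table(df)
}

#' Construct / validate a kingdom count table
#'
#' @param df data.frame with columns `sample`, the seven category counts
#'   and optionally `Total` (recomputed if absent; validated if present).
#' @return the validated table, classed `kingdom_count_table`.
#' @export
kingdom_count_table <- function(df) {
  need <- c("sample", KINGDOM_LEVELS)
  ab_assert(all(need %in% names(df)), "kingdom table needs columns: %s",
            paste(need, collapse = ", "))
  counts <- as.matrix(df[KINGDOM_LEVELS])
  ab_assert(all(counts >= 0), "negative counts in kingdom table")
  tot <- rowSums(counts)
  if ("Total" %in% names(df)) {
    ab_assert(all(df$Total == tot),
              "Total does not equal the sum of the seven categories")
  } else {
    df$Total <- tot
  }
  class(df) <- c("kingdom_count_table", "data.frame")
  df
}

#' Genus relative abundances and the low-abundance tail share
#'
#' Abundances are proportions of genus-labelled bacterial reads (reads
#' without genus resolution are excluded from the denominator). The tail
#' share is the summed abundance of genera individually below
#' `tail_cutoff` percent.
#'
#' @param genus_labels character vector of genus labels of the bacterial
#'   reads in one sample (`NA` = no genus resolution).
#' @param tail_cutoff percent cutoff defining the tail (default 2).
#' @return `list(profile, tail_share_pct)`; `profile` is a data.frame
#'   (`genus`, `count`, `abundance_pct`) sorted by decreasing abundance.
#' @export
genus_profile <- function(genus_labels, tail_cutoff = 2) {
  labels <- genus_labels[!is.na(genus_labels)]
  ab_assert(length(labels) > 0, "no genus-labelled reads")
  counts <- sort(table(labels), decreasing = TRUE)
  pct <- 100 * as.numeric(counts) / length(labels)
  profile <- data.frame(genus = names(counts), count = as.integer(counts),
                        abundance_pct = pct, stringsAsFactors = FALSE)
  list(profile = profile,
       tail_share_pct = sum(pct[pct < tail_cutoff]))
}
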