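# Readers and writers for the formats the pipeline consumes: FASTA/FASTQ
# reads, twelve-column tabular alignment hits, 3-column BED masks,
# subject-taxonomy maps. Coordinate conventions are centralized here:
# hit tables are 1-based inclusive (the dialect's convention), mask
# intervals are 0-based half-open.

KINGDOM_LEVELS <- c("Archaea", "Bacteria", "Eukaryota", "Mixed",
                    "Viruses", "Other", "Unclassified")

#' Construct a read set
#'
#' The atom of the pipeline: identified nucleotide sequences with a sample
#' label. Sequences are normalized to uppercase; `U` becomes `T`; ambiguity
#' codes other than `N` become `N` (counted and logged).
#'
#' @param id character vector of unique read identifiers.
#' @param seq character vector of nucleotide sequences.
#' @param sample sample label (recycled) or vector.
#' @return a `data.frame` with columns `id`, `seq`, `sample`, `length`.
#' @export
read_set <- function(id, seq, sample = "sample1") {
  ab_assert(length(id) == length(seq), "id and seq lengths differ")
  seq <- normalize_sequences(as.character(seq))
  ab_assert(all(nchar(seq) > 0L), "empty sequences are not allowed")
  df <- data.frame(id = as.character(id), seq = seq,
                   sample = rep_len(as.character(sample), length(id)),
                   length = nchar(seq), stringsAsFactors = FALSE)
  dup <- df$id[duplicated(paste(df$sample, df$id))]
  ab_assert(length(dup) == 0L, "duplicate read ids within a sample: %s",
            paste(utils::head(dup, 5), collapse = ", "))
  df
}

normalize_sequences <- function(seq) {
  up <- toupper(chartr("u", "t", seq))
  n_lower <- sum(up != seq & toupper(seq) == up)
  clean <- gsub("[^ACGTN]", "N", up)
  n_amb <- sum(nchar(gsub("[^ACGTN]", "", up)) != nchar(up))
  if (n_lower > 0) ab_log("upper-cased %d sequences on ingest", n_lower)
  if (n_amb > 0) {
    ab_log("replaced non-ACGTN ambiguity codes with N in %d sequences", n_amb)
  }
  clean
}

#' Read sequences from FASTA or FASTQ
#'
#' Ids are taken verbatim up to the first whitespace; record order is
#' preserved. An empty file yields an empty read set. Malformed FASTQ
#' records (including quality strings whose length differs from the
#' sequence) raise a parse error naming the offending line.
#'
#' @param path input file.
#' @param format `"fasta"` or `"fastq"`.
#' @param sample sample label attached to every read; defaults to the file
#'   name without extension.
#' @return a read set `data.frame` (see [read_set()]).
#' @export
read_sequences <- function(path, format = c("fasta", "fastq"),
                           sample = NULL) {
  format <- match.arg(format)
  ab_assert(file.exists(path), "no such file: %s", path)
  if (is.null(sample)) sample <- tools::file_path_sans_ext(basename(path))
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                    error = function(e) {
                      stop(sprintf("parse error in FASTA '%s': %s",
                                   path, conditionMessage(e)), call. = FALSE)
                    })
    if (length(set) == 0L) return(empty_read_set(sample))
    ids <- sub("\\s.*$", "", names(set))
    return(read_set(ids, as.character(set), sample))
  }
  lines <- readLines(path)
  if (length(lines) == 0L) return(empty_read_set(sample))
  ab_assert(length(lines) %% 4L == 0L,
            "parse error in FASTQ '%s': truncated record at line %d",
            path, length(lines))
  idx <- seq(1L, length(lines), by = 4L)
  for (i in idx) {
    if (!startsWith(lines[i], "@")) {
      stop(sprintf("parse error in FASTQ '%s' at line %d: expected '@' header",
                   path, i), call. = FALSE)
    }
    if (!startsWith(lines[i + 2L], "+")) {
      stop(sprintf("parse error in FASTQ '%s' at line %d: expected '+' line",
                   path, i + 2L), call. = FALSE)
    }
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) {
      stop(sprintf(paste0("parse error in FASTQ '%s' at line %d: quality ",
                          "length %d != sequence length %d"),
                   path, i + 3L, nchar(lines[i + 3L]), nchar(lines[i + 1L])),
           call. = FALSE)
    }
  }
  ids <- sub("\\s.*$", "", sub("^@", "", lines[idx]))
  read_set(ids, lines[idx + 1L], sample)
}

empty_read_set <- function(sample) {
  data.frame(id = character(0), seq = character(0),
             sample = character(0), length = integer(0),
             stringsAsFactors = FALSE)
}

#' Write a read set as FASTA
#'
#' One unwrapped sequence line per record so that write/read round-trips are
#' byte-identical.
#'
#' @param reads a read set.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path) {
  out <- character(2L * nrow(reads))
  if (nrow(reads) > 0) {
    out[c(TRUE, FALSE)] <- paste0(">", reads$id)
    out[c(FALSE, TRUE)] <- reads$seq
  }
  writeLines(out, path)
  invisible(path)
}

HIT_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
              "mismatches", "gap_opens", "q_start", "q_end",
              "s_start", "s_end", "evalue", "bitscore")

#' Read a twelve-column tabular alignment hit table
#'
#' The standard tab-separated local-alignment dialect: query, subject,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score. Subject coordinates
#' with `s_start > s_end` denote a minus-strand match; they are normalized
#' so `s_start <= s_end` and recorded in a `strand` column.
#'
#' @param path input file; an empty file yields an empty table.
#' @return a `data.frame` of hit records with a 13th column `strand`.
#' @export
read_hit_table <- function(path) {
  ab_assert(file.exists(path), "no such file: %s", path)
  if (file.size(path) == 0L) return(empty_hit_table())
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  bad <- which(nf != 12L)
  ab_assert(length(bad) == 0L,
            "parse error in hit table '%s' at line %d: %d columns (need 12)",
            path, if (length(bad)) bad[1] else 0L,
            if (length(bad)) nf[bad[1]] else 0L)
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          col.names = HIT_COLS, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (cc in HIT_COLS[3:12]) {
    num <- suppressWarnings(as.numeric(df[[cc]]))
    ab_assert(!anyNA(num),
              "parse error in hit table '%s': non-numeric value in column %s",
              path, cc)
    df[[cc]] <- num
  }
  as_hit_table(df)
}

# normalize strand from raw 12-column records
as_hit_table <- function(df) {
  minus <- df$s_start > df$s_end
  tmp <- df$s_start[minus]
  df$s_start[minus] <- df$s_end[minus]
  df$s_end[minus] <- tmp
  df$strand <- ifelse(minus, "minus", "plus")
  ints <- c("aln_length", "mismatches", "gap_opens",
            "q_start", "q_end", "s_start", "s_end")
  for (cc in ints) df[[cc]] <- as.integer(df[[cc]])
  ab_assert(all(df$pct_identity >= 0 & df$pct_identity <= 100),
            "pct_identity outside [0,100]")
  ab_assert(all(df$q_start <= df$q_end), "q_start > q_end in hit table")
  df
}

empty_hit_table <- function() {
  df <- as.data.frame(stats::setNames(
    c(list(character(0), character(0)), rep(list(numeric(0)), 10)),
    HIT_COLS))
  df$strand <- character(0)
  df
}

#' Write a hit table in the twelve-column dialect
#'
#' Minus-strand records are serialized with swapped subject coordinates so
#' that [read_hit_table()] recovers identical records.
#'
#' @param hits a hit table `data.frame`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits[HIT_COLS]
  minus <- hits$strand == "minus"
  tmp <- out$s_start[minus]
  out$s_start[minus] <- out$s_end[minus]
  out$s_end[minus] <- tmp
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column BED mask file
#'
#' 0-based half-open intervals on reads (chromosome column carries the
#' read id).
#'
#' @param path input BED.
#' @return `data.frame` with `read_id`, `start`, `end`.
#' @export
read_mask_bed <- function(path) {
  ab_assert(file.exists(path), "no such file: %s", path)
  if (file.size(path) == 0L) {
    return(data.frame(read_id = character(0), start = integer(0),
                      end = integer(0)))
  }
  df <- utils::read.table(path, sep = "\t", quote = "",
                          col.names = c("read_id", "start", "end"),
                          colClasses = c("character", "integer", "integer"))
  ab_assert(all(df$start >= 0L & df$start < df$end),
            "invalid BED interval (need 0 <= start < end)")
  df
}

#' Read a subject-to-taxonomy map
#'
#' Tab-separated with header `subject_id`, `kingdom`, `phylum`, `genus`.
#' The kingdom column accepts the seven category tokens plus `other` for
#' unidentifiable/synthetic subjects.
#'
#' @param path input TSV.
#' @return `data.frame` keyed by `subject_id`.
#' @export
read_taxon_map <- function(path) {
  ab_assert(file.exists(path), "no such file: %s", path)
  df <- utils::read.table(path, sep = "\t", quote = "", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("subject_id", "kingdom", "phylum", "genus")
  ab_assert(all(need %in% names(df)),
            "taxon map must have columns: %s", paste(need, collapse = ", "))
  df$kingdom <- normalize_kingdom(df$kingdom)
  df
}

normalize_kingdom <- function(x) {
  x <- as.character(x)
  x[tolower(x) == "other"] <- "Other"
  x[tolower(x) %in% c("virus", "viruses")] <- "Viruses"
  ok <- x %in% c("Archaea", "Bacteria", "Eukaryota", "Viruses", "Other")
  ab_assert(all(ok), "unknown kingdom token(s): %s",
            paste(unique(x[!ok]), collapse = ", "))
  x
}

#' GC fraction of nucleotide sequences
#'
#' `(G + C) / (A + C + G + T)`; `N` and other ambiguity codes are excluded
#' from both numerator and denominator. A sequence with no unambiguous
#' bases yields `NA` (excluded downstream, counted in metadata).
#'
#' @param seq character vector of sequences (non-empty strings).
#' @return numeric vector in `[0, 1]` (or `NA` for all-N sequences).
#' @export
gc_fraction <- function(seq) {
  ab_assert(length(seq) > 0L && all(nchar(seq) > 0L),
            "gc_fraction: empty sequence")
  x <- Biostrings::DNAStringSet(normalize_sequences(seq))
  counts <- Biostrings::letterFrequency(x, letters = c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  gc <- (counts[, "G"] + counts[, "C"]) / denom
  gc[denom == 0] <- NA_real_
  unname(gc)
}
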