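# Synthetic communities, 454-style reads, amplification artifacts and GC
# mixtures with full truth labels. Every generator is a pure function of
# (spec, seed), so downstream filters can be scored against known truth
# without any external database or download.

#' Describe a synthetic community
#'
#' One row per source genome: label, kingdom, genus, genome length, target
#' GC fraction and relative abundance (must sum to 1).
#'
#' @param label character vector of genome labels.
#' @param kingdom kingdom per genome (`Archaea`, `Bacteria`, `Eukaryota`,
#'   `Viruses`).
#' @param genus genus label per genome.
#' @param length genome length in bases (>= 1000).
#' @param gc target GC fraction in (0, 1).
#' @param abundance relative abundances, summing to 1.
#' @return a `community_spec` data.frame.
#' @export
community_spec <- function(label, kingdom, genus, length, gc, abundance) {
  kingdom <- as.character(kingdom)
  ab_assert(all(kingdom %in% c("Archaea", "Bacteria", "Eukaryota", "Viruses")),
            "kingdom must be one of Archaea/Bacteria/Eukaryota/Viruses")
  ab_assert(all(length >= 1000L), "genome length must be >= 1000 bases")
  ab_assert(all(gc > 0 & gc < 1), "target GC must lie strictly in (0,1)")
  ab_assert(abs(sum(abundance) - 1) <= 1e-9, "abundances must sum to 1")
  ab_assert(all(abundance >= 0), "abundances must be non-negative")
  structure(data.frame(label = as.character(label), kingdom = kingdom,
                       genus = as.character(genus),
                       length = as.integer(length), gc = gc,
                       abundance = abundance, stringsAsFactors = FALSE),
            class = c("community_spec", "data.frame"))
}

#' Generate genome sequences for a community
#'
#' Bases are drawn iid with per-base GC probability equal to the target, so
#' the realized GC fraction concentrates within ~2 binomial standard
#' deviations of the target for genomes of the minimum length.
#'
#' @param spec a [community_spec()].
#' @param seed integer seed; the same seed reproduces the same genomes.
#' @return named character vector of genome sequences.
#' @export
generate_genomes <- function(spec, seed = 1L) {
  with_seed(as.integer(seed), {
    genomes <- vapply(seq_len(nrow(spec)), function(i) {
      g <- spec$gc[i]
      probs <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
      paste(sample(names(probs), spec$length[i], replace = TRUE, prob = probs),
            collapse = "")
    }, character(1))
    names(genomes) <- spec$label
    genomes
  })
}

#' Simulate single-end shotgun reads from a community
#'
#' Each read picks a source genome with probability equal to its abundance,
#' a uniform start position, a truncated-normal length (minimum 50 bases,
#' emulating 454 FLX/Titanium read lengths) and a uniform strand. The truth
#' table records source genome, interval and strand for every read.
#'
#' @param genomes named character vector from [generate_genomes()].
#' @param spec the [community_spec()] the genomes were built from.
#' @param n_reads number of reads (>= 1).
#' @param length_mean,length_sd,length_min read-length model in bases.
#' @param error_rate optional uniform substitution rate (default 0; the
#'   artifact filters are not error-driven).
#' @param sample sample label for the emitted reads.
#' @param seed integer seed.
#' @return `list(reads = <read set>, truth = <truth table>)`.
#' @export
simulate_reads <- function(genomes, spec, n_reads,
                           length_mean = 350, length_sd = 80,
                           length_min = 50L, error_rate = 0,
                           sample = "synthetic", seed = 1L) {
  ab_assert(n_reads >= 1L, "n_reads must be >= 1")
  ab_assert(all(nchar(genomes) >= length_min),
            "genome shorter than the minimum read length")
  with_seed(as.integer(seed), {
    gidx <- sample.int(length(genomes), n_reads, replace = TRUE,
                       prob = spec$abundance)
    len <- pmin(rtrunc_norm(n_reads, length_mean, length_sd, length_min),
                nchar(genomes)[gidx])
    start <- vapply(seq_len(n_reads), function(i) {
      sample.int(nchar(genomes)[gidx[i]] - len[i] + 1L, 1L)
    }, integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substr(genomes[gidx], start, start + len - 1L)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    if (error_rate > 0) seqs <- mutate_uniform(seqs, error_rate)
    ids <- sprintf("read%06d", seq_len(n_reads))
    reads <- read_set(ids, unname(seqs), sample)
    truth <- data.frame(
      read_id = ids, sample = sample,
      genome = names(genomes)[gidx], kingdom = spec$kingdom[gidx],
      genus = spec$genus[gidx],
      start = start, end = start + len - 1L, strand = strand,
      is_replicate = FALSE, replicate_group = NA_character_,
      is_chimera = FALSE, chimera_class = "none",
      lowcomp = FALSE, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

# truncated normal by resampling below the floor
rtrunc_norm <- function(n, mean, sd, minimum) {
  x <- round(stats::rnorm(n, mean, sd))
  while (any(x < minimum)) {
    bad <- x < minimum
    x[bad] <- round(stats::rnorm(sum(bad), mean, sd))
  }
  as.integer(x)
}

mutate_uniform <- function(seqs, rate) {
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Inject amplification and sequencing artifacts into a read set
#'
#' Three artifact classes, each flagged in the returned truth table:
#' * artificial replicates — copies of existing reads sharing the original's
#'   start, with up to 10% trailing truncation, appended to the set;
#' * MDA chimeras — a read is rebuilt from its source genome as either an
#'   *inverted* junction (prefix segment followed by the reverse complement
#'   of an overlapping segment; the overlap is the duplicated block) or a
#'   *transposed direct* junction (two same-strand segments emitted in
#'   swapped order, gap <= 2 kb);
#' * low-complexity stretches — a tandem dinucleotide repeat overwrites 55 to
#'   80% of the read.
#'
#' Chimera, low-complexity and replicate-origin reads are chosen from
#' disjoint subsets so each read carries one truth label. Inverted chimeras
#' draw their duplicated block length >= `block_min` except for a
#' `hard_fraction` of cases drawn from 10..(block_min - 1), which are
#' invisible to the internal-repeat rule by construction.
#'
#' @param reads,truth output of [simulate_reads()].
#' @param genomes the source genomes.
#' @param replicate_rate,chimera_rate,lowcomp_rate per-read Bernoulli rates
#'   in `[0, 1]`.
#' @param block_min minimum duplicated-block length for detectable inverted
#'   chimeras (default 25).
#' @param hard_fraction fraction of inverted chimeras given a sub-`block_min`
#'   duplicated block.
#' @param seed integer seed.
#' @return `list(reads, truth)` with artifacts applied.
#' @export
inject_artifacts <- function(reads, truth, genomes,
                             replicate_rate = 0, chimera_rate = 0,
                             lowcomp_rate = 0, block_min = 25L,
                             hard_fraction = 0, seed = 1L) {
  for (r in c(replicate_rate, chimera_rate, lowcomp_rate)) {
    ab_assert(r >= 0 && r <= 1, "artifact rates must lie in [0,1]")
  }
  with_seed(as.integer(seed), {
    n <- nrow(reads)
    u <- stats::runif(n)
    as_chimera <- u < chimera_rate
    as_lowcomp <- !as_chimera & u < chimera_rate + lowcomp_rate
    for (i in which(as_chimera)) {
      cls <- sample(c("inverted", "transposed_direct"), 1L)
      g <- genomes[[truth$genome[i]]]
      L <- reads$length[i]
      if (cls == "inverted") {
        d <- if (hard_fraction > 0 && stats::runif(1) < hard_fraction) {
          sample(10:(block_min - 1L), 1L)
        } else {
          sample(block_min:(block_min + 15L), 1L)
        }
        reads$seq[i] <- make_inverted_chimera(g, L, d)
      } else {
        reads$seq[i] <- make_transposed_chimera(g, L)
      }
      reads$length[i] <- nchar(reads$seq[i])
      truth$is_chimera[i] <- TRUE
      truth$chimera_class[i] <- cls
    }
    for (i in which(as_lowcomp)) {
      reads$seq[i] <- inject_lowcomp(reads$seq[i])
      truth$lowcomp[i] <- TRUE
    }
    eligible <- which(!as_chimera & !as_lowcomp)
    repl <- eligible[stats::runif(length(eligible)) < replicate_rate]
    if (length(repl) > 0) {
      trunc_frac <- stats::runif(length(repl), 0, 0.1)
      new_len <- pmax(50L, as.integer(ceiling(
        reads$length[repl] * (1 - trunc_frac))))
      new_seq <- substr(reads$seq[repl], 1L, new_len)
      new_ids <- paste0(reads$id[repl], "_dup1")
      add_reads <- data.frame(id = new_ids, seq = new_seq,
                              sample = reads$sample[repl],
                              length = nchar(new_seq),
                              stringsAsFactors = FALSE)
      add_truth <- truth[repl, ]
      add_truth$read_id <- new_ids
      add_truth$is_replicate <- TRUE
      add_truth$replicate_group <- truth$read_id[repl]
      truth$replicate_group[repl] <- truth$read_id[repl]
      reads <- rbind(reads, add_reads)
      truth <- rbind(truth, add_truth)
      rownames(reads) <- rownames(truth) <- NULL
    }
    list(reads = reads, truth = truth)
  })
}

# prefix genome[s .. s+l1-1] followed by revcomp(genome[s+l1-d .. +l2]):
# the d-base overlap becomes an exact inverted duplication in the read.
make_inverted_chimera <- function(genome, read_len, dup_block) {
  L <- read_len
  d <- dup_block
  l1 <- as.integer(ceiling((L + d) / 2))
  l2 <- L + d - l1
  glen <- nchar(genome)
  span <- l1 + l2 - d
  s <- sample.int(glen - span + 1L, 1L)
  seg1 <- substr(genome, s, s + l1 - 1L)
  s2 <- s + l1 - d
  seg2 <- substr(genome, s2, s2 + l2 - 1L)
  paste0(seg1, revcomp(seg2))
}

# two same-strand segments in swapped order, gap <= 2 kb, disjoint
make_transposed_chimera <- function(genome, read_len) {
  L <- read_len
  l1 <- L %/% 2L
  l2 <- L - l1
  glen <- nchar(genome)
  gap <- sample.int(min(2000L, max(1L, glen - L - 1L)), 1L)
  span <- L + gap
  a <- sample.int(glen - span + 1L, 1L)
  segA <- substr(genome, a, a + l2 - 1L)           # upstream segment
  cpos <- a + l2 + gap
  segB <- substr(genome, cpos, cpos + l1 - 1L)     # downstream segment
  paste0(segB, segA)                                # emitted swapped
}

inject_lowcomp <- function(seq) {
  L <- nchar(seq)
  frac <- stats::runif(1, 0.55, 0.8)
  w <- as.integer(ceiling(L * frac))
  unit <- sample(c("AC", "AT", "AG"), 1L)
  run <- substr(strrep(unit, ceiling(w / 2) + 1L), 1L, w)
  start <- sample.int(L - w + 1L, 1L)
  paste0(substr(seq, 1L, start - 1L), run, substr(seq, start + w, L))
}

#' Sample a two-component GC mixture with known labels
#'
#' Each draw comes from the eukaryotic component `E` with probability `p`,
#' otherwise from the prokaryotic/viral component `PV`. Components are
#' beta-shaped densities on (0, 1); the defaults place `E` around 0.40 and
#' `PV` around 0.60 GC, well separated so the mixing proportion is
#' identifiable.
#'
#' @param p mixing weight of `E`, in `[0, 1]`.
#' @param n number of draws (>= 1).
#' @param shape_e,shape_pv `c(alpha, beta)` of the two beta components.
#' @param seed integer seed.
#' @return `data.frame(gc, component)` with component labels `"E"`/`"PV"`.
#' @export
sample_gc_mixture <- function(p, n, shape_e = c(40, 60),
                              shape_pv = c(60, 40), seed = 1L) {
  ab_assert(p >= 0 && p <= 1, "p must lie in [0,1]")
  ab_assert(n >= 1L, "n must be >= 1")
  with_seed(as.integer(seed), {
    from_e <- stats::runif(n) < p
    gc <- numeric(n)
    gc[from_e] <- stats::rbeta(sum(from_e), shape_e[1], shape_e[2])
    gc[!from_e] <- stats::rbeta(sum(!from_e), shape_pv[1], shape_pv[2])
    data.frame(gc = gc, component = ifelse(from_e, "E", "PV"),
               stringsAsFactors = FALSE)
  })
}

#' Fabricate hit tables and peptide annotations consistent with truth
#'
#' Produces the inputs the taxonomy stage consumes, wired to the truth
#' table: a nucleotide hit table (eukaryote-source reads hit their own
#' genome's nucleotide subject), a peptide annotation table (prokaryote/
#' viral-source reads get peptides annotated with their truth kingdom,
#' genus, a KO and a gene length), and the subject-to-taxonomy map. A
#' `hit_fraction` of reads receives hits; a `noise_fraction` of those
#' additionally receives a conflicting-kingdom peptide (driving the read to
#' `Mixed` under the transfer rules); the rest receive nothing and tabulate
#' as `Unclassified`.
#'
#' @param reads,truth a read set and its truth table.
#' @param spec the [community_spec()].
#' @param hit_fraction fraction of reads that get any hit.
#' @param noise_fraction fraction of hit-bearing reads given a
#'   conflicting-kingdom peptide.
#' @param ko_pool character vector of KO identifiers to draw from.
#' @param seed integer seed.
#' @return `list(nt_hits, peptides, taxon_map)`.
#' @export
fabricate_hit_tables <- function(reads, truth, spec,
                                 hit_fraction = 0.9, noise_fraction = 0,
                                 ko_pool = sprintf("K%05d", 1:40),
                                 seed = 1L) {
  ab_assert(all(reads$id %in% truth$read_id), "truth must cover all reads")
  with_seed(as.integer(seed), {
    tr <- truth[match(reads$id, truth$read_id), ]
    has_hit <- stats::runif(nrow(reads)) < hit_fraction
    noisy <- has_hit & (stats::runif(nrow(reads)) < noise_fraction)
    taxon_map <- data.frame(
      subject_id = c(paste0("nt|", spec$label), paste0("pep|", spec$label)),
      kingdom = rep(spec$kingdom, 2),
      phylum = rep(paste0(spec$kingdom, "_phylum"), 2),
      genus = rep(spec$genus, 2), stringsAsFactors = FALSE)
    euk <- has_hit & tr$kingdom == "Eukaryota"
    nt <- lapply(which(euk), function(i) {
      subj <- paste0("nt|", tr$genome[i])
      if (noisy[i]) {
        other <- spec$label[spec$kingdom != "Eukaryota"]
        if (length(other) > 0) subj <- c(subj, paste0("nt|", other[1]))
      }
      data.frame(query_id = reads$id[i], subject_id = subj,
                 pct_identity = 98, aln_length = reads$length[i],
                 mismatches = 2L, gap_opens = 0L,
                 q_start = 1L, q_end = reads$length[i],
                 s_start = 1L, s_end = reads$length[i],
                 evalue = 1e-20, bitscore = 2 * reads$length[i],
                 strand = "plus", stringsAsFactors = FALSE)
    })
    nt_hits <- if (length(nt)) do.call(rbind, nt) else empty_hit_table()
    pep_rows <- lapply(which(has_hit), function(i) {
      king <- tr$kingdom[i]
      if (king == "Eukaryota" && !noisy[i]) return(NULL)
      kingdoms <- king
      if (noisy[i]) {
        pool <- setdiff(unique(spec$kingdom), king)
        if (length(pool) == 0) pool <- "Other"
        kingdoms <- c(king, sample(pool, 1L))
      }
      data.frame(
        peptide_id = paste0(reads$id[i], "_pep", seq_along(kingdoms)),
        read_id = reads$id[i], sample = reads$sample[i],
        kingdom = kingdoms, genus = tr$genus[i],
        ko = sample(ko_pool, length(kingdoms), replace = TRUE),
        cog = NA_character_,
        gene_len_aa = sample(150:600, length(kingdoms), replace = TRUE),
        pct_identity = 95, pct_coverage = 95, stringsAsFactors = FALSE)
    })
    peptides <- do.call(rbind, pep_rows)
    if (is.null(peptides)) {
      peptides <- data.frame(peptide_id = character(0), read_id = character(0),
                             sample = character(0), kingdom = character(0),
                             genus = character(0), ko = character(0),
                             cog = character(0), gene_len_aa = integer(0),
                             pct_identity = numeric(0),
                             pct_coverage = numeric(0))
    }
    list(nt_hits = nt_hits, peptides = peptides, taxon_map = taxon_map)
  })
}
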