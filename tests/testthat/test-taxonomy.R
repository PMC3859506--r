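# Two-tier taxonomy: prescreen "all eukaryotic" rule, peptide best-hit
# assignment with deterministic tie-break, transfer rules, tabulation
# conservation, genus tail share.

tax_map <- data.frame(
  subject_id = c("euk1", "euk2", "bact1", "arch1", "vir1", "synth1"),
  kingdom = c("Eukaryota", "Eukaryota", "Bacteria", "Archaea", "Viruses",
              "Other"),
  phylum = "p", genus = c("Aspergillus", "Alternaria", "Pseudomonas",
                          "Halobacterium", "Phage", NA),
  stringsAsFactors = FALSE)

nt_hit <- function(subject, evalue = 1e-20, bitscore = 100) {
  data.frame(query_id = "r1", subject_id = subject, pct_identity = 95,
             aln_length = 100L, mismatches = 5L, gap_opens = 0L,
             q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
             evalue = evalue, bitscore = bitscore, strand = "plus")
}

test_that("prescreen returns Eukaryota only when every retained hit is
           eukaryotic", {
  all_euk <- rbind(nt_hit("euk1"), nt_hit("euk2"), nt_hit("euk1"))
  expect_equal(nucleotide_prescreen(all_euk, tax_map), "Eukaryota")
  mixed <- rbind(nt_hit("euk1"), nt_hit("euk2"), nt_hit("bact1"))
  expect_equal(nucleotide_prescreen(mixed, tax_map), "undetermined")
  weak <- nt_hit("euk1", evalue = 1e-4)
  expect_equal(nucleotide_prescreen(weak, tax_map), "undetermined")
  expect_error(nucleotide_prescreen(nt_hit("unknown"), tax_map),
               "unknown")
})

test_that("prescreen retains only the top ten hits by bit score", {
  # ten strong eukaryotic hits outrank one weak bacterial hit
  hits <- do.call(rbind, c(
    lapply(1:10, function(i) nt_hit("euk1", bitscore = 200 + i)),
    list(nt_hit("bact1", bitscore = 50))))
  expect_equal(nucleotide_prescreen(hits, tax_map), "Eukaryota")
  # the bacterial hit inside the top ten blocks the call
  hits2 <- rbind(hits[1:9, ], nt_hit("bact1", bitscore = 500))
  expect_equal(nucleotide_prescreen(hits2, tax_map), "undetermined")
})

test_that("peptide taxonomy takes the best hit with a deterministic,
           order-invariant tie-break", {
  hits <- rbind(nt_hit("bact1", bitscore = 300), nt_hit("euk1", 1e-10, 100))
  expect_equal(assign_peptide_taxonomy(hits, tax_map), "Bacteria")
  expect_equal(assign_peptide_taxonomy(hits[0, ], tax_map), "unclassified")
  tie <- rbind(nt_hit("euk1", bitscore = 300),
               nt_hit("bact1", bitscore = 300))
  for (perm in list(1:2, 2:1)) {
    expect_equal(assign_peptide_taxonomy(tie[perm, ], tax_map), "Bacteria")
  }
})

test_that("peptide-to-read transfer follows the consensus/conflict rules", {
  expect_equal(transfer_to_read(c("Bacteria", "Bacteria")), "Bacteria")
  expect_equal(transfer_to_read(c("Bacteria", "Eukaryota")), "Mixed")
  expect_equal(transfer_to_read(c("Bacteria", "unclassified")), "Bacteria")
  expect_equal(transfer_to_read(character(0)), "Unclassified")
  expect_equal(transfer_to_read(c("unclassified", "unclassified")),
               "Unclassified")
  # Other behaves as a kingdom in the conflict test
  expect_equal(transfer_to_read(c("Other", "Bacteria")), "Mixed")
  expect_equal(transfer_to_read("Other"), "Other")
})

test_that("six-frame peptide prediction finds constructed ORFs and is
           strand-symmetric", {
  orf <- paste0("ATG", strrep("GCT", 99), "TAA")   # 100 codons then stop
  flank5 <- "TTAATTAA"                              # stops in other frames
  read <- read_set("r1", paste0(flank5, orf))
  peps <- predict_peptides(read)
  expect_true(any(peps$aa_len >= 100))
  rc_read <- read_set("r1", revcomp(read$seq))
  peps_rc <- predict_peptides(rc_read)
  expect_setequal(peps$aa_seq, peps_rc$aa_seq)
  # a 150-base read cannot host a 60-aa ORF in any frame -> empty
  short <- random_seq(150, seed = 202)
  expect_equal(nrow(predict_peptides(read_set("r2", short))), 0L)
})

test_that("tabulation conserves read counts over the seven categories", {
  cats <- data.frame(
    read_id = sprintf("r%d", 1:10),
    sample = rep(c("s1", "s2"), each = 5),
    category = c("Bacteria", "Bacteria", "Eukaryota", "Mixed", "Other",
                 rep("Unclassified", 5)))
  tab <- tabulate_kingdoms(cats)
  expect_equal(sort(tab$sample), c("s1", "s2"))
  expect_equal(tab$Total, c(5L, 5L))
  s2 <- tab[tab$sample == "s2", ]
  expect_equal(s2$Unclassified, 5L)
  expect_equal(sum(s2[c("Archaea", "Bacteria", "Eukaryota", "Mixed",
                        "Viruses", "Other")]), 0)
  expect_error(kingdom_count_table(within(as.data.frame(tab),
                                          Total <- Total + 1)),
               "Total")
})

test_that("prescreen-eukaryotic reads never reach the peptide path", {
  reads <- read_set("r1", random_seq(150, seed = 201))
  nt <- nt_hit("euk1")
  # a conflicting peptide annotation exists but must be ignored
  peps <- data.frame(peptide_id = "r1_p1", read_id = "r1", sample = "s",
                     kingdom = "Bacteria", genus = "Pseudomonas",
                     ko = "K00001", cog = NA, gene_len_aa = 300,
                     pct_identity = 99, pct_coverage = 99)
  cats <- assign_read_taxonomy(reads, nt, peps, tax_map)
  expect_equal(cats$category, "Eukaryota")
})

test_that("genus tail share sums genera under the 2% cutoff", {
  expect_equal(genus_profile(rep("A", 50))$tail_share_pct, 0)
  many <- rep(sprintf("g%03d", 1:100), each = 1)
  expect_equal(genus_profile(many)$tail_share_pct, 100)
  toy <- c(rep("A", 50), rep("B", 30), sprintf("s%02d", 1:20))
  res <- genus_profile(toy)
  expect_equal(res$tail_share_pct, 20)
  # reads without genus resolution leave the denominator
  res2 <- genus_profile(c(toy, rep(NA, 100)))
  expect_equal(res2$tail_share_pct, 20)
})
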