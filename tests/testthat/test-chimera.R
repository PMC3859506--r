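# The four chimera rules: internal repeats (boundary at 25 bases, both
# orientations), strict propagation thresholds, pair-pattern geometry,
# strict-majority voting, and equivalence with the brute-force oracle.

test_that("forward repeats flag at 25 bases and not at 24", {
  block25 <- nonrepetitive_block(25, seed = 101)
  r25 <- make_forward_repeat_read(block25, seed = 102)
  res <- find_internal_repeats(r25, 25L)
  expect_true(res$flagged)
  expect_equal(res$orientation, "forward")
  expect_gte(res$block_length, 25L)
  block24 <- substr(block25, 1, 24)
  r24 <- make_forward_repeat_read(block24, seed = 102)
  expect_false(find_internal_repeats(r24, 25L)$flagged)
})

test_that("reverse-direction repeats (inverted) flag at 25 bases", {
  block <- nonrepetitive_block(25, seed = 103)
  r <- make_reverse_repeat_read(block, seed = 104)
  res <- find_internal_repeats(r, 25L)
  expect_true(res$flagged)
  expect_equal(res$orientation, "reverse")
})

test_that("random reads are clean and agree with the brute-force
           comparator", {
  withr::with_seed(105, {
    for (i in 1:15) {
      s <- random_seq(sample(80:300, 1))
      expect_equal(find_internal_repeats(s, 25L)$flagged,
                   brute_internal_repeat(s, 25))
    }
  })
  # and on constructed positives of both orientations
  fwd <- make_forward_repeat_read(nonrepetitive_block(30, seed = 106))
  rev <- make_reverse_repeat_read(nonrepetitive_block(30, seed = 107))
  expect_true(brute_internal_repeat(fwd, 25))
  expect_true(brute_internal_repeat(rev, 25))
})

test_that("flag propagation uses strict >90 identity over >95 coverage of
           the candidate read", {
  reads <- read_set(c("seed", "near", "edge"),
                    c(random_seq(200, seed = 108),
                      random_seq(200, seed = 109),
                      random_seq(200, seed = 110)))
  hit <- function(q, s, ident, cov_len) {
    data.frame(query_id = q, subject_id = s, pct_identity = ident,
               aln_length = cov_len, mismatches = 0L, gap_opens = 0L,
               q_start = 1L, q_end = cov_len, s_start = 1L, s_end = cov_len,
               evalue = 1e-30, bitscore = 300, strand = "plus")
  }
  hits <- rbind(hit("seed", "near", 92, 192),   # 92% over 96% -> flagged
                hit("seed", "edge", 90, 200))   # exactly 90% -> excluded
  prop <- propagate_similarity_flags(reads, "seed", hits)
  expect_equal(prop$read_id, "near")
  # no seeds -> nothing propagates
  expect_equal(nrow(propagate_similarity_flags(reads, character(0), hits)),
               0L)
  # single pass: a propagated flag does not seed further propagation
  hits2 <- rbind(hits, hit("near", "edge", 99, 200))
  prop2 <- propagate_similarity_flags(reads, "seed", hits2)
  expect_false("edge" %in% prop2$read_id)
})

test_that("pair patterns classify the two rearrangement geometries", {
  mk <- function(qs, qe, ss, se, strand = "plus", bs = 200) {
    data.frame(query_id = "a", subject_id = "b", pct_identity = 99,
               aln_length = qe - qs + 1L, mismatches = 0L, gap_opens = 0L,
               q_start = qs, q_end = qe, s_start = ss, s_end = se,
               evalue = 1e-20, bitscore = bs, strand = strand)
  }
  # query order 1 < 151 but subject order 201 > 1: transposed direct
  td <- rbind(mk(1, 100, 201, 300), mk(151, 250, 1, 100))
  expect_equal(classify_pair_pattern(td)$pattern, "transposed_direct")
  # opposite strands with overlapping subject intervals: inverted
  inv <- rbind(mk(1, 100, 1, 100), mk(151, 250, 40, 139, strand = "minus"))
  expect_equal(classify_pair_pattern(inv)$pattern, "inverted")
  # single long hit: collinear
  expect_equal(classify_pair_pattern(mk(1, 200, 1, 200))$pattern,
               "collinear")
  # consistent order, same strand: collinear
  col <- rbind(mk(1, 100, 1, 100), mk(151, 250, 151, 250))
  expect_equal(classify_pair_pattern(col)$pattern, "collinear")
  # opposite strands, subjects far apart: ambiguous
  amb <- rbind(mk(1, 100, 1, 100), mk(151, 250, 500, 599, strand = "minus"))
  expect_equal(classify_pair_pattern(amb)$pattern, "ambiguous")
  # hits failing the length/evalue filter are ignored
  weak <- rbind(mk(1, 20, 201, 220), mk(151, 170, 1, 20))
  expect_equal(classify_pair_pattern(weak)$pattern, "ambiguous")
})

test_that("voting needs a strict majority of chimeric-pattern neighbours", {
  pairs <- data.frame(
    read_a = "x",
    read_b = paste0("n", 1:5),
    pattern = c("inverted", "transposed_direct", "inverted",
                "collinear", "ambiguous"))
  v <- vote_chimeras(pairs)
  expect_true("x" %in% v$read_id)        # 3 vs 2
  tie <- pairs[c(1, 2, 4, 5), ]          # 2 chimeric vs 2 plain
  expect_false("x" %in% vote_chimeras(tie)$read_id)  # 2 vs 2 tie
  expect_equal(nrow(vote_chimeras(pairs[0, ])), 0L)  # isolated reads
})

test_that("the full stage matches the brute-force oracle on a mixed
           synthetic set", {
  spec <- default_community()
  g <- generate_genomes(spec, seed = 120)
  sim <- simulate_reads(g, spec, 150, seed = 121)
  art <- inject_artifacts(sim$reads, sim$truth, g, chimera_rate = 0.15,
                          hard_fraction = 0.3, seed = 122)
  hits <- all_vs_all_hits(art$reads)
  got <- run_chimera_stage(art$reads, hits)
  oracle <- brute_chimera_flags(art$reads, hits)
  expect_equal(got$verdicts$status,
               unname(oracle[got$verdicts$read_id]))
})

test_that("a chimera-free random set yields no flags and flagged reads are
           removed from the kept set", {
  spec <- default_community()
  g <- generate_genomes(spec, seed = 130)
  sim <- simulate_reads(g, spec, 200, seed = 131)
  hits <- all_vs_all_hits(sim$reads)
  res <- run_chimera_stage(sim$reads, hits)
  expect_equal(sum(res$verdicts$status != "clean"), 0L)
  expect_equal(nrow(res$kept), 200L)
  expect_error(run_chimera_stage(sim$reads, NULL), "all_vs_all_hits")
})

test_that("adding reads never un-flags a repeat-flagged read and >30%
           flagging warns", {
  block <- nonrepetitive_block(30, seed = 140)
  chim <- make_forward_repeat_read(block, seed = 141)
  reads1 <- read_set("c1", chim)
  hits0 <- all_vs_all_hits(reads1)
  expect_equal(suppressWarnings(
    run_chimera_stage(reads1, hits0)$verdicts$status), "flagged_repeat")
  reads2 <- read_set(c("c1", "r2", "r3"),
                     c(chim, random_seq(250, seed = 142),
                       random_seq(250, seed = 143)))
  res2 <- suppressWarnings(run_chimera_stage(reads2, all_vs_all_hits(reads2)))
  expect_equal(res2$verdicts$status[res2$verdicts$read_id == "c1"],
               "flagged_repeat")
  expect_warning(run_chimera_stage(reads1, hits0), "small fraction")
})
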