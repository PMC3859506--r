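# The simulator's statistical contracts: GC targeting, abundance
# sampling, artifact injection rates, mixture label fractions,
# determinism, conservation.

test_that("generated genomes hit their GC target within binomial bounds", {
  spec <- community_spec("g1", "Bacteria", "Pseudomonas",
                         100000, 0.5, 1)
  g <- generate_genomes(spec, seed = 11)
  expect_equal(nchar(g[["g1"]]), 100000L)
  expect_gt(gc_fraction(g[["g1"]]), 0.48)
  expect_lt(gc_fraction(g[["g1"]]), 0.52)
})

test_that("genome generation is deterministic in the seed and rejects
           unreachable GC targets", {
  spec <- default_community()
  expect_identical(generate_genomes(spec, seed = 5),
                   generate_genomes(spec, seed = 5))
  expect_error(community_spec("g", "Bacteria", "x", 10000, 0.0, 1),
               "GC")
})

test_that("read sampling follows abundances within 3 binomial sd", {
  spec <- community_spec(c("g1", "g2"), c("Bacteria", "Bacteria"),
                         c("A", "B"), c(50000, 50000), c(0.5, 0.5),
                         c(0.9, 0.1))
  g <- generate_genomes(spec, seed = 2)
  sim <- simulate_reads(g, spec, 10000, seed = 3)
  n1 <- sum(sim$truth$genome == "g1")
  sd3 <- 3 * sqrt(10000 * 0.9 * 0.1)
  expect_lt(abs(n1 - 9000), sd3)
  expect_true(all(sim$reads$length >= 50))
  # truth intervals really are the source substrings
  i <- which(sim$truth$strand == "+")[1]
  expect_equal(sim$reads$seq[i],
               substr(g[[sim$truth$genome[i]]], sim$truth$start[i],
                      sim$truth$end[i]))
  expect_identical(simulate_reads(g, spec, 100, seed = 9)$reads,
                   simulate_reads(g, spec, 100, seed = 9)$reads)
})

test_that("single-genome simulation points all truth labels at it", {
  spec <- community_spec("only", "Viruses", "Phage", 20000, 0.5, 1)
  g <- generate_genomes(spec, seed = 1)
  sim <- simulate_reads(g, spec, 1000, seed = 1)
  expect_true(all(sim$truth$genome == "only"))
})

test_that("artifact injection respects rates, conservation and truth flags", {
  spec <- default_community()
  g <- generate_genomes(spec, seed = 21)
  sim <- simulate_reads(g, spec, 5000, seed = 22)
  art <- inject_artifacts(sim$reads, sim$truth, g,
                          replicate_rate = 0.1, chimera_rate = 0.1,
                          lowcomp_rate = 0.05, seed = 23)
  n_rep <- sum(art$truth$is_replicate)
  expect_equal(nrow(art$reads), 5000 + n_rep)       # conservation
  expect_equal(nrow(art$truth), nrow(art$reads))
  expect_true(all((art$truth$chimera_class == "none") ==
                    !art$truth$is_chimera))
  for (obs_exp in list(c(sum(art$truth$is_chimera), 0.1),
                       c(sum(art$truth$lowcomp), 0.05))) {
    expected <- 5000 * obs_exp[2]
    expect_lt(abs(obs_exp[1] - expected),
              3 * sqrt(5000 * obs_exp[2] * (1 - obs_exp[2])))
  }
  # zero rates inject nothing
  clean <- inject_artifacts(sim$reads, sim$truth, g, seed = 4)
  expect_identical(clean$reads, sim$reads)
  expect_equal(sum(clean$truth$is_chimera), 0L)
})

test_that("every injected inverted chimera with a >=25-base block carries a
           detectable internal inverted repeat", {
  spec <- default_community()
  g <- generate_genomes(spec, seed = 31)
  sim <- simulate_reads(g, spec, 400, seed = 32)
  art <- inject_artifacts(sim$reads, sim$truth, g, chimera_rate = 0.3,
                          block_min = 25L, seed = 33)
  inv <- art$truth$read_id[art$truth$chimera_class == "inverted"]
  expect_gt(length(inv), 10)
  flagged <- vapply(art$reads$seq[match(inv, art$reads$id)], function(s) {
    find_internal_repeats(s, 25L)$flagged
  }, logical(1))
  expect_true(all(flagged))
})

test_that("gc mixture sampling respects p exactly at the boundaries and
           within 3 sd elsewhere", {
  expect_true(all(sample_gc_mixture(1, 500, seed = 1)$component == "E"))
  expect_true(all(sample_gc_mixture(0, 500, seed = 1)$component == "PV"))
  m <- sample_gc_mixture(0.7, 50000, seed = 5)
  frac <- mean(m$component == "E")
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 50000))
  expect_error(sample_gc_mixture(1.2, 10), "p must")
})

test_that("fabricated hit tables recover truth when noise-free and give
           all-unclassified when no read has hits", {
  spec <- default_community()
  g <- generate_genomes(spec, seed = 41)
  sim <- simulate_reads(g, spec, 400, seed = 42)
  fab <- fabricate_hit_tables(sim$reads, sim$truth, spec,
                              hit_fraction = 1, noise_fraction = 0,
                              seed = 43)
  cat_df <- assign_read_taxonomy(sim$reads, fab$nt_hits, fab$peptides,
                                 fab$taxon_map)
  expect_equal(cat_df$category,
               sim$truth$kingdom[match(cat_df$read_id, sim$truth$read_id)])
  none <- fabricate_hit_tables(sim$reads, sim$truth, spec,
                               hit_fraction = 0, seed = 44)
  cat0 <- assign_read_taxonomy(sim$reads, none$nt_hits, none$peptides,
                               none$taxon_map)
  expect_true(all(cat0$category == "Unclassified"))
})

test_that("noisy fabricated tables produce a Mixed fraction near the noise
           rate", {
  spec <- default_community()
  g <- generate_genomes(spec, seed = 51)
  sim <- simulate_reads(g, spec, 4000, seed = 52)
  fab <- fabricate_hit_tables(sim$reads, sim$truth, spec,
                              hit_fraction = 1, noise_fraction = 0.2,
                              seed = 53)
  cat_df <- assign_read_taxonomy(sim$reads, fab$nt_hits, fab$peptides,
                                 fab$taxon_map)
  n_mixed <- sum(cat_df$category == "Mixed")
  expect_lt(abs(n_mixed - 4000 * 0.2), 3 * sqrt(4000 * 0.2 * 0.8))
})
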