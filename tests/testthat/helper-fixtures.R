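# Fixture builders shared across test files. All randomness is seeded at
# the call site.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(BASES, n, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# A read containing block `block` at two positions, with flanking bases
# pinned so the duplicated region cannot extend by coincidence: the
# characters before/after each copy are forced to differ between copies.
make_forward_repeat_read <- function(block, seed = 1) {
  withr::with_seed(seed, {
    left <- random_seq(40)
    mid <- random_seq(50)
    right <- random_seq(40)
  })
  # pin boundaries: before copy1 = A / before copy2 = C, after copy1 = G /
  # after copy2 = T
  paste0(left, "A", block, "G", mid, "C", block, "T", right)
}

make_reverse_repeat_read <- function(block, seed = 1) {
  withr::with_seed(seed, {
    left <- random_seq(40)
    mid <- random_seq(50)
    right <- random_seq(40)
  })
  rc <- aerobiome::revcomp(block)
  # the base preceding/following each copy is pinned so that neither the
  # forward pair nor the inverted pair can extend coincidentally
  paste0(left, "A", block, "A", mid, "C", rc, "C", right)
}

# a block guaranteed to contain no internal repeats and not to be its own
# reverse complement: alternating motif with unique tail
nonrepetitive_block <- function(len, seed = 99) random_seq(len, seed = seed)

default_community <- function() {
  community_spec(
    label = c("bact1", "bact2", "euk1", "vir1"),
    kingdom = c("Bacteria", "Bacteria", "Eukaryota", "Viruses"),
    genus = c("Pseudomonas", "Sphingomonas", "Aspergillus", "Phage"),
    length = c(50000, 50000, 80000, 20000),
    gc = c(0.62, 0.55, 0.42, 0.48),
    abundance = c(0.35, 0.25, 0.3, 0.1))
}
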