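# Run configuration: every numeric threshold used by the pipeline lives here
# so a run can be reproduced from its manifest.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default. All
#' percentage-valued thresholds are expressed on the 0--100 scale.
#'
#' @param min_repeat_len minimum exact internal-repeat length (bases) that
#'   flags a read as a candidate MDA chimera. Default 25.
#' @param propagate_min_identity percent identity a similarity hit must
#'   *exceed* (strict) for a chimera flag to propagate. Default 90.
#' @param propagate_min_cov percent of the candidate read's length a hit must
#'   *exceed* (strict) for propagation. Default 95.
#' @param mask_drop_fraction percent of a read's length that must be masked
#'   (strictly more than) before the read is dropped. Default 50.
#' @param max_nt_hits maximum nucleotide hits retained per read in the
#'   taxonomy prescreen. Default 10.
#' @param nt_evalue_cutoff e-value cutoff (hits must be strictly below) for
#'   the nucleotide prescreen. Default 1e-5.
#' @param stringent_identity,stringent_cov inclusive percent identity /
#'   peptide-coverage floor for resistance/virulence matches. Default 90/90.
#' @param genus_tail_cutoff percent abundance below which a genus counts
#'   toward the long-tail share. Default 2.
#' @param dust_window,dust_level DUST window size (bases) and score level for
#'   low-complexity masking. Defaults 64 and 20.
#' @param pair_min_hit_len,pair_evalue minimum aligned length and maximum
#'   e-value for hits entering pair-pattern classification. Defaults 25, 1e-5.
#' @param pair_overlap_tol distance (bases) within which two subject
#'   intervals on opposite strands still count as an inverted pattern.
#'   Default 100.
#' @param replicate_min_identity,replicate_max_len_diff artificial-replicate
#'   grouping thresholds: minimum prefix identity (fraction) and maximum
#'   length difference as a fraction of the longer read. Defaults 0.9, 0.1.
#' @param reverse_repeat_mode `"revcomp"` (inverted repeat, the MDA
#'   branch-migration geometry) or `"plain"` (plain reversed string) for the
#'   reverse-direction internal-repeat search.
#' @param seed integer seed from which all randomness in a run flows.
#' @return an object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(min_repeat_len = 25L,
                            propagate_min_identity = 90,
                            propagate_min_cov = 95,
                            mask_drop_fraction = 50,
                            max_nt_hits = 10L,
                            nt_evalue_cutoff = 1e-5,
                            stringent_identity = 90,
                            stringent_cov = 90,
                            genus_tail_cutoff = 2,
                            dust_window = 64L,
                            dust_level = 20,
                            pair_min_hit_len = 25L,
                            pair_evalue = 1e-5,
                            pair_overlap_tol = 100L,
                            replicate_min_identity = 0.9,
                            replicate_max_len_diff = 0.1,
                            reverse_repeat_mode = c("revcomp", "plain"),
                            seed = 1L) {
  reverse_repeat_mode <- match.arg(reverse_repeat_mode)
  cfg <- list(
    min_repeat_len = as.integer(min_repeat_len),
    propagate_min_identity = propagate_min_identity,
    propagate_min_cov = propagate_min_cov,
    mask_drop_fraction = mask_drop_fraction,
    max_nt_hits = as.integer(max_nt_hits),
    nt_evalue_cutoff = nt_evalue_cutoff,
    stringent_identity = stringent_identity,
    stringent_cov = stringent_cov,
    genus_tail_cutoff = genus_tail_cutoff,
    dust_window = as.integer(dust_window),
    dust_level = dust_level,
    pair_min_hit_len = as.integer(pair_min_hit_len),
    pair_evalue = pair_evalue,
    pair_overlap_tol = as.integer(pair_overlap_tol),
    replicate_min_identity = replicate_min_identity,
    replicate_max_len_diff = replicate_max_len_diff,
    reverse_repeat_mode = reverse_repeat_mode,
    seed = as.integer(seed)
  )
  pcts <- c("propagate_min_identity", "propagate_min_cov",
            "mask_drop_fraction", "stringent_identity", "stringent_cov",
            "genus_tail_cutoff")
  for (p in pcts) {
    ab_assert(cfg[[p]] >= 0 && cfg[[p]] <= 100,
              "config field '%s' must lie in [0,100], got %s", p, cfg[[p]])
  }
  ab_assert(cfg$min_repeat_len >= 1L, "min_repeat_len must be positive")
  ab_assert(is.finite(cfg$seed), "seed must be a finite integer")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  ab_assert(file.exists(path), "config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json, got: ", path, call. = FALSE)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  ab_assert(length(bad) == 0L, "unknown config keys: %s",
            paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("aerobiome pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
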