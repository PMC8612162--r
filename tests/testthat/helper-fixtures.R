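# Shared fixtures built in code.

# Minimal profile for variant-pool construction with controllable
# divergence structure.
make_profile <- function(divergences = numeric(0), dominant = 0.95,
                         template_length = 373L, name = "test_sp") {
  species_profile(name,
                  stage_cv_means = c(log = 1e4, resting_cyst = 2e3),
                  template_length = template_length,
                  variant_divergences = divergences,
                  dominant_fraction = dominant)
}

# Deterministic pool from explicit sequences/counts.
make_pool <- function(sequences, counts, error = 0) {
  variant_pool(sequences, counts, residual_error_rate = error)
}

# Random ACGT string (uses ambient RNG; wrap in withr::with_seed or
# set.seed in the test for determinism).
rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute exactly k evenly spaced positions (cyclic base replacement;
# offset shifts the pattern so sibling variants hit different sites).
# Isolated substitutions keep the optimal global alignment ungapped, so
# the identity to s is exactly (L - k)/L.
sub_k <- function(s, k, offset = 0L) {
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  pos <- round(seq(1L + offset, L, length.out = k))
  bases <- c("A", "C", "G", "T")
  chars[pos] <- bases[(match(chars[pos], bases) %% 4L) + 1L]
  paste(chars, collapse = "")
}
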