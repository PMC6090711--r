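# Shared fixtures built in code.

# Construct a minimal harmonizable summary-statistics table.
make_variants <- function(bx, by, sx = rep(0.005, length(bx)),
                          sy = rep(0.015, length(bx)),
                          ids = paste0("rs", seq_along(bx))) {
  data.frame(
    variant_id = ids,
    gene = NA_character_,
    chromosome = NA_integer_,
    effect_allele = rep("A", length(bx)),
    other_allele = rep("G", length(bx)),
    beta_exposure = bx, se_exposure = sx,
    beta_outcome = by, se_outcome = sy,
    stringsAsFactors = FALSE
  )
}

# The six-variant instrument (25-OHD exposure / colorectal cancer outcome).
six_variants <- function() vitd_crc_variants()

# Random harmonized variant sets for property-style checks.
random_variants <- function(k = 6L) {
  make_variants(
    bx = stats::runif(k, 0.01, 0.1),
    by = stats::rnorm(k, 0, 0.02),
    sx = stats::runif(k, 0.001, 0.005),
    sy = stats::runif(k, 0.01, 0.03)
  )
}
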