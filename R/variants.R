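#' Read a per-variant summary-statistics table
#'
#' Reads a tab-separated table of harmonizable per-variant GWAS summary
#' statistics: the effect of each instrument variant on the exposure
#' (log-transformed circulating 25-OHD, nmol/L) and on the outcome
#' (colorectal cancer, log-odds scale), with standard errors.
#'
#' Required columns: `variant_id`, `effect_allele`, `beta_exposure`,
#' `se_exposure`, `beta_outcome`, `se_outcome`. Optional annotation columns
#' `gene`, `chromosome`, `other_allele` are carried through when present.
#'
#' @param path Path to a headered, tab-separated file.
#' @return A `data.frame` with one row per variant.
#' @seealso [vitd_crc_variants()] for the bundled six-variant instrument.
#' @export
read_summary_stats <- function(path) {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) {
    stop("summary-statistics file is empty: ", path)
  }
  required <- c("variant_id", "effect_allele", "beta_exposure",
                "se_exposure", "beta_outcome", "se_outcome")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("summary-statistics file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  num_cols <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) & nzchar(trimws(raw[[col]])))
    if (length(bad)) {
      stop("malformed numeric value in column '", col, "' at data line(s) ",
           paste(bad, collapse = ", "))
    }
    raw[[col]] <- vals
  }
  if ("chromosome" %in% names(raw)) {
    raw$chromosome <- suppressWarnings(as.integer(raw$chromosome))
  }
  validate_variants(raw)
  raw
}

#' The bundled six-variant 25-OHD instrument
#'
#' Returns the six-variant instrument used throughout: per-allele effects of
#' each variant on log-transformed circulating 25-OHD (from a large European
#' GWAS meta-analysis of serum 25-OHD) and on colorectal cancer risk (from an
#' 11-study case-control GWAS meta-analysis), all oriented to the
#' 25-OHD-increasing allele.
#'
#' @return A `data.frame` with 6 rows; see [read_summary_stats()] for columns.
#' @export
vitd_crc_variants <- function() {
  path <- system.file("extdata", "vitd_crc_summary_stats.tsv",
                      package = "vitdmr", mustWork = TRUE)
  read_summary_stats(path)
}

validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  if (anyDuplicated(variants$variant_id)) {
    stop("duplicate variant_id: ",
         paste(unique(variants$variant_id[duplicated(variants$variant_id)]),
               collapse = ", "))
  }
  if (any(variants$se_exposure <= 0, na.rm = TRUE) ||
      any(variants$se_outcome <= 0, na.rm = TRUE)) {
    stop("standard errors must be strictly positive")
  }
  invisible(variants)
}

#' Harmonize variants to the exposure-increasing allele
#'
#' Orients every variant so that the effect allele is the allele that
#' increases the exposure: rows with a negative `beta_exposure` have both
#' betas sign-flipped and the allele labels swapped. Variants with a zero
#' exposure effect have no defined orientation and are dropped with a
#' warning. The operation is idempotent and preserves row order.
#'
#' @param variants A summary-statistics `data.frame` (see
#'   [read_summary_stats()]).
#' @return The harmonized `data.frame` (all `beta_exposure > 0`).
#' @export
harmonize_variants <- function(variants) {
  validate_variants(variants)
  zero <- variants$beta_exposure == 0
  if (any(zero)) {
    warning("dropping variant(s) with zero exposure effect (undefined ",
            "orientation): ",
            paste(variants$variant_id[zero], collapse = ", "))
    variants <- variants[!zero, , drop = FALSE]
  }
  flip <- variants$beta_exposure < 0
  if (any(flip)) {
    variants$beta_exposure[flip] <- -variants$beta_exposure[flip]
    variants$beta_outcome[flip] <- -variants$beta_outcome[flip]
    if (all(c("effect_allele", "other_allele") %in% names(variants))) {
      ea <- variants$effect_allele[flip]
      variants$effect_allele[flip] <- variants$other_allele[flip]
      variants$other_allele[flip] <- ea
    } else if ("effect_allele" %in% names(variants)) {
      # no partner allele recorded: mark the orientation change
      variants$effect_allele[flip] <- paste0("flip(",
                                             variants$effect_allele[flip], ")")
    }
  }
  rownames(variants) <- NULL
  variants
}

assert_harmonized <- function(variants, caller) {
  if (any(variants$beta_exposure <= 0)) {
    stop(caller, " requires harmonized input (all beta_exposure > 0); ",
         "run harmonize_variants() first")
  }
  invisible(variants)
}

#' Per-variant Wald ratio estimates
#'
#' The causal log-odds ratio per unit exposure implied by one variant is the
#' ratio of its outcome effect to its exposure effect. The standard error is
#' the first-order delta approximation `se_outcome / |beta_exposure|`
#' (exposure-side uncertainty is ignored within the summary-statistics
#' methods, matching the inverse-variance weights, which involve only the
#' outcome standard error). The inverse-variance weight of each variant is
#' `beta_exposure^2 / se_outcome^2`.
#'
#' @param variants A summary-statistics `data.frame`.
#' @return A `data.frame` with columns `variant_id`, `ratio`, `ratio_se`,
#'   `iv_weight`.
#' @export
wald_ratios <- function(variants) {
  validate_variants(variants)
  if (any(variants$beta_exposure == 0)) {
    stop("Wald ratio undefined for zero exposure effect: ",
         paste(variants$variant_id[variants$beta_exposure == 0],
               collapse = ", "))
  }
  data.frame(
    variant_id = variants$variant_id,
    ratio = variants$beta_outcome / variants$beta_exposure,
    ratio_se = variants$se_outcome / abs(variants$beta_exposure),
    iv_weight = variants$beta_exposure^2 / variants$se_outcome^2,
    stringsAsFactors = FALSE
  )
}
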