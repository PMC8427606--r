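#' Select the top cis-eQTL instrument for a locus
#'
#' The SMR test uses a single instrumental variable per probe: the cis SNP
#' most strongly associated with the probe's expression, required to reach
#' genome-wide significance (default `P_eQTL < 5e-8`). A probe with no SNP
#' below the threshold is not testable and is excluded upstream.
#'
#' By default the eQTL association is measured by the z-score recomputed as
#' `beta/se`; `use_reported_p = TRUE` ranks by the file's `p` column instead.
#' Exact ties on the p-value are broken by larger `|z|`, then by smaller
#' base-pair position, so selection is deterministic.
#'
#' @param locus A `harmonized_locus`.
#' @param p_instrument_max Instrument significance threshold (strict `<`).
#' @param use_reported_p Rank by the reported `p_zx` column rather than by
#'   `beta/se`.
#' @return Integer index of the instrument into the locus arrays, or
#'   `NA_integer_` if no SNP qualifies (including the empty locus).
#' @export
select_top_instrument <- function(locus, p_instrument_max = 5e-8,
                                  use_reported_p = FALSE) {
  m <- locus_size(locus)
  if (m == 0L) return(NA_integer_)
  z <- locus$b_zx / locus$se_zx
  logp <- if (use_reported_p) log(locus$p_zx) else
    stats::pchisq(z^2, df = 1, lower.tail = FALSE, log.p = TRUE)
  if (min(logp) >= log(p_instrument_max)) return(NA_integer_)
  cand <- which(logp == min(logp))
  if (length(cand) > 1L) cand <- cand[abs(z[cand]) == max(abs(z[cand]))]
  if (length(cand) > 1L) cand <- cand[which.min(locus$bp[cand])]
  cand[1L]
}

#' The SMR test statistic
#'
#' Combines the GWAS and eQTL z-statistics of the instrument into
#' `T_SMR = (z_zy^2 * z_zx^2) / (z_zy^2 + z_zx^2)`, the approximate
#' chi-square(1) statistic for the expression-on-trait effect `b_xy`. The
#' statistic is symmetric in its two arguments and bounded above by
#' `min(z_zx^2, z_zy^2)`; it equals 0 when either z is 0.
#'
#' @param z_zx eQTL z-statistic(s), `beta/se`.
#' @param z_zy GWAS z-statistic(s).
#' @return `t_smr`, vectorized over the inputs.
#' @export
smr_statistic <- function(z_zx, z_zy) {
  x2 <- z_zx^2
  y2 <- z_zy^2
  denom <- x2 + y2
  if (any(denom == 0)) {
    warning("smr_statistic: both z-statistics are zero; T_SMR defined as 0")
  }
  ifelse(denom == 0, 0, x2 * y2 / denom)
}

#' P-value of the SMR statistic
#'
#' Upper tail of the chi-square distribution with 1 degree of freedom,
#' evaluated in log space so that extreme statistics (|z| up to ~40 and
#' beyond) give a finite log p-value instead of underflowing to zero.
#'
#' @param t_smr Nonnegative SMR statistic(s).
#' @param log10p Return `log10(p)` instead of `p`.
#' @return `p` in `(0, 1]` (possibly denormal for extreme inputs), or its
#'   base-10 logarithm.
#' @export
smr_pvalue <- function(t_smr, log10p = FALSE) {
  if (any(t_smr < 0, na.rm = TRUE)) stop("t_smr must be nonnegative")
  lp <- stats::pchisq(t_smr, df = 1, lower.tail = FALSE, log.p = TRUE)
  if (log10p) lp / log(10) else exp(lp)
}

#' The SMR effect estimate and its delta-method standard error
#'
#' The effect of expression on the trait is the ratio of the instrument's
#' GWAS and eQTL effects, `b_xy = b_zy / b_zx` (trait units per standard
#' deviation of expression). Its standard error follows from the first-order
#' delta method for a ratio of independent estimates:
#' `se_xy^2 = se_zy^2 / b_zx^2 + b_zy^2 * se_zx^2 / b_zx^4`.
#'
#' @param b_zy,se_zy GWAS effect and standard error of the instrument.
#' @param b_zx,se_zx eQTL effect and standard error of the instrument.
#' @return List with `b_xy` and `se_xy`, vectorized.
#' @export
estimate_bxy <- function(b_zy, se_zy, b_zx, se_zx) {
  if (any(b_zx == 0)) stop("estimate_bxy: b_zx = 0 gives an undefined ratio")
  b_xy <- b_zy / b_zx
  se_xy <- sqrt(se_zy^2 / b_zx^2 + b_zy^2 * se_zx^2 / b_zx^4)
  list(b_xy = b_xy, se_xy = se_xy)
}

#' Default extended-MHC interval (GRCh37)
#'
#' The extended major histocompatibility complex on chromosome 6,
#' chr6:28,477,797-33,448,354 in GRCh37 coordinates. Probes inside it are
#' excluded from the analysis: the region's extreme long-range LD violates
#' the single-causal-variant assumption behind SMR and HEIDI.
#'
#' @return List with `chr`, `start`, `end` (closed interval).
#' @export
mhc_grch37 <- function() list(chr = "6", start = 28477797, end = 33448354)

#' Does a position fall inside the MHC exclusion region?
#'
#' @param chr Chromosome (character or numeric).
#' @param bp 1-based position, e.g. a probe transcription start site.
#' @param region Interval as returned by [mhc_grch37()]; closed on both ends.
#' @return Logical, vectorized over `chr`/`bp`.
#' @export
in_mhc <- function(chr, bp, region = mhc_grch37()) {
  as.character(chr) == as.character(region$chr) &
    bp >= region$start & bp <= region$end
}
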