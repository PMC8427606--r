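#' HEIDI configuration
#'
#' Thresholds governing which cis SNPs enter the heterogeneity test. The
#' defaults follow the published practice of the SMR-HEIDI method:
#' SNPs must show some eQTL signal (`p_zx < 1.57e-3`, i.e. chi-square(1) >
#' 10, so their `b_xy` ratios are stable), must be in informative but not
#' near-perfect LD with the top SNP (`r^2` in `[0.05, 0.9]`; near-perfect LD
#' duplicates the top SNP, near-zero LD carries no heterogeneity
#' information), at most `m_cap` SNPs are used (the smallest eQTL p-values),
#' and at least `min_snps` SNPs including the top are required for the test
#' to be meaningful — loci with only one or two cis SNPs are reported as
#' `too_few_snps` and carry no HEIDI p-value.
#'
#' @param p_zx_max eQTL p-value ceiling for non-top SNPs.
#' @param r2_min,r2_max LD r-squared window to the top SNP.
#' @param m_cap Maximum number of SNPs used (including the top).
#' @param min_snps Minimum number of SNPs (including the top).
#' @param method Null approximation for the weighted chi-square mixture:
#'   `"satterthwaite"` (two-moment, default) or `"imhof"` (numerical
#'   inversion of the characteristic function).
#' @return List of class `heidi_config`.
#' @export
heidi_config <- function(p_zx_max = 1.57e-3, r2_min = 0.05, r2_max = 0.9,
                         m_cap = 20L, min_snps = 3L,
                         method = c("satterthwaite", "imhof")) {
  stopifnot(p_zx_max > 0, r2_min >= 0, r2_max <= 1, r2_min < r2_max,
            m_cap >= 1, min_snps >= 2)
  structure(list(p_zx_max = p_zx_max, r2_min = r2_min, r2_max = r2_max,
                 m_cap = as.integer(m_cap), min_snps = as.integer(min_snps),
                 method = match.arg(method)),
            class = "heidi_config")
}

#' Select the SNPs entering the HEIDI test
#'
#' Always includes the top SNP (exempt from all filters). Other SNPs qualify
#' when their recomputed eQTL p-value is below `p_zx_max` and their LD
#' r-squared with the top SNP lies in `[r2_min, r2_max]`. If more than
#' `m_cap` SNPs qualify, the `m_cap` with the smallest eQTL p-values are
#' kept. The returned indices are in locus (base-pair) order, so the
#' selection is deterministic.
#'
#' @param locus A `harmonized_locus`.
#' @param top Index of the instrument SNP in the locus.
#' @param p_zx_max,r2_min,r2_max,m_cap See [heidi_config()].
#' @return Integer indices into the locus arrays, including `top`.
#' @export
select_heidi_snps <- function(locus, top, p_zx_max = 1.57e-3,
                              r2_min = 0.05, r2_max = 0.9, m_cap = 20L) {
  m <- locus_size(locus)
  stopifnot(top >= 1, top <= m)
  z2 <- (locus$b_zx / locus$se_zx)^2
  p_zx <- stats::pchisq(z2, df = 1, lower.tail = FALSE)
  r2 <- unname(locus$ld_r[, top])^2
  ok <- p_zx < p_zx_max & r2 >= r2_min & r2 <= r2_max
  ok[top] <- FALSE                       # handled separately, always kept
  idx <- unname(which(ok))
  if (length(idx) > m_cap - 1L) {
    idx <- idx[order(p_zx[idx])][seq_len(m_cap - 1L)]
  }
  sort(c(top, idx))
}

#' Delta-method covariance of per-SNP SMR effect estimates
#'
#' Each SNP i in the cis window yields its own ratio estimate
#' `b_xy(i) = b_zy(i)/b_zx(i)`. Because the per-SNP GWAS (and eQTL) estimates
#' are correlated through LD, so are the ratios. Assuming non-overlapping
#' GWAS and eQTL cohorts (zero cross-covariance between the two studies),
#' the first-order delta method gives
#' \deqn{Cov(b_{xy,i}, b_{xy,j}) = r_{ij} \frac{se_{zy,i} se_{zy,j}}{b_{zx,i} b_{zx,j}}
#'   + r_{ij} \frac{b_{zy,i} b_{zy,j} se_{zx,i} se_{zx,j}}{b_{zx,i}^2 b_{zx,j}^2}}
#' with `r_ij` the LD correlation; the diagonal reduces to the single-SNP
#' variance of [estimate_bxy()].
#'
#' @param locus A `harmonized_locus`.
#' @param idx Indices of the SNP subset (all must have `b_zx != 0`).
#' @return Symmetric covariance matrix of `b_xy` over `idx`.
#' @export
bxy_covariance <- function(locus, idx = seq_len(locus_size(locus))) {
  b_zx <- locus$b_zx[idx]; se_zx <- locus$se_zx[idx]
  b_zy <- locus$b_zy[idx]; se_zy <- locus$se_zy[idx]
  if (any(b_zx == 0)) stop("bxy_covariance: b_zx = 0 in subset")
  r <- unname(locus$ld_r[idx, idx, drop = FALSE])
  v <- r * outer(se_zy, se_zy) / outer(b_zx, b_zx) +
    r * outer(b_zy, b_zy) * outer(se_zx, se_zx) / outer(b_zx^2, b_zx^2)
  v <- (v + t(v)) / 2
  dimnames(v) <- NULL
  if (any(diag(v) <= 0)) {
    stop("bxy_covariance: non-positive variance; corrupt inputs?")
  }
  v
}

#' The HEIDI heterogeneity statistic
#'
#' Under a single shared causal variant, every cis SNP's ratio estimate
#' targets the same `b_xy`, so the contrasts
#' `d_i = b_xy(i) - b_xy(top)` are all zero in expectation. The statistic
#' sums the squared standardized contrasts, `t_heidi = sum z_d,i^2` with
#' `z_d,i = d_i / sqrt(Var(d_i))`; departures indicate two or more distinct
#' causal variants in LD (linkage). Contrast variances and correlations come
#' from the delta-method covariance via the usual contrast rule
#' `Var(d_i) = V_ii + V_tt - 2 V_it`.
#'
#' @param locus A `harmonized_locus`.
#' @param idx SNP subset (from [select_heidi_snps()]).
#' @param top Index of the top SNP *within the locus* (must be in `idx`).
#' @param cov Optional precomputed covariance from [bxy_covariance()].
#' @return List: `t_heidi`, `z_d` (one per non-top SNP), `r_zd` (correlation
#'   matrix of the contrasts), `used` (locus indices of the contrasts kept;
#'   contrasts with non-positive variance are dropped with a warning).
#' @export
heidi_statistic <- function(locus, idx, top, cov = NULL) {
  stopifnot(top %in% idx)
  if (is.null(cov)) cov <- bxy_covariance(locus, idx)
  est <- estimate_bxy(locus$b_zy[idx], locus$se_zy[idx],
                      locus$b_zx[idx], locus$se_zx[idx])
  t_pos <- match(top, idx)
  others <- setdiff(seq_along(idx), t_pos)
  d <- est$b_xy[others] - est$b_xy[t_pos]
  cd <- cov[others, others, drop = FALSE] -
    outer(cov[others, t_pos], rep(1, length(others))) -
    outer(rep(1, length(others)), cov[others, t_pos]) +
    cov[t_pos, t_pos]
  vard <- diag(cd)
  keep <- vard > 0
  if (!all(keep)) {
    warning("heidi_statistic: dropping ", sum(!keep),
            " contrast(s) with non-positive variance")
    d <- d[keep]; cd <- cd[keep, keep, drop = FALSE]; vard <- vard[keep]
  }
  z_d <- d / sqrt(vard)
  r_zd <- cd / sqrt(outer(vard, vard))
  list(t_heidi = sum(z_d^2), z_d = z_d, r_zd = r_zd,
       used = idx[others][keep])
}

.imhof_tail <- function(t, lambda) {
  lambda <- lambda[lambda > 0]
  f <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * t * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(theta) / (u * rho)
    # limit at u -> 0 is (sum(lambda) - t) / 2
    out[u == 0] <- (sum(lambda) - t) / 2
    out
  }
  val <- stats::integrate(f, 0, Inf, rel.tol = 1e-8, abs.tol = 1e-10,
                          subdivisions = 50000L, stop.on.error = FALSE)
  min(max(0.5 + val$value / pi, 0), 1)
}

#' P-value for the HEIDI statistic
#'
#' Because the contrasts `z_d` are correlated, `t_heidi` is not chi-square
#' distributed: under the null it follows a weighted mixture
#' `sum_k lambda_k chi2_1`, where `lambda_k` are the eigenvalues of the
#' contrast correlation matrix (negative eigenvalues from numerical noise
#' are clipped at zero). The default two-moment (Satterthwaite) approximation
#' matches the mixture's mean and variance with a scaled chi-square:
#' scale `sum(lambda^2)/sum(lambda)` and degrees of freedom
#' `sum(lambda)^2/sum(lambda^2)`. `method = "imhof"` instead inverts the
#' characteristic function numerically, which is more accurate deep in the
#' tail.
#'
#' With an identity correlation the approximation is exact and reduces to
#' chi-square with one degree of freedom per contrast.
#'
#' @param t_heidi Nonnegative statistic.
#' @param r_zd Correlation matrix of the contrasts (positive semi-definite
#'   up to numerical noise).
#' @param method `"satterthwaite"` or `"imhof"`.
#' @return `p_heidi` in `(0, 1]`.
#' @export
heidi_pvalue <- function(t_heidi, r_zd,
                         method = c("satterthwaite", "imhof")) {
  method <- match.arg(method)
  stopifnot(t_heidi >= 0)
  r_zd <- as.matrix(r_zd)
  lambda <- eigen(r_zd, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 0] <- 0
  if (sum(lambda) == 0) {
    warning("heidi_pvalue: degenerate contrast correlation; p = 1")
    return(1)
  }
  if (method == "imhof") {
    if (t_heidi == 0) return(1)
    return(.imhof_tail(t_heidi, lambda))
  }
  s1 <- sum(lambda); s2 <- sum(lambda^2)
  scale <- s2 / s1
  df <- s1^2 / s2
  stats::pchisq(t_heidi / scale, df = df, lower.tail = FALSE)
}

#' Run the HEIDI test for one locus
#'
#' Composes SNP selection, delta-method covariance, the heterogeneity
#' statistic and its mixture p-value. The retention decision
#' (`p_heidi > threshold` keeps the probe as pleiotropy/causality) belongs to
#' the pipeline, not to this function.
#'
#' @param locus A `harmonized_locus`.
#' @param top Instrument index from [select_top_instrument()].
#' @param config A [heidi_config()].
#' @return List of class `heidi_result`: `probe_id`, `n_snps_used`
#'   (including the top SNP), `t_heidi`, `p_heidi`, `status` in
#'   `{"tested", "too_few_snps"}`. For `too_few_snps` the statistic and
#'   p-value are `NA`.
#' @export
run_heidi <- function(locus, top, config = heidi_config()) {
  idx <- select_heidi_snps(locus, top,
                           p_zx_max = config$p_zx_max,
                           r2_min = config$r2_min, r2_max = config$r2_max,
                           m_cap = config$m_cap)
  if (length(idx) < config$min_snps) {
    return(structure(list(probe_id = locus$probe$probe_id,
                          n_snps_used = length(idx),
                          t_heidi = NA_real_, p_heidi = NA_real_,
                          status = "too_few_snps"),
                     class = "heidi_result"))
  }
  st <- heidi_statistic(locus, idx, top)
  if (length(st$z_d) == 0L) {
    return(structure(list(probe_id = locus$probe$probe_id,
                          n_snps_used = length(idx),
                          t_heidi = NA_real_, p_heidi = NA_real_,
                          status = "too_few_snps"),
                     class = "heidi_result"))
  }
  p <- heidi_pvalue(st$t_heidi, st$r_zd, method = config$method)
  structure(list(probe_id = locus$probe$probe_id,
                 n_snps_used = length(st$used) + 1L,
                 t_heidi = st$t_heidi, p_heidi = p, status = "tested"),
            class = "heidi_result")
}

#' @export
print.heidi_result <- function(x, ...) {
  cat("HEIDI: probe ", x$probe_id, ", status ", x$status, sep = "")
  if (x$status == "tested") {
    cat(sprintf(", %d SNPs, t = %.3f, p = %.4g", x$n_snps_used,
                x$t_heidi, x$p_heidi))
  }
  cat("\n")
  invisible(x)
}
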