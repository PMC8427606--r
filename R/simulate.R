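#' Simulation configuration for a cis locus
#'
#' Describes one synthetic cis-eQTL locus and the generating model relating
#' a SNP, miRNA expression and a quantitative trait:
#' * `pleiotropy` — one causal SNP affects both expression and trait
#'   directly (`b_zx`, `b_zy`);
#' * `causality` — the SNP affects expression (`b_zx`), and expression
#'   affects the trait (`b_xy`);
#' * `linkage` — two distinct SNPs in LD affect expression and trait
#'   separately; the trait-SNP is chosen so its realized dosage LD with the
#'   expression-SNP is within `linkage_r_tol` of `linkage_r_target`.
#'
#' Genotypes are AR(1) Gaussian-copula haplotypes thresholded to allele
#' indicators, summed to dosages, with per-SNP minor-allele frequencies
#' drawn from `maf_range`; `rho` controls how fast LD decays along the
#' block. Effects are on the standardized-genotype and standardized-
#' expression scale, so `b_zx` is in expression-SD units per genotype SD.
#'
#' @param model Generating model.
#' @param n_gwas,n_eqtl,n_ld Sample sizes of the GWAS cohort, eQTL cohort
#'   and the independent LD reference cohort.
#' @param m_snps Number of SNPs in the cis block (1 kb spacing, probe TSS at
#'   the block center).
#' @param maf_range Range minor-allele frequencies are drawn from.
#' @param rho AR(1) decay of the latent haplotype correlation, in `[0, 1)`.
#' @param b_zx Causal eQTL effect (expression SD per genotype SD).
#' @param b_zy Direct SNP effect on the trait (pleiotropy and linkage).
#' @param b_xy Effect of expression on the trait (causality model).
#' @param linkage_r_target Target dosage LD between the two causal SNPs.
#' @param linkage_r_tol Acceptable deviation of the realized LD.
#' @param standardized Emit summary statistics from standardized-genotype
#'   regressions (default); `FALSE` emits per-allele (unstandardized)
#'   effects, exercising harmonization scaling downstream.
#' @param seed Mandatory integer seed; the generator has no hidden
#'   randomness.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(model = c("pleiotropy", "causality", "linkage"),
                       n_gwas = 20000, n_eqtl = 20000, n_ld = 5000,
                       m_snps = 30, maf_range = c(0.05, 0.5), rho = 0.8,
                       b_zx = 0.3, b_zy = 0.1, b_xy = 0.3,
                       linkage_r_target = 0.3, linkage_r_tol = 0.05,
                       standardized = TRUE, seed) {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory")
  stopifnot(n_gwas >= 2, n_eqtl >= 2, n_ld >= 2, m_snps >= 2,
            rho >= 0, rho < 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] <= maf_range[2],
            abs(b_zx) < 1, abs(b_zy) < 1, abs(b_xy) < 1)
  structure(list(model = model, n_gwas = as.integer(n_gwas),
                 n_eqtl = as.integer(n_eqtl), n_ld = as.integer(n_ld),
                 m_snps = as.integer(m_snps), maf_range = maf_range,
                 rho = rho, b_zx = b_zx, b_zy = b_zy, b_xy = b_xy,
                 linkage_r_target = linkage_r_target,
                 linkage_r_tol = linkage_r_tol,
                 standardized = isTRUE(standardized),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.haplotypes <- function(n, m, rho, thr) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0 && m > 1L) {
    a <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1L] + a * z[, j]
  }
  z < matrix(thr, n, m, byrow = TRUE)
}

#' Simulate a dosage matrix over an AR(1) LD block
#'
#' Each of two haplotypes per individual is a latent AR(1) Gaussian vector
#' thresholded at `qnorm(maf)` per SNP; the dosage is their sum, so each
#' SNP is marginally Binomial(2, maf) and adjacent SNPs are in LD that
#' strengthens with `rho`.
#'
#' @param n Individuals.
#' @param m SNPs (at least 2).
#' @param maf Optional vector of allele frequencies (recycled); when `NULL`
#'   they are drawn uniformly from `maf_range`.
#' @param maf_range Range to draw frequencies from.
#' @param rho AR(1) decay parameter in `[0, 1)`.
#' @param seed Optional seed (set for standalone use; [simulate_scenario()]
#'   manages the RNG itself).
#' @return Integer dosage matrix `n x m` with values in `{0, 1, 2}` and the
#'   frequencies in attribute `"maf"`.
#' @export
simulate_genotypes <- function(n, m, maf = NULL, maf_range = c(0.05, 0.5),
                               rho = 0.8, seed = NULL) {
  if (m < 2) stop("simulate_genotypes: need at least 2 SNPs")
  stopifnot(rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- stats::runif(m, maf_range[1], maf_range[2])
  maf <- rep_len(maf, m)
  thr <- stats::qnorm(maf)
  g <- .haplotypes(n, m, rho, thr) + .haplotypes(n, m, rho, thr)
  storage.mode(g) <- "integer"
  attr(g, "maf") <- maf
  g
}

# marginal least squares of y on each (standardized) genotype column
.marginal_stats <- function(g, y, standardized = TRUE) {
  n <- nrow(g)
  mu <- colMeans(g)
  sd_g <- sqrt(colSums(g^2) / (n - 1) - mu^2 * n / (n - 1))
  if (any(sd_g == 0)) {
    stop("monomorphic SNP in simulated cohort; increase n or maf_range")
  }
  gc_ <- sweep(g, 2, mu, "-")
  if (standardized) gc_ <- sweep(gc_, 2, sd_g, "/")
  yc <- y - mean(y)
  sxx <- colSums(gc_^2)
  sxy <- drop(crossprod(gc_, yc))
  syy <- sum(yc^2)
  b <- sxy / sxx
  rss <- pmax(syy - b^2 * sxx, 0)
  se <- sqrt(rss / ((n - 2) * sxx))
  z <- b / se
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  list(beta = b, se = se, p = p, eaf = mu / 2)
}

.allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Simulate paired GWAS and eQTL summary statistics for one cis locus
#'
#' Generates three independent cohorts from the same population (eQTL, GWAS
#' and LD reference), builds the phenotypes according to the configured
#' causal model, runs per-SNP marginal regressions in each of the first two
#' cohorts, and returns the results in the summary-statistic dialect the
#' rest of the package consumes, together with the generating truth.
#'
#' Expression in the eQTL cohort is
#' `x = b_zx * g_c + e`, `e ~ N(0, 1 - b_zx^2)` on the standardized-genotype
#' scale, so `Var(x) = 1`. The trait is `y = b_zy * g_c + e` (pleiotropy),
#' `y = b_xy * x + e` with expression regenerated in the GWAS cohort
#' (causality), or `y = b_zy * g_c2 + e` at a second SNP in LD with the
#' first (linkage). The LD reference is the dosage correlation of the third
#' cohort. About half of the GWAS rows have their effect/other alleles
#' swapped (with beta negated and frequency complemented), so harmonization
#' is exercised on every simulated dataset; allele pairs are never
#' strand-ambiguous, since ambiguous SNPs would be dropped downstream.
#'
#' @param config A [sim_config()].
#' @return List of class `smr_scenario`: `gwas`, `eqtl` (summary
#'   `data.frame`s), `ld` (an `ld_reference`), `probes` (one-row probe
#'   table) and `truth` (model, causal indices and ids, generating effects,
#'   realized LD between causal SNPs, seed).
#' @export
simulate_scenario <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$m_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  pair <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                        drop = FALSE]
  snp <- sprintf("rs%05d", seq_len(m))
  c1 <- as.integer(ceiling(m / 2))
  bp <- 2e6 + (seq_len(m) - c1) * 1000
  tss <- bp[c1]
  thr <- stats::qnorm(maf)

  g_e <- .haplotypes(config$n_eqtl, m, config$rho, thr) +
    .haplotypes(config$n_eqtl, m, config$rho, thr)
  g_g <- .haplotypes(config$n_gwas, m, config$rho, thr) +
    .haplotypes(config$n_gwas, m, config$rho, thr)
  g_l <- .haplotypes(config$n_ld, m, config$rho, thr) +
    .haplotypes(config$n_ld, m, config$rho, thr)

  std <- function(v) (v - mean(v)) / stats::sd(v)

  # expression in the eQTL cohort
  x_e <- config$b_zx * std(g_e[, c1]) +
    stats::rnorm(config$n_eqtl, 0, sqrt(1 - config$b_zx^2))
  eqtl_stats <- .marginal_stats(g_e, x_e, config$standardized)

  c2 <- NA_integer_
  realized_r <- NA_real_
  if (config$model == "pleiotropy") {
    y <- config$b_zy * std(g_g[, c1]) +
      stats::rnorm(config$n_gwas, 0, sqrt(1 - config$b_zy^2))
  } else if (config$model == "causality") {
    x_g <- config$b_zx * std(g_g[, c1]) +
      stats::rnorm(config$n_gwas, 0, sqrt(1 - config$b_zx^2))
    y <- config$b_xy * x_g +
      stats::rnorm(config$n_gwas, 0, sqrt(1 - config$b_xy^2))
  } else {
    r_to_c1 <- drop(stats::cor(g_g[, c1], g_g))
    cand <- setdiff(which(abs(abs(r_to_c1) - config$linkage_r_target) <=
                            config$linkage_r_tol), c1)
    if (length(cand) == 0L) {
      stop("simulate_scenario: no SNP with LD within ", config$linkage_r_tol,
           " of r = ", config$linkage_r_target,
           " to the causal SNP; adjust rho or linkage_r_target")
    }
    c2 <- cand[which.min(abs(abs(r_to_c1[cand]) - config$linkage_r_target))]
    realized_r <- r_to_c1[c2]
    y <- config$b_zy * std(g_g[, c2]) +
      stats::rnorm(config$n_gwas, 0, sqrt(1 - config$b_zy^2))
  }
  gwas_stats <- .marginal_stats(g_g, y, config$standardized)

  probe_id <- "hsa-miR-sim-1"
  eqtl <- data.frame(snp = snp, chr = "1", bp = bp,
                     a1 = pair[, 1], a2 = pair[, 2],
                     freq = eqtl_stats$eaf, beta = eqtl_stats$beta,
                     se = eqtl_stats$se, p = eqtl_stats$p,
                     n = config$n_eqtl, probe_id = probe_id,
                     probe_chr = "1", probe_tss = tss,
                     stringsAsFactors = FALSE)
  gwas <- data.frame(snp = snp, chr = "1", bp = bp,
                     a1 = pair[, 1], a2 = pair[, 2],
                     freq = gwas_stats$eaf, beta = gwas_stats$beta,
                     se = gwas_stats$se, p = gwas_stats$p,
                     n = config$n_gwas, stringsAsFactors = FALSE)
  flip <- stats::runif(m) < 0.5
  gwas$a1[flip] <- pair[flip, 2]
  gwas$a2[flip] <- pair[flip, 1]
  gwas$beta[flip] <- -gwas$beta[flip]
  gwas$freq[flip] <- 1 - gwas$freq[flip]

  ld <- ld_reference(stats::cor(g_l), snp_ids = snp)
  probes <- data.frame(probe_id = probe_id, chr = "1", tss = tss,
                       stringsAsFactors = FALSE)
  truth <- list(model = config$model, causal_index = c1,
                causal_snp = snp[c1], causal_index2 = c2,
                causal_snp2 = if (is.na(c2)) NA_character_ else snp[c2],
                b_zx = config$b_zx,
                b_zy = if (config$model == "causality") NA_real_ else
                  config$b_zy,
                b_xy = if (config$model == "causality") config$b_xy else
                  if (config$model == "pleiotropy")
                    config$b_zy / config$b_zx else NA_real_,
                realized_r = realized_r, maf = maf, seed = config$seed)
  structure(list(gwas = gwas, eqtl = eqtl, ld = ld, probes = probes,
                 truth = truth, config = config),
            class = "smr_scenario")
}

#' Write a simulated scenario to disk
#'
#' Writes `gwas.tsv`, `eqtl.tsv`, `ld_corr.tsv`, `probes.tsv` (the formats
#' read by [read_summary_table()], [load_ld_reference()] and
#' [read_probe_table()]) plus `truth.json` into a directory.
#'
#' @param scenario An `smr_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "smr_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_results(scenario$gwas, file.path(dir, "gwas.tsv"))
  write_results(scenario$eqtl, file.path(dir, "eqtl.tsv"))
  write_results(scenario$probes, file.path(dir, "probes.tsv"))
  r <- scenario$ld$r
  out <- data.frame(snp = rownames(r),
                    apply(r, 2, .fmt_num), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, file.path(dir, "ld_corr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- scenario$truth
  truth$maf <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Simulate a miRNA count matrix with tumor/normal groups
#'
#' Negative-binomial (gamma-mixed Poisson) counts with per-sample library
#' size factors; a `de_fraction` of the miRNAs has its tumor mean shifted
#' by `fold`. Baseline means are log-normal across miRNAs unless supplied.
#'
#' @param n_mirnas Number of miRNAs (rows).
#' @param n_per_group Samples per condition (at least 2).
#' @param de_fraction Fraction of miRNAs that are differentially expressed.
#' @param fold Fold change applied in the tumor group (`> 0`; 1 = no
#'   effect).
#' @param dispersion NB dispersion (`Var = mu + dispersion * mu^2`).
#' @param base_mean Optional baseline mean(s), recycled across miRNAs.
#' @param libsize_sd SD of the log-normal per-sample library factor.
#' @param seed Mandatory seed.
#' @return List: `counts` (integer matrix with dimnames), `condition`
#'   (per-sample labels), `truth` (`data.frame` with `mirna_id`, `is_de`,
#'   `fold`).
#' @export
simulate_counts <- function(n_mirnas = 2000, n_per_group = 20,
                            de_fraction = 0, fold = 2, dispersion = 0.05,
                            base_mean = NULL, libsize_sd = 0.3, seed) {
  if (missing(seed) || is.null(seed)) stop("simulate_counts: seed is mandatory")
  stopifnot(n_per_group >= 2, fold > 0, dispersion > 0,
            de_fraction >= 0, de_fraction <= 1)
  set.seed(as.integer(seed))
  if (is.null(base_mean)) {
    base_mean <- stats::rlnorm(n_mirnas, meanlog = log(100), sdlog = 1.2)
  }
  base_mean <- rep_len(base_mean, n_mirnas)
  n_de <- round(de_fraction * n_mirnas)
  is_de <- seq_len(n_mirnas) <= n_de
  if (fold == 1) is_de[] <- FALSE   # fold 1 is no effect: truth is all-null
  n_s <- 2L * n_per_group
  condition <- rep(c("normal", "tumor"), each = n_per_group)
  lib <- exp(stats::rnorm(n_s, 0, libsize_sd))
  mu <- outer(base_mean, lib)
  tumor_cols <- condition == "tumor"
  mu[is_de, tumor_cols] <- mu[is_de, tumor_cols] * fold
  counts <- matrix(stats::rnbinom(n_mirnas * n_s, mu = mu,
                                  size = 1 / dispersion),
                   n_mirnas, n_s)
  dimnames(counts) <- list(sprintf("hsa-miR-sim-%04d", seq_len(n_mirnas)),
                           sprintf("sample_%02d", seq_len(n_s)))
  truth <- data.frame(mirna_id = rownames(counts), is_de = is_de,
                      fold = ifelse(is_de, fold, 1),
                      stringsAsFactors = FALSE)
  list(counts = counts, condition = condition, truth = truth)
}
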