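#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j >= i}(p_(j) * m / j)` capped at 1 and
#' mapped back to the input order (delegates to [stats::p.adjust()]). Applied
#' within one analysis run, i.e. across the probes actually tested for one
#' cancer/GWAS dataset.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Vector of q-values of the same length (empty in, empty out).
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify the causal model from the HEIDI p-value
#'
#' Small HEIDI p-values indicate heterogeneity among the per-SNP ratio
#' estimates, the signature of two distinct causal variants in LD: such
#' probes are labelled `linkage` and discarded from the significant set.
#' `p_heidi` above the threshold is consistent with a single shared causal
#' variant (`non_linkage`, i.e. pleiotropy or causality — the test cannot
#' tell those two apart). Probes without a HEIDI p-value are `untested`.
#'
#' The default threshold is 0.01: retaining probes at `p_heidi > 0.01`
#' rather than the more conservative 0.05 keeps associations whose
#' heterogeneity is mild, which follow-up studies of the method found to
#' predict better.
#'
#' @param p_heidi HEIDI p-value(s), `NA` when not tested.
#' @param threshold Retention threshold (default 0.01).
#' @return Character vector in `{"non_linkage", "linkage", "untested"}`.
#' @export
classify_model <- function(p_heidi, threshold = 0.01) {
  ifelse(is.na(p_heidi), "untested",
         ifelse(p_heidi > threshold, "non_linkage", "linkage"))
}

#' Predict the miRNA's role from the sign of the SMR effect
#'
#' A negative `b_xy` means higher genetically predicted miRNA expression
#' lowers disease risk: the miRNA is called tumor-suppressive. A positive
#' effect is called oncogenic. An exactly zero effect is indeterminate.
#'
#' @param b_xy SMR effect estimate(s).
#' @return Character vector in
#'   `{"tumor_suppressive", "oncogenic", "indeterminate"}`.
#' @export
classify_role <- function(b_xy) {
  ifelse(is.na(b_xy), "indeterminate",
         ifelse(b_xy < 0, "tumor_suppressive",
                ifelse(b_xy > 0, "oncogenic", "indeterminate")))
}

#' Analysis configuration
#'
#' All tunable thresholds of the SMR-HEIDI pipeline in one object. Defaults
#' reproduce the standard analysis: 1 Mb cis window each side of the probe
#' TSS, genome-wide instrument threshold `5e-8`, FDR significance at 0.05,
#' HEIDI retention at `p_heidi > 0.01`, extended-MHC exclusion on GRCh37.
#'
#' @param cis_window_bp Cis-window half-width in bp.
#' @param p_instrument_max Instrument eQTL p-value threshold.
#' @param fdr_alpha FDR significance level for the SMR step.
#' @param heidi_threshold HEIDI retention threshold.
#' @param heidi A [heidi_config()].
#' @param mhc_region MHC exclusion interval, see [mhc_grch37()].
#' @param heidi_everywhere Run HEIDI for every tested probe instead of only
#'   the FDR-significant ones.
#' @param use_reported_p Select instruments by the reported eQTL p column
#'   instead of recomputed `beta/se` z-scores.
#' @param drop_ambiguous,eaf_resolve,eaf_margin Harmonization options, see
#'   [harmonize_locus()].
#' @param seed Unused by the deterministic pipeline; accepted so that a
#'   config file can carry one seed for the simulation commands.
#' @return List of class `smr_config`.
#' @export
smr_config <- function(cis_window_bp = 1e6, p_instrument_max = 5e-8,
                       fdr_alpha = 0.05, heidi_threshold = 0.01,
                       heidi = heidi_config(), mhc_region = mhc_grch37(),
                       heidi_everywhere = FALSE, use_reported_p = FALSE,
                       drop_ambiguous = TRUE, eaf_resolve = FALSE,
                       eaf_margin = 0.08, seed = NULL) {
  stopifnot(cis_window_bp > 0, p_instrument_max > 0, p_instrument_max <= 1,
            fdr_alpha > 0, fdr_alpha <= 1,
            heidi_threshold >= 0, heidi_threshold < 1)
  structure(list(cis_window_bp = cis_window_bp,
                 p_instrument_max = p_instrument_max,
                 fdr_alpha = fdr_alpha, heidi_threshold = heidi_threshold,
                 heidi = heidi, mhc_region = mhc_region,
                 heidi_everywhere = isTRUE(heidi_everywhere),
                 use_reported_p = isTRUE(use_reported_p),
                 drop_ambiguous = isTRUE(drop_ambiguous),
                 eaf_resolve = isTRUE(eaf_resolve),
                 eaf_margin = eaf_margin, seed = seed),
            class = "smr_config")
}

#' Read an analysis configuration from YAML
#'
#' Recognized keys mirror the [smr_config()] arguments; `heidi:` is a nested
#' mapping with the [heidi_config()] keys and `mhc_region:` a mapping with
#' `chr`, `start`, `end`. Unknown keys are an error, so typos do not pass
#' silently.
#'
#' @param path YAML file.
#' @return An `smr_config`.
#' @export
read_smr_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(smr_config)), c("heidi", "mhc_region"))
  extra <- setdiff(names(y), c(known, "heidi", "mhc_region"))
  if (length(extra) > 0L) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  }
  args <- y[intersect(names(y), known)]
  if (!is.null(y$heidi)) args$heidi <- do.call(heidi_config, y$heidi)
  if (!is.null(y$mhc_region)) {
    args$mhc_region <- list(chr = as.character(y$mhc_region$chr),
                            start = y$mhc_region$start,
                            end = y$mhc_region$end)
  }
  do.call(smr_config, args)
}

#' Fit the SMR-HEIDI transcriptome-wide association model
#'
#' The main entry point: for every probe outside the MHC exclusion region,
#' harmonizes its cis window across the eQTL table, the GWAS table and the
#' LD reference, selects the top cis-eQTL instrument (probes with no SNP at
#' `P_eQTL < p_instrument_max` are excluded), and computes the SMR ratio
#' estimate `b_xy = b_zy/b_zx`, its delta-method standard error and the
#' chi-square(1) p-value of `T_SMR`. Benjamini-Hochberg FDR is then applied
#' across all tested probes of this run, and the HEIDI heterogeneity test is
#' run for the FDR-significant probes (all probes with
#' `heidi_everywhere = TRUE`). A probe is flagged `significant` when
#' `fdr_SMR < fdr_alpha`, `p_HEIDI > heidi_threshold` and the model call is
#' `non_linkage`. The run is deterministic given its inputs and
#' configuration.
#'
#' @param gwas GWAS summary statistics: a path or a `data.frame` from
#'   [read_summary_table()].
#' @param eqtl eQTL summary statistics: a path or a `data.frame`.
#' @param ld LD reference: a path to a correlation-matrix TSV, a correlation
#'   matrix with SNP dimnames, or an `ld_reference`.
#' @param probes Probe annotation (`probe_id chr tss`): a path, a
#'   `data.frame`, or `NULL` to take it from the eQTL table's probe columns.
#' @param config An [smr_config()].
#' @param cancer_label Label recorded in the `cancer` column, distinguishing
#'   e.g. breast ER-subtype runs of the same pipeline.
#' @return An object of class `smr`: a list with `results` (one row per
#'   tested probe, columns `cancer probe chr bp topSNP b_SMR se_SMR p_SMR
#'   fdr_SMR p_HEIDI n_HEIDI_snps HEIDI_status model_call role_call
#'   significant`), `exclusions` (probe, reason), `config`, `cancer_label`
#'   and `n_probes`. Methods: `print`, `summary`, `coef`, `plot`,
#'   [write_results()].
#' @examples
#' scen <- simulate_scenario(sim_config(model = "pleiotropy", seed = 1,
#'                                      n_gwas = 4000, n_eqtl = 4000,
#'                                      n_ld = 1000, m_snps = 12))
#' fit <- smr(scen$gwas, scen$eqtl, scen$ld, scen$probes)
#' coef(fit)
#' @export
smr <- function(gwas, eqtl, ld, probes = NULL, config = smr_config(),
                cancer_label = "trait") {
  if (is.character(gwas)) gwas <- read_summary_table(gwas, "gwas")
  if (is.character(eqtl)) eqtl <- read_summary_table(eqtl, "eqtl")
  if (is.character(ld)) ld <- load_ld_reference(ld, "correlation")
  if (is.matrix(ld)) ld <- ld_reference(ld)
  stopifnot(inherits(ld, "ld_reference"))
  if (is.null(probes)) probes <- probes_from_eqtl(eqtl)
  if (is.character(probes)) probes <- read_probe_table(probes)
  stopifnot(inherits(config, "smr_config"))

  excl <- list()
  rows <- list()
  loci <- list()
  tops <- integer(0)
  for (k in seq_len(nrow(probes))) {
    pr <- probes[k, ]
    if (in_mhc(pr$chr, pr$tss, config$mhc_region)) {
      excl[[length(excl) + 1L]] <- data.frame(probe = pr$probe_id,
                                              reason = "mhc")
      next
    }
    locus <- harmonize_locus(pr, eqtl, gwas, ld,
                             window = config$cis_window_bp,
                             drop_ambiguous = config$drop_ambiguous,
                             eaf_resolve = config$eaf_resolve,
                             eaf_margin = config$eaf_margin)
    top <- select_top_instrument(locus, config$p_instrument_max,
                                 use_reported_p = config$use_reported_p)
    if (is.na(top)) {
      excl[[length(excl) + 1L]] <- data.frame(probe = pr$probe_id,
                                              reason = "no_instrument")
      next
    }
    z_zx <- locus$b_zx[top] / locus$se_zx[top]
    z_zy <- locus$b_zy[top] / locus$se_zy[top]
    t_smr <- smr_statistic(z_zx, z_zy)
    est <- estimate_bxy(locus$b_zy[top], locus$se_zy[top],
                        locus$b_zx[top], locus$se_zx[top])
    rows[[length(rows) + 1L]] <- data.frame(
      cancer = cancer_label, probe = pr$probe_id,
      chr = as.character(locus$probe$chr), bp = locus$bp[top],
      topSNP = locus$snp[top],
      b_SMR = est$b_xy, se_SMR = est$se_xy, p_SMR = smr_pvalue(t_smr),
      stringsAsFactors = FALSE)
    loci[[length(loci) + 1L]] <- locus
    tops <- c(tops, top)
  }

  excl <- if (length(excl) > 0L) do.call(rbind, excl) else
    data.frame(probe = character(0), reason = character(0))
  if (length(rows) == 0L) {
    res <- data.frame(cancer = character(0), probe = character(0),
                      chr = character(0), bp = numeric(0),
                      topSNP = character(0), b_SMR = numeric(0),
                      se_SMR = numeric(0), p_SMR = numeric(0),
                      fdr_SMR = numeric(0), p_HEIDI = numeric(0),
                      n_HEIDI_snps = integer(0), HEIDI_status = character(0),
                      model_call = character(0), role_call = character(0),
                      significant = logical(0))
    message("smr: no testable probe (", nrow(excl), " excluded)")
    return(structure(list(results = res, exclusions = excl, config = config,
                          cancer_label = cancer_label,
                          n_probes = nrow(probes)),
                     class = "smr"))
  }

  res <- do.call(rbind, rows)
  res$fdr_SMR <- adjust_fdr(pmax(res$p_SMR, .Machine$double.xmin))
  res$p_HEIDI <- NA_real_
  res$n_HEIDI_snps <- NA_integer_
  res$HEIDI_status <- "skipped"
  do_heidi <- if (config$heidi_everywhere) rep(TRUE, nrow(res)) else
    res$fdr_SMR < config$fdr_alpha
  for (i in which(do_heidi)) {
    h <- run_heidi(loci[[i]], tops[i], config$heidi)
    res$p_HEIDI[i] <- h$p_heidi
    res$n_HEIDI_snps[i] <- h$n_snps_used
    res$HEIDI_status[i] <- h$status
  }
  res$model_call <- classify_model(res$p_HEIDI, config$heidi_threshold)
  res$role_call <- classify_role(res$b_SMR)
  res$significant <- res$fdr_SMR < config$fdr_alpha &
    !is.na(res$p_HEIDI) & res$p_HEIDI > config$heidi_threshold &
    res$model_call == "non_linkage"
  rownames(res) <- NULL

  structure(list(results = res, exclusions = excl, config = config,
                 cancer_label = cancer_label, n_probes = nrow(probes)),
            class = "smr")
}

#' @export
print.smr <- function(x, ...) {
  cat("SMR-HEIDI transcriptome-wide association fit\n")
  cat("  analysis: ", x$cancer_label, "\n", sep = "")
  cat("  probes: ", x$n_probes, " supplied, ", nrow(x$results),
      " tested, ", nrow(x$exclusions), " excluded\n", sep = "")
  cat("  significant (FDR < ", x$config$fdr_alpha, ", P_HEIDI > ",
      x$config$heidi_threshold, "): ", sum(x$results$significant),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.smr <- function(object, ...) {
  res <- object$results
  out <- list(cancer_label = object$cancer_label,
              n_probes = object$n_probes,
              n_tested = nrow(res),
              exclusion_counts = table(object$exclusions$reason),
              heidi_counts = table(res$HEIDI_status),
              n_significant = sum(res$significant),
              significant = res[res$significant, , drop = FALSE])
  class(out) <- "summary.smr"
  out
}

#' @export
print.summary.smr <- function(x, ...) {
  cat("SMR-HEIDI analysis '", x$cancer_label, "'\n", sep = "")
  cat("  probes tested: ", x$n_tested, " / ", x$n_probes, "\n", sep = "")
  if (length(x$exclusion_counts) > 0L) {
    cat("  exclusions:\n")
    for (r in names(x$exclusion_counts)) {
      cat("    ", r, ": ", x$exclusion_counts[[r]], "\n", sep = "")
    }
  }
  cat("  HEIDI status:\n")
  for (r in names(x$heidi_counts)) {
    cat("    ", r, ": ", x$heidi_counts[[r]], "\n", sep = "")
  }
  cat("  significant associations: ", x$n_significant, "\n", sep = "")
  if (nrow(x$significant) > 0L) {
    print(x$significant[, c("probe", "topSNP", "b_SMR", "se_SMR",
                            "fdr_SMR", "p_HEIDI", "role_call")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.smr <- function(object, ...) {
  stats::setNames(object$results$b_SMR, object$results$probe)
}

#' Volcano-style plot of an SMR fit
#'
#' Plots each tested probe's SMR effect against `-log10(p_SMR)`, marking
#' the probes that survive the full FDR + HEIDI filter.
#'
#' @param x An `smr` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.smr <- function(x, ...) {
  res <- x$results
  if (nrow(res) == 0L) {
    stop("nothing to plot: no tested probe")
  }
  lp <- -log10(pmax(res$p_SMR, .Machine$double.xmin))
  graphics::plot(res$b_SMR, lp, xlab = expression(hat(b)[xy]),
                 ylab = expression(-log[10](p[SMR])),
                 pch = ifelse(res$significant, 19, 1),
                 col = ifelse(res$significant, "firebrick", "grey40"), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Cross-run overlap of significant miRNAs
#'
#' Joins several `smr` fits (e.g. different cancers or ER subtypes) and
#' reports which probes are significant in more than one run.
#'
#' @param ... `smr` fits, or a single list of them.
#' @return `data.frame` with `probe`, `n_runs` and a comma-separated
#'   `runs` column, sorted by decreasing `n_runs`.
#' @export
smr_overlap <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "smr")) fits <- fits[[1L]]
  sig <- lapply(fits, function(f) {
    r <- f$results
    data.frame(probe = r$probe[r$significant],
               run = f$cancer_label, stringsAsFactors = FALSE)
  })
  sig <- do.call(rbind, sig)
  if (is.null(sig) || nrow(sig) == 0L) {
    return(data.frame(probe = character(0), n_runs = integer(0),
                      runs = character(0)))
  }
  agg <- stats::aggregate(run ~ probe, data = sig,
                          FUN = function(r) paste(sort(unique(r)),
                                                  collapse = ","))
  agg$n_runs <- lengths(strsplit(agg$run, ","))
  out <- data.frame(probe = agg$probe, n_runs = agg$n_runs, runs = agg$run,
                    stringsAsFactors = FALSE)
  out[order(-out$n_runs, out$probe), , drop = FALSE]
}
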