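#' Median-of-ratios size factors
#'
#' Library-size normalization for count matrices: each gene's counts are
#' divided by the gene's geometric mean across samples, and a sample's size
#' factor is the median of those ratios over genes. Genes containing a zero
#' count have no finite log geometric mean and are excluded from the
#' reference; when no gene is positive in every sample, the geometric mean
#' is computed over positive counts only (with a warning), and a matrix with
#' no positive counts at all is an error.
#'
#' @param counts Nonnegative integer matrix, genes in rows, samples in
#'   columns.
#' @return Positive numeric vector of per-sample factors, named by the
#'   column names.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (all(counts == 0)) stop("size_factors: all counts are zero")
  loggeo <- rowMeans(log(counts))
  if (!any(is.finite(loggeo))) {
    warning("no gene has all-positive counts; ",
            "using positive counts only for the geometric means")
    loggeo <- apply(counts, 1, function(x) {
      if (any(x > 0)) mean(log(x[x > 0])) else -Inf
    })
  }
  geomean <- exp(loggeo)
  sf <- apply(counts, 2, function(cnts) {
    ratio <- cnts / geomean
    stats::median(ratio[is.finite(loggeo) & cnts > 0])
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("size_factors: could not estimate a positive factor for every sample")
  }
  stats::setNames(sf, colnames(counts))
}

.row_group_stats <- function(y, grp) {
  n <- sum(grp)
  m <- rowMeans(y[, grp, drop = FALSE])
  v <- rowSums((y[, grp, drop = FALSE] - m)^2) / (n - 1)
  list(n = n, mean = m, var = v)
}

#' Negative-binomial Wald test for tumor-versus-normal expression
#'
#' A deliberately simple tumor-vs-normal differential-expression test on a
#' miRNA count matrix: median-of-ratios normalization, per-gene
#' method-of-moments negative-binomial dispersion pooled across the two
#' groups (floored at `dispersion_floor`, no empirical-Bayes shrinkage), and
#' a Wald test of the log2 fold change on the normalized group means with a
#' t reference on `n - 2` degrees of freedom. This is the model class used
#' by the established NB differential-expression tools, but with
#' closed-form moment estimators instead of their shrunken GLM fits, so it
#' does not reproduce their exact p-values; its contract is correct NB Wald
#' behaviour (type-I calibration and fold-change recovery) under simulation.
#'
#' Genes with zero counts everywhere are reported with `NA` statistics and
#' class `ns`. Genes observed in only one condition get a 0.5 pseudocount in
#' both groups so the fold change stays finite. FDR adjustment is
#' Benjamini-Hochberg across the genes actually tested.
#'
#' @param counts Nonnegative integer matrix (miRNAs x samples).
#' @param condition Per-sample labels, `"tumor"` or `"normal"`; both must be
#'   present with at least 2 samples each.
#' @param alpha FDR level used for the MA classification.
#' @param dispersion_floor Lower bound on the dispersion estimate.
#' @return An object of class `nb_de`: a `data.frame` with columns
#'   `mirna_id, base_mean, log2fc, se_log2fc, p, fdr, ma_class` (fold change
#'   is tumor over normal), with the size factors in attribute
#'   `"size_factors"`. Methods: `print`, `summary`, `plot` (MA plot).
#' @export
nb_wald_test <- function(counts, condition, alpha = 0.05,
                         dispersion_floor = 1e-8) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  if (length(condition) != ncol(counts)) {
    stop("condition must label every sample column")
  }
  bad <- setdiff(unique(condition), c("tumor", "normal"))
  if (length(bad) > 0L) {
    stop("condition labels must be 'tumor' or 'normal', got: ",
         paste(bad, collapse = ", "))
  }
  tum <- condition == "tumor"
  if (sum(tum) < 2L || sum(!tum) < 2L) {
    stop("need at least 2 samples in each of tumor and normal")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("mirna_", seq_len(nrow(counts)))
  }

  sf <- size_factors(counts)
  y <- sweep(counts, 2, sf, "/")
  all_zero <- rowSums(counts) == 0

  # 0.5 pseudocount for genes silent in exactly one condition
  m0_raw <- rowMeans(y[, !tum, drop = FALSE])
  m1_raw <- rowMeans(y[, tum, drop = FALSE])
  needs_pseudo <- !all_zero & (m0_raw == 0 | m1_raw == 0)
  if (any(needs_pseudo)) {
    y[needs_pseudo, ] <- sweep(counts[needs_pseudo, , drop = FALSE] + 0.5,
                               2, sf, "/")
  }

  g0 <- .row_group_stats(y, !tum)
  g1 <- .row_group_stats(y, tum)
  inv0 <- mean(1 / sf[!tum])
  inv1 <- mean(1 / sf[tum])

  # method-of-moments dispersion: Var(K/s) = mu/s + alpha mu^2, pooled over
  # groups with df weights
  mom <- function(g, inv) (g$var - g$mean * inv) / g$mean^2
  w0 <- g0$n - 1; w1 <- g1$n - 1
  disp <- (w0 * mom(g0, inv0) + w1 * mom(g1, inv1)) / (w0 + w1)
  disp <- pmax(disp, dispersion_floor)

  log2fc <- log2(g1$mean) - log2(g0$mean)
  v0 <- inv0 / (g0$n * g0$mean) + disp / g0$n   # Var(log mu0)
  v1 <- inv1 / (g1$n * g1$mean) + disp / g1$n
  se_log2fc <- sqrt(v0 + v1) / log(2)
  tstat <- log2fc / se_log2fc
  df <- ncol(counts) - 2L
  p <- 2 * stats::pt(-abs(tstat), df = df)

  log2fc[all_zero] <- NA_real_
  se_log2fc[all_zero] <- NA_real_
  p[all_zero] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  fdr[tested] <- adjust_fdr(pmax(p[tested], .Machine$double.xmin))

  res <- data.frame(mirna_id = rownames(counts),
                    base_mean = rowMeans(y),
                    log2fc = log2fc, se_log2fc = se_log2fc,
                    p = p, fdr = fdr, stringsAsFactors = FALSE)
  res$base_mean[all_zero] <- 0
  res <- ma_classify(res, alpha = alpha)
  rownames(res) <- NULL
  attr(res, "size_factors") <- sf
  attr(res, "condition") <- condition
  attr(res, "alpha") <- alpha
  class(res) <- c("nb_de", "data.frame")
  res
}

#' MA significance classification
#'
#' Labels each gene `up` (FDR < alpha and positive log2 fold change),
#' `down` (FDR < alpha and negative log2 fold change) or `ns` otherwise —
#' the colouring rule of an MA plot. The FDR cut is strict (`fdr = alpha`
#' is `ns`) and a zero fold change is never called in either direction.
#'
#' @param results `data.frame` with `fdr` and `log2fc` columns (e.g. an
#'   `nb_de`).
#' @param alpha FDR level, default 0.05.
#' @return `results` with an added/replaced `ma_class` column.
#' @export
ma_classify <- function(results, alpha = 0.05) {
  sig <- !is.na(results$fdr) & results$fdr < alpha
  results$ma_class <- ifelse(sig & results$log2fc > 0, "up",
                             ifelse(sig & results$log2fc < 0, "down", "ns"))
  results
}

#' @export
print.nb_de <- function(x, ...) {
  cls <- table(factor(x$ma_class, levels = c("up", "down", "ns")))
  cat("NB Wald differential expression: ", nrow(x), " miRNA(s), ",
      sum(!is.na(x$p)), " tested\n", sep = "")
  cat("  up ", cls[["up"]], ", down ", cls[["down"]], ", ns ",
      cls[["ns"]], " (FDR < ", attr(x, "alpha"), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.nb_de <- function(object, ...) {
  print(object)
  sig <- object[object$ma_class != "ns", , drop = FALSE]
  if (nrow(sig) > 0L) {
    print(as.data.frame(sig)[, c("mirna_id", "base_mean", "log2fc",
                                 "fdr", "ma_class")], row.names = FALSE)
  }
  invisible(object)
}

#' MA plot of a differential-expression result
#'
#' Log2 mean normalized expression (A) against log2 fold change (M);
#' significant miRNAs are drawn in red (up) and green (down).
#'
#' @param x An `nb_de`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nb_de <- function(x, ...) {
  ok <- !is.na(x$p)
  a <- log2(x$base_mean[ok] + 0.5)
  m <- x$log2fc[ok]
  cl <- x$ma_class[ok]
  graphics::plot(a, m, xlab = "A = log2 mean expression",
                 ylab = "M = log2 fold change (tumor/normal)",
                 col = ifelse(cl == "up", "firebrick",
                              ifelse(cl == "down", "forestgreen", "grey60")),
                 pch = ifelse(cl == "ns", 1, 19), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Export MA-plot data
#'
#' Writes `mirna_id, A, M, ma_class` as TSV for external plotting.
#'
#' @param x An `nb_de`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ma_data <- function(x, path) {
  out <- data.frame(mirna_id = x$mirna_id,
                    A = log2(x$base_mean + 0.5),
                    M = x$log2fc, ma_class = x$ma_class)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
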