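#' Read a GWAS or eQTL summary-statistic table
#'
#' Reads a tab-separated summary-statistic file in the COJO-`.ma`-like dialect
#' used throughout the package and validates every row. Mandatory columns are
#' `snp chr bp a1 a2 freq beta se p n`; eQTL tables additionally carry
#' `probe_id probe_chr probe_tss` locating the miRNA probe. `a1` is the effect
#' allele: `beta` is the estimated additive effect per copy of `a1` on the
#' trait (GWAS) or on the expression level of the probe (eQTL). Lines starting
#' with `#` are ignored and missing values are encoded `NA`.
#'
#' Rows violating the per-variant invariants (non-ACGT or identical alleles,
#' `se <= 0`, `p` outside `(0, 1]`, `bp < 1`, non-numeric `beta`/`se`) are
#' dropped rather than failing the whole file; the dropped rows and the reason
#' for each are attached as the `"rejections"` attribute. Indels are rejected:
#' the analysis is defined for biallelic SNPs only.
#'
#' As a sanity check, z-scores recomputed as `beta/se` are compared with the
#' reported `p` column on the chi-square scale; a warning summarizes rows where
#' the two disagree by more than 10 percent, which usually indicates rounded or
#' mismatched input columns. The reported `p` is retained but downstream tests
#' recompute z from `beta/se`.
#'
#' @param path Path to a tab-separated file.
#' @param kind `"gwas"` or `"eqtl"`; controls the required column set.
#' @return A `data.frame` with the validated rows (standardized column names,
#'   upper-cased alleles), carrying a `"rejections"` attribute: a `data.frame`
#'   with `line` (1-based line number in the file, counting the header) and
#'   `reason`.
#' @seealso [harmonize_locus()], [load_ld_reference()], [write_results()]
#' @export
read_summary_table <- function(path, kind = c("gwas", "eqtl")) {
  kind <- match.arg(kind)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", na.strings = "NA",
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  req <- c("snp", "chr", "bp", "a1", "a2", "freq", "beta", "se", "p", "n")
  if (kind == "eqtl") req <- c(req, "probe_id", "probe_chr", "probe_tss")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0L) {
    stop("summary table '", path, "' is missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  raw <- raw[req]
  n_in <- nrow(raw)

  num <- function(x) suppressWarnings(as.numeric(x))
  bp <- num(raw$bp); freq <- num(raw$freq); beta <- num(raw$beta)
  se <- num(raw$se); p <- num(raw$p); n <- num(raw$n)
  a1 <- toupper(trimws(raw$a1)); a2 <- toupper(trimws(raw$a2))

  reason <- rep(NA_character_, n_in)
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[bad & is.na(reason)] <<- why
  }
  flag(!is.na(raw$beta) & is.na(beta), "non-numeric beta")
  flag(!is.na(raw$se) & is.na(se), "non-numeric se")
  flag(is.na(beta), "missing beta")
  flag(is.na(se), "missing se")
  flag(se <= 0, "se not positive")
  flag(is.na(p) | p <= 0 | p > 1, "p outside (0, 1]")
  flag(is.na(bp) | bp < 1, "bp not a positive position")
  flag(!(a1 %in% c("A", "C", "G", "T")) | !(a2 %in% c("A", "C", "G", "T")),
       "allele not a single A/C/G/T base (indel?)")
  flag(a1 == a2, "effect and other allele identical")
  flag(!is.na(freq) & (freq < 0 | freq > 1), "freq outside [0, 1]")
  if (kind == "eqtl") {
    tss <- num(raw$probe_tss)
    flag(is.na(raw$probe_id) | raw$probe_id == "", "missing probe_id")
    flag(is.na(tss) | tss < 1, "probe_tss not a positive position")
  }

  keep <- is.na(reason)
  out <- data.frame(snp = raw$snp[keep], chr = trimws(raw$chr[keep]),
                    bp = bp[keep], a1 = a1[keep], a2 = a2[keep],
                    freq = freq[keep], beta = beta[keep], se = se[keep],
                    p = p[keep], n = n[keep], stringsAsFactors = FALSE)
  if (kind == "eqtl") {
    out$probe_id <- raw$probe_id[keep]
    out$probe_chr <- trimws(raw$probe_chr[keep])
    out$probe_tss <- num(raw$probe_tss)[keep]
  }

  # reported p vs beta/se consistency on the chi-square scale
  if (nrow(out) > 0L) {
    chi_rep <- stats::qchisq(out$p, df = 1, lower.tail = FALSE)
    chi_z <- (out$beta / out$se)^2
    # p at the edge of double range cannot carry the z-score's information
    ok <- is.finite(chi_rep) & chi_rep > 0 & out$p > 1e-300
    bad <- ok & abs(chi_z - chi_rep) / pmax(chi_rep, 1e-12) > 0.10 &
      abs(sqrt(chi_z) - sqrt(chi_rep)) > 0.05
    if (any(bad)) {
      warning(sum(bad), " row(s) in '", basename(path),
              "' have reported p inconsistent with beta/se by >10% ",
              "on the chi-square scale")
    }
  }

  rej <- data.frame(line = which(!keep) + 1L,
                    reason = reason[!keep], stringsAsFactors = FALSE)
  attr(out, "rejections") <- rej
  if (nrow(rej) > 0L) {
    message("read_summary_table: rejected ", nrow(rej), "/", n_in,
            " row(s) from '", basename(path), "'")
  }
  out
}

#' Read a probe annotation table
#'
#' @param path Tab-separated file with columns `probe_id chr tss`.
#' @return `data.frame` with columns `probe_id`, `chr`, `tss`.
#' @export
read_probe_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  req <- c("probe_id", "chr", "tss")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("probe table missing column(s): ", paste(miss, collapse = ", "))
  }
  df$chr <- as.character(df$chr)
  df$tss <- as.numeric(df$tss)
  if (any(is.na(df$tss) | df$tss < 1)) stop("probe tss must be >= 1")
  df[req]
}

#' Extract the probe annotation carried inside an eQTL summary table
#'
#' @param eqtl A validated eQTL `data.frame` from [read_summary_table()].
#' @return One row per distinct `probe_id` with columns `probe_id chr tss`.
#' @export
probes_from_eqtl <- function(eqtl) {
  first <- !duplicated(eqtl$probe_id)
  data.frame(probe_id = eqtl$probe_id[first],
             chr = eqtl$probe_chr[first],
             tss = eqtl$probe_tss[first],
             stringsAsFactors = FALSE)
}

#' Merge eQTL summary tables from related tissues
#'
#' Concatenates two or more validated eQTL tables (e.g. colon and rectal
#' studies combined into a colorectal analysis) and de-duplicates rows that
#' report the same probe/SNP pair. `dedup = "min_p"` (default) keeps the
#' most significant record of each pair; `"first"` keeps the record from
#' the earliest table, giving one tissue precedence.
#'
#' @param ... eQTL `data.frame`s from [read_summary_table()].
#' @param dedup `"min_p"` or `"first"`.
#' @return One combined eQTL `data.frame`.
#' @export
merge_eqtl_tables <- function(..., dedup = c("min_p", "first")) {
  dedup <- match.arg(dedup)
  tabs <- list(...)
  stopifnot(length(tabs) >= 1)
  out <- do.call(rbind, tabs)
  if (dedup == "min_p") out <- out[order(out$probe_id, out$snp, out$p), ]
  keep <- !duplicated(out[c("probe_id", "snp")])
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct an LD reference from a correlation matrix
#'
#' @param r Square SNP-by-SNP correlation matrix.
#' @param snp_ids SNP identifiers; defaults to the matrix dimnames.
#' @param tol Symmetry tolerance.
#' @return An object of class `ld_reference`: a list with `snp_ids` and the
#'   correlation matrix `r`.
#' @export
ld_reference <- function(r, snp_ids = rownames(r), tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD correlation matrix must be square")
  if (is.null(snp_ids)) stop("LD reference needs SNP identifiers")
  if (max(abs(r - t(r))) > tol) {
    stop("LD correlation matrix is not symmetric (tolerance ", tol, ")")
  }
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > tol) stop("LD correlation diagonal must be 1")
  if (any(r < -1 - tol | r > 1 + tol)) stop("LD correlations outside [-1, 1]")
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r = r),
            class = "ld_reference")
}

#' Load an LD reference panel
#'
#' Two on-disk layouts are supported. A `correlation` file is a square matrix
#' with a SNP-id header row and first column. A `dosage` file is a
#' samples-by-SNPs matrix of allele dosages in `[0, 2]` with a SNP-id header;
#' the pairwise Pearson correlation of its columns becomes the reference.
#' Dosage columns with zero variance carry no LD information and are excluded
#' with a warning.
#'
#' @param path Tab-separated file.
#' @param kind `"correlation"` or `"dosage"`.
#' @return An `ld_reference` object.
#' @export
load_ld_reference <- function(path, kind = c("correlation", "dosage")) {
  kind <- match.arg(kind)
  if (kind == "correlation") {
    m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE, comment.char = "#")
    m <- as.matrix(m)
    return(ld_reference(m, snp_ids = rownames(m)))
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, comment.char = "#")
  d <- as.matrix(d)
  if (any(d < 0 | d > 2, na.rm = TRUE)) {
    stop("dosage entries must lie in [0, 2]")
  }
  v <- apply(d, 2, stats::var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " zero-variance SNP(s) from the LD panel: ",
            paste(colnames(d)[v == 0], collapse = ", "))
    d <- d[, v > 0, drop = FALSE]
  }
  ld_reference(stats::cor(d), snp_ids = colnames(d))
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Allele-harmonize one probe's cis window
#'
#' Restricts the eQTL rows of one probe to its cis window (`tss - window` to
#' `tss + window`, closed on both ends), intersects the surviving SNPs with
#' the GWAS table and the LD panel, and aligns all effect estimates to the
#' eQTL effect allele. A GWAS row whose alleles match the eQTL alleles swapped
#' (directly or on the opposite strand) has its beta negated and its frequency
#' complemented; allele-incompatible SNPs are dropped with a warning.
#'
#' Strand-ambiguous SNPs (A/T and C/G) cannot be aligned from alleles alone
#' and are dropped by default. With `eaf_resolve = TRUE` they are kept when
#' both studies report an informative allele frequency (`|freq - 0.5| >
#' eaf_margin` in both) and the frequencies identify the shared allele;
#' otherwise they are still dropped.
#'
#' SNP order in the result is ascending base-pair position, ties broken by
#' SNP id, so harmonization output is deterministic.
#'
#' @param probe A list or one-row `data.frame` with `probe_id`, `chr`, `tss`.
#' @param eqtl eQTL rows (for any set of probes; rows of other probes are
#'   ignored if a `probe_id` column is present).
#' @param gwas GWAS summary `data.frame`.
#' @param ld An `ld_reference`.
#' @param window Cis-window half-width in bp; default 1 Mb on each side of
#'   the transcription start site.
#' @param drop_ambiguous Drop strand-ambiguous SNPs (default `TRUE`).
#' @param eaf_resolve Resolve ambiguous SNPs by allele frequency instead of
#'   dropping them.
#' @param eaf_margin Minimum `|freq - 0.5|` in both studies for frequency
#'   resolution to be trusted.
#' @return An object of class `harmonized_locus`: parallel vectors `snp`,
#'   `bp`, `a1`, `a2`, `eaf`, `b_zx`, `se_zx`, `p_zx`, `b_zy`, `se_zy`,
#'   `p_zy` and the matching LD submatrix `ld_r`. Zero-length vectors (an
#'   empty locus) are a valid result, not an error.
#' @export
harmonize_locus <- function(probe, eqtl, gwas, ld, window = 1e6,
                            drop_ambiguous = TRUE, eaf_resolve = FALSE,
                            eaf_margin = 0.08) {
  probe <- as.list(probe)
  stopifnot(!is.null(probe$probe_id), !is.null(probe$chr), !is.null(probe$tss))
  probe$chr <- as.character(probe$chr)

  e <- eqtl
  if (!is.null(e$probe_id)) e <- e[e$probe_id == probe$probe_id, , drop = FALSE]
  on_chr <- e$chr == probe$chr
  if (nrow(e) > 0L && !any(on_chr)) {
    warning("probe ", probe$probe_id, ": no eQTL SNP on chromosome ",
            probe$chr, "; empty locus")
  }
  e <- e[on_chr & abs(e$bp - probe$tss) <= window, , drop = FALSE]

  ids <- intersect(intersect(e$snp, gwas$snp), ld$snp_ids)
  e <- e[match(ids, e$snp), , drop = FALSE]
  g <- gwas[match(ids, gwas$snp), , drop = FALSE]

  empty <- function() {
    structure(list(probe = probe, snp = character(0), bp = numeric(0),
                   a1 = character(0), a2 = character(0), eaf = numeric(0),
                   b_zx = numeric(0), se_zx = numeric(0), p_zx = numeric(0),
                   b_zy = numeric(0), se_zy = numeric(0), p_zy = numeric(0),
                   ld_r = matrix(numeric(0), 0, 0)),
              class = "harmonized_locus")
  }
  if (length(ids) == 0L) return(empty())

  ambiguous <- .complement[e$a1] == e$a2
  same  <- g$a1 == e$a1 & g$a2 == e$a2
  swap  <- g$a1 == e$a2 & g$a2 == e$a1
  csame <- .complement[g$a1] == e$a1 & .complement[g$a2] == e$a2
  cswap <- .complement[g$a1] == e$a2 & .complement[g$a2] == e$a1

  flip <- rep(FALSE, length(ids))
  keep <- rep(TRUE, length(ids))
  flip[swap | (cswap & !ambiguous)] <- TRUE
  incompatible <- !(same | swap | csame | cswap)
  if (any(incompatible)) {
    warning("probe ", probe$probe_id, ": dropping ", sum(incompatible),
            " allele-incompatible SNP(s)")
    keep[incompatible] <- FALSE
  }
  if (any(ambiguous & keep)) {
    if (eaf_resolve) {
      fa <- e$freq; fg <- g$freq
      informative <- !is.na(fa) & !is.na(fg) &
        abs(fa - 0.5) > eaf_margin & abs(fg - 0.5) > eaf_margin
      amb <- ambiguous & keep
      agree <- (fg > 0.5) == (fa > 0.5)
      # frequencies on opposite sides of 0.5 mean the GWAS effect allele is
      # the complement of the eQTL one: flip
      flip[amb & informative & !agree] <- TRUE
      flip[amb & informative & agree] <- FALSE
      keep[amb & !informative] <- FALSE
    } else if (drop_ambiguous) {
      keep[ambiguous] <- FALSE
    }
  }

  e <- e[keep, , drop = FALSE]; g <- g[keep, , drop = FALSE]
  flip <- flip[keep]
  if (nrow(e) == 0L) return(empty())

  b_zy <- ifelse(flip, -g$beta, g$beta)
  ord <- order(e$bp, e$snp)
  snp <- e$snp[ord]
  r <- ld$r[snp, snp, drop = FALSE]

  structure(list(probe = probe,
                 snp = snp,
                 bp = e$bp[ord],
                 a1 = e$a1[ord], a2 = e$a2[ord],
                 eaf = e$freq[ord],
                 b_zx = e$beta[ord], se_zx = e$se[ord], p_zx = e$p[ord],
                 b_zy = b_zy[ord], se_zy = g$se[ord], p_zy = g$p[ord],
                 ld_r = r),
            class = "harmonized_locus")
}

#' @export
print.harmonized_locus <- function(x, ...) {
  cat("Harmonized locus for probe ", x$probe$probe_id,
      " (chr", x$probe$chr, ":", format(x$probe$tss, big.mark = ","),
      ")\n  ", length(x$snp), " SNP(s) shared by eQTL, GWAS and LD panel\n",
      sep = "")
  invisible(x)
}

#' Number of SNPs in a harmonized locus
#' @param locus A `harmonized_locus`.
#' @export
locus_size <- function(locus) length(locus$snp)

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a results (or any numeric) table as lossless TSV
#'
#' Numeric columns are written with 17 significant digits so that
#' write-then-read round-trips are exact at double precision.
#'
#' @param x An `smr` fit or a `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (inherits(x, "smr")) x <- x$results
  out <- x
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- .fmt_num(out[[j]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#' @param path Path to the TSV file.
#' @return `data.frame`.
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
}
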