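# Shared helpers: independent oracles and small in-code fixtures.

# literal step-up BH, written directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# literal two-pass median-of-ratios, straight from the definition
size_factors_oracle <- function(counts) {
  geomean <- apply(counts, 1, function(x) exp(mean(log(x))))
  ok <- is.finite(geomean) & geomean > 0
  apply(counts, 2, function(s) median(s[ok] / geomean[ok]))
}

# construct a harmonized locus directly from arrays (bypasses file I/O)
make_locus <- function(b_zx, se_zx, b_zy, se_zy, ld_r = NULL,
                       bp = NULL, snp = NULL, probe_id = "probe-1",
                       chr = "1", tss = 2e6) {
  m <- length(b_zx)
  if (is.null(ld_r)) ld_r <- diag(m)
  if (is.null(bp)) bp <- tss + seq_len(m) * 1000
  if (is.null(snp)) snp <- sprintf("rs%04d", seq_len(m))
  dimnames(ld_r) <- list(snp, snp)
  structure(list(probe = list(probe_id = probe_id, chr = chr, tss = tss),
                 snp = snp, bp = bp,
                 a1 = rep("A", m), a2 = rep("G", m),
                 eaf = rep(0.3, m),
                 b_zx = b_zx, se_zx = se_zx,
                 p_zx = 2 * pnorm(-abs(b_zx / se_zx)),
                 b_zy = b_zy, se_zy = se_zy,
                 p_zy = 2 * pnorm(-abs(b_zy / se_zy)),
                 ld_r = ld_r),
            class = "harmonized_locus")
}

# write a summary-statistic data.frame to a temp TSV and return the path
write_sumstats_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

gwas_row <- function(snp = "rs1", chr = "1", bp = 1e6, a1 = "A", a2 = "G",
                     freq = 0.3, beta = 0.1, se = 0.02,
                     p = 2 * pnorm(-abs(beta / se)), n = 10000) {
  data.frame(snp = snp, chr = chr, bp = bp, a1 = a1, a2 = a2, freq = freq,
             beta = beta, se = se, p = p, n = n, stringsAsFactors = FALSE)
}

eqtl_row <- function(..., probe_id = "hsa-miR-test-1", probe_chr = "1",
                     probe_tss = 1e6) {
  cbind(gwas_row(...),
        data.frame(probe_id = probe_id, probe_chr = probe_chr,
                   probe_tss = probe_tss, stringsAsFactors = FALSE))
}

# a small fully-specified analysis: `n_probes` probes over a shared panel of
# 5 SNPs, of which probes 1..n_strong have a genome-wide instrument
make_toy_analysis <- function(n_probes = 10, n_strong = 4) {
  snp <- sprintf("rs%d", 1:5)
  bp <- 2e6 + (1:5) * 1000
  gwas <- do.call(rbind, lapply(1:5, function(j) {
    gwas_row(snp = snp[j], bp = bp[j], beta = 0.05, se = 0.01)
  }))
  eqtl <- do.call(rbind, lapply(seq_len(n_probes), function(k) {
    strong <- k <= n_strong
    do.call(rbind, lapply(1:5, function(j) {
      beta <- if (strong && j == 1) 0.5 else 0.02
      se <- if (strong && j == 1) 0.05 else 0.05
      eqtl_row(snp = snp[j], bp = bp[j], beta = beta, se = se,
               probe_id = sprintf("hsa-miR-toy-%02d", k),
               probe_tss = 2e6 + 3000)
    }))
  }))
  ld <- ld_reference(diag(5), snp_ids = snp)
  probes <- probes_from_eqtl(eqtl)
  list(gwas = gwas, eqtl = eqtl, ld = ld, probes = probes)
}
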