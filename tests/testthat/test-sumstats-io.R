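test_that("well-formed tables are read fully and invalid rows are rejected with reasons", {
  df <- rbind(gwas_row(snp = "rs1", bp = 100),
              gwas_row(snp = "rs2", bp = 200),
              gwas_row(snp = "rs3", bp = 300))
  path <- write_sumstats_tsv(df)
  out <- read_summary_table(path, "gwas")
  expect_equal(nrow(out), 3)
  expect_equal(out$snp, c("rs1", "rs2", "rs3"))
  expect_equal(nrow(attr(out, "rejections")), 0)

  # se = 0 invalidates a single row, not the file
  df$se[2] <- 0
  out <- suppressMessages(read_summary_table(write_sumstats_tsv(df), "gwas"))
  expect_equal(nrow(out), 2)
  rej <- attr(out, "rejections")
  expect_equal(rej$line, 3L)  # header is line 1
  expect_match(rej$reason, "se")

  # non-numeric beta carries its line number
  df2 <- rbind(gwas_row(snp = "rs1"), gwas_row(snp = "rs2"))
  df2$beta <- as.character(df2$beta)
  df2$beta[2] <- "xx"
  out2 <- suppressMessages(read_summary_table(write_sumstats_tsv(df2), "gwas"))
  expect_equal(nrow(out2), 1)
  expect_equal(attr(out2, "rejections")$reason, "non-numeric beta")

  # indels are not SNPs
  df3 <- gwas_row(a1 = "AT", a2 = "A")
  out3 <- suppressMessages(read_summary_table(write_sumstats_tsv(df3), "gwas"))
  expect_equal(nrow(out3), 0)
})

test_that("a missing mandatory column is a format error naming the column", {
  df <- gwas_row()
  df$se <- NULL
  expect_error(read_summary_table(write_sumstats_tsv(df), "gwas"), "se")
})

test_that("eQTL tables carry probe columns and group by probe", {
  df <- rbind(eqtl_row(snp = "rs1", probe_id = "hsa-miR-a"),
              eqtl_row(snp = "rs2", probe_id = "hsa-miR-a"),
              eqtl_row(snp = "rs1", probe_id = "hsa-miR-b"))
  out <- read_summary_table(write_sumstats_tsv(df), "eqtl")
  expect_equal(nrow(out), 3)
  probes <- probes_from_eqtl(out)
  expect_equal(sort(probes$probe_id), c("hsa-miR-a", "hsa-miR-b"))
  by_probe <- split(out, out$probe_id)
  expect_length(by_probe, 2)
  expect_equal(nrow(by_probe[["hsa-miR-a"]]), 2)
})

test_that("inconsistent reported p versus beta/se triggers a warning", {
  df <- gwas_row(beta = 0.5, se = 0.05, p = 0.5)  # z = 10 but p says ~0
  expect_warning(read_summary_table(write_sumstats_tsv(df), "gwas"),
                 "inconsistent")
})

test_that("dosage-derived LD matches direct column correlation", {
  set.seed(11)
  d <- matrix(sample(0:2, 200, replace = TRUE), 50, 4)
  d[, 2] <- d[, 1]
  colnames(d) <- sprintf("rs%d", 1:4)
  path <- tempfile(fileext = ".tsv")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- load_ld_reference(path, "dosage")
  expect_equal(ld$r["rs1", "rs2"], 1.0)
  expect_equal(ld$r, cor(d), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("independent dosage columns give near-zero LD at large n", {
  set.seed(12)
  n <- 10000
  d <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  colnames(d) <- sprintf("rs%d", 1:5)
  path <- tempfile(fileext = ".tsv")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- load_ld_reference(path, "dosage")
  off <- ld$r[upper.tri(ld$r)]
  expect_true(all(abs(off) < 0.05))
})

test_that("correlation input is returned verbatim after symmetry checks", {
  r <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(snp = rownames(r), r, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  ld <- load_ld_reference(path, "correlation")
  expect_equal(ld$r, r)

  bad <- r; bad[1, 2] <- 0.5
  expect_error(ld_reference(bad), "symmetric")
})

test_that("zero-variance dosage SNPs are excluded with a warning", {
  d <- cbind(rs1 = c(0, 1, 2, 1, 0), rs2 = rep(2, 5), rs3 = c(2, 1, 0, 1, 2))
  path <- tempfile(fileext = ".tsv")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(ld <- load_ld_reference(path, "dosage"), "zero-variance")
  expect_equal(ld$snp_ids, c("rs1", "rs3"))
})

test_that("allele-swapped GWAS rows are sign-flipped onto the eQTL effect allele", {
  probe <- list(probe_id = "hsa-miR-test-1", chr = "1", tss = 1e6)
  eqtl <- eqtl_row(a1 = "G", a2 = "A", beta = 0.20, se = 0.02)
  gwas <- gwas_row(a1 = "A", a2 = "G", beta = 0.10, se = 0.02, freq = 0.7)
  ld <- ld_reference(matrix(1, 1, 1), snp_ids = "rs1")
  loc <- harmonize_locus(probe, eqtl, gwas, ld)
  expect_equal(loc$b_zx, 0.20)
  expect_equal(loc$b_zy, -0.10)
  # opposite-strand swapped representation resolves the same way
  gwas2 <- gwas_row(a1 = "T", a2 = "C", beta = 0.10, se = 0.02)
  loc2 <- harmonize_locus(probe, eqtl, gwas2, ld)
  expect_equal(loc2$b_zy, -0.10)
})

test_that("the cis window is closed at +/- 1 Mb and off-window SNPs drop", {
  probe <- list(probe_id = "hsa-miR-test-1", chr = "1", tss = 2e6)
  eqtl <- rbind(eqtl_row(snp = "rs_in", bp = 2e6 + 1e6, probe_tss = 2e6),
                eqtl_row(snp = "rs_out", bp = 2e6 + 1e6 + 1, probe_tss = 2e6))
  gwas <- rbind(gwas_row(snp = "rs_in", bp = 2e6 + 1e6),
                gwas_row(snp = "rs_out", bp = 2e6 + 1e6 + 1))
  ld <- ld_reference(diag(2), snp_ids = c("rs_in", "rs_out"))
  loc <- harmonize_locus(probe, eqtl, gwas, ld)
  expect_equal(loc$snp, "rs_in")
})

test_that("strand-ambiguous SNPs are dropped by default but can be eaf-resolved", {
  probe <- list(probe_id = "hsa-miR-test-1", chr = "1", tss = 1e6)
  eqtl <- eqtl_row(a1 = "A", a2 = "T", freq = 0.1)
  gwas <- gwas_row(a1 = "A", a2 = "T", freq = 0.1)
  ld <- ld_reference(matrix(1, 1, 1), snp_ids = "rs1")
  expect_equal(locus_size(harmonize_locus(probe, eqtl, gwas, ld)), 0)

  loc <- harmonize_locus(probe, eqtl, gwas, ld, eaf_resolve = TRUE)
  expect_equal(locus_size(loc), 1)
  expect_equal(loc$b_zy, gwas$beta)
  # frequencies on opposite sides of 0.5: the GWAS allele is the complement
  gwas_flip <- gwas_row(a1 = "A", a2 = "T", freq = 0.9)
  loc2 <- harmonize_locus(probe, eqtl, gwas_flip, ld, eaf_resolve = TRUE)
  expect_equal(loc2$b_zy, -gwas_flip$beta)
  # uninformative frequency: still dropped
  gwas_mid <- gwas_row(a1 = "A", a2 = "T", freq = 0.52)
  expect_equal(locus_size(harmonize_locus(probe, eqtl, gwas_mid, ld,
                                          eaf_resolve = TRUE)), 0)
})

test_that("allele-incompatible SNPs drop with a warning; wrong chromosome empties the locus", {
  probe <- list(probe_id = "hsa-miR-test-1", chr = "1", tss = 1e6)
  eqtl <- eqtl_row(a1 = "A", a2 = "G")
  gwas <- gwas_row(a1 = "A", a2 = "C")
  ld <- ld_reference(matrix(1, 1, 1), snp_ids = "rs1")
  expect_warning(loc <- harmonize_locus(probe, eqtl, gwas, ld),
                 "incompatible")
  expect_equal(locus_size(loc), 0)

  probe7 <- list(probe_id = "hsa-miR-test-1", chr = "7", tss = 1e6)
  expect_warning(loc7 <- harmonize_locus(probe7, eqtl,
                                         gwas_row(a1 = "A", a2 = "G"), ld),
                 "chromosome")
  expect_equal(locus_size(loc7), 0)
})

test_that("harmonization is idempotent and invariant to input allele orientation", {
  set.seed(21)
  m <- 6
  snp <- sprintf("rs%d", 1:m)
  bp <- 1e6 + (1:m) * 500
  eqtl <- do.call(rbind, lapply(1:m, function(j) {
    eqtl_row(snp = snp[j], bp = bp[j], a1 = "A", a2 = "G",
             beta = rnorm(1, 0, 0.2), se = runif(1, 0.01, 0.05))
  }))
  gwas <- do.call(rbind, lapply(1:m, function(j) {
    gwas_row(snp = snp[j], bp = bp[j], a1 = "A", a2 = "G",
             beta = rnorm(1, 0, 0.05), se = runif(1, 0.005, 0.02))
  }))
  r <- outer(1:m, 1:m, function(i, j) 0.7^abs(i - j))
  ld <- ld_reference(r, snp_ids = snp)
  probe <- list(probe_id = "hsa-miR-test-1", chr = "1", tss = 1e6)

  loc <- harmonize_locus(probe, eqtl, gwas, ld)
  # feed the aligned arrays back through as input tables: nothing may change
  gwas_aligned <- gwas
  gwas_aligned$beta <- loc$b_zy[match(gwas$snp, loc$snp)]
  loc2 <- harmonize_locus(probe, eqtl, gwas_aligned, ld)
  expect_identical(loc2$b_zy, loc$b_zy)
  expect_identical(loc2$b_zx, loc$b_zx)
  expect_identical(loc2$snp, loc$snp)

  # flipping effect/other and negating beta in the GWAS input is a no-op
  gwas_flipped <- gwas
  gwas_flipped$a1 <- gwas$a2
  gwas_flipped$a2 <- gwas$a1
  gwas_flipped$beta <- -gwas$beta
  gwas_flipped$freq <- 1 - gwas$freq
  loc3 <- harmonize_locus(probe, eqtl, gwas_flipped, ld)
  expect_equal(loc3$b_zy, loc$b_zy, tolerance = 1e-15)
  expect_identical(loc3$snp, loc$snp)
})

test_that("merged eQTL tables de-duplicate shared probe/SNP pairs", {
  colon <- rbind(eqtl_row(snp = "rs1", p = 1e-10, beta = 0.3),
                 eqtl_row(snp = "rs2", p = 1e-4, beta = 0.1))
  rectal <- rbind(eqtl_row(snp = "rs1", p = 1e-6, beta = 0.2),
                  eqtl_row(snp = "rs3", p = 1e-5, beta = 0.2))
  merged <- merge_eqtl_tables(colon, rectal)
  expect_equal(nrow(merged), 3)
  # min_p keeps the colon record for the shared SNP
  expect_equal(merged$beta[merged$snp == "rs1"], 0.3)

  first <- merge_eqtl_tables(rectal, colon, dedup = "first")
  expect_equal(first$beta[first$snp == "rs1"], 0.2)
})

test_that("results tables round-trip through write/read exactly", {
  df <- data.frame(cancer = "toy", probe = "hsa-miR-x",
                   b_SMR = c(-0.0517123456789, 1 / 3),
                   p_SMR = c(6.02e-43, 0.123456789123456789),
                   n = c(3L, 4L), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_results(df, path)
  back <- read_results(path)
  expect_identical(back$b_SMR, df$b_SMR)
  expect_identical(back$p_SMR, df$p_SMR)
  expect_identical(back$cancer, df$cancer)
})
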