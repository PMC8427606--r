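test_that("HEIDI SNP selection applies the LD window, the p ceiling and the cap", {
  m <- 31
  r <- outer(1:m, 1:m, function(i, j) 0.6^abs(i - j))
  top <- 16L
  # strong eQTL signal everywhere
  loc <- make_locus(b_zx = rep(0.3, m), se_zx = rep(0.02, m),
                    b_zy = rep(0.05, m), se_zy = rep(0.01, m), ld_r = r)
  idx <- select_heidi_snps(loc, top)
  expect_true(top %in% idx)
  r2 <- r[, top]^2
  expect_true(all(r2[setdiff(idx, top)] >= 0.05 & r2[setdiff(idx, top)] <= 0.9))

  # r^2 = 0.95 to the top SNP is excluded
  r2mat <- diag(3); r2mat[1, 2] <- r2mat[2, 1] <- sqrt(0.95)
  r2mat[2, 3] <- r2mat[3, 2] <- sqrt(0.5)
  r2mat[1, 3] <- r2mat[3, 1] <- sqrt(0.4)
  loc2 <- make_locus(b_zx = rep(0.3, 3), se_zx = rep(0.02, 3),
                     b_zy = rep(0.05, 3), se_zy = rep(0.01, 3), ld_r = r2mat)
  expect_false(1L %in% select_heidi_snps(loc2, 2L))
  expect_true(3L %in% select_heidi_snps(loc2, 2L))

  # 30 eligible non-top SNPs: exactly 20 SNPs total, the smallest eQTL p
  r3 <- matrix(0.5, m, m); diag(r3) <- 1
  se_zx <- seq(0.010, 0.040, length.out = m)  # increasing p with index
  loc3 <- make_locus(b_zx = rep(0.3, m), se_zx = se_zx,
                     b_zy = rep(0.05, m), se_zy = rep(0.01, m), ld_r = r3)
  idx3 <- select_heidi_snps(loc3, 1L)
  expect_length(idx3, 20)
  expect_equal(idx3, 1:20)  # smallest se = smallest p
})

test_that("loci with fewer than three usable SNPs get status too_few_snps", {
  r <- matrix(c(1, 0.5, 0.5, 1), 2)
  loc <- make_locus(b_zx = rep(0.3, 2), se_zx = rep(0.02, 2),
                    b_zy = rep(0.05, 2), se_zy = rep(0.01, 2), ld_r = r)
  h <- run_heidi(loc, 1L)
  expect_equal(h$status, "too_few_snps")
  expect_true(is.na(h$p_heidi))
})

test_that("the delta-method covariance reduces correctly and matches Monte Carlo", {
  # independence: zero LD gives zero covariance between ratios
  loc <- make_locus(b_zx = c(0.4, 0.3), se_zx = c(0.02, 0.02),
                    b_zy = c(0.05, 0.04), se_zy = c(0.01, 0.01),
                    ld_r = diag(2))
  v <- bxy_covariance(loc)
  expect_equal(v[1, 2], 0)
  # the diagonal is the single-SNP delta-method variance
  est <- estimate_bxy(loc$b_zy, loc$se_zy, loc$b_zx, loc$se_zx)
  expect_equal(diag(v), est$se_xy^2, tolerance = 1e-12)

  # 5-SNP locus against a 1e6-draw Monte-Carlo covariance with LD-correlated
  # sampling noise in both studies
  set.seed(41)
  m <- 5
  r <- outer(1:m, 1:m, function(i, j) 0.65^abs(i - j))
  b_zx <- c(0.50, 0.42, 0.35, 0.30, 0.28)
  se_zx <- rep(0.010, m)
  b_zy <- c(0.050, 0.043, 0.036, 0.031, 0.028)
  se_zy <- rep(0.008, m)
  loc5 <- make_locus(b_zx, se_zx, b_zy, se_zy, ld_r = r)
  v5 <- bxy_covariance(loc5)

  n_draw <- 1e6
  cl <- chol(r)
  draw <- function(mu, se) {
    sweep(matrix(rnorm(n_draw * m), n_draw, m) %*% cl, 2, se, "*") +
      matrix(mu, n_draw, m, byrow = TRUE)
  }
  bzy_s <- draw(b_zy, se_zy)
  bzx_s <- draw(b_zx, se_zx)
  v_mc <- cov(bzy_s / bzx_s)
  expect_true(all(abs(v_mc - v5) <= 0.03 * pmax(abs(v5), max(abs(v5)) * 0.05)))
})

test_that("perfect homogeneity gives t = 0 and one contrast gives t = z^2", {
  r <- outer(1:4, 1:4, function(i, j) 0.5^abs(i - j))
  # all per-SNP ratios identical: b_zy proportional to b_zx
  b_zx <- c(0.5, 0.4, 0.35, 0.3)
  loc <- make_locus(b_zx, rep(0.02, 4), b_zy = 0.2 * b_zx,
                    se_zy = rep(0.01, 4), ld_r = r)
  st <- heidi_statistic(loc, 1:4, top = 1L)
  expect_equal(st$t_heidi, 0, tolerance = 1e-20)
  expect_true(all(abs(st$z_d) < 1e-12))

  loc2 <- make_locus(b_zx = c(0.5, 0.3), se_zx = rep(0.02, 2),
                     b_zy = c(0.10, 0.09), se_zy = rep(0.01, 2),
                     ld_r = matrix(c(1, 0.4, 0.4, 1), 2))
  st2 <- heidi_statistic(loc2, 1:2, top = 1L)
  expect_length(st2$z_d, 1)
  expect_equal(st2$t_heidi, st2$z_d^2)
})

test_that("the mixture p-value is exact for identity correlation and the {2,0} pair", {
  # m independent contrasts reduce to chi-square(m)
  for (m in c(3, 7)) {
    t95 <- qchisq(0.95, df = m)
    expect_equal(heidi_pvalue(t95, diag(m)), 0.05, tolerance = 1e-3 / 0.05)
  }
  expect_equal(heidi_pvalue(0, matrix(1, 1, 1)), 1)

  # duplicated contrast: eigenvalues {2, 0}; p equals the one-contrast p at t/2
  dup <- matrix(1, 2, 2)
  for (t in c(1, 3, 6)) {
    expect_equal(heidi_pvalue(t, dup),
                 pchisq(t / 2, df = 1, lower.tail = FALSE), tolerance = 1e-10)
  }

  # and against brute-force Monte Carlo of the lambda = {2, 0} mixture
  set.seed(42)
  q <- 2 * rnorm(1e6)^2
  for (t in c(qchisq(c(0.6, 0.9, 0.99), df = 1) * 2)) {
    p_mc <- mean(q > t)
    p_sat <- heidi_pvalue(t, dup)
    expect_equal(p_sat, p_mc, tolerance = 0.1)
  }
})

test_that("the Imhof inversion agrees with Satterthwaite in the moderate-p regime", {
  set.seed(43)
  for (k in c(3, 6)) {
    a <- matrix(rnorm(k * k), k)
    r <- cov2cor(crossprod(a) + diag(k))
    for (t in c(k / 2, k, 2 * k)) {
      p_s <- heidi_pvalue(t, r, method = "satterthwaite")
      p_i <- heidi_pvalue(t, r, method = "imhof")
      if (p_i > 1e-4) {
        expect_equal(p_s, p_i, tolerance = 0.15)
      }
    }
  }
  # for exact chi-square cases the two must agree tightly
  expect_equal(heidi_pvalue(7, diag(4), method = "imhof"),
               pchisq(7, df = 4, lower.tail = FALSE), tolerance = 1e-6)
})

test_that("t_heidi is invariant to the effect-allele orientation at non-top SNPs", {
  set.seed(44)
  m <- 6
  r <- outer(1:m, 1:m, function(i, j) 0.6^abs(i - j))
  b_zx <- runif(m, 0.2, 0.5)
  loc <- make_locus(b_zx, rep(0.015, m),
                    b_zy = 0.2 * b_zx + rnorm(m, 0, 0.01),
                    se_zy = rep(0.008, m), ld_r = r)
  st <- heidi_statistic(loc, 1:m, top = 3L)

  # flip alleles at SNP 5: negate b_zx, b_zy and the LD row/column
  loc_f <- loc
  loc_f$b_zx[5] <- -loc_f$b_zx[5]
  loc_f$b_zy[5] <- -loc_f$b_zy[5]
  loc_f$ld_r[5, ] <- -loc_f$ld_r[5, ]
  loc_f$ld_r[, 5] <- -loc_f$ld_r[, 5]
  st_f <- heidi_statistic(loc_f, 1:m, top = 3L)
  expect_equal(st_f$t_heidi, st$t_heidi, tolerance = 1e-12)
})

test_that("inflating GWAS standard errors can only increase the HEIDI p-value", {
  set.seed(45)
  m <- 8
  r <- outer(1:m, 1:m, function(i, j) 0.6^abs(i - j))
  for (rep in 1:20) {
    b_zx <- runif(m, 0.2, 0.5)
    loc <- make_locus(b_zx, rep(0.015, m),
                      b_zy = 0.2 * b_zx + rnorm(m, 0, 0.02),
                      se_zy = runif(m, 0.005, 0.02), ld_r = r)
    p <- sapply(c(1, 2, 5), function(f) {
      l <- loc
      l$se_zy <- f * l$se_zy
      st <- heidi_statistic(l, 1:m, top = 1L)
      heidi_pvalue(st$t_heidi, st$r_zd)
    })
    expect_true(all(diff(p) >= -1e-12))
  }
})

test_that("run_heidi composes the stages and reports the SNP count used", {
  set.seed(46)
  scen <- simulate_scenario(sim_config(model = "pleiotropy", seed = 461,
                                       n_gwas = 8000, n_eqtl = 8000,
                                       n_ld = 2000, m_snps = 16))
  loc <- harmonize_locus(scen$probes[1, ], scen$eqtl, scen$gwas, scen$ld)
  top <- select_top_instrument(loc)
  h <- run_heidi(loc, top)
  expect_equal(h$status, "tested")
  expect_gte(h$n_snps_used, 3)
  expect_true(h$p_heidi > 0 && h$p_heidi <= 1)
})
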