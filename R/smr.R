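# Summary-data Mendelian randomization: instrument selection, the SMR
# ratio test, the HEIDI heterogeneity (pleiotropy) test, Benjamini-
# Hochberg FDR, and the per-layer driver.
#
# The causal effect of a molecular exposure x on an outcome y, using one
# cis-SNP z as instrument, is estimated as the ratio
#     b_xy = b_zy / b_zx
# with the chi-square(1) statistic
#     T_SMR = z_zx^2 z_zy^2 / (z_zx^2 + z_zy^2)
# and delta-method variance
#     var(b_xy) = se_zy^2 / b_zx^2 + b_zy^2 se_zx^2 / b_zx^4 .
# HEIDI asks whether b_xy is constant across SNPs in LD with the top
# instrument: under a single shared causal variant it is; under linkage or
# pleiotropy it is not.

#' Select the top cis instrument SNP for a probe
#'
#' Returns the SNP inside the cis-window with the smallest exposure
#' p-value among those below `p_threshold` (genome-wide significance by
#' default). Ties on p are broken by distance to the probe midpoint, then
#' lexicographically by SNP id, so selection is deterministic.
#'
#' @param exposure an `assoc_dataset` of exposure summary statistics.
#' @param probe one-row data.frame/list with `chr`, `start`, `end`.
#' @param window numeric `c(start, end)` from [cis_window()].
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @return the selected SNP id, or `NULL` when no SNP qualifies.
#' @export
select_instrument <- function(exposure, probe, window, p_threshold = 5e-8) {
  rec <- exposure$records
  inw <- rec$chr == probe$chr & rec$pos >= window[1] & rec$pos <= window[2] &
    rec$p < p_threshold
  if (!any(inw)) return(NULL)
  cand <- rec[inw, , drop = FALSE]
  mid <- (probe$start + probe$end) / 2
  ord <- order(cand$p, abs(cand$pos - mid), cand$snp)
  cand$snp[ord[1]]
}

ratio_se <- function(b_zx, se_zx, b_zy, se_zy) {
  sqrt(se_zy^2 / b_zx^2 + b_zy^2 * se_zx^2 / b_zx^4)
}

#' SMR ratio test at the top instrument
#'
#' @param b_zx,se_zx instrument -> exposure effect and SE.
#' @param b_zy,se_zy instrument -> outcome effect and SE (harmonized to
#'   the same effect allele).
#' @param binary_outcome if `TRUE`, also report the odds ratio
#'   `exp(b_xy)` with a 95% confidence interval.
#' @return list with `b_xy`, `se_xy`, `t_smr`, `p_smr` and (for binary
#'   outcomes) `or_xy`, `ci_low`, `ci_high`.
#' @export
smr_test <- function(b_zx, se_zx, b_zy, se_zy, binary_outcome = FALSE) {
  stopifnot(se_zx > 0, se_zy > 0)
  if (b_zx == 0) stop("undefined ratio: instrument has zero exposure effect")
  z_zx <- b_zx / se_zx
  z_zy <- b_zy / se_zy
  b_xy <- b_zy / b_zx
  se_xy <- ratio_se(b_zx, se_zx, b_zy, se_zy)
  t_smr <- if (z_zy == 0) 0 else (z_zx^2 * z_zy^2) / (z_zx^2 + z_zy^2)
  p_smr <- stats::pchisq(t_smr, df = 1, lower.tail = FALSE)
  out <- list(b_xy = b_xy, se_xy = se_xy, t_smr = t_smr, p_smr = p_smr)
  if (binary_outcome) {
    out$or_xy <- exp(b_xy)
    out$ci_low <- exp(b_xy - 1.96 * se_xy)
    out$ci_high <- exp(b_xy + 1.96 * se_xy)
  }
  out
}

#' HEIDI test for heterogeneity in dependent instruments
#'
#' Tests whether the SMR ratio is constant across cis-SNPs in LD with the
#' top instrument. Eligible SNPs have LD r-squared with the top SNP in
#' `[r2_min, r2_max]` and exposure |z| above `z_min` (the published tool's
#' p < 1.57e-3); at most `max_snps` are kept, by exposure significance.
#' For each eligible SNP i, d_i = b_xy(i) - b_xy(top); the joint
#' covariance of d follows from the delta method with cov(b_i, b_j) =
#' r_ij se_i se_j within each trait and independence across traits. The
#' statistic T = sum z_d^2 is a quadratic form in correlated normals; its
#' p-value uses Satterthwaite two-moment matching on the correlation
#' matrix of z_d (scaled chi-square, df = (sum lambda)^2 / sum lambda^2).
#'
#' @param exposure,outcome `assoc_dataset`s over the harmonized cis SNPs.
#' @param ld `ld_matrix` covering the same SNPs.
#' @param top_snp instrument SNP id.
#' @param r2_min,r2_max LD eligibility bounds (defaults 0.05 and 0.9).
#' @param z_min exposure |z| eligibility bound (default 3.16).
#' @param max_snps maximum number of test SNPs (default 20).
#' @return list with `p_heidi` (`NA` when not evaluable) and
#'   `n_heidi_snps`.
#' @export
heidi_test <- function(exposure, outcome, ld, top_snp,
                       r2_min = 0.05, r2_max = 0.9, z_min = 3.16,
                       max_snps = 20) {
  ex <- exposure$records
  ou <- outcome$records
  stopifnot(identical(ex$snp, ou$snp))
  if (!all(ex$snp %in% ld$snp_ids)) stop("LD matrix does not cover all SNPs")
  idx <- match(ex$snp, ld$snp_ids)
  r <- ld$r[idx, idx, drop = FALSE]
  ti <- match(top_snp, ex$snp)
  if (is.na(ti)) stop("top SNP not present in harmonized data")

  r2 <- r[, ti]^2
  z_zx <- ex$beta / ex$se
  elig <- which(seq_along(r2) != ti & r2 >= r2_min & r2 <= r2_max &
                  abs(z_zx) > z_min)
  if (!length(elig)) {
    return(list(p_heidi = NA_real_, n_heidi_snps = 0L))
  }
  if (length(elig) > max_snps) {
    elig <- elig[order(-abs(z_zx[elig]))][seq_len(max_snps)]
  }

  sel <- c(ti, elig)           # position 1 = top
  bx <- ex$beta[sel]; sx <- ex$se[sel]
  by <- ou$beta[sel]; sy <- ou$se[sel]
  rs <- r[sel, sel, drop = FALSE]
  bxy <- by / bx
  d <- bxy[-1] - bxy[1]

  # cov(b_xy_i, b_xy_j) by the delta method, exposure and outcome cohorts
  # independent: (r_ij sy_i sy_j)/(bx_i bx_j) + bxy_i bxy_j (r_ij sx_i sx_j)/(bx_i bx_j)
  k <- length(bx)
  cov_xy <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cov_xy[i, j] <- rs[i, j] * sy[i] * sy[j] / (bx[i] * bx[j]) +
        bxy[i] * bxy[j] * rs[i, j] * sx[i] * sx[j] / (bx[i] * bx[j])
    }
  }
  vd <- matrix(0, k - 1, k - 1)
  for (i in 2:k) {
    for (j in 2:k) {
      vd[i - 1, j - 1] <- cov_xy[i, j] - cov_xy[i, 1] - cov_xy[j, 1] + cov_xy[1, 1]
    }
  }
  sd_d <- sqrt(pmax(diag(vd), 0))
  # a zero-variance contrast with d = 0 is a perfect-LD duplicate of the
  # top SNP: it carries no heterogeneity information and is dropped; with
  # d != 0 it is definitive heterogeneity
  zero_var <- sd_d < sqrt(.Machine$double.eps) * max(sd_d, 1)
  if (any(zero_var & abs(d) > 1e-12)) {
    return(list(p_heidi = 0, n_heidi_snps = length(elig)))
  }
  if (all(zero_var)) {
    return(list(p_heidi = 1, n_heidi_snps = length(elig)))
  }
  d <- d[!zero_var]; sd_d <- sd_d[!zero_var]
  vd <- vd[!zero_var, !zero_var, drop = FALSE]
  zd <- d / sd_d
  t_heidi <- sum(zd^2)
  corr_d <- vd / tcrossprod(sd_d)
  lambda <- eigen((corr_d + t(corr_d)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  s1 <- sum(lambda); s2 <- sum(lambda^2)
  if (s2 <= 0) return(list(p_heidi = 1, n_heidi_snps = length(elig)))
  scale <- s2 / s1
  df <- s1^2 / s2
  p <- stats::pchisq(t_heidi / scale, df = df, lower.tail = FALSE)
  list(p_heidi = p, n_heidi_snps = length(elig))
}

#' Benjamini-Hochberg step-up false-discovery-rate adjustment
#'
#' @param p vector of p-values in (0, 1\].
#' @return vector of q-values, same order as `p`, clipped at 1.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Run SMR + HEIDI for every probe of one omics layer against one outcome
#'
#' For each probe: build the cis-window (gene-body anchor, `flank` bp),
#' pick the top instrument, harmonize the pair over the window against
#' the LD reference, run the SMR test at the instrument and the HEIDI
#' test over the region. FDR is computed across the probes of this
#' (layer, outcome) family, and a probe is flagged `significant` iff
#' q < `q_threshold` and p_HEIDI > `heidi_threshold`; probes whose HEIDI
#' test is not evaluable are flagged separately rather than excluded.
#'
#' @param exposure an `assoc_dataset` of the molecular layer. A named list
#'   of datasets (one per probe id) is also accepted.
#' @param outcome disease `assoc_dataset`.
#' @param probes probe annotation data.frame (see [read_probes()]).
#' @param ld an `ld_matrix`, or a named list of `ld_matrix` keyed by probe
#'   id.
#' @param flank cis-window flank in bp (default 1 Mb).
#' @param p_instrument instrument threshold (default 5e-8).
#' @param q_threshold,heidi_threshold significance and pleiotropy cutoffs
#'   (defaults 0.05 and 0.05).
#' @param significance `"fdr"` (flag on q) or `"nominal"` (flag on p_smr;
#'   used for low-powered outcomes such as disease complications).
#' @return data.frame with one row per analysable probe: `probe_id,
#'   gene_id, top_snp, b_zx, se_zx, b_zy, se_zy, b_xy, se_xy, or_xy,
#'   ci_low, ci_high, p_smr, q_smr, p_heidi, n_heidi_snps, flag`.
#' @export
run_layer <- function(exposure, outcome, probes, ld, flank = 1e6,
                      p_instrument = 5e-8, q_threshold = 0.05,
                      heidi_threshold = 0.05, significance = c("fdr", "nominal")) {
  significance <- match.arg(significance)
  binary <- outcome$trait_type == "case_control"
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    probe <- probes[i, ]
    expo <- if (inherits(exposure, "assoc_dataset")) exposure else exposure[[probe$probe_id]]
    if (is.null(expo)) next
    ldr <- if (inherits(ld, "ld_matrix")) ld else ld[[probe$probe_id]]
    win <- cis_window(probe, flank = flank, anchor = "gene_body")
    top <- select_instrument(expo, probe, win, p_threshold = p_instrument)
    if (is.null(top)) {
      message(sprintf("run_layer: no instrument for probe %s (skipped)", probe$probe_id))
      next
    }
    rec <- expo$records
    keep <- rec$chr == probe$chr & rec$pos >= win[1] & rec$pos <= win[2]
    expo_win <- assoc_dataset(rec[keep, , drop = FALSE], expo$trait_id,
                              expo$trait_type, expo$n_cases, expo$n_controls)
    h <- harmonize(expo_win, outcome, ld = ldr)
    if (!top %in% h$exposure$records$snp) {
      message(sprintf("run_layer: instrument %s for probe %s lost in harmonization (skipped)",
                      top, probe$probe_id))
      next
    }
    ti <- match(top, h$exposure$records$snp)
    ex <- h$exposure$records[ti, ]
    ou <- h$outcome$records[ti, ]
    fit <- smr_test(ex$beta, ex$se, ou$beta, ou$se, binary_outcome = TRUE)
    hd <- heidi_test(h$exposure, h$outcome, h$ld, top)
    rows[[length(rows) + 1L]] <- data.frame(
      probe_id = probe$probe_id, gene_id = probe$gene_id, top_snp = top,
      b_zx = ex$beta, se_zx = ex$se, b_zy = ou$beta, se_zy = ou$se,
      b_xy = fit$b_xy, se_xy = fit$se_xy,
      or_xy = if (binary) fit$or_xy else NA_real_,
      ci_low = if (binary) fit$ci_low else NA_real_,
      ci_high = if (binary) fit$ci_high else NA_real_,
      p_smr = fit$p_smr, p_heidi = hd$p_heidi, n_heidi_snps = hd$n_heidi_snps,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(probe_id = character(0), gene_id = character(0),
                      top_snp = character(0), b_zx = numeric(0), se_zx = numeric(0),
                      b_zy = numeric(0), se_zy = numeric(0), b_xy = numeric(0),
                      se_xy = numeric(0), or_xy = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p_smr = numeric(0), q_smr = numeric(0),
                      p_heidi = numeric(0), n_heidi_snps = integer(0),
                      flag = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  # p_smr can underflow to exactly 0 for very strong instruments
  out$q_smr <- bh_fdr(pmax(out$p_smr, .Machine$double.xmin))
  passes <- if (significance == "fdr") out$q_smr < q_threshold else out$p_smr < q_threshold
  out$flag <- ifelse(!passes, "not_significant",
                     ifelse(is.na(out$p_heidi), "heidi_not_evaluable",
                            ifelse(out$p_heidi > heidi_threshold, "significant",
                                   "pleiotropic")))
  out[, c("probe_id", "gene_id", "top_snp", "b_zx", "se_zx", "b_zy", "se_zy",
          "b_xy", "se_xy", "or_xy", "ci_low", "ci_high", "p_smr", "q_smr",
          "p_heidi", "n_heidi_snps", "flag")]
}
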