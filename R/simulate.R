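# Summary-level simulator of cis-regions.
#
# Summary statistics are generated directly at the summary level: for
# standardized genotypes with correlation matrix R and joint (causal)
# effect vector b, the marginal GWAS z-scores satisfy
#     z_hat ~ MVN( sqrt(n_eff) * R b,  R )
# (the standard result for shared-sample marginal regressions). Observed
# betas are recovered as z_hat * se with per-SNP standard errors
#     quantitative:  se_j = 1 / (sqrt(n)   * s_j)
#     case-control:  se_j = 1 / (sqrt(n v) * s_j),  v = (ncase/n)(nctrl/n)
# where s_j = sqrt(2 maf_j (1 - maf_j)) converts from the standardized-
# genotype scale to the per-allele scale on which results are reported.
# This is orders of magnitude faster than individual-level simulation and
# is exactly what SMR/HEIDI/coloc consume.

#' Specify a synthetic cis-region
#'
#' @param m_snps number of SNPs (>= 1).
#' @param maf_range minor-allele-frequency range, a subset of (0, 0.5].
#' @param ld_model `"ar1"` (r_ij = rho^|i-j|) or `"block"` (block-diagonal
#'   with constant within-block correlation).
#' @param rho AR(1) decay parameter in \[0, 1).
#' @param block_sizes,within_r block sizes (must sum to `m_snps`) and the
#'   constant within-block correlation, for `ld_model = "block"`.
#' @param chrom,start_pos,spacing chromosome label, first SNP position and
#'   inter-SNP spacing in bp.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(m_snps, maf_range = c(0.05, 0.5),
                        ld_model = c("ar1", "block"), rho = 0.8,
                        block_sizes = NULL, within_r = 0.8,
                        chrom = "1", start_pos = 1e6, spacing = 2000) {
  ld_model <- match.arg(ld_model)
  stopifnot(m_snps >= 1, length(maf_range) == 2L,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2])
  if (ld_model == "ar1") {
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  } else {
    if (is.null(block_sizes) || sum(block_sizes) != m_snps) {
      stop("block sizes must sum to m_snps")
    }
    if (abs(within_r) >= 1) stop("within_r must lie in (-1, 1)")
  }
  structure(list(m_snps = as.integer(m_snps), maf_range = maf_range,
                 ld_model = ld_model, rho = rho, block_sizes = block_sizes,
                 within_r = within_r, chrom = as.character(chrom),
                 start_pos = start_pos, spacing = spacing),
            class = "region_spec")
}

#' Simulate a cis-region: SNP annotations, LD matrix and MAF vector
#'
#' Deterministic for a fixed `seed`. Under the AR(1) model the LD matrix
#' is exactly r_ij = rho^|i-j|; under the block model it is block-diagonal
#' with unit diagonal and `within_r` off-diagonal within blocks.
#'
#' @param spec a [region_spec()].
#' @param seed integer seed.
#' @return list with `snps` (data.frame: snp, chr, pos, ea, oa), `ld` (an
#'   `ld_matrix` carrying the true panel frequencies), `maf` (numeric).
#' @export
simulate_region <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "region_spec"))
  m <- spec$m_snps
  rng <- local_rng(seed)
  maf <- rng$runif(m, spec$maf_range[1], spec$maf_range[2])

  if (spec$ld_model == "ar1") {
    r <- spec$rho ^ abs(outer(seq_len(m), seq_len(m), "-"))
  } else {
    r <- matrix(0, m, m)
    off <- 0L
    for (b in spec$block_sizes) {
      idx <- off + seq_len(b)
      r[idx, idx] <- spec$within_r
      off <- off + b
    }
    diag(r) <- 1
  }

  # non-palindromic allele pairs so harmonization keeps every SNP
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  pick <- pairs[rng$sample_int(4L, m, replace = TRUE), , drop = FALSE]
  snps <- data.frame(
    snp = sprintf("rs%06d", seq_len(m)),
    chr = spec$chrom,
    pos = spec$start_pos + (seq_len(m) - 1L) * spec$spacing,
    ea = pick[, 1], oa = pick[, 2], stringsAsFactors = FALSE)

  list(snps = snps, ld = ld_matrix(r, snps$snp, ea = snps$ea, eaf = maf),
       maf = maf)
}

#' Specify a two-trait causal scenario over a region
#'
#' The five hypotheses of colocalization: H0 (neither trait associated),
#' H1/H2 (only trait 1 / trait 2), H3 (both, distinct causal variants),
#' H4 (both, one shared causal variant).
#'
#' @param hypothesis one of `"H0".."H4"`.
#' @param causal_index_1,causal_index_2 1-based SNP indices of the causal
#'   variants (ignored where the hypothesis has no causal variant; must be
#'   equal under H4 and distinct under H3).
#' @param var_explained_1,var_explained_2 fraction of trait variance (or
#'   liability variance for binary traits) explained by the causal SNP,
#'   in (0, 1).
#' @param n1,n2 sample sizes.
#' @param trait2_type `"quantitative"` or `"case_control"`.
#' @param n_cases,n_controls case/control split of trait 2 (must sum to
#'   `n2`) when `trait2_type = "case_control"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(hypothesis = c("H0", "H1", "H2", "H3", "H4"),
                          causal_index_1 = NULL, causal_index_2 = NULL,
                          var_explained_1 = 0.01, var_explained_2 = 0.01,
                          n1 = 10000, n2 = 10000,
                          trait2_type = c("quantitative", "case_control"),
                          n_cases = NULL, n_controls = NULL) {
  hypothesis <- match.arg(hypothesis)
  trait2_type <- match.arg(trait2_type)
  if (var_explained_1 >= 1 || var_explained_2 >= 1 ||
      var_explained_1 <= 0 || var_explained_2 <= 0) {
    stop("var_explained must lie in (0, 1)")
  }
  if (hypothesis %in% c("H1", "H3", "H4") && is.null(causal_index_1)) {
    stop(hypothesis, " requires causal_index_1")
  }
  if (hypothesis %in% c("H2", "H3") && is.null(causal_index_2)) {
    stop(hypothesis, " requires causal_index_2")
  }
  if (hypothesis == "H4") causal_index_2 <- causal_index_1
  if (hypothesis == "H3" && causal_index_1 == causal_index_2) {
    stop("H3 requires distinct causal indices")
  }
  if (trait2_type == "case_control") {
    if (is.null(n_cases) || is.null(n_controls)) {
      stop("case_control trait 2 requires n_cases and n_controls")
    }
    n2 <- n_cases + n_controls
  }
  structure(list(hypothesis = hypothesis,
                 causal_index_1 = causal_index_1, causal_index_2 = causal_index_2,
                 var_explained_1 = var_explained_1, var_explained_2 = var_explained_2,
                 n1 = n1, n2 = n2, trait2_type = trait2_type,
                 n_cases = n_cases, n_controls = n_controls),
            class = "scenario_spec")
}

# one marginal summary-statistic draw on the per-allele scale
draw_sumstats <- function(region, causal_index, var_explained, n,
                          rng, v = 1, chol_r = NULL) {
  m <- nrow(region$snps)
  r <- region$ld$r
  beta_joint <- numeric(m)
  if (!is.null(causal_index)) {
    stopifnot(causal_index >= 1, causal_index <= m)
    beta_joint[causal_index] <- sqrt(var_explained)
  }
  z_mean <- sqrt(n * v) * drop(r %*% beta_joint)
  if (is.null(chol_r)) chol_r <- chol_psd(r)
  z <- z_mean + drop(crossprod(chol_r, rng$rnorm(m)))
  s <- sqrt(2 * region$maf * (1 - region$maf))
  se <- 1 / (sqrt(n * v) * s)
  data.frame(snp = region$snps$snp, chr = region$snps$chr, pos = region$snps$pos,
             ea = region$snps$ea, oa = region$snps$oa, eaf = region$maf,
             beta = z * se, se = se, p = 2 * stats::pnorm(-abs(z)), n = n,
             stringsAsFactors = FALSE)
}

#' Simulate a pair of trait summary-statistic datasets over one region
#'
#' @param region output of [simulate_region()].
#' @param scenario a [scenario_spec()].
#' @param seed integer seed.
#' @return list of two `assoc_dataset`s, `trait1` and `trait2`.
#' @export
simulate_sumstats <- function(region, scenario, seed = 1L) {
  stopifnot(inherits(scenario, "scenario_spec"))
  rng <- local_rng(seed)
  h <- scenario$hypothesis
  ci1 <- if (h %in% c("H1", "H3", "H4")) scenario$causal_index_1 else NULL
  ci2 <- if (h %in% c("H2", "H3", "H4")) scenario$causal_index_2 else NULL
  chol_r <- chol_psd(region$ld$r)

  v2 <- 1
  if (scenario$trait2_type == "case_control") {
    v2 <- (scenario$n_cases / scenario$n2) * (scenario$n_controls / scenario$n2)
  }
  t1 <- draw_sumstats(region, ci1, scenario$var_explained_1, scenario$n1,
                      rng, chol_r = chol_r)
  t2 <- draw_sumstats(region, ci2, scenario$var_explained_2, scenario$n2,
                      rng, v = v2, chol_r = chol_r)
  list(
    trait1 = assoc_dataset(t1, "trait1", "quantitative"),
    trait2 = assoc_dataset(t2, "trait2", scenario$trait2_type,
                           n_cases = scenario$n_cases,
                           n_controls = scenario$n_controls))
}

#' Specify a methylation -> expression -> protein -> disease causal chain
#'
#' All molecular layers share one causal SNP. Layer traits are kept on the
#' SD scale by construction (each downstream molecular trait is rescaled
#' to unit variance), so the true SMR ratio methylation -> expression is
#' exactly `theta_me`, expression -> protein is `theta_ep`, and expression
#' -> disease on the log-odds scale is `theta_ed`.
#'
#' @param theta_me effect of methylation on expression (SD per SD).
#' @param theta_ep effect of expression on protein (SD per SD).
#' @param theta_ed effect of expression on disease liability (log-odds per
#'   SD of expression).
#' @param causal_index shared causal SNP index.
#' @param var_qtl variance of methylation explained by the causal SNP.
#' @param n_meth,n_expr,n_prot molecular-layer sample sizes (>= 100).
#' @param n_cases,n_controls disease GWAS case/control counts.
#' @return An object of class `chain_spec`.
#' @export
chain_spec <- function(theta_me = -0.5, theta_ep = 0.5, theta_ed = 0.2,
                       causal_index = 1L, var_qtl = 0.05,
                       n_meth = 10000, n_expr = 30000, n_prot = 30000,
                       n_cases = 10000, n_controls = 40000) {
  stopifnot(is.finite(theta_me), is.finite(theta_ep), is.finite(theta_ed),
            abs(theta_me) < 1, abs(theta_ep) < 1,
            var_qtl > 0, var_qtl < 1,
            n_meth >= 100, n_expr >= 100, n_prot >= 100,
            n_cases >= 100, n_controls >= 100)
  structure(list(theta_me = theta_me, theta_ep = theta_ep, theta_ed = theta_ed,
                 causal_index = as.integer(causal_index), var_qtl = var_qtl,
                 n_meth = n_meth, n_expr = n_expr, n_prot = n_prot,
                 n_cases = n_cases, n_controls = n_controls),
            class = "chain_spec")
}

#' Simulate the four layers of a multi-omics causal chain
#'
#' Methylation M carries the direct QTL effect `b_m = sqrt(var_qtl)`;
#' expression E = theta_me * M + noise (standardized), protein
#' P = theta_ep * E + noise (standardized), and disease liability carries
#' `theta_ed * beta_E` on the log-odds scale. Each layer's summary
#' statistics are drawn from an independent cohort.
#'
#' @param region output of [simulate_region()].
#' @param chain a [chain_spec()].
#' @param seed integer seed.
#' @return named list of `assoc_dataset`s: `methylation`, `expression`,
#'   `protein`, `disease`.
#' @export
simulate_chain <- function(region, chain, seed = 1L) {
  stopifnot(inherits(chain, "chain_spec"))
  rng <- local_rng(seed)
  m <- nrow(region$snps)
  r <- region$ld$r
  chol_r <- chol_psd(r)
  s <- sqrt(2 * region$maf * (1 - region$maf))
  ci <- chain$causal_index
  stopifnot(ci >= 1, ci <= m)

  b_m <- sqrt(chain$var_qtl)                       # per-SD-genotype on M
  b_e <- chain$theta_me * b_m                      # E standardized
  b_p <- chain$theta_ep * b_e                      # P standardized
  b_d <- chain$theta_ed * b_e                      # log-odds per SD genotype

  n_dis <- chain$n_cases + chain$n_controls
  v_dis <- (chain$n_cases / n_dis) * (chain$n_controls / n_dis)

  draw_layer <- function(b_causal, n, v = 1) {
    beta_joint <- numeric(m)
    beta_joint[ci] <- b_causal
    z_mean <- sqrt(n * v) * drop(r %*% beta_joint)
    z <- z_mean + drop(crossprod(chol_r, rng$rnorm(m)))
    se <- 1 / (sqrt(n * v) * s)
    data.frame(snp = region$snps$snp, chr = region$snps$chr,
               pos = region$snps$pos, ea = region$snps$ea, oa = region$snps$oa,
               eaf = region$maf, beta = z * se, se = se,
               p = 2 * stats::pnorm(-abs(z)), n = n, stringsAsFactors = FALSE)
  }

  list(
    methylation = assoc_dataset(draw_layer(b_m, chain$n_meth),
                                "methylation", "quantitative"),
    expression = assoc_dataset(draw_layer(b_e, chain$n_expr),
                               "expression", "quantitative"),
    protein = assoc_dataset(draw_layer(b_p, chain$n_prot),
                            "protein", "quantitative"),
    disease = assoc_dataset(draw_layer(b_d, n_dis, v_dis),
                            "disease", "case_control",
                            n_cases = chain$n_cases,
                            n_controls = chain$n_controls))
}

#' Cohort-size presets matching large published QTL/GWAS resources
#'
#' Named effective sample sizes for the blood mQTL, eQTL and plasma pQTL
#' meta-analyses and the type-2-diabetes GWAS this package is designed
#' around; simulation defaults use desk-scale sizes instead.
#'
#' @return named numeric vector.
#' @export
cohort_presets <- function() {
  c(mqtl_blood = 1980, eqtlgen = 31684, decode = 35559,
    diagram_cases = 242283, diagram_controls = 1569734)
}
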