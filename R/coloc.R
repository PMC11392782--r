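# Bayesian colocalization over a cis-region.
#
# Per-SNP evidence is a Wakefield approximate Bayes factor computed from
# the estimate and its standard error under a normal prior N(0, W) on the
# effect size. Region-level posteriors compare five hypotheses:
#   H0 neither trait associated          H1 only trait 1
#   H2 only trait 2                      H3 both, distinct causal variants
#   H4 both, one shared causal variant
# assuming at most one causal variant per trait in the region.

#' Colocalization priors
#'
#' Per-SNP prior probabilities of association with trait 1 only (`p1`),
#' trait 2 only (`p2`), and both traits (`p12`). Defaults are the
#' conventional 1e-4, 1e-4, 1e-5.
#'
#' @param p1,p2,p12 per-SNP priors.
#' @return list of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  stopifnot(p1 > 0, p2 > 0, p12 >= 0)  # p12 = 0 nullifies H4
  if (p12 > min(p1, p2)) stop("p12 must not exceed min(p1, p2)")
  if (p1 + p2 + p12 >= 1) stop("p1 + p2 + p12 must be < 1")
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor for one SNP association
#'
#' With V = se^2, z = beta/se, prior effect variance W and shrinkage
#' r = W/(V+W): lABF = 0.5 (log(1-r) + r z^2). The default prior SD is
#' 0.15 on the per-SD scale for quantitative traits and 0.2 on the
#' log-odds scale for case-control traits.
#'
#' @param beta,se effect estimate and standard error (vectorized).
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param sd_prior override for the prior effect-size SD.
#' @return numeric vector of log ABFs.
#' @export
wakefield_labf <- function(beta, se, trait_type = c("quantitative", "case_control"),
                           sd_prior = NULL) {
  trait_type <- match.arg(trait_type)
  if (any(se <= 0)) stop("se must be positive")
  if (is.null(sd_prior)) sd_prior <- if (trait_type == "quantitative") 0.15 else 0.2
  v <- se^2
  w <- sd_prior^2
  r <- w / (v + w)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

coloc_label <- function(pp_h4) {
  if (pp_h4 > 0.7) "strong" else if (pp_h4 > 0.5) "moderate" else "none"
}

#' Posterior probabilities of the five colocalization hypotheses
#'
#' Combines per-SNP log ABFs for two traits over the same harmonized SNP
#' set into PP.H0..PP.H4 using log-sum-exp arithmetic. The H3 term (both
#' traits associated, different SNPs) is the off-diagonal double sum,
#' computed via the identity lse_{i != j}(a_i + b_j) =
#' log(exp(S1 + S2) - exp(S12)); negative round-off is clamped to -Inf.
#' PP.H4 > 0.7 is labelled "strong" colocalization, 0.5 < PP.H4 <= 0.7
#' "moderate".
#'
#' @param labf1,labf2 equal-length numeric vectors of log ABFs.
#' @param priors a [coloc_priors()].
#' @param probe_id,outcome_id optional identifiers carried into the
#'   result.
#' @return list of class `coloc_result` with `n_snps`, `pp` (named vector
#'   PP.H0..PP.H4 summing to 1) and `label`.
#' @export
coloc_pp <- function(labf1, labf2, priors = coloc_priors(),
                     probe_id = NA_character_, outcome_id = NA_character_) {
  stopifnot(inherits(priors, "coloc_priors"))
  m <- length(labf1)
  if (m == 0L) stop("empty region: no SNPs")
  if (length(labf2) != m) stop("labf1 and labf2 must have equal length")

  s1 <- logsumexp(labf1)
  s2 <- logsumexp(labf2)
  s12 <- logsumexp(labf1 + labf2)
  lp1 <- log(priors$p1); lp2 <- log(priors$p2); lp12 <- log(priors$p12)

  lh <- c(
    H0 = 0,
    H1 = lp1 + s1,
    H2 = lp2 + s2,
    H3 = if (m == 1L) -Inf else lp1 + lp2 + suppressWarnings(logdiff(s1 + s2, s12)),
    H4 = lp12 + s12)
  denom <- logsumexp(lh)
  pp <- exp(lh - denom)
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP.", names(lh))

  structure(list(probe_id = probe_id, outcome_id = outcome_id, n_snps = m,
                 pp = pp, label = coloc_label(pp[["PP.H4"]])),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %s vs %s over %d SNPs (%s)\n",
              x$probe_id, x$outcome_id, x$n_snps, x$label))
  print(round(x$pp, 4))
  invisible(x)
}

#' Exhaustive-enumeration colocalization oracle
#'
#' Enumerates all (m + 1)^2 single-causal-variant configuration pairs
#' (including "no causal variant") with their exact prior weights and
#' Bayes factors, then sums posterior mass per hypothesis. Exponential
#' only in bookkeeping, not in m, but restricted to m <= 12 because its
#' purpose is to cross-validate [coloc_pp()] on small regions, not to be
#' fast.
#'
#' @inheritParams coloc_pp
#' @return list of class `coloc_result`.
#' @export
coloc_enumerate <- function(labf1, labf2, priors = coloc_priors(),
                            probe_id = NA_character_, outcome_id = NA_character_) {
  m <- length(labf1)
  if (m == 0L) stop("empty region: no SNPs")
  if (m > 12L) stop("enumeration oracle restricted to m <= 12")
  stopifnot(length(labf2) == m, inherits(priors, "coloc_priors"))

  lw <- matrix(-Inf, m + 1L, m + 1L)  # row: trait1 config (1 = none); col: trait2
  hyp <- matrix("", m + 1L, m + 1L)
  for (i in 0:m) {
    for (j in 0:m) {
      l <- 0
      if (i > 0) l <- l + labf1[i]
      if (j > 0) l <- l + labf2[j]
      if (i == 0 && j == 0) { pr <- 0; h <- "H0" }
      else if (j == 0) { pr <- log(priors$p1); h <- "H1" }
      else if (i == 0) { pr <- log(priors$p2); h <- "H2" }
      else if (i != j) { pr <- log(priors$p1) + log(priors$p2); h <- "H3" }
      else { pr <- log(priors$p12); h <- "H4" }
      lw[i + 1L, j + 1L] <- pr + l
      hyp[i + 1L, j + 1L] <- h
    }
  }
  denom <- logsumexp(as.vector(lw))
  pp <- vapply(c("H0", "H1", "H2", "H3", "H4"), function(h) {
    sel <- lw[hyp == h]
    if (!length(sel)) 0 else exp(logsumexp(sel) - denom)
  }, numeric(1))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP.", c("H0", "H1", "H2", "H3", "H4"))
  structure(list(probe_id = probe_id, outcome_id = outcome_id, n_snps = m,
                 pp = pp, label = coloc_label(pp[["PP.H4"]])),
            class = "coloc_result")
}

#' Run colocalization for a harmonized trait pair over a cis-region
#'
#' Convenience wrapper: harmonizes the two datasets (optionally windowed),
#' computes per-SNP Wakefield log ABFs with trait-appropriate priors, and
#' returns [coloc_pp()]. Window conventions follow the QTL layer: for
#' methylation probes the region is +/-500 kb around the top cis-SNP; for
#' expression and protein probes +/-1 Mb around the gene body.
#'
#' @param trait1,trait2 `assoc_dataset`s (trait1 = molecular layer,
#'   trait2 = outcome).
#' @param window optional numeric `c(start, end)` restriction applied
#'   before harmonization.
#' @param priors a [coloc_priors()].
#' @return list of class `coloc_result`.
#' @export
coloc_region <- function(trait1, trait2, window = NULL,
                         priors = coloc_priors()) {
  if (!is.null(window)) {
    subset_win <- function(d) {
      rec <- d$records
      rec <- rec[rec$pos >= window[1] & rec$pos <= window[2], , drop = FALSE]
      assoc_dataset(rec, d$trait_id, d$trait_type, d$n_cases, d$n_controls)
    }
    trait1 <- subset_win(trait1)
    trait2 <- subset_win(trait2)
  }
  h <- harmonize(trait1, trait2)
  l1 <- wakefield_labf(h$exposure$records$beta, h$exposure$records$se,
                       trait_type = h$exposure$trait_type)
  l2 <- wakefield_labf(h$outcome$records$beta, h$outcome$records$se,
                       trait_type = h$outcome$trait_type)
  coloc_pp(l1, l2, priors = priors,
           probe_id = trait1$trait_id, outcome_id = trait2$trait_id)
}
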