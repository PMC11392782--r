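# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities by a different route than the
# package implementation.

# Benjamini-Hochberg by the literal definition:
# q_i = min over j with p_(j) >= p_i of m * p_(j) / rank(j), clipped at 1.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranks <- match(seq_len(m), o)  # rank of each original element
  sapply(seq_len(m), function(i) {
    cand <- sapply(seq_len(m), function(jr) {
      if (p[o[jr]] >= p[i]) m * p[o[jr]] / jr else Inf
    })
    min(c(cand, 1))
  })
}

# Hypergeometric upper tail by explicit summation of the pmf.
brute_hyper_upper <- function(overlap, set_size, universe_size, query_size) {
  ks <- overlap:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(universe_size - set_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# Null-distribution oracle for P(sum lambda_k chi2_1 > t): exact closed
# form for one eigenvalue, otherwise direct Monte-Carlo enumeration of
# the eigenvalue sum (1e6 draws; SE < 5e-4, far inside the comparison
# tolerances used with it).
qform_null_pvalue <- function(t, lambda, n_draws = 1e6, seed = 97) {
  k <- length(lambda)
  if (k == 1L) return(stats::pchisq(t / lambda, df = 1, lower.tail = FALSE))
  set.seed(seed)
  total <- numeric(n_draws)
  for (j in seq_len(k)) total <- total + lambda[j] * stats::rchisq(n_draws, 1)
  mean(total > t)
}

# tiny well-formed summary-statistics data.frame
toy_records <- function(n = 3, seed = 1) {
  set.seed(seed)
  data.frame(
    snp = sprintf("rs%d", seq_len(n)),
    chr = "1", pos = 1000 * seq_len(n),
    ea = rep("A", n), oa = rep("G", n),
    eaf = runif(n, 0.1, 0.5),
    beta = rnorm(n, 0, 0.05), se = runif(n, 0.01, 0.03),
    p = NA_real_, n = 10000, stringsAsFactors = FALSE)
}

toy_dataset <- function(n = 3, seed = 1, trait_id = "toy") {
  assoc_dataset(toy_records(n, seed), trait_id, "quantitative")
}

top_snp_of <- function(d) d$records$snp[which.min(d$records$p)]
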