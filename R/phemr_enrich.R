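# Phenome-wide Wald-ratio screening and hypergeometric gene-set
# over-representation analysis.

#' Wald-ratio causal estimate for a single instrument
#'
#' b_xy = b_outcome / b_exposure with first-order delta-method standard
#' error and a two-sided normal p-value on b_xy / se_xy. The ratio and SE
#' are arithmetically identical to [smr_test()]'s on the same inputs (the
#' p-value convention differs: the SMR test uses the chi-square form in
#' both z-scores).
#'
#' @param b_exposure,se_exposure instrument -> exposure effect and SE.
#' @param b_outcome,se_outcome instrument -> outcome effect and SE.
#' @return list with `b_xy`, `se_xy`, `p`.
#' @export
wald_ratio <- function(b_exposure, se_exposure, b_outcome, se_outcome) {
  stopifnot(se_exposure > 0, se_outcome > 0)
  if (b_exposure == 0) stop("undefined ratio: zero exposure effect")
  b_xy <- b_outcome / b_exposure
  se_xy <- sqrt(se_outcome^2 / b_exposure^2 +
                  b_outcome^2 * se_exposure^2 / b_exposure^4)
  p <- 2 * stats::pnorm(-abs(b_xy / se_xy))
  list(b_xy = b_xy, se_xy = se_xy, p = p)
}

#' Phenome-wide Wald-ratio screen
#'
#' Tests each gene's instrument SNP against every phenotype of a phenome
#' table. Phenotypes with fewer than `min_cases` cases are excluded
#' before any testing; alleles are harmonized per (instrument, phenotype)
#' row (sign-flip on swap, mismatches dropped); a single BH FDR
#' correction is applied over all retained (gene, phenotype) tests, and
#' rows with q below `fdr_threshold` are flagged significant.
#'
#' @param instruments data.frame with one row per gene: `gene_id, snp,
#'   ea, oa, b_exposure, se_exposure`.
#' @param phenome data.frame with one row per (phenotype, snp):
#'   `phenotype_id, description, n_cases, n_controls, snp, ea, oa, beta,
#'   se` (log-odds scale).
#' @param min_cases minimum case count (default 500).
#' @param fdr_threshold significance cutoff on q (default 0.1).
#' @param family `"pooled"` (one correction over all tests, default) or
#'   `"per_gene"`.
#' @return data.frame with `gene_id, phenotype_id, description, snp,
#'   n_cases, b_xy, se_xy, or_xy, ci_low, ci_high, p, q, significant`.
#' @export
phemr_screen <- function(instruments, phenome, min_cases = 500,
                         fdr_threshold = 0.1, family = c("pooled", "per_gene")) {
  family <- match.arg(family)
  ph <- phenome[phenome$n_cases >= min_cases, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(instruments))) {
    iv <- instruments[i, ]
    hits <- ph[ph$snp == iv$snp, , drop = FALSE]
    if (!nrow(hits)) next
    same <- toupper(hits$ea) == toupper(iv$ea) & toupper(hits$oa) == toupper(iv$oa)
    swapped <- toupper(hits$ea) == toupper(iv$oa) & toupper(hits$oa) == toupper(iv$ea)
    hits <- hits[same | swapped, , drop = FALSE]
    if (!nrow(hits)) next
    flip <- swapped[same | swapped]
    b_out <- ifelse(flip, -hits$beta, hits$beta)
    for (j in seq_len(nrow(hits))) {
      w <- wald_ratio(iv$b_exposure, iv$se_exposure, b_out[j], hits$se[j])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = iv$gene_id, phenotype_id = hits$phenotype_id[j],
        description = hits$description[j], snp = iv$snp,
        n_cases = hits$n_cases[j], b_xy = w$b_xy, se_xy = w$se_xy,
        or_xy = exp(w$b_xy), ci_low = exp(w$b_xy - 1.96 * w$se_xy),
        ci_high = exp(w$b_xy + 1.96 * w$se_xy), p = w$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), phenotype_id = character(0),
                      description = character(0), snp = character(0),
                      n_cases = numeric(0), b_xy = numeric(0), se_xy = numeric(0),
                      or_xy = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
                      p = numeric(0), q = numeric(0), significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  p_safe <- pmax(out$p, .Machine$double.xmin)
  if (family == "pooled") {
    out$q <- bh_fdr(p_safe)
  } else {
    out$q <- NA_real_
    for (g in unique(out$gene_id)) {
      sel <- out$gene_id == g
      out$q[sel] <- bh_fdr(p_safe[sel])
    }
  }
  out$significant <- out$q < fdr_threshold
  out
}

#' Hypergeometric over-representation test for one gene set
#'
#' Upper-tail probability of observing at least the realized overlap
#' between the query genes and the gene set, drawing |query| genes from
#' the universe without replacement. The gene set is intersected with
#' the universe first.
#'
#' @param query character vector of query genes (must be a subset of
#'   `universe`).
#' @param gene_set character vector of set members.
#' @param universe character vector of background genes.
#' @return list with `p`, `overlap`, `expected` (expected overlap under
#'   the null), `set_size` (set size within the universe).
#' @export
ora_test <- function(query, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes must be a subset of the universe")
  set_in <- intersect(unique(gene_set), universe)
  if (!length(set_in)) stop("gene set has no members in the universe")
  n_univ <- length(universe)
  k_set <- length(set_in)
  n_query <- length(query)
  overlap <- length(intersect(query, set_in))
  p <- stats::phyper(overlap - 1, k_set, n_univ - k_set, n_query,
                     lower.tail = FALSE)
  list(p = p, overlap = overlap,
       expected = n_query * k_set / n_univ, set_size = k_set)
}

#' Over-representation analysis across a gene-set collection
#'
#' Runs [ora_test()] per set, applies BH FDR, flags sets with q below
#' `fdr_threshold` (the conventional relaxed 0.1 for pathway screens),
#' and marks the top `n_top` sets by q (ties broken by larger overlap,
#' then set id).
#'
#' @param query character vector of query genes.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe background gene list.
#' @param fdr_threshold cutoff on q (default 0.1).
#' @param n_top how many top sets to mark (default 10).
#' @return data.frame: `set_id, set_size, overlap, expected, p, q,
#'   significant, top`.
#' @export
ora_collection <- function(query, gene_sets, universe, fdr_threshold = 0.1,
                           n_top = 10) {
  keep <- vapply(gene_sets, function(s) length(intersect(s, universe)) > 0,
                 logical(1))
  gene_sets <- gene_sets[keep]
  if (!length(gene_sets)) stop("no gene set overlaps the universe")
  rows <- lapply(names(gene_sets), function(id) {
    t <- ora_test(query, gene_sets[[id]], universe)
    data.frame(set_id = id, set_size = t$set_size, overlap = t$overlap,
               expected = t$expected, p = t$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(pmax(out$p, .Machine$double.xmin))
  out$significant <- out$q < fdr_threshold
  ord <- order(out$q, -out$overlap, out$set_id)
  out$top <- FALSE
  out$top[ord[seq_len(min(n_top, nrow(out)))]] <- TRUE
  out[ord, ]
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited, one set per line: set id, description, then members.
#'
#' @param path file path.
#' @return named list of character vectors of gene ids; descriptions are
#'   kept in the `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: ", which(bad)[1])
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), names(sets))
  sets
}
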