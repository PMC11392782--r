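# Multi-omics evidence integration: per-gene collation of layer-level
# SMR + colocalization results, tier classification, cross-omics MR, and
# tissue-level validation bookkeeping.
#
# Tier rules (counted over the omics layers a gene has data for):
#   Tier 1: causal at >= 2 layers, colocalization support at >= 2 layers
#   Tier 2: causal at >= 2 layers, colocalization support at exactly 1
#   Tier 3: causal at >= 2 layers, no colocalization support
# where a layer is "causal" when any of its probes has FDR q < 0.05 and
# p_HEIDI > 0.05, and "coloc-supported" when a causal probe additionally
# has PP.H4 > 0.5. Genes causal at fewer than 2 layers are unclassified.

#' Evidence status of one gene at one omics layer
#'
#' @param probes data.frame of the gene's probes at this layer with
#'   columns `probe_id`, `q_smr`, `p_heidi`, `pp_h4` and optionally
#'   `b_xy` (direction).
#' @param q_threshold,heidi_threshold,pp_threshold cutoffs (defaults
#'   0.05, 0.05, 0.5).
#' @return list with `causal`, `coloc`, `best_probe` (causal probe with
#'   smallest q, coloc-supported probes preferred; `NA` when none).
#' @export
gene_layer_status <- function(probes, q_threshold = 0.05,
                              heidi_threshold = 0.05, pp_threshold = 0.5) {
  stopifnot(nrow(probes) >= 1L)
  heidi_ok <- !is.na(probes$p_heidi) & probes$p_heidi > heidi_threshold
  causal <- probes$q_smr < q_threshold & heidi_ok
  coloc <- causal & !is.na(probes$pp_h4) & probes$pp_h4 > pp_threshold
  best <- NA_character_
  if (any(causal)) {
    cand <- probes[causal, , drop = FALSE]
    cand_coloc <- coloc[causal]
    ord <- order(!cand_coloc, cand$q_smr)  # coloc-supported first, then min q
    best <- cand$probe_id[ord[1]]
  }
  list(causal = any(causal), coloc = any(coloc), best_probe = best)
}

#' Assign an evidence tier from per-layer statuses
#'
#' @param statuses named list (one element per available layer) of
#'   [gene_layer_status()] results.
#' @return list with `tier` (`"tier1"`, `"tier2"`, `"tier3"` or
#'   `"unclassified"`), `n_causal_layers`, `n_coloc_layers`.
#' @export
assign_tier <- function(statuses) {
  stopifnot(length(statuses) >= 1L)
  n_causal <- sum(vapply(statuses, `[[`, logical(1), "causal"))
  n_coloc <- sum(vapply(statuses, `[[`, logical(1), "coloc"))
  tier <- if (n_causal < 2L) "unclassified"
  else if (n_coloc >= 2L) "tier1"
  else if (n_coloc == 1L) "tier2"
  else "tier3"
  list(tier = tier, n_causal_layers = n_causal, n_coloc_layers = n_coloc)
}

#' Classify genes into evidence tiers from a collated evidence table
#'
#' @param evidence data.frame with one row per (gene, layer, probe):
#'   columns `gene_id`, `layer`, `probe_id`, `q_smr`, `p_heidi`, `pp_h4`
#'   and optionally `b_xy`.
#' @param q_threshold,heidi_threshold,pp_threshold cutoffs passed to
#'   [gene_layer_status()].
#' @return data.frame with one row per gene: `gene_id, tier,
#'   n_causal_layers, n_coloc_layers, layers, best_probes`; unclassified
#'   genes are omitted.
#' @export
classify_tiers <- function(evidence, q_threshold = 0.05,
                           heidi_threshold = 0.05, pp_threshold = 0.5) {
  need <- c("gene_id", "layer", "probe_id", "q_smr", "p_heidi", "pp_h4")
  missing_cols <- setdiff(need, names(evidence))
  if (length(missing_cols)) {
    stop("evidence is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  rows <- lapply(split(evidence, evidence$gene_id), function(g) {
    statuses <- lapply(split(g, g$layer, drop = TRUE), gene_layer_status,
                       q_threshold = q_threshold,
                       heidi_threshold = heidi_threshold,
                       pp_threshold = pp_threshold)
    tier <- assign_tier(statuses)
    causal_layers <- names(statuses)[vapply(statuses, `[[`, logical(1), "causal")]
    best <- vapply(statuses[causal_layers], `[[`, character(1), "best_probe")
    data.frame(gene_id = g$gene_id[1], tier = tier$tier,
               n_causal_layers = tier$n_causal_layers,
               n_coloc_layers = tier$n_coloc_layers,
               layers = paste(causal_layers, collapse = ","),
               best_probes = paste(best, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$tier != "unclassified", , drop = FALSE]
  rownames(out) <- NULL
  out[order(match(out$tier, c("tier1", "tier2", "tier3")), out$gene_id), ]
}

#' Cross-omics MR between two molecular layers
#'
#' Reuses the SMR engine with the lower layer as exposure (methylation ->
#' expression, expression -> protein): same instrument selection, ratio
#' test, HEIDI and FDR machinery as the disease analyses.
#'
#' @param exposure_layer,outcome_layer `assoc_dataset`s (or named lists
#'   per probe) for the two molecular layers.
#' @param probes probe annotations of the exposure layer.
#' @param ld LD matrix or per-probe list.
#' @param ... passed to [run_layer()].
#' @return [run_layer()] result table.
#' @export
cross_omics_mr <- function(exposure_layer, outcome_layer, probes, ld, ...) {
  run_layer(exposure_layer, outcome_layer, probes, ld, ...)
}

#' Directional consistency of a mediation triangle
#'
#' Checks whether sign(b upstream->mediator) x sign(b mediator->disease)
#' equals sign(b upstream->disease); reported, never enforced.
#'
#' @param b_up_med,b_med_dis,b_up_dis the three ratio estimates.
#' @return logical.
#' @export
direction_consistent <- function(b_up_med, b_med_dis, b_up_dis) {
  sign(b_up_med) * sign(b_med_dis) == sign(b_up_dis)
}

#' Tissue-level validation of blood-identified causal genes
#'
#' A gene is "validated" when at least one tissue shows nominal SMR
#' significance without pleiotropy (p_smr < `p_threshold` and p_HEIDI >
#' `heidi_threshold`); colocalization support is graded strong
#' (PP.H4 > 0.7) or moderate (PP.H4 > 0.5) on validated rows. Directional
#' concordance with the blood estimate is recorded when a blood direction
#' is supplied.
#'
#' @param tissue_results data.frame with one row per (gene, tissue):
#'   columns `gene_id`, `tissue`, `p_smr`, `p_heidi`, `pp_h4` and
#'   optionally `b_xy`.
#' @param blood_direction optional named numeric vector of blood-level
#'   effect signs per gene.
#' @param p_threshold,heidi_threshold cutoffs (defaults 0.05, 0.05).
#' @return list with `table` (per-row flags) and `validated_genes`
#'   (character vector of distinct validated genes).
#' @export
tissue_validate <- function(tissue_results, blood_direction = NULL,
                            p_threshold = 0.05, heidi_threshold = 0.05) {
  tr <- tissue_results
  need <- c("gene_id", "tissue", "p_smr", "p_heidi", "pp_h4")
  missing_cols <- setdiff(need, names(tr))
  if (length(missing_cols)) {
    stop("tissue_results is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  no_data <- is.na(tr$p_smr)
  ok <- !no_data & tr$p_smr < p_threshold &
    !is.na(tr$p_heidi) & tr$p_heidi > heidi_threshold
  tr$validated <- ok
  tr$coloc_support <- ifelse(!ok | is.na(tr$pp_h4), "none",
                             ifelse(tr$pp_h4 > 0.7, "strong",
                                    ifelse(tr$pp_h4 > 0.5, "moderate", "none")))
  tr$status <- ifelse(no_data, "no data", ifelse(ok, "validated", "not validated"))
  if (!is.null(blood_direction) && "b_xy" %in% names(tr)) {
    tr$concordant <- sign(tr$b_xy) == sign(blood_direction[tr$gene_id])
  }
  list(table = tr, validated_genes = sort(unique(tr$gene_id[ok])))
}
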