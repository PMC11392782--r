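# Configuration-driven orchestration: simulate (or ingest) -> per-layer
# SMR + HEIDI -> colocalization -> tier classification, with per-stage
# logging and a reproducibility manifest (config snapshot, seed, and an
# md5 per output file). Reruns with the same config and seed produce
# byte-identical outputs.

#' Default pipeline configuration
#'
#' Collects every tunable constant of the analysis in one list: the
#' instrument p-value threshold, FDR/HEIDI/colocalization cutoffs,
#' colocalization priors, per-layer window sizes, the simulation scenario
#' and the seed. Values can be overridden via `...` or by loading a JSON
#' config with [read_pipeline_config()].
#'
#' @param ... named overrides of the defaults.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    # thresholds
    p_instrument = 5e-8,
    q_threshold = 0.05,
    heidi_threshold = 0.05,
    pp_strong = 0.7,
    pp_moderate = 0.5,
    min_cases = 500,
    phemr_fdr = 0.1,
    ora_fdr = 0.1,
    # coloc priors
    priors = c(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5),
    # cis-window flanks (bp): methylation windows anchor at the top SNP
    flank_mqtl = 5e5,
    flank_eqtl = 1e6,
    flank_pqtl = 1e6,
    # simulated-world parameters (used when no dataset paths are given)
    sim = list(m_snps = 30L, rho = 0.9, maf_range = c(0.05, 0.5),
               theta_me = -0.5, theta_ep = 0.5, theta_ed = 0.5,
               causal_index = 15L, var_qtl = 0.05,
               n_meth = 10000, n_expr = 30000, n_prot = 30000,
               n_cases = 10000, n_controls = 40000))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$p_instrument > 0, cfg$p_instrument < 1,
            cfg$q_threshold > 0, cfg$q_threshold < 1,
            cfg$heidi_threshold > 0, cfg$heidi_threshold < 1,
            cfg$pp_moderate < cfg$pp_strong,
            cfg$flank_mqtl > 0, cfg$flank_eqtl > 0, cfg$flank_pqtl > 0)
  coloc_priors(cfg$priors[["p1"]], cfg$priors[["p2"]], cfg$priors[["p12"]])
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file of config overrides (same keys as
#'   [pipeline_config()]).
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[momicsmr] ", fmt), ...))

#' Run the full multi-omics MR pipeline on a simulated causal chain
#'
#' Demonstration-scale end-to-end run: simulates a methylation ->
#' expression -> protein -> disease causal chain over one LD-correlated
#' cis-region, runs SMR + HEIDI for each molecular layer against the
#' disease, colocalization per layer with the layer's window convention,
#' and classifies the gene into an evidence tier. All stage outputs are
#' written as TSV under `config$out_dir` (when set) and hashed into a
#' manifest.
#'
#' @param config a [pipeline_config()].
#' @return list with `layer_results` (per-layer SMR tables), `coloc`
#'   (per-layer `coloc_result`s), `evidence` (collated table), `tiers`
#'   (classification), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  log_stage("simulate: m=%d SNPs, seed=%d", sim$m_snps, config$seed)
  region <- simulate_region(
    region_spec(sim$m_snps, maf_range = sim$maf_range, rho = sim$rho),
    seed = config$seed)
  chain <- chain_spec(theta_me = sim$theta_me, theta_ep = sim$theta_ep,
                      theta_ed = sim$theta_ed, causal_index = sim$causal_index,
                      var_qtl = sim$var_qtl, n_meth = sim$n_meth,
                      n_expr = sim$n_expr, n_prot = sim$n_prot,
                      n_cases = sim$n_cases, n_controls = sim$n_controls)
  layers <- simulate_chain(region, chain, seed = config$seed + 1L)

  gene <- data.frame(probe_id = "GENE1", gene_id = "GENE1",
                     chr = region$snps$chr[1],
                     start = min(region$snps$pos), end = max(region$snps$pos),
                     stringsAsFactors = FALSE)
  flanks <- c(methylation = config$flank_mqtl, expression = config$flank_eqtl,
              protein = config$flank_pqtl)
  priors <- coloc_priors(config$priors[["p1"]], config$priors[["p2"]],
                         config$priors[["p12"]])

  layer_results <- list()
  coloc_results <- list()
  evid_rows <- list()
  for (layer in c("methylation", "expression", "protein")) {
    probes <- gene
    probes$layer <- layer
    res <- run_layer(layers[[layer]], layers$disease, probes, region$ld,
                     flank = flanks[[layer]],
                     p_instrument = config$p_instrument,
                     q_threshold = config$q_threshold,
                     heidi_threshold = config$heidi_threshold)
    log_stage("smr %s: %d probe(s) analysed, %d significant",
              layer, nrow(res), sum(res$flag == "significant"))
    layer_results[[layer]] <- res
    if (!nrow(res)) next

    top_pos <- layers[[layer]]$records$pos[
      match(res$top_snp[1], layers[[layer]]$records$snp)]
    win <- if (layer == "methylation") {
      cis_window(flank = flanks[[layer]], anchor = "top_snp", top_snp_pos = top_pos)
    } else {
      cis_window(gene, flank = flanks[[layer]], anchor = "gene_body")
    }
    cr <- coloc_region(layers[[layer]], layers$disease, window = win,
                       priors = priors)
    log_stage("coloc %s: PP.H4 = %.3f (%s)", layer, cr$pp[["PP.H4"]], cr$label)
    coloc_results[[layer]] <- cr
    evid_rows[[layer]] <- data.frame(
      gene_id = res$gene_id[1], layer = layer, probe_id = res$probe_id[1],
      b_xy = res$b_xy[1], q_smr = res$q_smr[1], p_heidi = res$p_heidi[1],
      pp_h4 = cr$pp[["PP.H4"]], stringsAsFactors = FALSE)
  }

  evidence <- do.call(rbind, evid_rows)
  rownames(evidence) <- NULL
  tiers <- classify_tiers(evidence, q_threshold = config$q_threshold,
                          heidi_threshold = config$heidi_threshold,
                          pp_threshold = config$pp_moderate)
  log_stage("tiers: %s", if (nrow(tiers)) {
    paste(sprintf("%s=%s", tiers$gene_id, tiers$tier), collapse = ", ")
  } else "no gene classified")

  manifest <- list(package = "momicsmr",
                   version = as.character(utils::packageVersion("momicsmr")),
                   seed = config$seed,
                   config = unclass(config),
                   outputs = list())
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_one <- function(df, name) {
      p <- file.path(config$out_dir, name)
      data.table::fwrite(df, p, sep = "\t", quote = FALSE)
      manifest$outputs[[name]] <<- unname(tools::md5sum(p))
    }
    for (layer in names(layer_results)) {
      write_one(layer_results[[layer]], paste0("smr_", layer, ".tsv"))
    }
    if (!is.null(evidence)) write_one(evidence, "evidence.tsv")
    if (nrow(tiers)) write_one(tiers, "tiers.tsv")
    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    log_stage("manifest written to %s", manifest_path)
  }

  list(layer_results = layer_results, coloc = coloc_results,
       evidence = evidence, tiers = tiers, manifest = manifest)
}
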