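# Reading, validation, harmonization and windowing of per-SNP summary
# statistics. Every downstream stage (SMR, HEIDI, coloc, Phe-MR) consumes
# only the containers defined here.
#
# Conventions:
#   * coordinates are 1-based, both-ends-inclusive;
#   * betas are per effect-allele copy, on the SD scale for quantitative
#     traits and the log-odds scale for case-control traits;
#   * an AssocDataset's `records` is a data.frame with canonical columns
#     snp, chr, pos, ea, oa, eaf, beta, se, p, n.

CANONICAL_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")

#' Construct an association dataset of per-SNP summary statistics
#'
#' Bundles a validated table of per-SNP summary statistics for one trait
#' (a molecular probe layer or a disease GWAS) together with its design
#' metadata. Rows violating per-variant invariants (non-positive standard
#' error, missing beta/se, allele-frequency outside \[0,1\], empty or
#' identical alleles, p outside (0,1\]) are dropped with a message.
#'
#' @param records data.frame with columns `snp, chr, pos, ea, oa, eaf,
#'   beta, se, p, n`. `p` may be `NA`, in which case it is recomputed from
#'   the two-sided normal tail of `beta/se`.
#' @param trait_id character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param n_cases,n_controls case/control counts, required when
#'   `trait_type = "case_control"`.
#' @return An object of class `assoc_dataset`.
#' @export
assoc_dataset <- function(records, trait_id, trait_type = c("quantitative", "case_control"),
                          n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.character(trait_id), length(trait_id) == 1L)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(CANONICAL_COLS, names(records))
  if (length(missing_cols)) {
    stop("records is missing required columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- records[CANONICAL_COLS]
  if (trait_type == "case_control") {
    if (is.null(n_cases) || is.null(n_controls) || n_cases < 1 || n_controls < 1) {
      stop("case_control datasets require n_cases >= 1 and n_controls >= 1")
    }
  }

  for (col in c("pos", "eaf", "beta", "se", "p", "n")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  records$snp <- as.character(records$snp)
  records$chr <- as.character(records$chr)
  records$ea <- toupper(as.character(records$ea))
  records$oa <- toupper(as.character(records$oa))

  keep <- !is.na(records$beta) & !is.na(records$se) & records$se > 0 &
    !is.na(records$eaf) & records$eaf >= 0 & records$eaf <= 1 &
    nzchar(records$ea) & nzchar(records$oa) & records$ea != records$oa &
    !is.na(records$n) & records$n > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(sprintf("assoc_dataset('%s'): dropped %d invalid row(s)", trait_id, n_dropped))
    records <- records[keep, , drop = FALSE]
  }
  if (anyDuplicated(records$snp)) {
    stop("duplicate snp ids within dataset '", trait_id, "'")
  }

  miss_p <- is.na(records$p)
  if (any(miss_p)) {
    z <- records$beta[miss_p] / records$se[miss_p]
    records$p[miss_p] <- 2 * stats::pnorm(-abs(z))
  }
  # Published tables often carry rounded p-values: check consistency with
  # the reported beta/se under a two-sided normal test, warn only.
  z <- abs(records$beta / records$se)
  p_expect <- 2 * stats::pnorm(-z)
  ok <- records$p <= 0 | p_expect <= 0 |
    abs(log(records$p) - log(p_expect)) <= abs(log(1.1)) | p_expect < 1e-300
  if (any(!ok, na.rm = TRUE)) {
    warning(sprintf("%d row(s) in '%s' have p inconsistent with beta/se beyond 10%% relative tolerance",
                    sum(!ok, na.rm = TRUE), trait_id))
  }
  records$p[records$p > 1] <- 1
  rownames(records) <- NULL

  structure(
    list(trait_id = trait_id, trait_type = trait_type,
         n_cases = n_cases, n_controls = n_controls, records = records),
    class = "assoc_dataset")
}

#' @export
print.assoc_dataset <- function(x, ...) {
  cat(sprintf("<assoc_dataset> %s (%s): %d SNPs\n", x$trait_id, x$trait_type,
              nrow(x$records)))
  if (x$trait_type == "case_control") {
    cat(sprintf("  cases: %d  controls: %d\n", x$n_cases, x$n_controls))
  }
  invisible(x)
}

#' Read per-SNP summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header line into an
#' [assoc_dataset()]. Column names are mapped through `schema`, a named
#' character vector from canonical names (`snp, chr, pos, ea, oa, eaf,
#' beta, se, p, n`) to the file's headers, so GCTA-COJO ".ma"-style and
#' other dialects load without editing the file.
#'
#' @param path file path.
#' @param trait_id trait name; defaults to the file stem.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @param schema named character vector mapping canonical to file column
#'   names; only entries that differ from the canonical names are needed.
#' @param n_cases,n_controls case/control counts for binary traits.
#' @return An `assoc_dataset`.
#' @export
read_sumstats <- function(path, trait_id = NULL,
                          trait_type = c("quantitative", "case_control"),
                          schema = NULL, n_cases = NULL, n_controls = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(trait_id)) trait_id <- sub("\\.[^.]*$", "", basename(path))
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1L))
  dt <- as.data.frame(dt)

  colmap <- stats::setNames(CANONICAL_COLS, CANONICAL_COLS)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), CANONICAL_COLS)
    if (length(bad)) stop("unknown canonical names in schema: ", paste(bad, collapse = ", "))
    colmap[names(schema)] <- schema
  }
  missing_cols <- colmap[!colmap %in% names(dt)]
  if (length(missing_cols)) {
    stop("missing required column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, unname(colmap)]
  names(dt) <- CANONICAL_COLS

  for (col in c("beta", "se")) {
    raw <- dt[[col]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & tolower(raw) != "na" & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric %s at line %d of %s: '%s'",
                   col, bad[1] + 1L, path, raw[bad[1]]))
    }
    dt[[col]] <- num
  }
  assoc_dataset(dt, trait_id = trait_id, trait_type = trait_type,
                n_cases = n_cases, n_controls = n_controls)
}

#' Write an association dataset as tab-delimited text
#'
#' Inverse of [read_sumstats()] for the canonical TSV dialect; numeric
#' fields are written at full precision so a read/write round trip is
#' lossless.
#'
#' @param x an `assoc_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "assoc_dataset"))
  out <- x$records
  # 17 significant digits round-trip doubles exactly
  for (col in c("pos", "eaf", "beta", "se", "p", "n")) {
    out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct an LD correlation matrix for a cis-region
#'
#' @param r square numeric matrix of pairwise allelic correlations, aligned
#'   to each variant's effect allele.
#' @param snp_ids character vector of SNP ids, one per row/column.
#' @param ea optional per-SNP effect alleles of the LD reference (used to
#'   sign-align against a dataset during harmonization).
#' @param eaf optional per-SNP effect-allele frequencies of the reference
#'   panel (used by the allele-frequency QC rule).
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r, snp_ids, ea = NULL, eaf = NULL) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r), length(snp_ids) == nrow(r))
  if (max(abs(r - t(r))) > 1e-8) stop("LD matrix is not symmetric")
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + 1e-8) stop("LD correlations must lie in [-1, 1]")
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6) {
    warning(sprintf("LD matrix is not PSD (min eigenvalue %.2e)", min(ev)))
  }
  dimnames(r) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r = r, ea = ea, eaf = eaf),
            class = "ld_matrix")
}

#' Read an LD matrix from TSV (square or long triplet format)
#'
#' Square format: header row of SNP ids, first column of SNP ids, numeric
#' body. Long format: three columns `snp_i, snp_j, r` (missing pairs
#' default to 0, the diagonal to 1).
#'
#' @param path file path.
#' @param format `"auto"`, `"square"` or `"long"`.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, format = c("auto", "square", "long")) {
  format <- match.arg(format)
  dt <- as.data.frame(data.table::fread(path, header = TRUE))
  if (format == "auto") {
    format <- if (ncol(dt) == 3L && !is.numeric(dt[[2]])) "long" else "square"
  }
  if (format == "long") {
    ids <- sort(unique(c(as.character(dt[[1]]), as.character(dt[[2]]))))
    r <- diag(length(ids))
    dimnames(r) <- list(ids, ids)
    i <- match(as.character(dt[[1]]), ids)
    j <- match(as.character(dt[[2]]), ids)
    r[cbind(i, j)] <- dt[[3]]
    r[cbind(j, i)] <- dt[[3]]
    return(ld_matrix(r, ids))
  }
  ids <- as.character(dt[[1]])
  r <- as.matrix(dt[, -1, drop = FALSE])
  ld_matrix(r, ids)
}

#' Write an LD matrix as square TSV
#' @param x an `ld_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(x, path) {
  stopifnot(inherits(x, "ld_matrix"))
  out <- data.frame(snp = x$snp_ids, x$r, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read probe annotations from BED-like TSV
#'
#' Expects columns `chrom, start, end, probe_id, gene_id, layer` in BED's
#' 0-based half-open convention; coordinates are converted to the package's
#' 1-based inclusive convention on load.
#'
#' @param path file path.
#' @return data.frame with columns `probe_id, gene_id, chr, start, end,
#'   layer` (1-based inclusive).
#' @export
read_probes <- function(path) {
  dt <- as.data.frame(data.table::fread(
    path, header = FALSE,
    col.names = c("chr", "start", "end", "probe_id", "gene_id", "layer")))
  if (!all(dt$layer %in% c("methylation", "expression", "protein"))) {
    stop("layer must be one of methylation/expression/protein")
  }
  out <- data.frame(probe_id = as.character(dt$probe_id),
                    gene_id = as.character(dt$gene_id),
                    chr = as.character(dt$chr),
                    start = as.integer(dt$start) + 1L,  # BED 0-based -> 1-based
                    end = as.integer(dt$end),
                    layer = dt$layer, stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("probe annotation with start > end")
  out
}

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

#' Harmonize an exposure/outcome dataset pair against an LD reference
#'
#' Restricts both datasets (and the LD matrix) to their shared SNPs, aligns
#' the outcome to the exposure's effect allele (sign-flipping betas and
#' complementing allele frequencies where effect/other alleles are
#' swapped), drops strand-ambiguous palindromic SNPs (A/T, C/G), drops
#' SNPs whose alleles cannot be reconciled, and excludes any SNP whose
#' effect-allele frequency differs by more than `eaf_tol` between any pair
#' of exposure, outcome and LD reference. LD rows/columns are subset and
#' sign-adjusted to the exposure's allele convention.
#'
#' @param exposure,outcome `assoc_dataset` objects.
#' @param ld optional `ld_matrix` covering the shared SNPs.
#' @param eaf_tol maximum tolerated pairwise allele-frequency difference
#'   (default 0.2).
#' @param drop_palindromic drop strand-ambiguous SNPs (default `TRUE`).
#' @return list with elements `exposure`, `outcome` (aligned
#'   `assoc_dataset`s over the same SNPs, same order) and `ld` (subset
#'   `ld_matrix` or `NULL`).
#' @export
harmonize <- function(exposure, outcome, ld = NULL, eaf_tol = 0.2,
                      drop_palindromic = TRUE) {
  stopifnot(inherits(exposure, "assoc_dataset"), inherits(outcome, "assoc_dataset"))
  ex <- exposure$records
  ou <- outcome$records
  shared <- intersect(ex$snp, ou$snp)
  if (!is.null(ld)) shared <- intersect(shared, ld$snp_ids)
  if (length(shared) == 0L) stop("no overlapping SNPs between exposure and outcome")
  ex <- ex[match(shared, ex$snp), , drop = FALSE]
  ou <- ou[match(shared, ou$snp), , drop = FALSE]

  same <- ou$ea == ex$ea & ou$oa == ex$oa
  swapped <- ou$ea == ex$oa & ou$oa == ex$ea
  keep <- same | swapped
  if (drop_palindromic) keep <- keep & !is_palindromic(ex$ea, ex$oa)

  flip <- swapped
  ou$beta[flip] <- -ou$beta[flip]
  ou$eaf[flip] <- 1 - ou$eaf[flip]
  ou$ea[flip] <- ex$ea[flip]
  ou$oa[flip] <- ex$oa[flip]

  ld_sign <- rep(1, length(shared))
  ld_eaf <- rep(NA_real_, length(shared))
  if (!is.null(ld) && !is.null(ld$ea)) {
    lea <- toupper(ld$ea[match(shared, ld$snp_ids)])
    ld_swapped <- lea == ex$oa
    ld_same <- lea == ex$ea
    keep <- keep & (ld_same | ld_swapped)
    ld_sign[ld_swapped] <- -1
    if (!is.null(ld$eaf)) {
      ld_eaf <- ld$eaf[match(shared, ld$snp_ids)]
      ld_eaf[ld_swapped] <- 1 - ld_eaf[ld_swapped]
    }
  } else if (!is.null(ld) && !is.null(ld$eaf)) {
    ld_eaf <- ld$eaf[match(shared, ld$snp_ids)]
  }

  # allele-frequency QC across every dataset pair, LD reference included
  eaf_diff <- abs(ex$eaf - ou$eaf)
  if (any(!is.na(ld_eaf))) {
    eaf_diff <- pmax(eaf_diff,
                     abs(ex$eaf - ld_eaf), abs(ou$eaf - ld_eaf), na.rm = TRUE)
  }
  keep <- keep & eaf_diff <= eaf_tol

  if (!any(keep)) stop("no SNPs left after harmonization")
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  rownames(ex) <- rownames(ou) <- NULL

  ld_out <- NULL
  if (!is.null(ld)) {
    idx <- match(ex$snp, ld$snp_ids)
    s <- ld_sign[keep]
    r <- ld$r[idx, idx, drop = FALSE] * tcrossprod(s)
    ld_out <- ld_matrix(r, ex$snp, ea = ex$ea,
                        eaf = if (any(!is.na(ld_eaf))) ld_eaf[keep] else NULL)
  }

  list(
    exposure = assoc_dataset(ex, exposure$trait_id, exposure$trait_type,
                             exposure$n_cases, exposure$n_controls),
    outcome = assoc_dataset(ou, outcome$trait_id, outcome$trait_type,
                            outcome$n_cases, outcome$n_controls),
    ld = ld_out)
}

#' Compute a cis-window around a probe or its top SNP
#'
#' @param probe one-row data.frame (or list) with `start`, `end` (1-based
#'   inclusive); ignored when `anchor = "top_snp"`.
#' @param flank flank size in bp, must be positive.
#' @param anchor `"gene_body"` (window around the annotated feature) or
#'   `"top_snp"` (window around a given position).
#' @param top_snp_pos position of the anchoring SNP; required iff
#'   `anchor = "top_snp"`.
#' @return numeric vector `c(start, end)`, 1-based inclusive, lower bound
#'   clipped at 1.
#' @export
cis_window <- function(probe = NULL, flank, anchor = c("gene_body", "top_snp"),
                       top_snp_pos = NULL) {
  anchor <- match.arg(anchor)
  if (!is.numeric(flank) || length(flank) != 1L || flank <= 0) {
    stop("flank must be a positive number of bp")
  }
  if (anchor == "top_snp") {
    if (is.null(top_snp_pos)) stop("top_snp_pos required when anchor = 'top_snp'")
    lo <- top_snp_pos - flank
    hi <- top_snp_pos + flank
  } else {
    if (is.null(probe)) stop("probe required when anchor = 'gene_body'")
    if (!is.null(top_snp_pos)) stop("top_snp_pos only valid with anchor = 'top_snp'")
    lo <- probe$start - flank
    hi <- probe$end + flank
  }
  c(start = max(1, lo), end = hi)
}
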