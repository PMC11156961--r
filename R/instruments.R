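#' Construct an LD matrix object
#'
#' @param r square numeric matrix of pairwise correlations in \[-1, 1\].
#' @param variant_ids variant identifiers, in matrix order.
#' @return `ld_matrix` object.
#' @export
ld_matrix <- function(r, variant_ids = rownames(r)) {
  r <- as.matrix(r)
  if (is.null(variant_ids)) stopf("ld_matrix needs variant ids")
  if (nrow(r) != ncol(r) || nrow(r) != length(variant_ids)) {
    stopf("LD matrix dimension (%d x %d) does not match %d variant ids",
          nrow(r), ncol(r), length(variant_ids))
  }
  if (max(abs(r - t(r))) > 1e-8) stopf("LD matrix must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) stopf("LD matrix must have unit diagonal")
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r = r),
            class = "ld_matrix")
}

#' Pairwise LD from a genotype dosage matrix
#'
#' @param dosage samples x variants numeric matrix of allele dosages.
#' @return `ld_matrix` of Pearson correlations.
#' @export
ld_from_dosage <- function(dosage) {
  if (is.null(colnames(dosage))) stopf("dosage matrix needs variant colnames")
  ld_matrix(stats::cor(dosage), colnames(dosage))
}

#' Select cis candidate instruments for a protein
#'
#' Retains variants on the protein's chromosome within `window` bp of the
#' transcription start site (inclusive at both ends), with association
#' p-value below `p_max` and minor allele frequency at least `maf_min`.
#'
#' @param assoc `assoc_table` of pQTL summary statistics for the protein.
#' @param meta list or one-row data.frame with `chrom` and `tss` (and
#'   optionally `protein_id`, `gene_symbol`).
#' @param p_max p-value threshold (default 1e-5).
#' @param window distance to TSS in bp (default 250 kb).
#' @param maf_min minimum minor allele frequency (default 0.01; 0.05 in
#'   replication mode).
#' @return filtered `assoc_table` (possibly zero rows).
#' @export
select_cis <- function(assoc, meta, p_max = 1e-5, window = 250000L,
                       maf_min = 0.01) {
  if (is.null(meta$chrom) || is.null(meta$tss)) stopf("meta needs chrom and tss")
  maf <- pmin(assoc$eaf, 1 - assoc$eaf)
  keep <- assoc$chrom == as.character(meta$chrom) &
    abs(assoc$pos - as.integer(meta$tss)) <= window &
    assoc$pvalue < p_max &
    maf >= maf_min
  out <- assoc[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: repeatedly take the remaining variant with the
#' smallest p-value (ties broken by larger |beta/se|, then by lexicographic
#' variant id), keep it, and discard all remaining variants with r-squared at
#' or above `r2_max` to it. The returned set is mutually independent at
#' r-squared below `r2_max` and is invariant to the input row order.
#'
#' @param candidates `assoc_table` of cis candidates.
#' @param ld `ld_matrix` covering the candidates; candidates missing from the
#'   LD matrix are dropped with a warning.
#' @param r2_max r-squared threshold (default 0.1).
#' @return clumped `assoc_table`.
#' @export
ld_clump <- function(candidates, ld, r2_max = 0.1) {
  if (!nrow(candidates)) return(candidates)
  present <- candidates$variant_id %in% ld$variant_ids
  if (any(!present)) {
    warnf("%d candidate(s) missing from the LD matrix were dropped", sum(!present))
    candidates <- candidates[present, , drop = FALSE]
  }
  if (!nrow(candidates)) return(candidates)
  z <- abs(candidates$beta / candidates$se)
  ord <- order(candidates$pvalue, -z, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  r2 <- ld$r[cand$variant_id, cand$variant_id, drop = FALSE]^2
  alive <- rep(TRUE, nrow(cand))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    alive[alive & r2[i, ] >= r2_max] <- FALSE
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument strength F-statistic
#'
#' Per-instrument approximate F-statistic beta^2 / se^2; values above 10 are
#' conventionally considered adequate instrument strength.
#'
#' @param beta effect size(s).
#' @param se standard error(s), all positive.
#' @return numeric F value(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stopf("f_statistic requires se > 0")
  (beta / se)^2
}

#' QC decision for a protein's instrument set
#'
#' A protein is analyzable when it has at least `min_iv` independent cis
#' instruments. Low-F instruments are flagged (not removed) unless
#' `drop_low_f` is set; instrument strength is a reported property, not a
#' default filter.
#'
#' @param instruments `assoc_table` or `harmonized_table` with `beta_x`/`se_x`
#'   (or `beta`/`se`) columns.
#' @param min_iv minimum instrument count (default 3).
#' @param f_min F-statistic flag threshold (default 10).
#' @param drop_low_f drop instruments with F below `f_min`.
#' @return list with `analyzable`, `n_iv`, `f`, `min_f`, `median_f`,
#'   `n_low_f`, `instruments`.
#' @export
qc_instrument_set <- function(instruments, min_iv = 3L, f_min = 10,
                              drop_low_f = FALSE) {
  beta <- instruments$beta_x %||% instruments$beta
  se <- instruments$se_x %||% instruments$se
  f <- if (length(beta)) f_statistic(beta, se) else numeric(0)
  if (drop_low_f && length(f)) {
    instruments <- instruments[f >= f_min, , drop = FALSE]
    f <- f[f >= f_min]
  }
  n <- nrow(instruments)
  list(
    analyzable = n >= min_iv,
    n_iv = n,
    f = f,
    min_f = if (length(f)) min(f) else NA_real_,
    median_f = if (length(f)) median(f) else NA_real_,
    n_low_f = sum(f < f_min),
    instruments = instruments
  )
}
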