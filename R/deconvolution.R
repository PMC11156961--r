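# Lawson-Hanson active-set non-negative least squares: min ||Ax - b|| s.t.
# x >= 0. Written here because no NNLS solver ships with the installed stack.
nnls_fit <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  p <- ncol(A)
  tol <- tol %||% (1e-10 * max(abs(crossprod(A, b))))
  x <- numeric(p)
  passive <- rep(FALSE, p)
  w <- as.vector(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * p) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(p)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- as.vector(qr.coef(qr(Ap), b))
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) break
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- z
    w <- as.vector(crossprod(A, b - A %*% x))
  }
  x
}

#' Select cell-type signature genes from a reference
#'
#' For each cell type, genes are scored by the ratio of their expression in
#' that type to the second-highest expression across types (plus a small
#' epsilon); the top `n_per_type` genes per type are retained and the union
#' returned. Flat genes with no specificity score near 1 and are only picked
#' to fill quota.
#'
#' @param ref signature genes x cell types non-negative matrix.
#' @param n_per_type genes kept per cell type (default 50).
#' @param eps stabilizer in the specificity ratio (default 1e-8).
#' @return character vector of selected gene names.
#' @export
select_signature_genes <- function(ref, n_per_type = 50L, eps = 1e-8) {
  ref <- as.matrix(ref)
  if (is.null(rownames(ref))) stopf("reference needs gene rownames")
  picked <- character(0)
  for (ct in seq_len(ncol(ref))) {
    other_max <- apply(ref[, -ct, drop = FALSE], 1, max)
    score <- ref[, ct] / (other_max + eps)
    ord <- order(-score, rownames(ref))
    picked <- union(picked, rownames(ref)[ord][seq_len(min(n_per_type, nrow(ref)))])
  }
  picked
}

# Map each column of `mat` onto the pooled empirical distribution of `target`
# by rank (quantile normalization against a fixed reference distribution).
quantile_normalize_to <- function(mat, target) {
  tq <- sort(as.vector(target))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    r <- rank(mat[, j], ties.method = "average")
    q <- (r - 0.5) / nrow(mat)
    out[, j] <- stats::quantile(tq, probs = q, names = FALSE, type = 4)
  }
  out
}

#' Reference-based digital cell quantification
#'
#' Deconvolution in the GEDIT mould: signature genes are selected with
#' [select_signature_genes()]; each signature gene's reference and bulk
#' values are scaled to \[0, 1\] by the gene's reference maximum and raised
#' to `row_power` (damping dominant genes); per-sample proportions solve a
#' non-negative least squares of the scaled bulk profile on the scaled
#' reference and are renormalized to sum to 1. The row transform is
#' positively homogeneous (no per-gene shift), so proportions are exactly
#' invariant to a global rescaling of a bulk sample, a bulk column equal to
#' a reference column recovers that cell type exactly, and (at
#' `row_power = 1`) noiseless mixtures are recovered exactly. Optional
#' quantile normalization against a target distribution is available for
#' cross-platform inputs but is off by default because it distorts
#' same-platform mixtures.
#'
#' @param bulk genes x samples matrix (non-negative expression scale).
#' @param ref signature genes x cell types reference matrix.
#' @param row_power row-scaling exponent (default 0.9).
#' @param n_per_type signature genes per cell type (default 50).
#' @param min_overlap minimum fraction of signature genes that must be
#'   present in the bulk matrix (default 0.5).
#' @param quantile_target optional numeric vector; when supplied, bulk
#'   columns are quantile-normalized onto its empirical distribution before
#'   deconvolution (cross-platform mode).
#' @return samples x cell types proportion matrix (rows sum to 1).
#' @export
estimate_proportions <- function(bulk, ref, row_power = 0.9,
                                 n_per_type = 50L, min_overlap = 0.5,
                                 quantile_target = NULL) {
  bulk <- as.matrix(bulk); ref <- as.matrix(ref)
  rownames(bulk) <- norm_symbol(rownames(bulk))
  rownames(ref) <- norm_symbol(rownames(ref))
  if (any(ref < 0)) stopf("reference must be non-negative")
  sig <- select_signature_genes(ref, n_per_type = n_per_type)
  overlap <- intersect(sig, rownames(bulk))
  frac <- length(overlap) / length(sig)
  if (frac < min_overlap) {
    stopf("bulk covers only %.1f%% of signature genes (need >= %.0f%%)",
          100 * frac, 100 * min_overlap)
  }
  if (!is.null(quantile_target)) {
    bulk <- quantile_normalize_to(bulk, quantile_target)
  }
  R <- ref[overlap, , drop = FALSE]
  B <- pmax(bulk[overlap, , drop = FALSE], 0)
  hi <- pmax(apply(R, 1, max), .Machine$double.xmin)
  Rs <- (R / hi)^row_power
  Bs <- (B / hi)^row_power
  props <- t(apply(Bs, 2, function(y) {
    x <- nnls_fit(Rs, y)
    if (sum(x) <= 0) rep(1 / ncol(Rs), ncol(Rs)) else x / sum(x)
  }))
  dimnames(props) <- list(colnames(bulk), colnames(ref))
  props
}

#' Compare cell-type proportions between groups
#'
#' Unpaired two-sided Student's t-test per cell type, BH-adjusted across
#' types. Cell types with zero variance in both groups and equal means are
#' reported with p = 1 and a warning.
#'
#' @param props samples x cell types proportion matrix.
#' @param groups length-nrow factor/character with two levels.
#' @return data.frame: `cell_type`, `mean_a`, `mean_b`, `t`, `pvalue`, `fdr`.
#' @export
compare_proportions <- function(props, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("exactly two groups required")
  if (any(table(groups) < 2)) stopf("each group needs n >= 2")
  a <- groups == levels(groups)[1]
  b <- groups == levels(groups)[2]
  rows <- lapply(colnames(props) %||% seq_len(ncol(props)), function(ct) {
    xa <- props[a, ct]; xb <- props[b, ct]
    if (sd(xa) == 0 && sd(xb) == 0) {
      if (mean(xa) == mean(xb)) {
        warnf("cell type '%s' is constant in both groups; p set to 1", ct)
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- list(statistic = sign(mean(xa) - mean(xb)) * Inf, p.value = 0)
      }
    } else {
      ht <- t.test(xa, xb)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(cell_type = as.character(ct), mean_a = mean(xa),
               mean_b = mean(xb), t = tt$statistic, pvalue = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- adjust_multiplicity(out$pvalue, "BH")
  out
}

#' PCA sample scores by singular value decomposition
#'
#' Columns are centered and scaled to unit variance (zero-variance columns
#' dropped with a warning) before SVD.
#'
#' @param mat samples x features matrix.
#' @param scale scale columns to unit variance (default TRUE).
#' @return list: `scores` (samples x PCs), `explained` (variance fractions,
#'   summing to 1), `sdev`.
#' @export
pca_scores <- function(mat, scale = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stopf("PCA needs >= 2 samples")
  v <- apply(mat, 2, var)
  if (scale && any(v == 0)) {
    warnf("%d zero-variance feature(s) dropped before PCA", sum(v == 0))
    mat <- mat[, v > 0, drop = FALSE]
  }
  if (ncol(mat) < 2) stopf("PCA needs >= 2 (non-constant) features")
  pc <- prcomp(mat, center = TRUE, scale. = scale)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained = expl, sdev = pc$sdev)
}
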