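#' Per-sample differential expression profile
#'
#' Centers each gene by its mean over a centering group: the grand mean
#' across all samples (default; both groups are scored) or the control-group
#' mean. The two modes differ per gene only by an additive constant.
#'
#' @param expr genes x samples normalized log-scale matrix.
#' @param centering `"grand_mean"` or `"control_mean"`.
#' @param groups required for `"control_mean"`: factor/character per sample;
#'   the first level is the control group.
#' @return genes x samples matrix of differential profiles.
#' @export
response_profile <- function(expr, centering = c("grand_mean", "control_mean"),
                             groups = NULL) {
  centering <- match.arg(centering)
  expr <- as.matrix(expr)
  center <- if (centering == "grand_mean") {
    rowMeans(expr)
  } else {
    if (is.null(groups)) stopf("control_mean centering needs groups")
    groups <- as.factor(groups)
    rowMeans(expr[, groups == levels(groups)[1], drop = FALSE])
  }
  expr - center
}

#' Ridge-regression cytokine activity with permutation z-scores
#'
#' For each sample profile y, solves the ridge system
#' beta = (S'S + lambda I)^-1 S'y on the genes shared with the signature
#' matrix S (genes x cytokines of expected log-fold responses). The activity
#' z-score standardizes each coefficient against a null built from `n_perm`
#' seeded permutations of the gene labels of y.
#'
#' @param profile genes x samples differential profile (from
#'   [response_profile()]).
#' @param sig genes x cytokines signature matrix.
#' @param lambda ridge penalty (default 1e4).
#' @param n_perm permutations for the null (default 1000).
#' @param seed RNG seed.
#' @param min_overlap minimum shared genes (default 100).
#' @return samples x cytokines matrix of activity z-scores; raw coefficients
#'   in attribute `beta`.
#' @export
ridge_activity <- function(profile, sig, lambda = 1e4, n_perm = 1000L,
                           seed = NULL, min_overlap = 100L) {
  profile <- as.matrix(profile); sig <- as.matrix(sig)
  rownames(profile) <- norm_symbol(rownames(profile))
  rownames(sig) <- norm_symbol(rownames(sig))
  if (any(colSums(sig != 0) == 0)) stopf("signature has an all-zero cytokine column")
  shared <- intersect(rownames(profile), rownames(sig))
  if (length(shared) < min_overlap) {
    stopf("only %d genes overlap the signature (need >= %d)",
          length(shared), min_overlap)
  }
  S <- sig[shared, , drop = FALSE]
  Y <- profile[shared, , drop = FALSE]
  M <- solve(crossprod(S) + diag(lambda, ncol(S)), t(S))  # cytokines x genes
  beta <- M %*% Y                                          # cytokines x samples
  z <- with_seed(seed, {
    g <- length(shared)
    perm_idx <- replicate(n_perm, sample.int(g))
    out <- matrix(NA_real_, ncol(S), ncol(Y))
    for (j in seq_len(ncol(Y))) {
      Yp <- matrix(Y[as.vector(perm_idx), j], nrow = g)
      Bp <- M %*% Yp                                       # cytokines x n_perm
      mu <- rowMeans(Bp)
      sdv <- apply(Bp, 1, sd)
      out[, j] <- (beta[, j] - mu) / ifelse(sdv > 0, sdv, 1)
    }
    out
  })
  acts <- t(z)
  dimnames(acts) <- list(colnames(profile), colnames(sig))
  attr(acts, "beta") <- t(beta)
  acts
}

#' Differential cytokine activity between groups
#'
#' Wilcoxon rank-sum test per cytokine: exact p-values when both groups have
#' at most 12 samples and no ties, normal approximation with tie and
#' continuity correction otherwise. BH FDR across cytokines.
#'
#' @param acts samples x cytokines activity matrix.
#' @param groups length-nrow factor/character with two levels.
#' @return data.frame: `cytokine`, `median_a`, `median_b`, `pvalue`, `fdr`.
#' @export
differential_activity <- function(acts, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("exactly two groups required")
  if (any(table(groups) < 3)) stopf("each group needs n >= 3")
  a <- groups == levels(groups)[1]
  b <- groups == levels(groups)[2]
  rows <- lapply(colnames(acts) %||% seq_len(ncol(acts)), function(ck) {
    xa <- acts[a, ck]; xb <- acts[b, ck]
    exact <- length(xa) <= 12 && length(xb) <= 12 &&
      !any(duplicated(c(xa, xb)))
    wt <- suppressWarnings(
      wilcox.test(xa, xb, exact = exact, correct = TRUE)
    )
    data.frame(cytokine = as.character(ck), median_a = median(xa),
               median_b = median(xb), pvalue = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- adjust_multiplicity(out$pvalue, "BH")
  out
}

#' Cytokine activity correlation dendrogram
#'
#' Pearson correlation between cytokine activity vectors (across samples),
#' then agglomerative clustering of the cytokines using the Euclidean
#' distance between their correlation profiles. Zero-variance cytokines are
#' excluded with a warning. The tree can be serialized to Newick.
#'
#' @param acts samples x cytokines activity matrix (>= 3 cytokines).
#' @param linkage hclust linkage (default "complete").
#' @return list: `correlation` (cytokines x cytokines), `tree` (hclust),
#'   `newick` (character).
#' @export
activity_dendrogram <- function(acts, linkage = "complete") {
  acts <- as.matrix(acts)
  v <- apply(acts, 2, var)
  if (any(v == 0)) {
    warnf("%d zero-variance cytokine(s) excluded from the dendrogram", sum(v == 0))
    acts <- acts[, v > 0, drop = FALSE]
  }
  if (ncol(acts) < 3) stopf("dendrogram needs >= 3 (non-constant) cytokines")
  cc <- cor(acts)
  tree <- hclust(dist(cc, method = "euclidean"), method = linkage)
  phy <- ape::as.phylo(tree)
  list(correlation = cc, tree = tree,
       newick = ape::write.tree(phy))
}
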