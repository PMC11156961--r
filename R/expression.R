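#' Variance-stabilizing generalized-log normalization
#'
#' Approximates vsn-style normalization by (i) per-sample affine calibration
#' to a common location and spread (each sample is shifted and scaled so its
#' median and MAD match the across-sample medians of those statistics) and
#' (ii) the generalized-log transform glog2(x) = log2((x + sqrt(x^2 + c^2))/2).
#' Under the additive + multiplicative error model
#' x = mu exp(eta) + epsilon the glog variance is exactly constant when
#' c equals sd(epsilon)/sd(eta), so the offset is set to that ratio using
#' robust moment estimates: the additive SD from the spread of
#' bottom-decile-intensity features and the multiplicative SD from the
#' coefficient of variation of top-decile features. When the estimate is
#' degenerate (single sample, or noise-free data) the offset falls back to
#' the 5th percentile of the calibrated intensities. For x >> c the
#' transform converges to log2(x); near zero it stays finite, damping the
#' additive-noise variance inflation of low intensities.
#'
#' @param raw features x samples numeric matrix (background-corrected
#'   intensities; small negative values tolerated).
#' @return matrix of the same shape on the glog2 scale (attribute `offset`
#'   records the fitted c).
#' @export
glog_normalize <- function(raw) {
  raw <- as.matrix(raw)
  if (any(!is.finite(raw))) stopf("non-finite values in expression matrix")
  med <- apply(raw, 2, median)
  spread <- apply(raw, 2, mad)
  t_med <- median(med)
  t_spread <- median(spread)
  cal <- raw
  for (j in seq_len(ncol(raw))) {
    s <- if (spread[j] > 0 && t_spread > 0) t_spread / spread[j] else 1
    cal[, j] <- (raw[, j] - med[j]) * s + t_med
  }
  c0 <- NA_real_
  if (ncol(cal) >= 2L) {
    m <- rowMeans(cal)
    s <- apply(cal, 1, sd)
    lo <- m <= quantile(m, 0.1)
    hi <- m >= quantile(m, 0.9)
    sd_add <- median(s[lo])
    sd_mult <- median(s[hi] / pmax(m[hi], .Machine$double.eps))
    if (is.finite(sd_add) && is.finite(sd_mult) &&
        sd_add > 0 && sd_mult > 0) {
      c0 <- sd_add / sd_mult
    }
  }
  if (!is.finite(c0) || c0 <= 0) {
    c0 <- max(abs(quantile(cal, 0.05, names = FALSE)), .Machine$double.eps)
  }
  out <- log2((cal + sqrt(cal^2 + c0^2)) / 2)
  attr(out, "offset") <- c0
  out
}

#' Collapse probes to genes by per-sample median
#'
#' @param mat probes x samples matrix; rownames (or attribute `feature_id`)
#'   are probe ids.
#' @param probe_map named character vector probe -> gene symbol.
#' @return genes x samples matrix; unmapped probes dropped, count in
#'   attribute `n_unmapped`.
#' @export
collapse_probes <- function(mat, probe_map) {
  probes <- attr(mat, "feature_id") %||% rownames(mat)
  genes <- norm_symbol(probe_map[probes])
  mapped <- !is.na(genes) & nzchar(genes)
  n_unmapped <- sum(!mapped)
  m <- mat[mapped, , drop = FALSE]
  genes <- genes[mapped]
  ug <- sort(unique(genes))
  out <- matrix(NA_real_, length(ug), ncol(mat),
                dimnames = list(ug, colnames(mat)))
  for (g in ug) {
    rows <- m[genes == g, , drop = FALSE]
    out[g, ] <- apply(rows, 2, median)
  }
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Per-gene two-group comparison with variance moderation: residual
#' variances s_g^2 (d_g = n1 + n2 - 2 df) are shrunk toward a common prior
#' via the scaled-F method-of-moments fit (limma's `squeezeVar`), giving the
#' posterior s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g); the moderated t is
#' log2fc / (s~_g sqrt(1/n1 + 1/n2)) on d0 + d_g df, with BH FDR across
#' genes. `d0_override = 0` reduces to the ordinary t-test;
#' `d0_override = Inf` pools all genes to the prior variance.
#'
#' @param mat genes x samples log2-scale matrix.
#' @param groups length-ncol factor/character with two levels; log2fc is
#'   second level minus first (case minus control when control is the first
#'   level).
#' @param d0_override optional prior df override (testing/limit cases).
#' @return data.frame: `gene`, `log2fc`, `t`, `pvalue`, `fdr`.
#' @export
moderated_t <- function(mat, groups, d0_override = NULL) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("exactly two groups required")
  if (any(table(groups) < 2)) stopf("each group needs n >= 2")
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  lfc <- m2 - m1
  ss1 <- rowSums((mat[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((mat[, g2, drop = FALSE] - m2)^2)
  dg <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / dg
  if (is.null(d0_override)) {
    sq <- limma::squeezeVar(s2, df = dg)
    d0 <- sq$df.prior
    post <- sq$var.post
  } else {
    d0 <- d0_override
    s02 <- limma::squeezeVar(s2, df = dg)$var.prior
    post <- if (is.infinite(d0)) rep(s02, length(s2)) else
      (d0 * s02 + dg * s2) / (d0 + dg)
  }
  tstat <- lfc / sqrt(post * (1 / n1 + 1 / n2))
  df_total <- dg + d0
  pv <- 2 * pt(-abs(tstat), df = df_total)
  pv[is.na(pv) & lfc == 0] <- 1
  data.frame(
    gene = rownames(mat) %||% as.character(seq_along(lfc)),
    log2fc = lfc, t = tstat, pvalue = pv,
    fdr = adjust_multiplicity(pv, "BH"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Filter differential-expression results
#'
#' Keeps genes with |log2fc| strictly above `lfc_min` and FDR strictly below
#' `fdr_max` (the reporting thresholds for valve leaflet DE genes).
#'
#' @param results data.frame from [moderated_t()].
#' @param lfc_min absolute log2 fold-change threshold (default 1.25).
#' @param fdr_max FDR threshold (default 0.05).
#' @return filtered data.frame with attribute `n_de`.
#' @export
de_filter <- function(results, lfc_min = 1.25, fdr_max = 0.05) {
  keep <- abs(results$log2fc) > lfc_min & results$fdr < fdr_max
  out <- results[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_de") <- nrow(out)
  out
}

# Weighted KS enrichment score from hit positions within a ranking.
# positions: sorted rank positions of set members; w: |score|^p at those
# positions; N: universe size. Returns the signed maximal deviation.
gsea_es <- function(positions, w, N) {
  K <- length(positions)
  d <- 1 / (N - K)
  csum <- cumsum(w) / sum(w)
  idx <- seq_len(K)
  after_hit <- csum - (positions - idx) * d
  before_hit <- c(0, csum[-K]) - (positions - idx) * d
  hi <- max(after_hit)
  lo <- min(c(before_hit, 0))
  if (hi >= -lo) hi else lo
}

#' Gene-set enrichment analysis on a fold-change ranking
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic on genes ordered by
#' decreasing score (fold change): hit increments proportional to
#' |score|^`p`, uniform miss decrements. Significance by seeded gene-label
#' permutation: each permutation redraws the set positions at random. NES is
#' ES divided by the mean |ES| of same-sign permutations; the FDR follows the
#' standard pooled positive/negative procedure.
#'
#' @param scores named numeric vector (gene -> ranking score).
#' @param sets named list of gene sets.
#' @param n_perm permutations per set (default 1000).
#' @param seed RNG seed.
#' @param p weighting exponent (default 1; 0 gives the classic KS).
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked universe (defaults 10 and 500).
#' @return data.frame: `set_name`, `size`, `es`, `nes`, `pvalue`, `fdr`.
#' @export
gsea <- function(scores, sets, n_perm = 1000L, seed = NULL, p = 1,
                 min_size = 10L, max_size = 500L) {
  if (is.null(names(scores))) stopf("scores must be a named vector")
  ord <- order(scores, decreasing = TRUE)
  genes <- norm_symbol(names(scores))[ord]
  sc <- abs(scores[ord])^p
  N <- length(genes)
  rank_of <- setNames(seq_len(N), genes)

  sizes <- integer(0); keep_sets <- list()
  for (nm in names(sets)) {
    members <- intersect(unique(norm_symbol(sets[[nm]])), genes)
    if (length(members) >= N) stopf("set '%s' covers the whole universe", nm)
    if (length(members) >= min_size && length(members) <= max_size) {
      keep_sets[[nm]] <- members
      sizes <- c(sizes, length(members))
    }
  }
  if (!length(keep_sets)) {
    return(data.frame(set_name = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      pvalue = numeric(0), fdr = numeric(0)))
  }

  with_seed(seed, {
    res <- lapply(names(keep_sets), function(nm) {
      pos <- sort(unname(rank_of[keep_sets[[nm]]]))
      es <- gsea_es(pos, sc[pos], N)
      es_perm <- vapply(seq_len(n_perm), function(b) {
        pp <- sort(sample.int(N, length(pos)))
        gsea_es(pp, sc[pp], N)
      }, numeric(1))
      pos_mean <- mean(es_perm[es_perm > 0])
      neg_mean <- mean(abs(es_perm[es_perm < 0]))
      nes <- if (es >= 0) es / pos_mean else -abs(es) / neg_mean
      nes_perm <- ifelse(es_perm >= 0, es_perm / pos_mean,
                         -abs(es_perm) / neg_mean)
      same <- if (es >= 0) es_perm >= 0 else es_perm < 0
      pv <- (1 + sum(same & abs(es_perm) >= abs(es))) / (1 + sum(same))
      list(set_name = nm, size = length(pos), es = es, nes = nes,
           pvalue = pv, nes_perm = nes_perm)
    })
    nes_all <- vapply(res, `[[`, numeric(1), "nes")
    pool <- unlist(lapply(res, `[[`, "nes_perm"))
    fdr <- vapply(nes_all, function(v) {
      if (is.na(v)) return(NA_real_)
      if (v >= 0) {
        num <- mean(pool[pool >= 0] >= v)
        den <- mean(nes_all[nes_all >= 0] >= v)
      } else {
        num <- mean(pool[pool < 0] <= v)
        den <- mean(nes_all[nes_all < 0] <= v)
      }
      min(1, num / max(den, .Machine$double.eps))
    }, numeric(1))
    out <- data.frame(
      set_name = vapply(res, `[[`, "", "set_name"),
      size = vapply(res, `[[`, integer(1), "size"),
      es = vapply(res, `[[`, numeric(1), "es"),
      nes = nes_all,
      pvalue = vapply(res, `[[`, numeric(1), "pvalue"),
      fdr = fdr, stringsAsFactors = FALSE
    )
    out[order(out$pvalue, out$set_name), , drop = FALSE]
  })
}
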