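mr_result <- function(method, theta, se, n_iv, pvalue = NULL, ci_level = 0.95) {
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  pvalue <- pvalue %||% (2 * pnorm(-abs(theta / se)))
  list(
    method = method, theta = theta, se = se, pvalue = pvalue,
    or_ = exp(theta),
    ci_low = exp(theta - zq * se), ci_high = exp(theta + zq * se),
    n_iv = n_iv
  )
}

#' Wald ratio estimator
#'
#' Single-instrument causal estimate: theta = beta_y / beta_x with the
#' first-order delta-method standard error se_y / |beta_x|.
#'
#' @param beta_x,se_x variant effect and SE on the exposure.
#' @param beta_y,se_y variant effect and SE on the outcome.
#' @return list with `theta` and `se` (vectorized over instruments).
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y) {
  if (any(beta_x == 0)) stopf("null exposure effect: Wald ratio undefined")
  list(theta = beta_y / beta_x, se = se_y / abs(beta_x))
}

ivw_weights <- function(beta_x, se_y) beta_x^2 / se_y^2

#' Inverse-variance-weighted MR with Cochran's Q heterogeneity
#'
#' Weighted average of per-instrument Wald ratios with weights
#' w_j = beta_x_j^2 / se_y_j^2 (the inverse first-order ratio variances).
#' Under the multiplicative random-effects model (default) the standard
#' error is inflated by max(1, sqrt(Q / df)). A single instrument falls back
#' to the Wald ratio with an undefined heterogeneity test.
#'
#' @param beta_x,se_x,beta_y,se_y aligned instrument effects and SEs.
#' @param model `"mult_random"` (default) or `"fixed"`.
#' @return list with `estimate` (an MR result: theta, se, pvalue, or_,
#'   ci_low, ci_high, n_iv) and `heterogeneity` (q_stat, df, pvalue).
#' @export
mr_ivw <- function(beta_x, se_x, beta_y, se_y,
                   model = c("mult_random", "fixed")) {
  model <- match.arg(model)
  n <- length(beta_x)
  if (n < 1) stopf("IVW requires at least one instrument")
  wr <- wald_ratio(beta_x, se_x, beta_y, se_y)
  w <- ivw_weights(beta_x, se_y)
  theta <- sum(w * wr$theta) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (wr$theta - theta)^2)
  df <- n - 1L
  if (model == "mult_random" && df > 0) se <- se * max(1, sqrt(q / df))
  het <- list(
    q_stat = q, df = df,
    pvalue = if (df > 0) pchisq(q, df, lower.tail = FALSE) else NA_real_
  )
  list(estimate = mr_result("ivw", theta, se, n), heterogeneity = het)
}

weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  stats::approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR
#'
#' Consistent when instruments carrying at least 50% of the weight are
#' valid. The point estimate interpolates the ordered Wald ratios at the
#' weighted midpoint 0.5; the standard error comes from a seeded parametric
#' bootstrap in which beta_x and beta_y are perturbed by their SEs.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap draws for the SE (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return MR result list (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(beta_x, se_x, beta_y, se_y, n_boot = 1000L,
                               seed = NULL) {
  n <- length(beta_x)
  if (n < 3) stopf("weighted median requires >= 3 instruments")
  wr <- wald_ratio(beta_x, se_x, beta_y, se_y)
  w <- ivw_weights(beta_x, se_y)
  theta <- weighted_median_point(wr$theta, w)
  boot <- with_seed(seed, {
    bx <- matrix(rnorm(n * n_boot, beta_x, se_x), nrow = n)
    by <- matrix(rnorm(n * n_boot, beta_y, se_y), nrow = n)
    bx[bx == 0] <- .Machine$double.eps
    vapply(seq_len(n_boot), function(b) {
      weighted_median_point(by[, b] / bx[, b], bx[, b]^2 / se_y^2)
    }, numeric(1))
  })
  se <- sd(boot)
  mr_result("weighted_median", theta, se, n)
}

#' MR-Egger regression
#'
#' Instruments are oriented so that beta_x >= 0 (both betas flipped), then
#' beta_y is regressed on beta_x by weighted least squares with weights
#' 1/se_y^2 and a free intercept. The intercept estimates average directional
#' pleiotropy; its two-sided p-value uses a t distribution with n_iv - 2 df.
#' The slope is returned as a causal estimate robust to directional
#' pleiotropy (under the InSIDE assumption).
#'
#' @inheritParams mr_ivw
#' @return list with `pleiotropy` (intercept, intercept_se, intercept_p) and
#'   `slope` (MR result, `method = "egger_slope"`).
#' @export
mr_egger <- function(beta_x, se_x, beta_y, se_y) {
  n <- length(beta_x)
  if (n < 3) stopf("Egger requires >=3 instruments")
  flip <- sign(beta_x)
  flip[flip == 0] <- 1
  bx <- beta_x * flip
  by <- beta_y * flip
  fit <- stats::lm(by ~ bx, weights = 1 / se_y^2)
  cf <- summary(fit)$coefficients
  int <- cf[1, 1]; int_se <- cf[1, 2]
  slope <- cf[2, 1]; slope_se <- cf[2, 2]
  df <- n - 2L
  int_p <- if (int_se > 0) 2 * pt(-abs(int / int_se), df) else NA_real_
  slope_p <- if (slope_se > 0) 2 * pt(-abs(slope / slope_se), df) else NA_real_
  list(
    pleiotropy = list(intercept = int, intercept_se = int_se, intercept_p = int_p),
    slope = mr_result("egger_slope", slope, slope_se, n, pvalue = slope_p)
  )
}

#' Steiger directionality filtering
#'
#' Per instrument, the variance explained on each trait is approximated by
#' r^2 = z^2 / (z^2 + n - 2) from the association z-score. A variant is kept
#' when it explains more exposure than outcome variance (strict inequality);
#' the direction p-value is a one-sided z-test on the difference of
#' Fisher-transformed |r| values. For the binary outcome the same
#' observed-scale z-score relation is used, a documented approximation; the
#' case fraction is accepted for the record but not used.
#'
#' @inheritParams mr_ivw
#' @param n_exposure,n_outcome effective sample sizes (> 2).
#' @param case_fraction outcome case fraction; logged only.
#' @param variant_id optional ids for the report.
#' @return data.frame (`variant_id`, `r2_exposure`, `r2_outcome`, `keep`,
#'   `direction_p`) with attribute `verdict` = "no reverse causation" iff all
#'   variants are kept.
#' @export
mr_steiger <- function(beta_x, se_x, beta_y, se_y, n_exposure, n_outcome,
                       case_fraction = NULL, variant_id = NULL) {
  if (n_exposure <= 2 || n_outcome <= 2) stopf("sample sizes must exceed 2")
  zx <- beta_x / se_x
  zy <- beta_y / se_y
  r2x <- zx^2 / (zx^2 + n_exposure - 2)
  r2y <- zy^2 / (zy^2 + n_outcome - 2)
  rx <- sqrt(r2x); ry <- sqrt(r2y)
  sed <- sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  zstat <- (atanh(pmin(rx, 1 - 1e-12)) - atanh(pmin(ry, 1 - 1e-12))) / sed
  out <- data.frame(
    variant_id = variant_id %||% paste0("iv", seq_along(beta_x)),
    r2_exposure = r2x, r2_outcome = r2y,
    keep = r2x > r2y,
    direction_p = pnorm(zstat, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  attr(out, "verdict") <- if (all(out$keep)) "no reverse causation" else "possible reverse causation"
  attr(out, "case_fraction") <- case_fraction
  out
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up FDR or Bonferroni family-wise correction
#' (capped at 1).
#'
#' @param pvalues numeric vector in (0, 1].
#' @param method `"BH"` or `"bonferroni"`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_multiplicity <- function(pvalues, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  p.adjust(pvalues, method = if (method == "BH") "BH" else "bonferroni")
}

#' All MR estimators and sensitivity analyses for one protein
#'
#' @param harm `harmonized_table` of the protein's selected instruments.
#' @param n_exposure,n_outcome sample sizes for Steiger filtering; defaults
#'   taken from the tables' `n` columns.
#' @param case_fraction outcome case fraction (logged in the Steiger record).
#' @param model IVW model, see [mr_ivw()].
#' @param n_boot,seed weighted-median bootstrap controls.
#' @return list (`protein_mr` class): `ivw`, `wm`, `egger`, `het`, `steiger`,
#'   `n_iv`, `f`.
#' @export
mr_protein <- function(harm, n_exposure = NULL, n_outcome = NULL,
                       case_fraction = NULL, model = "mult_random",
                       n_boot = 1000L, seed = NULL) {
  if (nrow(harm) < 3) stopf("protein MR requires >=3 instruments")
  bx <- harm$beta_x; sx <- harm$se_x; by <- harm$beta_y; sy <- harm$se_y
  n_exposure <- n_exposure %||% median(harm$n_x)
  n_outcome <- n_outcome %||% median(harm$n_y)
  iv <- mr_ivw(bx, sx, by, sy, model = model)
  wm <- mr_weighted_median(bx, sx, by, sy, n_boot = n_boot, seed = seed)
  eg <- mr_egger(bx, sx, by, sy)
  st <- mr_steiger(bx, sx, by, sy, n_exposure, n_outcome,
                   case_fraction = case_fraction,
                   variant_id = harm$variant_id)
  structure(list(
    ivw = iv$estimate, het = iv$heterogeneity, wm = wm,
    egger = eg, steiger = st,
    n_iv = nrow(harm), f = f_statistic(bx, sx)
  ), class = "protein_mr")
}

get_store <- function(store, id) {
  if (is.function(store)) store(id) else store[[id]]
}

#' Proteome-wide two-sample MR
#'
#' Runs the full per-protein pipeline over a cohort: cis instrument
#' selection, LD clumping, harmonization with the outcome, IVW /
#' weighted-median / Egger / Cochran's Q / Steiger, cohort-level BH FDR and
#' Bonferroni over the proteins actually tested, the robustness filter
#' (FDR_IVW < fdr_max, Q p > het_p_min, FDR_WM < fdr_max), and an optional
#' replication re-run restricted to common variants (MAF >= 5%).
#'
#' @param proteins data.frame with `protein_id`, `gene_symbol`, `chrom`, `tss`.
#' @param exposure_store named list (or function of protein_id) of per-protein
#'   pQTL `assoc_table`s.
#' @param outcome outcome GWAS `assoc_table`.
#' @param ld_store named list (or function) of per-protein [ld_matrix()]
#'   objects; `NULL` skips clumping (instruments assumed independent).
#' @param config list of thresholds; see [mr_config()].
#' @return list (`proteome_mr` class): `results` tidy data.frame (one row per
#'   protein), `details` per-protein `protein_mr` objects, `config`.
#' @export
run_proteome_mr <- function(proteins, exposure_store, outcome,
                            ld_store = NULL, config = mr_config()) {
  config <- utils::modifyList(mr_config(), config)
  run_once <- function(maf_min, boot_offset) {
    rows <- vector("list", nrow(proteins))
    details <- list()
    for (i in seq_len(nrow(proteins))) {
      meta <- proteins[i, ]
      pid <- meta$protein_id
      assoc <- get_store(exposure_store, pid)
      row <- data.frame(protein_id = pid,
                        gene_symbol = meta$gene_symbol %||% NA_character_,
                        status = "untested (<3 IVs)", n_iv = 0L,
                        theta_ivw = NA_real_, se_ivw = NA_real_,
                        or_ivw = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p_ivw = NA_real_, q_stat = NA_real_, q_p = NA_real_,
                        egger_intercept = NA_real_, egger_intercept_p = NA_real_,
                        theta_wm = NA_real_, se_wm = NA_real_, p_wm = NA_real_,
                        min_f = NA_real_, median_f = NA_real_,
                        steiger_all_kept = NA,
                        stringsAsFactors = FALSE)
      if (!is.null(assoc)) {
        cand <- select_cis(assoc, meta, p_max = config$p_max,
                           window = config$window, maf_min = maf_min)
        if (!is.null(ld_store) && nrow(cand)) {
          ld <- get_store(ld_store, pid)
          if (!is.null(ld)) cand <- ld_clump(cand, ld, r2_max = config$r2_max)
        }
        if (nrow(cand) >= config$min_iv) {
          harm <- tryCatch(
            harmonize(cand, outcome, drop_ambiguous = config$drop_ambiguous),
            error = function(e) NULL
          )
          if (!is.null(harm) && nrow(harm) >= config$min_iv) {
            fit <- mr_protein(harm,
                              case_fraction = config$case_fraction,
                              model = config$model, n_boot = config$n_boot,
                              seed = child_seed(config$seed, i + boot_offset))
            details[[pid]] <- fit
            row$status <- "tested"
            row$n_iv <- fit$n_iv
            row$theta_ivw <- fit$ivw$theta; row$se_ivw <- fit$ivw$se
            row$or_ivw <- fit$ivw$or_
            row$ci_low <- fit$ivw$ci_low; row$ci_high <- fit$ivw$ci_high
            row$p_ivw <- fit$ivw$pvalue
            row$q_stat <- fit$het$q_stat; row$q_p <- fit$het$pvalue
            row$egger_intercept <- fit$egger$pleiotropy$intercept
            row$egger_intercept_p <- fit$egger$pleiotropy$intercept_p
            row$theta_wm <- fit$wm$theta; row$se_wm <- fit$wm$se
            row$p_wm <- fit$wm$pvalue
            row$min_f <- min(fit$f); row$median_f <- median(fit$f)
            row$steiger_all_kept <- all(fit$steiger$keep)
          }
        }
      }
      rows[[i]] <- row
    }
    res <- do.call(rbind, rows)
    tested <- res$status == "tested"
    res$fdr_ivw <- NA_real_; res$fdr_wm <- NA_real_; res$bonferroni_p <- NA_real_
    res$fdr_ivw[tested] <- adjust_multiplicity(res$p_ivw[tested], "BH")
    res$fdr_wm[tested] <- adjust_multiplicity(res$p_wm[tested], "BH")
    res$bonferroni_p[tested] <- adjust_multiplicity(res$p_ivw[tested], "bonferroni")
    res$passes_robust_filter <- tested &
      res$fdr_ivw < config$fdr_max &
      res$q_p > config$het_p_min &
      res$fdr_wm < config$fdr_max
    res$passes_robust_filter[is.na(res$passes_robust_filter)] <- FALSE
    list(results = res, details = details)
  }

  main <- run_once(config$maf_min, 0L)
  out <- list(results = main$results, details = main$details, config = config)
  if (isTRUE(config$replicate)) {
    rep_run <- run_once(config$replication_maf, nrow(proteins))
    out$replication <- rep_run$results
    out$results$replicated <- out$results$passes_robust_filter &
      rep_run$results$status == "tested" &
      !is.na(rep_run$results$fdr_ivw) & rep_run$results$fdr_ivw < config$fdr_max
  }
  class(out) <- "proteome_mr"
  out
}

#' Default configuration for the proteome-wide MR pipeline
#'
#' Thresholds: cis p-value 1e-5, 250 kb TSS window, MAF >= 1% (replication
#' MAF >= 5%), LD clumping at r^2 < 0.1, >= 3 instruments, FDR 5%,
#' heterogeneity pass at Q p > 0.05, multiplicative random-effects IVW.
#'
#' @param ... overrides.
#' @return named list of settings.
#' @export
mr_config <- function(...) {
  cfg <- list(
    p_max = 1e-5, window = 250000L, maf_min = 0.01, replication_maf = 0.05,
    r2_max = 0.1, min_iv = 3L, fdr_max = 0.05, het_p_min = 0.05,
    model = "mult_random", n_boot = 1000L, drop_ambiguous = TRUE,
    case_fraction = NULL, replicate = FALSE, seed = NULL
  )
  utils::modifyList(cfg, list(...))
}
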