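test_that("wald_ratio implements the delta-method estimator", {
  expect_equal(wald_ratio(0.5, 0.1, 0.25, 0.1), list(theta = 0.5, se = 0.2))
  expect_equal(wald_ratio(0.5, 0.1, 0.0, 0.1)$theta, 0)
  wr <- wald_ratio(-0.4, 0.1, 0.2, 0.08)
  expect_equal(wr$theta, -0.5)
  expect_equal(wr$se, 0.2)
  expect_error(wald_ratio(0, 0.1, 0.1, 0.1), "null exposure effect")
})

test_that("IVW reduces to the weighted Wald-ratio average with Q heterogeneity", {
  # identical ratios: theta recovered, Q = 0, het p = 1
  fit <- mr_ivw(c(0.5, 0.4, 0.25), c(0.1, 0.1, 0.1),
                0.3 * c(0.5, 0.4, 0.25), c(0.1, 0.1, 0.05))
  expect_equal(fit$estimate$theta, 0.3)
  expect_equal(fit$heterogeneity$q_stat, 0)
  expect_equal(fit$heterogeneity$pvalue, 1)

  # derived closed-form oracle: beta_y = 0.2 * beta_x exactly
  bx <- c(0.5, 0.4, 0.25); sy <- c(0.1, 0.1, 0.05)
  by <- 0.2 * bx
  w <- bx^2 / sy^2
  oracle_theta <- sum(w * (by / bx)) / sum(w)
  fit2 <- mr_ivw(bx, rep(0.02, 3), by, sy)
  expect_equal(fit2$estimate$theta, oracle_theta)
  expect_equal(fit2$estimate$theta, 0.2)
  expect_equal(fit2$heterogeneity$q_stat, 0)

  # single-instrument fallback equals the Wald ratio
  one <- mr_ivw(0.5, 0.1, 0.25, 0.1)
  expect_equal(one$estimate$theta, 0.5)
  expect_equal(one$estimate$se, 0.2)
  expect_true(is.na(one$heterogeneity$pvalue))

  # OR/CI consistency
  expect_equal(fit2$estimate$or_, exp(fit2$estimate$theta))
  expect_lt(fit2$estimate$ci_low, fit2$estimate$or_)
  expect_gt(fit2$estimate$ci_high, fit2$estimate$or_)
})

test_that("IVW estimate is invariant under joint allele flips", {
  set.seed(3)
  bx <- rnorm(10, 0.1, 0.02); by <- 0.3 * bx + rnorm(10, 0, 0.01)
  sx <- rep(0.02, 10); sy <- rep(0.01, 10)
  base <- mr_ivw(bx, sx, by, sy)$estimate$theta
  flip <- rep(c(1, -1), 5)
  flipped <- mr_ivw(bx * flip, sx, by * flip, sy)$estimate$theta
  expect_equal(flipped, base)
})

test_that("weighted median interpolates the weight-ordered ratios", {
  # equal weights, odd n: the sample median
  wm <- mr_weighted_median(rep(1, 3), rep(0.01, 3), c(0.1, 0.2, 0.9),
                           rep(0.05, 3), n_boot = 50, seed = 1)
  expect_equal(wm$theta, 0.2)

  # equal weights and odd n equals the sample median on random draws
  for (seed in 1:5) {
    set.seed(seed)
    ratios <- rnorm(7)
    got <- mr_weighted_median(rep(1, 7), rep(0.01, 7), ratios, rep(0.05, 7),
                              n_boot = 10, seed = seed)$theta
    expect_equal(got, median(ratios))
  }

  # identical ratios: theta equals that value and the bootstrap se is small
  same <- mr_weighted_median(rep(1, 5), rep(1e-4, 5), rep(0.3, 5),
                             rep(1e-4, 5), n_boot = 200, seed = 2)
  expect_equal(same$theta, 0.3)
  expect_lt(same$se, 0.01)

  expect_error(mr_weighted_median(1:2, c(1, 1), 1:2, c(1, 1)), ">= 3")
})

test_that("weighted median resists 4/14 shifted instruments where IVW is biased", {
  set.seed(11)
  n <- 14
  bx <- rep(1, n); sx <- rep(0.01, n); sy <- rep(0.05, n)
  true_ratio <- c(rep(0.2, 10), rep(0.8, 4))
  by <- rnorm(n, true_ratio, sy)
  wm <- mr_weighted_median(bx, sx, by, sy, n_boot = 500, seed = 4)
  ivw <- mr_ivw(bx, sx, by, sy)$estimate
  expect_lt(abs(wm$theta - 0.2), 2 * wm$se)
  expect_gt(ivw$theta, 0.3)  # pulled upward by the invalid instruments
})

test_that("Egger regression recovers exact intercept and slope", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  fit <- mr_egger(bx, rep(0.02, 5), 0.05 + 0.2 * bx, rep(0.03, 5))
  expect_equal(fit$pleiotropy$intercept, 0.05, tolerance = 1e-10)
  expect_equal(fit$slope$theta, 0.2, tolerance = 1e-10)

  fit0 <- mr_egger(bx, rep(0.02, 5), 0.2 * bx, rep(0.03, 5))
  expect_equal(fit0$pleiotropy$intercept, 0, tolerance = 1e-12)
  expect_error(mr_egger(1:2, c(1, 1), 1:2, c(1, 1)), ">=3")
})

test_that("Egger intercept recovers planted directional pleiotropy (50 IVs)", {
  covered <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 50
    bx_true <- runif(n, 0.05, 0.3)
    sx <- rep(0.01, n); sy <- rep(0.05, n)
    bx <- rnorm(n, bx_true, sx)
    by <- rnorm(n, 0.1 + 0.25 * bx_true, sy)  # planted intercept c = 0.1
    fit <- mr_egger(bx, sx, by, sy)
    if (abs(fit$pleiotropy$intercept - 0.1) <= 2 * fit$pleiotropy$intercept_se)
      covered <- covered + 1L
  }
  expect_gte(covered, 17L)  # ~95% nominal coverage over 20 replicates
})

test_that("Steiger filtering compares variance explained with strict inequality", {
  st <- mr_steiger(10, 1, 1, 1, 30000, 30000)  # z_x = 10, z_y = 1
  expect_true(st$keep)
  expect_lt(st$direction_p, 1e-8)
  expect_equal(attr(st, "verdict"), "no reverse causation")

  # equal r2 -> keep FALSE (strict inequality)
  st2 <- mr_steiger(5, 1, 5, 1, 10000, 10000)
  expect_false(st2$keep)
  expect_equal(attr(st2, "verdict"), "possible reverse causation")

  expect_error(mr_steiger(1, 1, 1, 1, 2, 100), "exceed 2")
})

test_that("multiplicity adjustment matches hand computation and the step-up oracle", {
  expect_equal(adjust_multiplicity(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_multiplicity(0.04, "BH"), 0.04)
  expect_equal(adjust_multiplicity(0.04, "bonferroni"), 0.04)
  expect_equal(adjust_multiplicity(rep(0.2, 10), "bonferroni"), rep(1, 10))
  for (seed in 1:25) {
    set.seed(seed)
    p <- runif(sample(3:12, 1))
    expect_equal(adjust_multiplicity(p, "BH"), oracle_bh(p))
  }
})

test_that("mr_protein bundles all estimators and sensitivity analyses", {
  reg <- sim_cis_region(17, ld_rho = 0, seed = 5)
  ss <- sim_two_sample(0.3, reg, seed = 7)
  h <- harmonize(ss$exposure, ss$outcome)
  fit <- mr_protein(h, seed = 3, n_boot = 200)
  expect_s3_class(fit, "protein_mr")
  expect_equal(fit$n_iv, 17)
  expect_lt(abs(fit$ivw$theta - 0.3), 4 * fit$ivw$se)
  expect_lt(abs(fit$wm$theta - 0.3), 4 * fit$wm$se)
  expect_true(all(fit$f > 10))
  expect_equal(attr(fit$steiger, "verdict"), "no reverse causation")
})

test_that("run_proteome_mr separates planted from null proteins and flags <3 IVs", {
  sim <- sim_proteome(20, n_causal = 4, theta = 0.4, seed = 11)
  # one protein with too few instruments
  sim$exposure_store[["PROT020"]] <- sim$exposure_store[["PROT020"]][1:2, ]
  res <- run_proteome_mr(sim$proteins, sim$exposure_store, sim$outcome,
                         ld_store = sim$ld_store,
                         config = mr_config(n_boot = 200, seed = 5))
  tab <- res$results
  expect_equal(tab$status[tab$protein_id == "PROT020"], "untested (<3 IVs)")
  planted <- tab$protein_id %in% names(sim$truth)[sim$truth != 0]
  expect_gte(sum(tab$passes_robust_filter[planted]), 3)
  expect_lte(sum(tab$passes_robust_filter[!planted]), 1)
  # FDR columns only defined over tested proteins
  expect_true(all(is.na(tab$fdr_ivw[tab$status != "tested"])))
  expect_true(all(tab$bonferroni_p[tab$status == "tested"] >=
                    tab$p_ivw[tab$status == "tested"]))
})

test_that("replication re-run restricts to MAF >= 5% and flags replication", {
  sim <- sim_proteome(8, n_causal = 2, theta = 0.5, seed = 21)
  res <- run_proteome_mr(sim$proteins, sim$exposure_store, sim$outcome,
                         ld_store = sim$ld_store,
                         config = mr_config(n_boot = 100, seed = 5,
                                            replicate = TRUE))
  expect_true("replicated" %in% names(res$results))
  expect_true(all(res$replication$status %in% c("tested", "untested (<3 IVs)")))
  # replicated implies passing the robust filter in the main run
  expect_true(all(res$results$passes_robust_filter[res$results$replicated]))
})
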