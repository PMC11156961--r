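test_that("response profiles center genes by the requested group", {
  m <- matrix(c(1, 2, 3, 4, 5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  grand <- response_profile(m)
  expect_equal(unname(grand["g1", ]), c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(unname(grand["g2", ]), rep(0, 4))  # constant gene -> zero row

  ctl <- response_profile(m, "control_mean", groups = c("c", "c", "t", "t"))
  expect_equal(unname(rowMeans(ctl[, 1:2])), c(0, 0))
  # the two centerings differ by a per-gene constant
  diffs <- grand - ctl
  expect_lt(max(abs(diffs - rowMeans(diffs))), 1e-12)
  expect_error(response_profile(m, "control_mean"), "groups")
})

test_that("ridge activity solves the penalized normal equations", {
  sig <- sim_signature(400, 8, seed = 41)
  resp <- sim_cytokine_response(sig, "CYTO02", strengths = 1.5,
                                n_samples = 2, seed = 42)
  acts <- ridge_activity(resp$profile, sig, lambda = 1e4, n_perm = 100,
                         seed = 1, min_overlap = 50)
  beta <- attr(acts, "beta")
  S <- sig
  for (j in 1:2) {
    resid <- crossprod(S) %*% beta[j, ] + 1e4 * beta[j, ] -
      crossprod(S, resp$profile[, j])
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("planted cytokine activity gets the top z-score; null profile is flat", {
  sig <- sim_signature(600, 10, seed = 5)
  resp <- sim_cytokine_response(sig, "CYTO03", strengths = 1, n_samples = 3,
                                seed = 6)
  acts <- ridge_activity(resp$profile, sig, n_perm = 300, seed = 7,
                         min_overlap = 50)
  expect_equal(colnames(acts)[which.max(colMeans(acts))], "CYTO03")
  expect_gt(mean(acts[, "CYTO03"]), 3)

  # zero profile: beta = 0, z ~ 0
  zero <- matrix(0, nrow(sig), 1, dimnames = list(rownames(sig), "z"))
  az <- ridge_activity(zero, sig, n_perm = 50, seed = 1, min_overlap = 50)
  expect_true(all(abs(attr(az, "beta")) < 1e-12))
  expect_true(all(abs(az) < 1e-8))
})

test_that("ridge coefficients shrink monotonically with lambda", {
  sig <- sim_signature(300, 6, seed = 9)
  resp <- sim_cytokine_response(sig, "CYTO01", n_samples = 1, seed = 10)
  norms <- vapply(c(1e2, 1e4, 1e6), function(lam) {
    a <- ridge_activity(resp$profile, sig, lambda = lam, n_perm = 10,
                        seed = 1, min_overlap = 50)
    sqrt(sum(attr(a, "beta")^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("activity z-scores are invariant to global signature rescaling", {
  sig <- sim_signature(300, 6, seed = 13)
  resp <- sim_cytokine_response(sig, "CYTO04", n_samples = 1, seed = 14)
  a1 <- ridge_activity(resp$profile, sig, lambda = 1e4, n_perm = 200,
                       seed = 3, min_overlap = 50)
  # rescaling S by c rescales beta and its permutation null identically when
  # lambda is rescaled by c^2 (same regularization geometry)
  a2 <- ridge_activity(resp$profile, sig * 2, lambda = 4e4, n_perm = 200,
                       seed = 3, min_overlap = 50)
  expect_equal(unclass(a1), unclass(a2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("ridge activity enforces the gene-overlap floor", {
  sig <- sim_signature(300, 6, seed = 15)
  prof <- matrix(rnorm(50), 50, 1,
                 dimnames = list(rownames(sig)[1:50], "s"))
  expect_error(ridge_activity(prof, sig, min_overlap = 100), "overlap")
})

test_that("differential activity uses exact Wilcoxon for small groups", {
  set.seed(20)
  acts <- cbind(sep = c(rnorm(6, -3, 0.1), rnorm(6, 3, 0.1)),
                null = rnorm(12))
  groups <- rep(c("ctl", "case"), each = 6)
  res <- differential_activity(acts, groups)
  # fully separated groups at n=6/6: the minimal exact two-sided p
  expect_equal(res$pvalue[res$cytokine == "sep"], 2 / choose(12, 6))
  expect_gt(res$pvalue[res$cytokine == "null"], 0.05)

  # identical groups -> p = 1
  same <- cbind(x = rep(c(1, 2, 3, 4, 5, 6), 2))
  res1 <- differential_activity(same, groups)
  expect_equal(res1$pvalue, 1)
  expect_error(differential_activity(acts[1:4, ], groups[c(1, 1, 7, 7)]),
               "n >= 3")
})

test_that("normal approximation tracks the exact Wilcoxon p under ties", {
  set.seed(21)
  xa <- sample(rep(1:5, 2), 10)   # heavy ties
  xb <- xa + sample(c(0, 1), 10, replace = TRUE)
  approx_p <- suppressWarnings(
    wilcox.test(xa, xb, exact = FALSE, correct = TRUE)$p.value)
  # enumeration of the rank-sum distribution under ties via permutation
  pooled <- c(xa, xb)
  obs <- sum(rank(pooled)[1:10])
  perms <- replicate(20000, sum(rank(pooled)[sample(20, 10)]))
  exact_p <- mean(abs(perms - mean(perms)) >= abs(obs - mean(perms)) - 1e-9)
  expect_lt(abs(approx_p - exact_p) / exact_p, 0.25)
})

test_that("activity dendrogram merges duplicates at height zero", {
  set.seed(22)
  base <- matrix(rnorm(40), 10, 4,
                 dimnames = list(NULL, paste0("C", 1:4)))
  acts <- cbind(base, C4DUP = base[, 4])
  dd <- activity_dendrogram(acts)
  expect_equal(dd$correlation["C4", "C4DUP"], 1)
  m <- dd$tree$merge
  first <- sort(dd$tree$labels[-m[1, ]])
  expect_equal(first, c("C4", "C4DUP"))
  expect_lt(dd$tree$height[1], 1e-9)
  expect_match(dd$newick, "^\\(")

  # three cytokines -> a binary tree with 2 internal merges
  dd3 <- activity_dendrogram(base[, 1:3])
  expect_equal(nrow(dd3$tree$merge), 2)

  # anti-correlated blocks split first
  s <- rnorm(20)
  block <- cbind(a1 = s, a2 = s + rnorm(20, 0, 0.05),
                 b1 = -s, b2 = -s + rnorm(20, 0, 0.05))
  ddb <- activity_dendrogram(block)
  top_split <- cutree(ddb$tree, 2)
  expect_equal(length(unique(top_split[c("a1", "a2")])), 1)
  expect_equal(length(unique(top_split[c("b1", "b2")])), 1)
  expect_false(top_split[["a1"]] == top_split[["b1"]])

  const <- cbind(base[, 1:3], flat = 1)
  expect_warning(activity_dendrogram(const), "zero-variance")
})
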