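test_that("read_sumstats reads valid tables and counts invariant violations", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(
    variant_id = c("rs1", "rs2", "rs3"), chrom = "1", pos = 1:3,
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = c(0.1, -0.2, 0.05), se = 0.05,
    pvalue = 2 * pnorm(-abs(c(0.1, -0.2, 0.05) / 0.05)), n = 1000
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tbl <- read_sumstats(path)
  expect_s3_class(tbl, "assoc_table")
  expect_equal(nrow(tbl), 3)
  expect_equal(qc_report(tbl)$n_dropped, 0)

  # se = 0 row dropped with a per-reason count
  df2 <- df
  df2$se[2] <- 0
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tbl2 <- read_sumstats(path)
  expect_equal(nrow(tbl2), 2)
  expect_equal(qc_report(tbl2)$dropped$se_nonpositive, 1)
})

test_that("read_sumstats errors name the missing column and reject empty files", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(variant_id = "rs1", chrom = "1", pos = 1,
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   se = 0.05, pvalue = 0.5, n = 100)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path), "beta")
  writeLines(character(0), path)
  expect_error(read_sumstats(path), "empty")
})

test_that("record validation drops indels, bad frequencies and bad p-values", {
  df <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    chrom = "1", pos = 1:5,
    effect_allele = c("A", "AT", "A", "A", "A"),
    other_allele = c("G", "G", "A", "G", "G"),
    eaf = c(0.3, 0.3, 0.3, 1.2, 0.3),
    beta = 0.1, se = 0.05, pvalue = c(0.05, 0.05, 0.05, 0.05, 0),
    n = 100
  )
  tbl <- suppressWarnings(as_assoc_table(df))
  expect_equal(tbl$variant_id, "rs1")
  qc <- qc_report(tbl)
  expect_equal(qc$dropped$indel_or_multiallelic, 1)
  expect_equal(qc$dropped$identical_alleles, 1)
  expect_equal(qc$dropped$eaf_out_of_range, 1)
  expect_equal(qc$dropped$pvalue_out_of_range, 1)
})

test_that("p-value/z inconsistency triggers a warning, not a drop", {
  df <- data.frame(variant_id = "rs1", chrom = "1", pos = 1,
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   beta = 0.5, se = 0.05, pvalue = 0.9, n = 100)
  expect_warning(tbl <- as_assoc_table(df), "inconsistent")
  expect_equal(nrow(tbl), 1)
})

test_that("harmonize aligns, flips and drops with reason codes", {
  ex <- toy_assoc(c("rs1", "rs2", "rs3"), beta = c(0.2, 0.1, 0.3), se = 0.05,
                  ea = c("A", "A", "A"), oa = c("G", "T", "G"),
                  eaf = c(0.3, 0.5, 0.3))
  ot <- suppressWarnings(as_assoc_table(data.frame(
    variant_id = c("rs1", "rs2", "rs3"), chrom = "1", pos = 1:3,
    effect_allele = c("G", "A", "C"), other_allele = c("A", "T", "T"),
    eaf = c(0.7, 0.5, 0.3), beta = c(0.1, 0.05, 0.2), se = 0.02,
    pvalue = 0.001, n = 5000
  )))
  h <- harmonize(ex, ot)
  # rs1: outcome alleles swapped -> beta negated
  expect_equal(h$variant_id, "rs1")
  expect_equal(h$beta_y, -0.1)
  expect_true(h$flipped)
  qc <- qc_report(h)
  # rs2 palindromic with eaf 0.5 inside the band; rs3 allele mismatch
  expect_equal(qc$dropped$palindromic_ambiguous, 1)
  expect_equal(qc$dropped$allele_mismatch, 1)
})

test_that("harmonize keeps palindromic variants outside the MAF band or when disabled", {
  ex <- toy_assoc("rs2", beta = 0.1, se = 0.05, ea = "A", oa = "T", eaf = 0.2)
  ot <- toy_assoc("rs2", beta = 0.05, se = 0.02, ea = "A", oa = "T", eaf = 0.2)
  expect_equal(nrow(harmonize(ex, ot)), 1)
  ex50 <- toy_assoc("rs2", beta = 0.1, se = 0.05, ea = "A", oa = "T", eaf = 0.5)
  ot50 <- toy_assoc("rs2", beta = 0.05, se = 0.02, ea = "A", oa = "T", eaf = 0.5)
  expect_equal(nrow(harmonize(ex50, ot50, drop_ambiguous = FALSE)), 1)
  expect_error(harmonize(ex, toy_assoc("rs9", 0.1, 0.05)), "no shared variants")
})

test_that("harmonize is idempotent and leaves aligned allele pairs identical", {
  set.seed(42)
  m <- 20
  alle <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
  pick <- sample(4, m, replace = TRUE)
  ex <- toy_assoc(sprintf("rs%d", 1:m), beta = rnorm(m, 0, 0.1), se = 0.05,
                  ea = vapply(pick, function(i) alle[[i]][1], ""),
                  oa = vapply(pick, function(i) alle[[i]][2], ""),
                  eaf = runif(m, 0.1, 0.9))
  flip <- sample(c(TRUE, FALSE), m, replace = TRUE)
  ot_df <- as.data.frame(ex)
  ot_df$beta <- rnorm(m, 0, 0.05)
  ot_df$se <- 0.02
  ot_df$pvalue <- 2 * pnorm(-abs(ot_df$beta / ot_df$se))
  tmp_ea <- ifelse(flip, ot_df$other_allele, ot_df$effect_allele)
  tmp_oa <- ifelse(flip, ot_df$effect_allele, ot_df$other_allele)
  ot_df$beta <- ifelse(flip, -ot_df$beta, ot_df$beta)
  ot_df$eaf <- ifelse(flip, 1 - ot_df$eaf, ot_df$eaf)
  ot_df$effect_allele <- tmp_ea
  ot_df$other_allele <- tmp_oa
  ot <- as_assoc_table(ot_df)

  h1 <- harmonize(ex, ot)
  # reconstruct the aligned outcome as an assoc table and harmonize again
  ot2 <- as_assoc_table(data.frame(
    variant_id = h1$variant_id, chrom = h1$chrom, pos = h1$pos,
    effect_allele = h1$effect_allele, other_allele = h1$other_allele,
    eaf = h1$eaf_x, beta = h1$beta_y, se = h1$se_y, pvalue = h1$pvalue_y,
    n = h1$n_y
  ))
  ex2 <- ex[ex$variant_id %in% h1$variant_id, ]
  h2 <- harmonize(ex2, ot2)
  expect_equal(h2$beta_y, h1$beta_y)
  expect_equal(h2$effect_allele, h1$effect_allele)
  expect_false(any(h2$flipped))
})

test_that("sumstats round-trip write/read preserves every field", {
  tbl <- toy_assoc(c("rs1", "rs2"), beta = c(0.123456, -0.2), se = c(0.01, 0.3),
                   eaf = c(0.11, 0.77))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tbl, path)
  back <- read_sumstats(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl), tolerance = 1e-12)
})

test_that("GMT reading deduplicates members and rejects malformed lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("IMMUNE\tdesc\tA\tB\tB", "OTHER\tdesc\tc\tD"), path)
  sets <- read_gmt(path)
  expect_equal(sets$IMMUNE, c("A", "B"))
  expect_equal(sets$OTHER, c("C", "D"))  # symbols normalized

  writeLines(c("IMMUNE\tdesc\tA", "BAD\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 2")
  writeLines(c("X\td\tA", "X\td\tB"), path)
  expect_error(read_gmt(path), "duplicate")
})

test_that("edge lists are simplified and matrices validated", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("A A", "A B", "B A", "B C"), path)
  g <- read_edge_list(path)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::vcount(g), 3)

  mpath <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "G1\t1.5\t2.0", "G2\tx\t1.0"), mpath)
  expect_error(read_expr_matrix(mpath), "row 2.*s1|s1.*row 2")
  writeLines(c("gene\ts1\ts2", "G1\t1.5\t2.0", "G1\t3\t4"), mpath)
  m <- read_expr_matrix(mpath)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(attr(m, "feature_id"), c("G1", "G1"))
})
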