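#' Default column schema for summary statistics
#'
#' Maps the internal field names to the column names expected in the input
#' file. Override entries to adapt to a cohort's export format, e.g.
#' `sumstats_schema(beta = "Effect", se = "StdErr")`.
#'
#' @param ... named overrides, `internal_field = "file_column"`.
#' @return named character vector mapping internal fields to file columns.
#' @export
sumstats_schema <- function(...) {
  schema <- c(
    variant_id = "variant_id", chrom = "chrom", pos = "pos",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "eaf", beta = "beta", se = "se", pvalue = "pvalue", n = "n"
  )
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(schema))
    if (length(bad)) stopf("unknown schema field(s): %s", paste(bad, collapse = ", "))
    schema[names(dots)] <- dots
  }
  schema
}

assoc_fields <- function() {
  c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
    "eaf", "beta", "se", "pvalue", "n")
}

#' Validate and type an association table
#'
#' Applies the per-record invariants: positive standard errors, allele
#' frequencies in \[0, 1\], p-values in (0, 1\], single-nucleotide alleles
#' with effect allele distinct from the other allele, and positive sample
#' sizes. Rows failing any invariant are dropped and counted per reason in
#' the attached QC report. Rows whose p-value disagrees with the two-sided
#' normal approximation from |beta/se| by more than a factor of 10 trigger a
#' validation warning but are retained.
#'
#' @param df data.frame with the fields of [sumstats_schema()].
#' @return an `assoc_table`: the validated data.frame with a `qc` attribute.
#' @export
as_assoc_table <- function(df) {
  need <- assoc_fields()
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing required column: %s", paste(miss, collapse = ", "))
  df <- df[need]
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (f in c("eaf", "beta", "se", "pvalue")) df[[f]] <- as.numeric(df[[f]])
  df$n <- as.numeric(df$n)

  n_input <- nrow(df)
  reasons <- character(n_input)
  snv <- c("A", "C", "G", "T")
  flag <- function(cond, code) {
    cond[is.na(cond)] <- TRUE
    reasons[reasons == "" & cond] <<- code
  }
  flag(is.na(df$variant_id) | df$variant_id == "", "missing_id")
  flag(!(df$effect_allele %in% snv) | !(df$other_allele %in% snv),
       "indel_or_multiallelic")
  flag(df$effect_allele == df$other_allele, "identical_alleles")
  flag(df$se <= 0, "se_nonpositive")
  flag(df$eaf < 0 | df$eaf > 1, "eaf_out_of_range")
  flag(df$pvalue <= 0 | df$pvalue > 1, "pvalue_out_of_range")
  flag(df$n <= 0, "n_nonpositive")
  flag(is.na(df$beta) | is.na(df$pos), "missing_value")

  kept <- df[reasons == "", , drop = FALSE]
  if (anyDuplicated(kept$variant_id)) {
    dup <- duplicated(kept$variant_id) | duplicated(kept$variant_id, fromLast = TRUE)
    reasons[reasons == ""][dup] <- "duplicate_id"
    kept <- kept[!dup, , drop = FALSE]
  }
  rownames(kept) <- NULL

  if (nrow(kept)) {
    p_approx <- 2 * pnorm(-abs(kept$beta / kept$se))
    off <- p_approx > 1e-300 & kept$pvalue > 1e-300 &
      abs(log10(kept$pvalue) - log10(p_approx)) > 1
    if (any(off)) {
      warnf("%d row(s) have p-values inconsistent with |beta/se| by >10x", sum(off))
    }
  }

  drop_tab <- table(reasons[reasons != ""])
  attr(kept, "qc") <- list(
    n_input = n_input, n_kept = nrow(kept),
    n_dropped = n_input - nrow(kept),
    dropped = as.list(drop_tab)
  )
  class(kept) <- c("assoc_table", "data.frame")
  kept
}

#' Read GWAS or pQTL summary statistics
#'
#' Reads a tab- or comma-delimited file with a header, renames columns via
#' the schema, validates every record and attaches a machine-readable QC
#' report (see [qc_report()]).
#'
#' @param path file path.
#' @param schema column mapping from [sumstats_schema()].
#' @return an `assoc_table`.
#' @export
read_sumstats <- function(path, schema = sumstats_schema()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) stopf("empty file: %s", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!nrow(raw)) stopf("empty file: %s (header only)", path)
  miss <- setdiff(unname(schema), names(raw))
  if (length(miss)) {
    internal <- names(schema)[match(miss, unname(schema))]
    stopf("missing required column: %s (field %s)",
          paste(miss, collapse = ", "), paste(internal, collapse = ", "))
  }
  df <- raw[unname(schema)]
  names(df) <- names(schema)
  as_assoc_table(df)
}

#' Write an association table to TSV
#'
#' @param x assoc_table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  write.table(as.data.frame(x)[assoc_fields()], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retrieve the QC report attached to a validated table
#'
#' @param x object with a `qc` attribute (e.g. from [read_sumstats()] or
#'   [harmonize()]).
#' @return list of per-reason drop counts and totals.
#' @export
qc_report <- function(x) attr(x, "qc")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effects to the exposure's effect allele over the
#' intersection of variant ids. When the outcome's effect allele equals the
#' exposure's other allele, the outcome beta is negated and its frequency
#' complemented. Palindromic variants (A/T or C/G) whose exposure allele
#' frequency falls inside `ambiguous_maf_band` are dropped when
#' `drop_ambiguous` is set, because strand cannot be resolved by frequency.
#' Unresolvable allele pairs are dropped with reason codes. Variant-id
#' overlap below 10% of the smaller table triggers a genome-build-mismatch
#' warning.
#'
#' @param exposure,outcome `assoc_table`s.
#' @param drop_ambiguous drop frequency-ambiguous palindromic variants.
#' @param ambiguous_maf_band open interval of exposure EAF within which a
#'   palindromic variant is considered ambiguous.
#' @return `harmonized_table` data.frame with columns `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf_x`, `beta_x`, `se_x`,
#'   `pvalue_x`, `n_x`, `beta_y`, `se_y`, `pvalue_y`, `n_y`, `flipped`;
#'   QC drops in `qc_report()`.
#' @export
harmonize <- function(exposure, outcome, drop_ambiguous = TRUE,
                      ambiguous_maf_band = c(0.42, 0.58)) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (!length(shared)) stopf("no shared variants between exposure and outcome")
  n_min <- min(nrow(exposure), nrow(outcome))
  if (length(shared) < 0.1 * n_min) {
    warnf("variant-id overlap is %.1f%% of the smaller table; inputs may be on different genome builds",
          100 * length(shared) / n_min)
  }
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ot <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  same <- ot$effect_allele == ex$effect_allele & ot$other_allele == ex$other_allele
  swap <- ot$effect_allele == ex$other_allele & ot$other_allele == ex$effect_allele

  reasons <- character(length(shared))
  reasons[!same & !swap] <- "allele_mismatch"
  if (drop_ambiguous) {
    pal <- is_palindromic(ex$effect_allele, ex$other_allele)
    amb <- pal & ex$eaf > ambiguous_maf_band[1] & ex$eaf < ambiguous_maf_band[2]
    reasons[reasons == "" & amb] <- "palindromic_ambiguous"
  }
  keep <- reasons == ""

  beta_y <- ifelse(swap, -ot$beta, ot$beta)
  out <- data.frame(
    variant_id = ex$variant_id, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    eaf_x = ex$eaf, beta_x = ex$beta, se_x = ex$se,
    pvalue_x = ex$pvalue, n_x = ex$n,
    beta_y = beta_y, se_y = ot$se, pvalue_y = ot$pvalue, n_y = ot$n,
    flipped = swap,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  drop_tab <- table(reasons[reasons != ""])
  attr(out, "qc") <- list(
    n_shared = length(shared), n_kept = nrow(out),
    n_dropped = length(shared) - nrow(out),
    dropped = as.list(drop_tab)
  )
  class(out) <- c("harmonized_table", "data.frame")
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then members. Duplicate members are
#' removed; symbols are normalized with [norm_symbol()].
#'
#' @param path GMT file path.
#' @return named list of character vectors (member symbols).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("malformed GMT line %d: fewer than 3 fields", i)
    nm[i] <- f[1]
    sets[[i]] <- unique(norm_symbol(f[-(1:2)]))
  }
  if (anyDuplicated(nm)) stopf("duplicate set names in GMT: %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(sets) <- nm
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Two whitespace- or tab-separated symbols per line. Self-loops and
#' duplicate edges are collapsed; node identity is the normalized symbol.
#'
#' @param path edge-list file path.
#' @param directed ignored; PPIs are undirected.
#' @return an undirected simple [igraph::graph].
#' @export
read_edge_list <- function(path, directed = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty edge list: %s", path)
  parts <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad)) stopf("malformed edge at line %d: need two symbols", bad[1])
  el <- cbind(norm_symbol(vapply(parts, `[`, "", 1)),
              norm_symbol(vapply(parts, `[`, "", 2)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column is the feature id (duplicates allowed; collapse later with
#' [collapse_probes()]), remaining columns are numeric sample values.
#'
#' @param path TSV path.
#' @return numeric matrix with feature rownames (duplicated ids get
#'   `make.unique` rownames; originals kept in attribute `feature_id`).
#' @export
read_expr_matrix <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (ncol(df) < 2) stopf("expression matrix needs an id column and >=1 sample")
  ids <- as.character(df[[1]])
  vals <- df[-1]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]))
    if (length(bad)) {
      stopf("non-numeric value at row %d, column '%s'", bad[1], names(vals)[j])
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- make.unique(ids)
  attr(m, "feature_id") <- ids
  m
}

#' Read a two-column pair table (ligand-receptor or drug-gene)
#'
#' @param path TSV/CSV path with a header.
#' @return data.frame with normalized symbol columns and duplicates removed.
#' @export
read_pairs <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("pair table needs at least two columns")
  df[[1]] <- norm_symbol(df[[1]])
  df[[2]] <- norm_symbol(df[[2]])
  df[!duplicated(df), , drop = FALSE]
}
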