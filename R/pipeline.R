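#' Default pipeline configuration
#'
#' All thresholds default to the analysis' published settings: cis p < 1e-5,
#' 250 kb TSS window, MAF >= 1% (5% replication), r^2 < 0.1 clumping, >= 3
#' instruments, FDR 5%, |log2FC| > 1.25. `input_dir` must contain the files
#' written by [simulate_inputs()] (or real data in the same formats).
#'
#' @param input_dir directory of input files.
#' @param run_dir output directory.
#' @param seed integer seed used for every stochastic stage.
#' @param stages stages to run (default all).
#' @param ... threshold overrides merged into `$thresholds`.
#' @return config list.
#' @export
pipeline_config <- function(input_dir, run_dir, seed = 1L,
                            stages = c("mr", "enrichment", "network",
                                       "expression", "dcq", "cytokine",
                                       "integration"),
                            ...) {
  list(
    input_dir = input_dir, run_dir = run_dir, seed = as.integer(seed),
    stages = stages,
    thresholds = utils::modifyList(
      list(p_max = 1e-5, window = 250000L, maf_min = 0.01,
           replication_maf = 0.05, r2_max = 0.1, min_iv = 3L,
           fdr_max = 0.05, het_p_min = 0.05, lfc_min = 1.25,
           n_boot = 200L, n_perm = 200L, walktrap_t = 4L, lambda = 1e4),
      list(...))
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with at least `input_dir` and `run_dir`.
#' @return validated config list (defaults filled in).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("input_dir", "run_dir")) {
    if (is.null(raw[[f]])) stopf("config is missing required field '%s'", f)
  }
  cfg <- pipeline_config(raw$input_dir, raw$run_dir,
                         seed = raw$seed %||% 1L,
                         stages = raw$stages %||% c("mr", "enrichment",
                                                    "network", "expression",
                                                    "dcq", "cytokine",
                                                    "integration"))
  if (!is.null(raw$thresholds)) {
    cfg$thresholds <- utils::modifyList(cfg$thresholds, raw$thresholds)
  }
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Write a complete synthetic input bundle for the pipeline
#'
#' Generates every input class with planted ground truth (proteome summary
#' statistics, outcome GWAS, per-protein LD, expression matrix with groups,
#' cell reference, cytokine signatures, PPI edges, gene sets, ligand-receptor
#' pairs, drug-gene table) and writes them as the plain-text formats the
#' pipeline consumes. Truth is written to `truth.json`.
#'
#' @param dir output directory (created).
#' @param seed RNG seed.
#' @param n_proteins,n_causal,theta proteome scale and planted effect.
#' @param n_genes expression genes.
#' @return `dir`, invisibly.
#' @export
simulate_inputs <- function(dir, seed = 1L, n_proteins = 12L, n_causal = 3L,
                            theta = 0.3, n_genes = 1200L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pqtl"), showWarnings = FALSE)
  dir.create(file.path(dir, "ld"), showWarnings = FALSE)

  prot <- sim_proteome(n_proteins, n_causal = n_causal, theta = theta,
                       seed = child_seed(seed, 1L))
  write_tsv(prot$proteins, file.path(dir, "proteins.tsv"))
  write_sumstats(prot$outcome, file.path(dir, "outcome.tsv"))
  for (pid in names(prot$exposure_store)) {
    write_sumstats(prot$exposure_store[[pid]],
                   file.path(dir, "pqtl", paste0(pid, ".tsv")))
    write_matrix_tsv(prot$ld_store[[pid]]$r,
                     file.path(dir, "ld", paste0(pid, ".tsv")),
                     id_col = "variant_id")
  }

  expr <- sim_expression(n_genes, seed = child_seed(seed, 2L))
  write_matrix_tsv(round(expr$mat, 6), file.path(dir, "expression.tsv"),
                   id_col = "gene")
  write_tsv(data.frame(sample = colnames(expr$mat), group = expr$groups),
            file.path(dir, "groups.tsv"))

  ref <- sim_reference(n_types = 8L, n_markers = 20L, n_background = 100L,
                       seed = child_seed(seed, 3L))
  # the reference shares the expression matrix's gene universe so the
  # deconvolution stage operates on real overlap
  rownames(ref) <- rownames(expr$mat)[300L + seq_len(nrow(ref))]
  write_matrix_tsv(round(ref, 6), file.path(dir, "cell_reference.tsv"),
                   id_col = "gene")

  sig <- sim_signature(n_genes = 600L, n_cytokines = 20L,
                       seed = child_seed(seed, 4L))
  # signature genes are a subset of the expression universe so the ridge
  # stage has overlap
  rownames(sig) <- rownames(expr$mat)[seq_len(nrow(sig))]
  write_matrix_tsv(round(sig, 6), file.path(dir, "cytokine_signature.tsv"),
                   id_col = "gene")

  genes <- prot$proteins$gene_symbol
  extra <- sprintf("NODE%03d", seq_len(80))
  ppi <- sim_ppi(n = 100L, attach_m = 2L, seed = child_seed(seed, 5L))$graph
  igraph::V(ppi)$name <- c(genes, extra)[seq_len(igraph::vcount(ppi))]
  el <- igraph::as_edgelist(ppi)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), file.path(dir, "ppi_edges.tsv"))

  background <- unique(c(genes, extra, rownames(expr$mat)[1:200]))
  gs <- sim_genesets(background, query = genes, n_sets = 6L, set_size = 30L,
                     planted_overlap = min(5L, length(genes)),
                     seed = child_seed(seed, 6L))
  write_gmt(gs$sets, file.path(dir, "gene_sets.gmt"))

  lr <- data.frame(ligand = genes[seq_len(min(6L, length(genes)))],
                   receptor = rownames(expr$mat)[1:min(6L, length(genes))],
                   source = "database")
  write_tsv(lr, file.path(dir, "lr_pairs.tsv"))
  drugs <- data.frame(
    drug = sprintf("drug%02d", seq_len(min(6L, length(genes)))),
    gene = genes[seq_len(min(6L, length(genes)))],
    action = rep(c("inhibitor", "agonist", "unknown"),
                 length.out = min(6L, length(genes))))
  write_tsv(drugs, file.path(dir, "drug_gene.tsv"))

  jsonlite::write_json(
    list(theta = as.list(prot$truth),
         de_genes = expr$truth$gene[expr$truth$is_de],
         planted_set = "PLANTED"),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Checksums keyed by path relative to `dir`, so manifests are identical
# across run directories.
file_md5 <- function(dir, files) {
  files <- files[file.exists(file.path(dir, files))]
  md5 <- tools::md5sum(file.path(dir, files))
  setNames(as.list(unname(md5)), files)
}

#' Run the integrative pipeline
#'
#' Executes the enabled stages in dependency order (MR, then enrichment and
#' network on the MR candidates; expression DE, then GSEA, deconvolution and
#' cytokine activity; ligand-receptor / drug integration last), writing each
#' stage's tables under `run_dir` plus a manifest with the resolved
#' configuration, seed and input checksums. A stage whose inputs are
#' unchanged since the recorded manifest and whose outputs exist is skipped
#' (cache hit); a missing input for an enabled stage aborts before any
#' compute. Outputs contain no timestamps, so identical configurations give
#' byte-identical runs.
#'
#' @param config list from [pipeline_config()] / [read_pipeline_config()].
#' @return `run_dir`, invisibly.
#' @export
run_pipeline <- function(config) {
  ind <- config$input_dir
  rd <- config$run_dir
  th <- config$thresholds
  seed <- config$seed
  req <- c(mr = "outcome.tsv", mr = "proteins.tsv",
           enrichment = "gene_sets.gmt", network = "ppi_edges.tsv",
           expression = "expression.tsv", expression = "groups.tsv",
           dcq = "cell_reference.tsv", cytokine = "cytokine_signature.tsv",
           integration = "lr_pairs.tsv", integration = "drug_gene.tsv")
  need <- unname(req[names(req) %in% config$stages])
  missing <- need[!file.exists(file.path(ind, need))]
  if (length(missing)) {
    stopf("missing input file(s) for enabled stages: %s",
          paste(missing, collapse = ", "))
  }
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(rd, "manifest.json")
  old_manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else NULL
  manifest <- list(seed = seed, thresholds = th, stages = config$stages,
                   inputs = file_md5(ind, list.files(ind, recursive = TRUE)),
                   stage_inputs = list(), stage_outputs = list())

  # A stage is skipped when its recorded input checksums match and its
  # outputs exist with their recorded checksums; a checksum mismatch on an
  # existing output (corrupted cache entry) forces recomputation.
  cache_ok <- function(stage, in_files, out_files) {
    key <- file_md5(ind, in_files)
    manifest$stage_inputs[[stage]] <<- key
    old_out <- old_manifest$stage_outputs[[stage]]
    hit <- !is.null(old_manifest) &&
      identical(lapply(old_manifest$stage_inputs[[stage]], identity), key) &&
      !is.null(old_out) &&
      all(file.exists(file.path(rd, out_files)))
    if (hit) {
      cur <- file_md5(rd, out_files)
      if (!identical(lapply(old_out, identity), cur)) {
        warnf("stage '%s': cached output does not match its recorded checksum; recomputing",
              stage)
        hit <- FALSE
      }
    }
    if (hit) manifest$stage_outputs[[stage]] <<- old_out
    hit
  }
  record_outputs <- function(stage, out_files) {
    manifest$stage_outputs[[stage]] <<- file_md5(rd, out_files)
  }

  state <- new.env(parent = emptyenv())

  if ("mr" %in% config$stages) {
    outs <- "mr_results.tsv"
    if (!cache_ok("mr", c("outcome.tsv", "proteins.tsv"), outs)) {
      proteins <- read.delim(file.path(ind, "proteins.tsv"),
                             stringsAsFactors = FALSE)
      proteins$chrom <- as.character(proteins$chrom)
      outcome <- read_sumstats(file.path(ind, "outcome.tsv"))
      exposure_store <- function(pid) {
        p <- file.path(ind, "pqtl", paste0(pid, ".tsv"))
        if (file.exists(p)) read_sumstats(p) else NULL
      }
      ld_store <- function(pid) {
        p <- file.path(ind, "ld", paste0(pid, ".tsv"))
        if (!file.exists(p)) return(NULL)
        m <- read_expr_matrix(p)
        ld_matrix(m, rownames(m))
      }
      mr <- run_proteome_mr(proteins, exposure_store, outcome,
                            ld_store = ld_store,
                            config = mr_config(
                              p_max = th$p_max, window = th$window,
                              maf_min = th$maf_min, r2_max = th$r2_max,
                              min_iv = th$min_iv, fdr_max = th$fdr_max,
                              het_p_min = th$het_p_min, n_boot = th$n_boot,
                              seed = child_seed(seed, 101L)))
      write_tsv(mr$results, file.path(rd, "mr_results.tsv"))
      record_outputs("mr", outs)
      state$mr <- mr$results
    } else {
      state$mr <- read.delim(file.path(rd, "mr_results.tsv"),
                             stringsAsFactors = FALSE)
    }
  }

  candidates <- NULL
  if (!is.null(state$mr)) {
    hits <- state$mr[state$mr$passes_robust_filter %in% TRUE, , drop = FALSE]
    if (nrow(hits)) candidates <- candidate_proteins(hits)
  }

  if ("enrichment" %in% config$stages && !is.null(candidates)) {
    outs <- "enrichment.tsv"
    if (!cache_ok("enrichment", c("gene_sets.gmt", "proteins.tsv"), outs)) {
      sets <- read_gmt(file.path(ind, "gene_sets.gmt"))
      background <- unique(c(unlist(sets), state$mr$gene_symbol))
      enr <- ora_batch(candidates$gene_symbol, sets, background)
      write_tsv(enr, file.path(rd, "enrichment.tsv"))
      record_outputs("enrichment", outs)
    }
  }

  if ("network" %in% config$stages && !is.null(candidates)) {
    outs <- c("network_nodes.tsv", "network_modules.tsv")
    if (!cache_ok("network", c("ppi_edges.tsv", "gene_sets.gmt"), outs)) {
      ppi <- read_edge_list(file.path(ind, "ppi_edges.tsv"))
      seeds_in <- intersect(candidates$gene_symbol, igraph::V(ppi)$name)
      if (length(seeds_in)) {
        net <- extract_seed_subnetwork(ppi, seeds_in)
        deg <- degree_centrality(net)
        vr <- voterank(net)
        part <- walktrap_modules(net, t = th$walktrap_t)
        nodes <- data.frame(
          node = names(part$membership),
          seed = igraph::V(net)$seed[match(names(part$membership),
                                           igraph::V(net)$name)],
          degree = as.integer(deg[names(part$membership)]),
          voterank = match(names(part$membership), vr),
          module = as.integer(part$membership))
        nodes <- nodes[order(nodes$node), ]
        write_tsv(nodes, file.path(rd, "network_nodes.tsv"))
        sets <- read_gmt(file.path(ind, "gene_sets.gmt"))
        background <- unique(c(unlist(sets), names(part$membership)))
        mods <- annotate_modules(part, sets, background)
        write_tsv(mods, file.path(rd, "network_modules.tsv"))
      } else {
        write_tsv(data.frame(node = character(0)), file.path(rd, "network_nodes.tsv"))
        write_tsv(data.frame(module = integer(0)), file.path(rd, "network_modules.tsv"))
      }
      record_outputs("network", outs)
    }
  }

  de <- NULL
  if ("expression" %in% config$stages) {
    outs <- c("de_results.tsv", "gsea.tsv")
    if (!cache_ok("expression", c("expression.tsv", "groups.tsv",
                                  "gene_sets.gmt"), outs)) {
      mat <- read_expr_matrix(file.path(ind, "expression.tsv"))
      grp <- read.delim(file.path(ind, "groups.tsv"), stringsAsFactors = FALSE)
      groups <- factor(grp$group[match(colnames(mat), grp$sample)],
                       levels = unique(grp$group))
      de <- moderated_t(mat, groups)
      write_tsv(de, file.path(rd, "de_results.tsv"))
      scores <- setNames(de$log2fc, de$gene)
      sets <- read_gmt(file.path(ind, "gene_sets.gmt"))
      gs <- gsea(scores, sets, n_perm = th$n_perm,
                 seed = child_seed(seed, 102L), min_size = 3L)
      write_tsv(gs, file.path(rd, "gsea.tsv"))
      record_outputs("expression", outs)
    } else {
      de <- read.delim(file.path(rd, "de_results.tsv"), stringsAsFactors = FALSE)
    }
  }

  if ("dcq" %in% config$stages) {
    outs <- c("proportions.tsv", "proportion_tests.tsv")
    if (!cache_ok("dcq", c("expression.tsv", "groups.tsv",
                           "cell_reference.tsv"), outs)) {
      mat <- read_expr_matrix(file.path(ind, "expression.tsv"))
      grp <- read.delim(file.path(ind, "groups.tsv"), stringsAsFactors = FALSE)
      groups <- factor(grp$group[match(colnames(mat), grp$sample)],
                       levels = unique(grp$group))
      ref <- read_expr_matrix(file.path(ind, "cell_reference.tsv"))
      props <- tryCatch(
        estimate_proportions(2^mat, ref, min_overlap = 0),
        error = function(e) NULL)
      if (!is.null(props)) {
        write_matrix_tsv(round(props, 8), file.path(rd, "proportions.tsv"),
                         id_col = "sample")
        write_tsv(compare_proportions(props, groups),
                  file.path(rd, "proportion_tests.tsv"))
        record_outputs("dcq", outs)
      }
    }
  }

  if ("cytokine" %in% config$stages) {
    outs <- c("cytokine_activity.tsv", "cytokine_tests.tsv", "cytokine_tree.nwk")
    if (!cache_ok("cytokine", c("expression.tsv", "groups.tsv",
                                "cytokine_signature.tsv"), outs)) {
      mat <- read_expr_matrix(file.path(ind, "expression.tsv"))
      grp <- read.delim(file.path(ind, "groups.tsv"), stringsAsFactors = FALSE)
      groups <- factor(grp$group[match(colnames(mat), grp$sample)],
                       levels = unique(grp$group))
      sig <- read_expr_matrix(file.path(ind, "cytokine_signature.tsv"))
      prof <- response_profile(mat)
      acts <- ridge_activity(prof, sig, lambda = th$lambda,
                             n_perm = th$n_perm,
                             seed = child_seed(seed, 103L),
                             min_overlap = min(100L, nrow(sig)))
      write_matrix_tsv(round(acts, 8), file.path(rd, "cytokine_activity.tsv"),
                       id_col = "sample")
      write_tsv(differential_activity(acts, groups),
                file.path(rd, "cytokine_tests.tsv"))
      writeLines(activity_dendrogram(acts)$newick,
                 file.path(rd, "cytokine_tree.nwk"))
      record_outputs("cytokine", outs)
    }
  }

  if ("integration" %in% config$stages && !is.null(candidates)) {
    outs <- c("lr_interactions.tsv", "actionable_targets.tsv")
    if (!cache_ok("integration", c("lr_pairs.tsv", "drug_gene.tsv"), outs)) {
      pairs <- read_pairs(file.path(ind, "lr_pairs.tsv"))
      names(pairs)[1:2] <- c("ligand", "receptor")
      inter <- map_lr(candidates, pairs)
      if (!is.null(de) && nrow(inter)) {
        inter <- intersect_receptors_de(inter, de)
      }
      write_tsv(inter, file.path(rd, "lr_interactions.tsv"))
      drugs <- read.delim(file.path(ind, "drug_gene.tsv"),
                          stringsAsFactors = FALSE)
      act <- actionable_targets(candidates, drugs, interactions = inter)
      write_tsv(act, file.path(rd, "actionable_targets.tsv"))
      record_outputs("integration", outs)
    }
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(rd)
}

#' Collate a completed run into summary tables
#'
#' Reads the stage outputs (no recomputation) and writes a deterministic
#' `report.json` summarizing candidate proteins, enrichment, network metrics,
#' DE, deconvolution, cytokine and actionability tables. Missing stages are
#' listed rather than recomputed.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return list of summary tables (invisibly writes `report.json`).
#' @export
pipeline_report <- function(run_dir) {
  stage_files <- c(
    mr = "mr_results.tsv", enrichment = "enrichment.tsv",
    network_nodes = "network_nodes.tsv", modules = "network_modules.tsv",
    de = "de_results.tsv", gsea = "gsea.tsv",
    proportions = "proportion_tests.tsv", cytokine = "cytokine_tests.tsv",
    actionable = "actionable_targets.tsv")
  present <- file.exists(file.path(run_dir, stage_files))
  report <- list(missing_stages = names(stage_files)[!present])
  for (nm in names(stage_files)[present]) {
    report[[nm]] <- read.delim(file.path(run_dir, stage_files[[nm]]),
                               stringsAsFactors = FALSE)
  }
  if (!is.null(report$mr)) {
    report$summary <- list(
      n_tested = sum(report$mr$status == "tested"),
      n_candidates = sum(report$mr$passes_robust_filter %in% TRUE),
      candidates = report$mr$gene_symbol[report$mr$passes_robust_filter %in% TRUE]
    )
  }
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
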