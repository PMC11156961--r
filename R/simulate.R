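#' Simulate a cis region's LD structure and allele frequencies
#'
#' AR(1) correlation r_ij = ld_rho^|i-j| (positive definite by construction)
#' with uniform minor allele frequencies and evenly spaced positions inside a
#' TSS window.
#'
#' @param m_variants number of variants.
#' @param ld_rho AR(1) correlation parameter in \[0, 1).
#' @param maf_range uniform MAF range (default 0.05-0.5).
#' @param seed RNG seed.
#' @param chrom,tss,window region coordinates (defaults chrom "1",
#'   TSS 1e6, 250 kb window).
#' @return list: `ld` ([ld_matrix()]), `maf`, `pos`, `chrom`, `tss`,
#'   `variant_ids`.
#' @export
sim_cis_region <- function(m_variants, ld_rho = 0.0, maf_range = c(0.05, 0.5),
                           seed = NULL, chrom = "1", tss = 1000000L,
                           window = 250000L) {
  if (ld_rho < 0 || ld_rho >= 1) stopf("ld_rho must be in [0, 1)")
  ids <- sprintf("rs%06d", seq_len(m_variants))
  r <- ld_rho^abs(outer(seq_len(m_variants), seq_len(m_variants), "-"))
  maf <- with_seed(seed, runif(m_variants, maf_range[1], maf_range[2]))
  pos <- as.integer(round(seq(tss - window, tss + window,
                              length.out = m_variants)))
  list(ld = ld_matrix(r, ids), maf = maf, pos = pos, chrom = chrom,
       tss = as.integer(tss), variant_ids = ids)
}

assoc_from_sim <- function(region, beta, se, n) {
  as_assoc_table(data.frame(
    variant_id = region$variant_ids, chrom = region$chrom, pos = region$pos,
    effect_allele = "A", other_allele = "G",
    eaf = region$maf, beta = beta, se = se,
    pvalue = pmax(2 * pnorm(-abs(beta / se)), 1e-300),
    n = n, stringsAsFactors = FALSE
  ))
}

#' Simulate two-sample MR summary statistics with planted truth
#'
#' Draws true variant effects on a protein (SD units), propagates them
#' through the region's LD to marginal effects, and emits exposure and
#' outcome association tables with realistic standard errors:
#' se_x = 1/sqrt(2 maf (1-maf) n_exp) for the continuous exposure and
#' se_y = 1/sqrt(2 maf (1-maf) n_out cf (1-cf)) for the binary (log-odds)
#' outcome. A fraction of instruments can be made invalid through a
#' directional pleiotropy offset added to their outcome effects.
#'
#' @param theta true causal log-odds per 1 SD of protein.
#' @param region from [sim_cis_region()].
#' @param n_exp exposure sample size (default 35559, aptamer-cohort scale).
#' @param n_out outcome sample size (default 439533 = 4884 + 434649).
#' @param case_frac outcome case fraction (default 4884/439533).
#' @param k_causal number of variants with true protein effects (default all).
#' @param effect_range uniform range of |true effect| in SD units
#'   (default 0.05-0.2, giving instrument F well above 10 at `n_exp`).
#' @param pleiotropy list `frac_invalid`, `offset`: invalid instruments get
#'   a direct outcome effect of `offset` on their exposure-increasing allele
#'   orientation (i.e. the offset is sign-aligned with the variant's protein
#'   effect), the standard construction of directional pleiotropy.
#' @param seed RNG seed.
#' @return list: `exposure`, `outcome` (`assoc_table`s), `truth` (theta,
#'   per-variant true marginal effects, invalid flags, offsets).
#' @export
sim_two_sample <- function(theta, region, n_exp = 35559, n_out = 439533,
                           case_frac = 4884 / 439533, k_causal = NULL,
                           effect_range = c(0.05, 0.2),
                           pleiotropy = list(frac_invalid = 0, offset = 0),
                           seed = NULL) {
  m <- length(region$variant_ids)
  k_causal <- k_causal %||% m
  if (k_causal > m) stopf("k_causal exceeds the number of variants")
  with_seed(seed, {
    b <- numeric(m)
    which_causal <- sample.int(m, k_causal)
    b[which_causal] <- sample(c(-1, 1), k_causal, replace = TRUE) *
      runif(k_causal, effect_range[1], effect_range[2])
    mu_x <- as.vector(region$ld$r %*% b)
    alpha <- numeric(m)
    n_invalid <- round((pleiotropy$frac_invalid %||% 0) * m)
    invalid <- rep(FALSE, m)
    if (n_invalid > 0) {
      invalid[sample.int(m, n_invalid)] <- TRUE
      # direct effects act on the exposure-increasing orientation, so they
      # shift all invalid Wald ratios the same way (directional pleiotropy)
      sgn <- sign(b[invalid])
      sgn[sgn == 0] <- 1
      alpha[invalid] <- (pleiotropy$offset %||% 0) * sgn
    }
    mu_y <- theta * mu_x + as.vector(region$ld$r %*% alpha)
    se_x <- 1 / sqrt(2 * region$maf * (1 - region$maf) * n_exp)
    se_y <- 1 / sqrt(2 * region$maf * (1 - region$maf) * n_out *
                       case_frac * (1 - case_frac))
    bx <- rnorm(m, mu_x, se_x)
    by <- rnorm(m, mu_y, se_y)
    list(
      exposure = assoc_from_sim(region, bx, se_x, n_exp),
      outcome = assoc_from_sim(region, by, se_y, n_out),
      truth = list(theta = theta, mu_x = mu_x, mu_y = mu_y,
                   invalid = invalid, alpha = alpha,
                   case_frac = case_frac)
    )
  })
}

#' Simulate a synthetic proteome for end-to-end MR testing
#'
#' Generates per-protein cis regions and two-sample summary statistics with a
#' subset of proteins carrying a planted causal effect, plus the pooled
#' outcome table, protein metadata and per-protein LD, ready for
#' [run_proteome_mr()].
#'
#' @param n_proteins proteins in the panel.
#' @param n_causal proteins with true effect `theta` (the rest are null).
#' @param theta planted causal effect.
#' @param m_variants variants per cis region (default 17, the
#'   aptamer-cohort median instrument count; regions are generated
#'   LD-independent so every variant is an instrument).
#' @param ld_rho within-region AR(1) LD (default 0).
#' @param seed RNG seed.
#' @param ... passed to [sim_two_sample()].
#' @return list: `proteins` (metadata), `exposure_store`, `outcome`,
#'   `ld_store`, `truth` (named vector of true thetas).
#' @export
sim_proteome <- function(n_proteins, n_causal = 0L, theta = 0,
                         m_variants = 17L, ld_rho = 0, seed = 1L, ...) {
  pid <- sprintf("PROT%03d", seq_len(n_proteins))
  causal <- seq_len(n_proteins) <= n_causal
  exposure_store <- list()
  ld_store <- list()
  outcomes <- vector("list", n_proteins)
  truth <- setNames(ifelse(causal, theta, 0), pid)
  proteins <- data.frame(
    protein_id = pid, gene_symbol = pid,
    chrom = as.character(seq_len(n_proteins)),
    tss = 1000000L, stringsAsFactors = FALSE
  )
  for (i in seq_len(n_proteins)) {
    region <- sim_cis_region(m_variants, ld_rho = ld_rho,
                             seed = child_seed(seed, 2L * i),
                             chrom = proteins$chrom[i])
    region$variant_ids <- sprintf("%s_%s", pid[i], region$variant_ids)
    dimnames(region$ld$r) <- list(region$variant_ids, region$variant_ids)
    region$ld$variant_ids <- region$variant_ids
    ss <- sim_two_sample(truth[i], region, seed = child_seed(seed, 2L * i + 1L),
                         ...)
    exposure_store[[pid[i]]] <- ss$exposure
    ld_store[[pid[i]]] <- region$ld
    outcomes[[i]] <- as.data.frame(ss$outcome)
  }
  outcome <- as_assoc_table(do.call(rbind, outcomes))
  list(proteins = proteins, exposure_store = exposure_store,
       outcome = outcome, ld_store = ld_store, truth = truth)
}

#' Simulate a two-group log-scale expression matrix with planted DE genes
#'
#' Log-normal baseline, Gaussian noise, and group shifts planted in a random
#' subset of genes (half up, half down in the second group).
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (default 12, the valve-leaflet
#'   microarray design).
#' @param frac_de fraction of genes with a planted shift.
#' @param lfc planted |log2 fold change| (scalar, or function(k) drawing k
#'   values).
#' @param noise_sd within-group SD on the log2 scale (default 0.5).
#' @param seed RNG seed.
#' @param group_labels two labels, control first (default c("control","case")).
#' @return list: `mat` (genes x samples, log2 scale), `groups`, `truth`
#'   (data.frame gene, is_de, lfc).
#' @export
sim_expression <- function(n_genes, n_per_group = 12L, frac_de = 0.1,
                           lfc = 2, noise_sd = 0.5, seed = NULL,
                           group_labels = c("control", "case")) {
  with_seed(seed, {
    n <- 2L * n_per_group
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    base <- rnorm(n_genes, mean = 8, sd = 2)
    n_de <- round(frac_de * n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    shifts <- numeric(n_genes)
    if (n_de > 0) {
      mag <- if (is.function(lfc)) lfc(n_de) else rep(lfc, n_de)
      shifts[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) * mag
    }
    groups <- factor(rep(group_labels, each = n_per_group),
                     levels = group_labels)
    mu <- outer(base, rep(0, n)) +
      outer(shifts, as.numeric(groups == group_labels[2]))
    mat <- mu + matrix(rnorm(n_genes * n, sd = noise_sd), n_genes, n)
    dimnames(mat) <- list(genes, paste0(rep(group_labels, each = n_per_group),
                                        "_", rep(seq_len(n_per_group), 2)))
    list(mat = mat, groups = groups,
         truth = data.frame(gene = genes, is_de = seq_len(n_genes) %in% de_idx,
                            lfc = shifts, stringsAsFactors = FALSE))
  })
}

#' Simulate raw microarray intensities with additive + multiplicative noise
#'
#' The error model the glog transform is designed for: intensity
#' x = mu * exp(eta) + epsilon with multiplicative noise eta and additive
#' background epsilon.
#'
#' @param n_genes,n_samples matrix dimensions.
#' @param sd_mult multiplicative (log-scale) noise SD (default 0.15).
#' @param sd_add additive background noise SD (default 60).
#' @param seed RNG seed.
#' @return genes x samples intensity matrix (attribute `mu` holds the truth).
#' @export
sim_microarray <- function(n_genes, n_samples, sd_mult = 0.15, sd_add = 60,
                           seed = NULL) {
  with_seed(seed, {
    mu <- exp(rnorm(n_genes, mean = log(300), sd = 1.6))
    x <- outer(mu, rep(1, n_samples)) *
      exp(matrix(rnorm(n_genes * n_samples, sd = sd_mult), n_genes)) +
      matrix(rnorm(n_genes * n_samples, sd = sd_add), n_genes)
    dimnames(x) <- list(sprintf("GENE%05d", seq_len(n_genes)),
                        sprintf("S%02d", seq_len(n_samples)))
    attr(x, "mu") <- mu
    x
  })
}

#' Simulate a marker-structured cell-type reference matrix
#'
#' Each cell type gets `n_markers` dedicated marker genes expressed `fold`
#' times above the shared baseline, mimicking an immune signature matrix.
#'
#' @param n_types cell types (default 22).
#' @param n_markers marker genes per type (default 30).
#' @param n_background non-specific background genes (default 200).
#' @param fold marker over-expression factor (default 20).
#' @param seed RNG seed.
#' @return genes x types non-negative matrix.
#' @export
sim_reference <- function(n_types = 22L, n_markers = 30L, n_background = 200L,
                          fold = 20, seed = NULL) {
  with_seed(seed, {
    n_genes <- n_types * n_markers + n_background
    base <- exp(rnorm(n_genes, log(20), 0.6))
    ref <- matrix(rep(base, n_types), n_genes, n_types)
    for (ct in seq_len(n_types)) {
      idx <- (ct - 1L) * n_markers + seq_len(n_markers)
      ref[idx, ct] <- ref[idx, ct] * fold * exp(rnorm(n_markers, 0, 0.2))
    }
    dimnames(ref) <- list(sprintf("MRK%05d", seq_len(n_genes)),
                          sprintf("CT%02d", seq_len(n_types)))
    ref
  })
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = alpha), n, k, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate bulk mixtures of a reference with known proportions
#'
#' bulk = ref x proportions' with per-entry multiplicative Gaussian noise of
#' SD `noise_sd` times the signal.
#'
#' @param ref genes x types reference matrix.
#' @param dirichlet_alpha Dirichlet concentration (scalar or per type).
#' @param n_samples number of mixtures (default 40).
#' @param noise_sd noise SD as a fraction of signal (default 0.1).
#' @param seed RNG seed.
#' @return list: `bulk` (genes x samples), `props` (samples x types truth).
#' @export
sim_mixture <- function(ref, dirichlet_alpha = 1, n_samples = 40L,
                        noise_sd = 0.1, seed = NULL) {
  with_seed(seed, {
    k <- ncol(ref)
    alpha <- rep(dirichlet_alpha, length.out = k)
    props <- rdirichlet(n_samples, alpha)
    signal <- as.matrix(ref) %*% t(props)
    bulk <- pmax(signal * (1 + matrix(rnorm(length(signal), sd = noise_sd),
                                      nrow(signal))), 0)
    dimnames(bulk) <- list(rownames(ref), sprintf("MIX%02d", seq_len(n_samples)))
    dimnames(props) <- list(colnames(bulk), colnames(ref))
    list(bulk = bulk, props = props)
  })
}

#' Simulate a cytokine response signature matrix
#'
#' @param n_genes genes (default 1500).
#' @param n_cytokines cytokines (default 43, the activity-profiling panel
#'   size).
#' @param seed RNG seed.
#' @return genes x cytokines matrix of expected log-fold responses.
#' @export
sim_signature <- function(n_genes = 1500L, n_cytokines = 43L, seed = NULL) {
  with_seed(seed, {
    s <- matrix(rnorm(n_genes * n_cytokines, sd = 1), n_genes, n_cytokines)
    dimnames(s) <- list(sprintf("GENE%05d", seq_len(n_genes)),
                        sprintf("CYTO%02d", seq_len(n_cytokines)))
    s
  })
}

#' Simulate expression responses driven by known cytokine activities
#'
#' profile = sig\[, active\] x strengths + Gaussian noise, replicated over
#' samples.
#'
#' @param sig signature matrix from [sim_signature()].
#' @param active_set cytokine names (or indices) that are active.
#' @param strengths activity strength per active cytokine (recycled).
#' @param noise_sd residual SD (default 0.5).
#' @param n_samples replicate profiles (default 1).
#' @param seed RNG seed.
#' @return list: `profile` (genes x samples), `truth` (active set,
#'   strengths).
#' @export
sim_cytokine_response <- function(sig, active_set, strengths = 1,
                                  noise_sd = 0.5, n_samples = 1L,
                                  seed = NULL) {
  with_seed(seed, {
    strengths <- rep(strengths, length.out = length(active_set))
    signal <- if (length(active_set)) {
      as.matrix(sig[, active_set, drop = FALSE]) %*% strengths
    } else {
      matrix(0, nrow(sig), 1)
    }
    prof <- matrix(rep(signal, n_samples), nrow(sig)) +
      matrix(rnorm(nrow(sig) * n_samples, sd = noise_sd), nrow(sig))
    dimnames(prof) <- list(rownames(sig), sprintf("S%02d", seq_len(n_samples)))
    list(profile = prof,
         truth = list(active = active_set, strengths = strengths))
  })
}

#' Simulate a PPI-like graph
#'
#' Without planted communities: a Barabasi-Albert scale-free graph. With
#' `planted_comms = list(sizes, p_in, p_out)`: a planted-partition graph with
#' Bernoulli within-block probability `p_in` and between-block probability
#' `p_out`, plus truth membership.
#'
#' @param n nodes (ignored when `planted_comms$sizes` is given).
#' @param attach_m Barabasi-Albert attachment edges (default 2).
#' @param planted_comms optional list(sizes, p_in, p_out).
#' @param seed RNG seed.
#' @return list: `graph` (igraph, nodes named "G1"...), `membership`
#'   (truth; NULL for plain scale-free graphs).
#' @export
sim_ppi <- function(n = 60L, attach_m = 2L, planted_comms = NULL,
                    seed = NULL) {
  with_seed(seed, {
    if (is.null(planted_comms)) {
      g <- igraph::sample_pa(n, m = attach_m, directed = FALSE)
      igraph::V(g)$name <- paste0("G", seq_len(n))
      return(list(graph = g, membership = NULL))
    }
    sizes <- planted_comms$sizes
    p_in <- planted_comms$p_in %||% 0.35
    p_out <- planted_comms$p_out %||% 0.02
    nn <- sum(sizes)
    pm <- matrix(p_out, length(sizes), length(sizes))
    diag(pm) <- p_in
    g <- igraph::sample_sbm(nn, pref.matrix = pm, block.sizes = sizes)
    igraph::V(g)$name <- paste0("G", seq_len(nn))
    membership <- setNames(rep(seq_along(sizes), sizes), igraph::V(g)$name)
    list(graph = igraph::simplify(g), membership = membership)
  })
}

#' Simulate gene sets with a planted overlap to a query
#'
#' Random sets drawn from the background, plus one planted set built to share
#' exactly `planted_overlap` genes with the query.
#'
#' @param background universe of symbols.
#' @param query query gene vector (required if `planted_overlap > 0`).
#' @param n_sets random sets (default 20).
#' @param set_size set size (default 50, recycled).
#' @param planted_overlap planted hits between query and the planted set.
#' @param seed RNG seed.
#' @return list: `sets` (named list; planted set named "PLANTED"), `truth`.
#' @export
sim_genesets <- function(background, query = NULL, n_sets = 20L,
                         set_size = 50L, planted_overlap = 0L, seed = NULL) {
  with_seed(seed, {
    background <- unique(norm_symbol(background))
    set_size <- rep(set_size, length.out = n_sets)
    sets <- lapply(seq_len(n_sets), function(i) {
      sample(background, set_size[i])
    })
    names(sets) <- sprintf("RANDOM%02d", seq_len(n_sets))
    if (planted_overlap > 0) {
      if (is.null(query)) stopf("planted overlap requires a query")
      query <- intersect(unique(norm_symbol(query)), background)
      if (planted_overlap > length(query)) stopf("overlap exceeds query size")
      inside <- sample(query, planted_overlap)
      K <- max(set_size[1], planted_overlap)
      outside <- sample(setdiff(background, query), K - planted_overlap)
      sets$PLANTED <- c(inside, outside)
    }
    list(sets = sets,
         truth = list(planted_overlap = planted_overlap))
  })
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster assignments; 1 means identical
#' partitions, 0 is the expectation under random labelling. Used to score
#' community-detection recovery against planted truth.
#'
#' @param a,b cluster assignments over the same elements (matched by name
#'   when both are named).
#' @return numeric in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  if (length(a) != length(b)) stopf("partitions must cover the same elements")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
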