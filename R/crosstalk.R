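#' Build a candidate-protein table from MR results
#'
#' @param results `proteome_mr` results data.frame (or compatible) filtered to
#'   the candidates of interest.
#' @param roles optional named character vector gene -> role
#'   (`ligand`, `receptor`, `soluble_receptor`, `other`).
#' @return data.frame: `gene_symbol`, `mr_direction` (+1 if OR > 1 else -1),
#'   `or_`, `p`, `role`.
#' @export
candidate_proteins <- function(results, roles = NULL) {
  genes <- norm_symbol(results$gene_symbol)
  role <- rep("other", length(genes))
  if (!is.null(roles)) {
    names(roles) <- norm_symbol(names(roles))
    hit <- genes %in% names(roles)
    role[hit] <- roles[genes[hit]]
  }
  data.frame(
    gene_symbol = genes,
    mr_direction = ifelse(results$or_ivw > 1, 1L, -1L),
    or_ = results$or_ivw,
    p = results$p_ivw,
    role = role,
    stringsAsFactors = FALSE
  )
}

#' Map candidate proteins onto ligand-receptor pairs
#'
#' Returns every pair in which a candidate appears as the ligand or the
#' receptor, tagged with the candidate's role in the pair and its MR risk
#' direction. Curated additions (e.g. interactions absent from the published
#' compilation) can be supplied with their own source label.
#'
#' @param candidates data.frame from [candidate_proteins()].
#' @param pairs data.frame with columns `ligand`, `receptor` and optionally
#'   `source`.
#' @param additions optional extra pairs data.frame; rows lacking a `source`
#'   are labelled "curated".
#' @return data.frame: `candidate`, `candidate_role_in_pair`, `partner`,
#'   `ligand`, `receptor`, `mr_direction`, `source`.
#' @export
map_lr <- function(candidates, pairs, additions = NULL) {
  pairs <- data.frame(ligand = norm_symbol(pairs$ligand),
                      receptor = norm_symbol(pairs$receptor),
                      source = if (!is.null(pairs$source)) pairs$source else "database",
                      stringsAsFactors = FALSE)
  if (!is.null(additions)) {
    additions <- data.frame(ligand = norm_symbol(additions$ligand),
                            receptor = norm_symbol(additions$receptor),
                            source = if (!is.null(additions$source)) additions$source else "curated",
                            stringsAsFactors = FALSE)
    pairs <- rbind(pairs, additions)
  }
  pairs <- pairs[!duplicated(pairs[c("ligand", "receptor")]), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    g <- candidates$gene_symbol[i]
    as_lig <- pairs[pairs$ligand == g, , drop = FALSE]
    as_rec <- pairs[pairs$receptor == g, , drop = FALSE]
    if (nrow(as_lig)) {
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = g, candidate_role_in_pair = "ligand",
        partner = as_lig$receptor, ligand = as_lig$ligand,
        receptor = as_lig$receptor,
        mr_direction = candidates$mr_direction[i], source = as_lig$source,
        stringsAsFactors = FALSE)
    }
    if (nrow(as_rec)) {
      rows[[length(rows) + 1L]] <- data.frame(
        candidate = g, candidate_role_in_pair = "receptor",
        partner = as_rec$ligand, ligand = as_rec$ligand,
        receptor = as_rec$receptor,
        mr_direction = candidates$mr_direction[i], source = as_rec$source,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(candidate = character(0),
                      candidate_role_in_pair = character(0),
                      partner = character(0), ligand = character(0),
                      receptor = character(0), mr_direction = integer(0),
                      source = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell-type enrichment of cognate receptors
#'
#' Tests whether the receptors of candidate blood ligands are
#' over-represented in cell-type-enriched gene sets (e.g. the nine cardiac
#' cell types), via [ora_batch()].
#'
#' @param receptors character vector of receptor symbols.
#' @param celltype_sets named list of cell-type gene sets.
#' @param background explicit universe.
#' @return [ora_batch()] data.frame.
#' @export
receptor_celltype_enrichment <- function(receptors, celltype_sets, background) {
  ora_batch(receptors, celltype_sets, background)
}

#' Annotate ligand-receptor interactions with valve DE results
#'
#' Each interaction row gains the tissue partner's log2 fold change, p-value,
#' FDR and DE flag; partners absent from the DE table are marked
#' "not measured". The count of DE partners is stored in attribute `n_de`.
#'
#' @param interactions data.frame from [map_lr()].
#' @param de DE results data.frame (from [moderated_t()], with DE flags
#'   applied via the thresholds of [de_filter()]).
#' @param lfc_min,fdr_max DE flag thresholds (defaults 1.25 and 0.05).
#' @return annotated interactions data.frame.
#' @export
intersect_receptors_de <- function(interactions, de, lfc_min = 1.25,
                                   fdr_max = 0.05) {
  de_gene <- norm_symbol(de$gene)
  idx <- match(norm_symbol(interactions$partner), de_gene)
  interactions$partner_log2fc <- de$log2fc[idx]
  interactions$partner_pvalue <- de$pvalue[idx]
  interactions$partner_fdr <- de$fdr[idx]
  measured <- !is.na(idx)
  flag <- measured & abs(interactions$partner_log2fc) > lfc_min &
    interactions$partner_fdr < fdr_max
  interactions$partner_de <- ifelse(measured,
                                    ifelse(flag, "de", "not_de"),
                                    "not measured")
  attr(interactions, "n_de") <- length(unique(interactions$partner[flag %in% TRUE]))
  interactions
}

inhibitor_class <- c("inhibitor", "antagonist", "blocker", "neutralizer",
                     "inverse agonist", "blocking antibody",
                     "neutralizing antibody", "suppressor", "antibody")
agonist_class <- c("agonist", "activator", "inducer", "partial agonist",
                   "stimulator")

normalize_action <- function(action) {
  a <- tolower(trimws(action))
  out <- rep("other", length(a))
  out[a %in% inhibitor_class] <- "inhibitor_like"
  out[a %in% agonist_class] <- "agonist_like"
  out
}

#' Directional drug-target actionability
#'
#' Joins candidate proteins (and, via the interaction table, their tissue
#' partners) with a drug-gene table and applies direction-aware rules:
#' (a) a risk-increasing candidate (OR > 1) is actionable through
#' inhibitor-class drugs on the candidate itself or on its receptor;
#' (b) a risk-decreasing candidate is actionable through agonist-class drugs
#' on the candidate or its receptor; (c) a risk-decreasing soluble
#' (decoy) receptor makes inhibitor-class drugs on its cognate ligand
#' actionable, because the decoy itself dampens the ligand's signaling.
#' Rows with unrecognized action verbs are kept and flagged
#' "unclassified action".
#'
#' @param candidates data.frame from [candidate_proteins()].
#' @param drug_table data.frame with columns `drug`, `gene`, `action`.
#' @param interactions optional data.frame from [map_lr()] to reach partners.
#' @return data.frame: `protein`, `target_gene`, `partner`, `drug`,
#'   `drug_action`, `actionable`, `rationale`.
#' @export
actionable_targets <- function(candidates, drug_table, interactions = NULL) {
  drug_table <- data.frame(drug = as.character(drug_table$drug),
                           gene = norm_symbol(drug_table$gene),
                           action = as.character(drug_table$action),
                           stringsAsFactors = FALSE)
  cls <- normalize_action(drug_table$action)
  rows <- list()
  add_row <- function(protein, target_gene, partner, i, actionable, rationale) {
    rows[[length(rows) + 1L]] <<- data.frame(
      protein = protein, target_gene = target_gene, partner = partner,
      drug = drug_table$drug[i], drug_action = drug_table$action[i],
      action_class = cls[i], actionable = actionable, rationale = rationale,
      stringsAsFactors = FALSE)
  }
  for (ci in seq_len(nrow(candidates))) {
    g <- candidates$gene_symbol[ci]
    dir <- candidates$mr_direction[ci]
    role <- candidates$role[ci]
    partners <- if (!is.null(interactions)) {
      unique(interactions$partner[interactions$candidate == g])
    } else character(0)
    # drugs on the candidate itself or on its pair partners
    targets <- c(setNames(rep("self", 1), g),
                 setNames(rep("partner", length(partners)), partners))
    for (tg in names(targets)) {
      hit <- which(drug_table$gene == tg)
      for (i in hit) {
        kind <- targets[[tg]]
        partner <- if (kind == "partner") tg else NA_character_
        if (cls[i] == "other") {
          add_row(g, tg, partner, i, FALSE, "unclassified action")
        } else if (dir == 1L && cls[i] == "inhibitor_like") {
          add_row(g, tg, partner, i, TRUE,
                  if (kind == "self") "risk_up_inhibit_candidate"
                  else "risk_up_inhibit_partner")
        } else if (dir == -1L && cls[i] == "agonist_like" &&
                   role != "soluble_receptor") {
          add_row(g, tg, partner, i, TRUE,
                  if (kind == "self") "protective_agonize_candidate"
                  else "protective_agonize_partner")
        } else if (dir == -1L && role == "soluble_receptor" &&
                   kind == "partner" && cls[i] == "inhibitor_like") {
          add_row(g, tg, partner, i, TRUE, "decoy_ligand_neutralizer")
        } else {
          add_row(g, tg, partner, i, FALSE, "direction mismatch")
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(protein = character(0), target_gene = character(0),
                      partner = character(0), drug = character(0),
                      drug_action = character(0), action_class = character(0),
                      actionable = logical(0), rationale = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("protein", "target_gene", "drug")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
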