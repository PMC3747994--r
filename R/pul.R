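# Polysaccharide utilization locus (PUL) activation: susC/susD marker-pair
# identification, fold-changes versus the minimal-medium-glucose reference,
# and the >100-fold reporting/activation criteria.

#' Identify susC/susD marker pairs
#'
#' Forms pairs from a susC gene followed (in genome order, allowing up to
#' `max_intervening` intervening genes) by a susD gene of the same PUL;
#' unpaired homologs are listed separately.
#'
#' @param annotation Gene annotation data frame with `gene_id`,
#'   `species_id`, `start`, `sus_role` (susC/susD/none) and `pul` columns.
#' @param max_intervening Maximum genes allowed between the susC and susD
#'   members of a pair.
#' @return List with `pairs` (data frame: susC_gene_id, susD_gene_id,
#'   pul_id, species_id) and `unpaired` (character vector of gene ids).
#' @export
pair_suscd <- function(annotation, max_intervening = 1L) {
  stopifnot(all(c("gene_id", "species_id", "start", "sus_role") %in%
                  names(annotation)))
  pairs <- list(); paired <- character(0)
  for (s in unique(annotation$species_id)) {
    g <- annotation[annotation$species_id == s, ]
    g <- g[order(g$start), ]
    susC_idx <- which(g$sus_role == "susC")
    for (i in susC_idx) {
      cand <- seq(i + 1L, min(i + 1L + max_intervening, nrow(g)))
      cand <- cand[cand <= nrow(g) & cand > i]
      j <- cand[g$sus_role[cand] == "susD" &
                  !g$gene_id[cand] %in% paired &
                  (is.na(g$pul[cand]) | is.na(g$pul[i]) |
                     g$pul[cand] == g$pul[i])]
      if (length(j)) {
        j <- j[1]
        pairs[[length(pairs) + 1L]] <- data.frame(
          susC_gene_id = g$gene_id[i], susD_gene_id = g$gene_id[j],
          pul_id = g$pul[i], species_id = s, stringsAsFactors = FALSE)
        paired <- c(paired, g$gene_id[i], g$gene_id[j])
      }
    }
  }
  pairs_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(susC_gene_id = character(), susD_gene_id = character(),
               pul_id = character(), species_id = character())
  sus_all <- annotation$gene_id[annotation$sus_role %in% c("susC", "susD")]
  list(pairs = pairs_df, unpaired = setdiff(sus_all, paired))
}

#' Fold-changes versus a reference condition
#'
#' Per-gene, per-replicate fold-change of normalized expression relative to
#' the mean of the reference condition (conventionally minimal medium plus
#' glucose, MM-Glc), with a pseudocount guarding against zeros:
#' FC = (value + pseudocount) / (mean reference + pseudocount).
#'
#' @param normalized_counts Genes x samples matrix of normalized values.
#' @param condition Character vector over samples naming each sample's
#'   condition.
#' @param reference Name of the reference condition.
#' @param pseudocount Added to numerator and denominator (default 1).
#' @return Genes x non-reference-samples matrix of fold-changes.
#' @export
fold_change_vs_reference <- function(normalized_counts, condition,
                                     reference = "MM-Glc", pseudocount = 1) {
  normalized_counts <- as.matrix(normalized_counts)
  ref_cols <- which(condition == reference)
  if (!length(ref_cols)) stop("reference condition '", reference,
                              "' has no samples")
  ref_mean <- rowMeans(normalized_counts[, ref_cols, drop = FALSE])
  other <- which(condition != reference)
  fc <- sweep(normalized_counts[, other, drop = FALSE] + pseudocount, 1,
              ref_mean + pseudocount, "/")
  fc
}

#' Reporting filter for a susC/susD pair on a substrate
#'
#' A pair is reported when either of its genes shows a greater-than-100-fold
#' increase relative to the reference in at least one replicate (strictly
#' greater; a fold-change of exactly 100 does not qualify).
#'
#' @param susC_fc,susD_fc Per-replicate fold-changes of the two genes.
#' @param fold_gt Strict threshold (default 100).
#' @return Logical.
#' @export
reporting_filter <- function(susC_fc, susD_fc, fold_gt = 100) {
  if (!length(susC_fc) || !length(susD_fc)) stop("need >= 1 replicate")
  any(susC_fc > fold_gt) || any(susD_fc > fold_gt)
}

#' PUL activation call for a susC/susD pair on a substrate
#'
#' A pair is called activated when, for BOTH genes, (i) the fold-change
#' exceeds the threshold in at least `min_reps` replicates and (ii) the mean
#' fold-change across all replicates exceeds the threshold.  Both
#' comparisons are strict.  The mean is arithmetic by default
#' (`mean_type = "geometric"` selects the geometric mean).
#'
#' @param susC_fc,susD_fc Per-replicate fold-changes (>= 2 replicates).
#' @param fold_gt Strict threshold (default 100).
#' @param min_reps Minimum replicates above threshold (default 2).
#' @param mean_type `"arithmetic"` or `"geometric"`.
#' @return Logical (with a warning and FALSE when only one replicate).
#' @examples
#' activation_call(c(150, 120, 130), c(200, 110, 160))  # TRUE
#' activation_call(c(150, 120, 130), c(200, 90, 60))    # FALSE
#' @export
activation_call <- function(susC_fc, susD_fc, fold_gt = 100, min_reps = 2L,
                            mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  if (length(susC_fc) < 2 || length(susD_fc) < 2) {
    warning("activation requires >= 2 replicates")
    return(FALSE)
  }
  mfun <- if (mean_type == "arithmetic") mean else
    function(x) exp(mean(log(x)))
  gene_ok <- function(fc) sum(fc > fold_gt) >= min_reps && mfun(fc) > fold_gt
  gene_ok(susC_fc) && gene_ok(susD_fc)
}

#' Cross-reference a pair's in-vivo RNA and protein detection
#'
#' For each diet, a pair is "expressed" at the RNA level when both genes are
#' detected in at least 5 of 7 animals (threshold scales as
#' `ceiling(5/7 * n)` for other group sizes), and at the protein level when
#' both genes are detected in all animals assayed (2 of 2 in the emulated
#' design).  A pair that is expressed and differentially expressed between
#' diets is "expressed_significant".
#'
#' @param rna_detect Logical matrix, genes x animals, per diet: a named list
#'   `list(dietA = matrix, dietB = matrix)` with both pair genes as rows.
#' @param protein_detect Same structure for protein-level detection.
#' @param de_flags Named logical vector per assay (`rna`, `protein`): was
#'   the pair significantly diet-responsive in that assay.
#' @return Data frame: diet x assay categories in
#'   \{expressed_significant, expressed, absent\}.
#' @export
crossref_in_vivo <- function(rna_detect, protein_detect,
                             de_flags = c(rna = FALSE, protein = FALSE)) {
  categorize <- function(mat, frac_rule) {
    n <- ncol(mat)
    thr <- if (frac_rule) ceiling(5 / 7 * n) else n
    all(rowSums(mat) >= thr)
  }
  diets <- names(rna_detect)
  out <- do.call(rbind, lapply(diets, function(d) {
    rna_ok <- categorize(rna_detect[[d]], frac_rule = TRUE)
    pro_ok <- categorize(protein_detect[[d]], frac_rule = FALSE)
    data.frame(
      diet = d,
      rna = if (rna_ok && de_flags[["rna"]]) "expressed_significant"
            else if (rna_ok) "expressed" else "absent",
      protein = if (pro_ok && de_flags[["protein"]]) "expressed_significant"
                else if (pro_ok) "expressed" else "absent",
      stringsAsFactors = FALSE)
  }))
  out
}
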