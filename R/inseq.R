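# Transposon-insertion (INSeq) fitness: per-mutant output/input
# representation ratios with the "<0.01" flooring convention, gene-level
# aggregation under the first-80% insertion rule, and library statistics.

#' Normalize insertion libraries to proportions
#'
#' Converts input and output counts to within-population proportions
#' (count / population total), the representation scale on which fitness is
#' defined.
#'
#' @param table Data frame with `mutant_id`, `input_count`, `output_count`
#'   (e.g. an `inseq_table`).
#' @return The table with `input_prop` and `output_prop` columns, each
#'   summing to 1.
#' @export
normalize_library <- function(table) {
  stopifnot(all(c("mutant_id", "input_count", "output_count") %in%
                  names(table)))
  if (nrow(table) == 0) stop("empty insertion table")
  ti <- sum(table$input_count); to <- sum(table$output_count)
  if (ti <= 0 || to <= 0) stop("input and output totals must be positive")
  table$input_prop <- table$input_count / ti
  table$output_prop <- table$output_count / to
  table
}

#' Per-mutant fitness with flooring
#'
#' Fitness is the mutant's output proportion divided by its input
#' proportion.  Mutants never observed in the output (and any computed ratio
#' below the floor) are reported at the floor value with `floored = TRUE`,
#' matching the convention of plotting undetectable mutants as "<0.01"; the
#' raw ratio is kept alongside.  Mutants absent from the input cannot be
#' normalized and are excluded (with a note attribute).
#'
#' @param table Output of [normalize_library()].
#' @param floor Floor value (default 0.01).
#' @return The table (input-positive rows) with `fitness_raw`, `fitness`
#'   and `floored` columns.
#' @export
mutant_fitness <- function(table, floor = 0.01) {
  stopifnot(all(c("input_prop", "output_prop") %in% names(table)))
  excluded <- table$mutant_id[table$input_prop == 0]
  table <- table[table$input_prop > 0, , drop = FALSE]
  raw <- table$output_prop / table$input_prop
  table$fitness_raw <- raw
  table$floored <- raw < floor
  table$fitness <- pmax(raw, floor)
  attr(table, "excluded_zero_input") <- excluded
  table
}

#' Gene-level fitness aggregates
#'
#' Aggregates mutant fitness by disrupted gene over qualifying insertions:
#' genic insertions lying within the first `coverage_cutoff` fraction of the
#' gene (insertions near the 3' end may not disrupt function and are
#' excluded).  Gene fitness is the arithmetic mean of qualifying mutant
#' fitness values; genes with no qualifying insertion are absent from the
#' output.
#'
#' @param table Output of [mutant_fitness()] with `gene_id` and
#'   `position_fraction` columns.
#' @param coverage_cutoff Fraction of gene length considered disruptive
#'   (default 0.8).
#' @return Data frame: `gene_id`, `gene_fitness`, `n_insertions`.
#' @export
gene_fitness <- function(table, coverage_cutoff = 0.8) {
  stopifnot(all(c("gene_id", "position_fraction", "fitness") %in%
                  names(table)))
  q <- !is.na(table$gene_id) & table$position_fraction <= coverage_cutoff
  tq <- table[q, , drop = FALSE]
  if (nrow(tq) == 0)
    return(data.frame(gene_id = character(), gene_fitness = numeric(),
                      n_insertions = integer()))
  gf <- tapply(tq$fitness, tq$gene_id, mean)
  out <- data.frame(gene_id = names(gf), gene_fitness = as.numeric(gf),
                    n_insertions = as.integer(table(tq$gene_id)[names(gf)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Insertion-library statistics
#'
#' Library summary under the same first-80% rule used for gene fitness: the
#' number of distinct mutants, the percentage of ORFs covered by at least
#' one qualifying insertion, and the mean number of distinct qualifying
#' insertions per covered ORF.
#'
#' @param table Insertion table with `mutant_id`, `gene_id`,
#'   `position_fraction`.
#' @param gene_catalog Character vector of all ORF ids.
#' @param coverage_cutoff First-fraction rule (default 0.8).
#' @return List: `n_distinct_mutants`, `pct_orfs_covered`,
#'   `mean_insertions_per_orf` (NA when nothing is covered).
#' @export
library_stats <- function(table, gene_catalog, coverage_cutoff = 0.8) {
  q <- !is.na(table$gene_id) & table$position_fraction <= coverage_cutoff
  per_gene <- table(table$gene_id[q])
  covered <- names(per_gene)[per_gene >= 1]
  list(n_distinct_mutants = length(unique(table$mutant_id)),
       pct_orfs_covered = 100 * length(covered) / length(gene_catalog),
       mean_insertions_per_orf = if (length(covered))
         mean(as.numeric(per_gene[covered])) else NA_real_)
}
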