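#' Specify a synthetic defined-community experiment
#'
#' A `synthetic_design` captures the experimental design emulated by the
#' in-package simulators: a defined bacterial community colonising groups of
#' gnotobiotic animals that are switched between diets in phases.  All
#' simulators derive their randomness from the single `seed` stored here, so a
#' design fully determines every simulated dataset.
#'
#' @param n_species Number of community members (the motivating studies use
#'   defined assemblages of about a dozen sequenced species).
#' @param genome_length_per_species Genome length in bp for every species.
#' @param genes_per_species Number of protein-coding genes placed on each
#'   genome.
#' @param homology_blocks List of blocks copied between species pairs to
#'   create inter-species homology (the source of ambiguous reads and shared
#'   peptides).  Each element is a list with `pair` (integer vector of length
#'   2: donor, acceptor), `shared_fraction` in \[0, 1\], `percent_identity`
#'   in \[0, 100\], and optionally `start` (1-based position on both genomes,
#'   default 1).
#' @param diet_labels Character vector of diet names; the first is the
#'   reference diet.
#' @param phase_schedule List of phases, each `list(phase, diet, days =
#'   c(first, last))`; day ranges must be disjoint and ordered.
#' @param animals_per_group Animals per treatment group.
#' @param per_gene_log2_diet_effect Magnitude (log2) of the expression change
#'   given to diet-responsive genes.
#' @param species_load_multiplier_per_diet Multiplier applied to a
#'   diet-shifted species' total transcriptome output on the second diet
#'   (values below 1 shrink the species' contribution, the mechanism behind
#'   community-level masking).
#' @param nb_dispersion Negative-binomial dispersion shared by all genes
#'   (variance = mean + dispersion * mean^2); 0 gives Poisson counts.
#' @param sequencing_depth Expected total counts (or reads) per sample.
#' @param seed Integer seed from which all randomness flows.
#'
#' @return An object of class `synthetic_design` (a validated list).
#' @examples
#' d <- synthetic_design(n_species = 3, genome_length_per_species = 2000,
#'                       genes_per_species = 8, seed = 1)
#' d$n_species
#' @export
synthetic_design <- function(n_species = 12,
                             genome_length_per_species = 10000L,
                             genes_per_species = 30L,
                             homology_blocks = list(),
                             diet_labels = c("LF/HPP", "HF/HS"),
                             phase_schedule = list(
                               list(phase = 1L, diet = "LF/HPP", days = c(1L, 13L)),
                               list(phase = 2L, diet = "HF/HS", days = c(14L, 27L))
                             ),
                             animals_per_group = 4L,
                             per_gene_log2_diet_effect = 2,
                             species_load_multiplier_per_diet = 1,
                             nb_dispersion = 0.05,
                             sequencing_depth = 200000L,
                             seed = 1L) {
  stopifnot(n_species >= 1, genome_length_per_species >= 100,
            genes_per_species >= 1, animals_per_group >= 1,
            nb_dispersion >= 0, sequencing_depth >= 1,
            length(diet_labels) >= 1)
  for (hb in homology_blocks) {
    if (is.null(hb$pair) || length(hb$pair) != 2)
      stop("each homology block needs a 'pair' of two species indices")
    if (hb$shared_fraction < 0 || hb$shared_fraction > 1)
      stop("shared_fraction must lie in [0, 1]")
    if (hb$percent_identity < 0 || hb$percent_identity > 100)
      stop("percent_identity must lie in [0, 100]")
  }
  days <- t(vapply(phase_schedule, function(p) as.integer(p$days), integer(2)))
  if (nrow(days) > 1) {
    if (any(days[, 1] > days[, 2]) || any(diff(as.vector(t(days))) <= 0))
      stop("phase day ranges must be ordered and disjoint")
  }
  structure(list(
    n_species = as.integer(n_species),
    genome_length_per_species = as.integer(genome_length_per_species),
    genes_per_species = as.integer(genes_per_species),
    homology_blocks = homology_blocks,
    diet_labels = diet_labels,
    phase_schedule = phase_schedule,
    animals_per_group = as.integer(animals_per_group),
    per_gene_log2_diet_effect = per_gene_log2_diet_effect,
    species_load_multiplier_per_diet = species_load_multiplier_per_diet,
    nb_dispersion = nb_dispersion,
    sequencing_depth = as.integer(sequencing_depth),
    seed = as.integer(seed)
  ), class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("Synthetic defined-community design\n")
  cat(sprintf("  %d species x %d bp, %d genes each\n", x$n_species,
              x$genome_length_per_species, x$genes_per_species))
  cat(sprintf("  diets: %s; %d animals/group; depth %d; NB dispersion %g\n",
              paste(x$diet_labels, collapse = " -> "), x$animals_per_group,
              x$sequencing_depth, x$nb_dispersion))
  cat(sprintf("  %d homology block(s); seed %d\n",
              length(x$homology_blocks), x$seed))
  invisible(x)
}
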