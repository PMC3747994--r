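revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate fixed-length shotgun reads from a community
#'
#' Draws reads from the community genomes with per-read true-origin labels.
#' The number of reads per species is multinomial with weights proportional
#' to `proportions * genome length` (shotgun reads sample DNA mass, not
#' cells), start positions are uniform, strands are random, and sequencing
#' error is an independent per-base substitution.
#'
#' @param genomes A `community_genomes` object.
#' @param proportions Per-species proportions (summing to 1).
#' @param n_reads Number of reads.
#' @param read_length Read length in bp (communities profiled this way are
#'   typically trimmed to short uniform reads, e.g. 25 bp).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A `read_set`: data frame with `read_id`, `sequence`,
#'   `true_species`.
#' @examples
#' g <- generate_genomes(synthetic_design(n_species = 2,
#'        genome_length_per_species = 1200, genes_per_species = 3, seed = 1))
#' r <- simulate_shotgun_reads(g, c(0.5, 0.5), 100, 25, seed = 2)
#' table(r$true_species)
#' @export
simulate_shotgun_reads <- function(genomes, proportions, n_reads,
                                   read_length = 25L, error_rate = 0,
                                   seed = 1L) {
  stopifnot(inherits(genomes, "community_genomes"))
  if (any(proportions < 0)) stop("negative proportion")
  if (abs(sum(proportions) - 1) > 1e-6) stop("proportions must sum to 1")
  lens <- genome_lengths(genomes)
  if (read_length > min(lens)) stop("read_length exceeds shortest genome")
  set.seed(seed)
  w <- proportions * lens
  n_per <- as.vector(stats::rmultinom(1, n_reads, w / sum(w)))
  out <- vector("list", length(lens))
  for (i in seq_along(lens)) {
    if (n_per[i] == 0) next
    starts <- sample.int(lens[i] - read_length + 1L, n_per[i], replace = TRUE)
    seqs <- substring(genomes$sequences[i], starts, starts + read_length - 1L)
    rc <- stats::runif(n_per[i]) < 0.5
    if (any(rc)) seqs[rc] <- revcomp_chr(seqs[rc])
    if (error_rate > 0) {
      seqs <- vapply(seqs, substitute_chars, character(1), rate = error_rate,
                     alphabet = c("A", "C", "G", "T"), USE.NAMES = FALSE)
    }
    out[[i]] <- data.frame(sequence = seqs,
                           true_species = genomes$species_id[i],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(sequence = character(), true_species = character())
  }
  res <- res[sample.int(nrow(res)), , drop = FALSE]
  res <- data.frame(read_id = sprintf("read%06d", seq_len(nrow(res))), res,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("read_set", "data.frame")
  res
}

#' Simulate a feature-by-sample count matrix
#'
#' Draws per-gene negative-binomial counts for a two-diet design with mean
#' `depth_scale * species_load(diet) * gene_baseline * 2^(diet_effect)`,
#' a dispersion shared across genes (variance = mu + dispersion * mu^2;
#' dispersion 0 gives Poisson counts).  Gene baselines are log-normal and sum
#' to 1 at reference loads, so `design$sequencing_depth` is the expected
#' per-sample total under reference conditions.  For the spectral assay each
#' sample's counts are additionally split into two technical runs by binomial
#' thinning (p = 0.5), mirroring duplicate mass-spectrometry runs.
#'
#' Species-load shifts (a multiplier below 1 on the second diet) scale all of
#' a species' gene means together; combined with a within-species up-effect
#' on one gene this reproduces community-level masking of a species-level
#' response.
#'
#' @param design A [synthetic_design()].
#' @param genomes A `community_genomes` built from the design.
#' @param assay `"rnaseq"` or `"spectral"`.
#' @param diet_effects Named numeric vector (gene_id -> log2 effect on the
#'   second diet).  Default: none.
#' @param species_loads Named numeric vector (species_id -> multiplier on the
#'   second diet).  Default: 1 for all species.
#' @return A `count_matrix` object: list with `counts` (features x samples),
#'   `samples` (sample metadata: sample_id, animal, diet), `features`
#'   (gene annotations), `assay`, `state = "raw"`, and for the spectral
#'   assay `runs`, a list of two run-level matrices summing to `counts`.
#' @export
simulate_count_matrix <- function(design, genomes,
                                  assay = c("rnaseq", "spectral"),
                                  diet_effects = NULL,
                                  species_loads = NULL) {
  stopifnot(inherits(design, "synthetic_design"),
            inherits(genomes, "community_genomes"))
  assay <- match.arg(assay)
  set.seed(design$seed + 1000L)
  genes <- genomes$genes
  nG <- nrow(genes)
  diets <- design$diet_labels[1:2]
  nA <- design$animals_per_group

  samples <- data.frame(
    sample_id = sprintf("%s_a%d", rep(c("dietA", "dietB"), each = nA),
                        rep(seq_len(nA), 2)),
    animal = sprintf("m%02d", seq_len(2 * nA)),
    diet = rep(diets, each = nA),
    stringsAsFactors = FALSE)

  base <- stats::rlnorm(nG, meanlog = 0, sdlog = 1)
  base <- base / sum(base)
  eff <- stats::setNames(rep(0, nG), genes$gene_id)
  if (!is.null(diet_effects)) eff[names(diet_effects)] <- diet_effects
  loads <- stats::setNames(rep(1, length(genomes$species_id)),
                           genomes$species_id)
  if (!is.null(species_loads)) loads[names(species_loads)] <- species_loads

  counts <- matrix(0L, nG, nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample_id))
  for (s in seq_len(nrow(samples))) {
    on_b <- samples$diet[s] == diets[2]
    mu <- design$sequencing_depth * base *
      (if (on_b) loads[genes$species_id] * 2^eff else 1)
    counts[, s] <- if (design$nb_dispersion <= 0) {
      stats::rpois(nG, mu)
    } else {
      stats::rnbinom(nG, mu = mu, size = 1 / design$nb_dispersion)
    }
  }

  obj <- structure(list(counts = counts, samples = samples,
                        features = genes, assay = assay, state = "raw"),
                   class = "count_matrix")
  if (assay == "spectral") {
    run1 <- matrix(stats::rbinom(length(counts), as.vector(counts), 0.5),
                   nG, ncol(counts), dimnames = dimnames(counts))
    obj$runs <- list(run1 = run1, run2 = counts - run1)
  }
  obj
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("%s count matrix (%s): %d features x %d samples\n",
              x$assay, x$state, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Simulate a transposon-insertion (INSeq) experiment
#'
#' Places `n_mutants` single-insertion mutants uniformly over the
#' concatenated community genome, assigns each insertion to a gene (or
#' intergenic space), then draws input counts multinomially with uniform
#' weights and output counts multinomially with weights
#' `input_count * fitness(disrupted gene)`; intergenic insertions have
#' fitness 1.
#'
#' @param genomes A `community_genomes` object.
#' @param n_mutants Number of distinct insertion mutants.
#' @param per_gene_fitness Named numeric vector (gene_id -> fitness >= 0);
#'   unlisted genes default to 1.
#' @param bottleneck Sequencing/selection depth used for both the input and
#'   output multinomial draws.
#' @param seed Integer seed.
#' @return Data frame (`inseq_table`): `mutant_id`, `species_id`, `position`,
#'   `gene_id` (NA if intergenic), `gene_length`, `position_fraction`,
#'   `input_count`, `output_count`.
#' @export
simulate_inseq <- function(genomes, n_mutants, per_gene_fitness = NULL,
                           bottleneck = 10L * n_mutants, seed = 1L) {
  stopifnot(inherits(genomes, "community_genomes"))
  if (n_mutants <= 0) stop("n_mutants must be positive")
  if (!is.null(per_gene_fitness) && any(per_gene_fitness < 0))
    stop("fitness values must be >= 0")
  set.seed(seed)
  lens <- genome_lengths(genomes)
  offs <- c(0, cumsum(as.numeric(lens)))
  pos_global <- sort(sample.int(sum(lens), n_mutants, replace = FALSE))
  sp_idx <- findInterval(pos_global, offs + 1)
  position <- pos_global - offs[sp_idx]
  species <- genomes$species_id[sp_idx]

  genes <- genomes$genes
  gene_id <- rep(NA_character_, n_mutants)
  gene_length <- rep(NA_integer_, n_mutants)
  position_fraction <- rep(NA_real_, n_mutants)
  for (i in seq_len(n_mutants)) {
    g <- genes[genes$species_id == species[i] &
                 genes$start <= position[i] & genes$end >= position[i], ]
    if (nrow(g) == 1) {
      gene_id[i] <- g$gene_id
      gene_length[i] <- g$end - g$start + 1L
      position_fraction[i] <- (position[i] - g$start + 1) / gene_length[i]
    }
  }
  fit <- rep(1, n_mutants)
  if (!is.null(per_gene_fitness)) {
    hit <- !is.na(gene_id) & gene_id %in% names(per_gene_fitness)
    fit[hit] <- per_gene_fitness[gene_id[hit]]
  }
  input_count <- as.vector(stats::rmultinom(1, bottleneck,
                                            rep(1, n_mutants)))
  w <- input_count * fit
  output_count <- if (sum(w) == 0) rep(0L, n_mutants) else
    as.vector(stats::rmultinom(1, bottleneck, w))
  res <- data.frame(mutant_id = sprintf("mut%06d", seq_len(n_mutants)),
                    species_id = species, position = position,
                    gene_id = gene_id, gene_length = gene_length,
                    position_fraction = position_fraction,
                    input_count = input_count, output_count = output_count,
                    stringsAsFactors = FALSE)
  class(res) <- c("inseq_table", "data.frame")
  res
}

#' Simulate logistic OD600 growth curves
#'
#' Each substrate grows as a lagged logistic rescaled to start exactly at
#' `initial` and end exactly at `carrying_capacity` over the run, with
#' maximum slope `max_rate` and additive Gaussian noise (clamped at 0 OD).
#'
#' @param params Data frame with columns `substrate`, `lag` (h), `max_rate`
#'   (OD/h), `carrying_capacity` (OD), `initial` (OD), `noise_sd` (OD).
#' @param n_replicates Curves per substrate (growth phenotyping studies
#'   commonly pool replicate wells across independent runs, e.g. n = 6).
#' @param duration Total time in hours (default 72 h, i.e. 3 days).
#' @param dt Sampling interval in hours.
#' @param seed Integer seed.
#' @return A `growth_curve_set`: long data frame with `substrate`,
#'   `replicate`, `time_h`, `od600`.
#' @export
simulate_growth_curves <- function(params, n_replicates = 6L, duration = 72,
                                   dt = 0.5, seed = 1L) {
  stopifnot(is.data.frame(params),
            all(c("substrate", "lag", "max_rate", "carrying_capacity",
                  "initial", "noise_sd") %in% names(params)))
  if (duration <= 0) stop("duration must be positive")
  if (any(params$carrying_capacity <= params$initial & params$max_rate > 0))
    stop("carrying_capacity must exceed initial OD")
  if (any(params$initial < 0)) stop("initial OD must be >= 0")
  set.seed(seed)
  tt <- seq(0, duration, by = dt)
  out <- list()
  for (i in seq_len(nrow(params))) {
    p <- params[i, ]
    span <- p$carrying_capacity - p$initial
    if (p$max_rate <= 0 || span <= 0) {
      clean <- rep(p$initial, length(tt))
    } else {
      r <- 4 * p$max_rate / span
      tmid <- p$lag + span / (2 * p$max_rate)
      g <- 1 / (1 + exp(-r * (tt - tmid)))
      # rescale so the trajectory attains initial at t=0 and capacity at t=end
      clean <- p$initial + span * (g - g[1]) / (g[length(g)] - g[1])
    }
    for (rep_i in seq_len(n_replicates)) {
      od <- clean + stats::rnorm(length(tt), sd = p$noise_sd)
      od[od < 0] <- 0
      out[[length(out) + 1L]] <- data.frame(
        substrate = p$substrate, replicate = rep_i, time_h = tt, od600 = od,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("growth_curve_set", "data.frame")
  res
}
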