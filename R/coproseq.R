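# Community profiling by sequencing (COPRO-Seq): species proportions from
# fixed-length shotgun reads, normalized for genome uniqueness within the
# defined community.

# all k-mers of a genome in canonical form (lexicographic min of the k-mer
# and its reverse complement), position-ordered
canonical_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (k > L) return(character(0))
  n <- L - k + 1L
  fwd <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  rcseq <- revcomp_chr(seq)
  rc_all <- substring(rcseq, seq_len(n), seq_len(n) + k - 1L)
  # the reverse complement of the k-mer at forward position i starts at
  # position L - i - k + 2 of the reverse-complemented genome
  rc <- rc_all[L - seq_len(n) - k + 2L]
  pmin(fwd, rc)
}

#' Informative genome sizes within a defined community
#'
#' The informative size of a genome is the number of positions whose length-k
#' substring (canonical over both strands) occurs exactly once in the union
#' of all community genomes.  It is the denominator that converts
#' unambiguously assigned read counts into abundances comparable across
#' species whose genomes share different amounts of sequence.
#'
#' @param genomes A `community_genomes` object.
#' @param k K-mer length; use the (trimmed) read length, conventionally 25.
#' @return An `informative_sizes` object: list with `sizes` (named integer
#'   vector) and `k`.
#' @examples
#' g <- generate_genomes(synthetic_design(n_species = 2,
#'        genome_length_per_species = 1200, genes_per_species = 3, seed = 1))
#' compute_informative_sizes(g, k = 25)$sizes
#' @export
compute_informative_sizes <- function(genomes, k = 25L) {
  stopifnot(inherits(genomes, "community_genomes"), k >= 1)
  lens <- genome_lengths(genomes)
  if (k > min(lens)) stop("k exceeds the shortest genome")
  km <- lapply(genomes$sequences, canonical_kmers, k = k)
  all_km <- unlist(km, use.names = FALSE)
  tab <- table(all_km)
  uniq <- names(tab)[tab == 1L]
  sizes <- vapply(km, function(x) sum(x %in% uniq), integer(1))
  structure(list(sizes = sizes, k = as.integer(k)),
            class = "informative_sizes")
}

#' @export
print.informative_sizes <- function(x, ...) {
  cat(sprintf("Informative genome sizes (k = %d):\n", x$k))
  print(x$sizes)
  invisible(x)
}

# map from canonical k-mer to owning species ("*" when shared by >= 2)
.kmer_species_map <- function(genomes, k) {
  per_sp <- lapply(genomes$sequences,
                   function(s) unique(canonical_kmers(s, k)))
  kk <- unlist(per_sp, use.names = FALSE)
  sp <- rep(names(per_sp), lengths(per_sp))
  n_owner <- table(kk)
  owner <- sp[match(names(n_owner), kk)]
  owner[n_owner > 1L] <- "*"
  stats::setNames(owner, names(n_owner))
}

#' Assign reads to community members by exact unique matching
#'
#' A read is assigned to a species iff it matches exactly (either strand) a
#' location in exactly one species' genome; reads matching two or more
#' species are ambiguous, reads matching none are unassigned.  Reads are
#' trimmed to the first `k` bases before matching (the profiling protocol
#' this emulates trims all reads to a fixed short length).
#'
#' @param reads A `read_set` (or data frame with a `sequence` column).
#' @param genomes A `community_genomes` object.
#' @param k Match length; reads must be at least this long.
#' @return A `read_assignment`: list with `unique_counts` (named integer
#'   vector per species), `ambiguous`, `unassigned`, `total`, `k`, and
#'   `read_species` (per-read label: species, `"*"` or NA).
#' @export
assign_reads <- function(reads, genomes, k = 25L) {
  stopifnot(inherits(genomes, "community_genomes"))
  seqs <- reads$sequence
  if (length(seqs) && any(nchar(seqs) < k))
    stop("all reads must have length >= k")
  map <- .kmer_species_map(genomes, k)
  lab <- rep(NA_character_, length(seqs))
  if (length(seqs)) {
    rk <- substr(seqs, 1L, k)
    rc <- revcomp_chr(rk)
    canon <- pmin(rk, rc)
    lab <- unname(map[canon])
  }
  uc <- stats::setNames(integer(length(genomes$species_id)),
                        genomes$species_id)
  hit <- table(lab[!is.na(lab) & lab != "*"])
  uc[names(hit)] <- as.integer(hit)
  structure(list(unique_counts = uc,
                 ambiguous = sum(!is.na(lab) & lab == "*"),
                 unassigned = sum(is.na(lab)),
                 total = length(seqs), k = as.integer(k),
                 read_species = lab),
            class = "read_assignment")
}

#' @export
print.read_assignment <- function(x, ...) {
  cat(sprintf("Read assignment (k = %d): %d reads, %d unique, %d ambiguous, %d unassigned\n",
              x$k, x$total, sum(x$unique_counts), x$ambiguous, x$unassigned))
  invisible(x)
}

#' Species proportions from unique counts and informative sizes
#'
#' Normalized abundance = unique read count / informative genome size;
#' intrasample proportion = normalized abundance as a percentage of the
#' sample's total normalized abundance.
#'
#' @param unique_counts Named integer vector (species -> unique read count),
#'   or a matrix with species rows and sample columns.
#' @param informative_sizes An `informative_sizes` object (or named vector).
#' @param metadata Optional per-sample data frame (sample_id, animal, day,
#'   diet, source) joined onto the result.
#' @param threshold Presence threshold in percent (see [presence_filter()]).
#' @return An `abundance_table`: data frame with `sample_id`, `species_id`,
#'   `unique_read_count`, `normalized_abundance`, `proportion` (percent,
#'   summing to 100 per sample) and `present`.
#' @examples
#' quantify(c(A = 100, B = 100), c(A = 1000, B = 500))
#' @export
quantify <- function(unique_counts, informative_sizes, metadata = NULL,
                     threshold = 0.003) {
  sizes <- if (inherits(informative_sizes, "informative_sizes"))
    informative_sizes$sizes else informative_sizes
  if (is.null(dim(unique_counts))) {
    unique_counts <- matrix(unique_counts,
                            dimnames = list(names(unique_counts), "sample1"))
  }
  species <- rownames(unique_counts)
  if (!all(species %in% names(sizes)))
    stop("informative sizes missing for some species")
  sizes <- sizes[species]
  bad <- sizes == 0 & rowSums(unique_counts) > 0
  if (any(bad))
    stop("informative size is 0 for species with nonzero counts: ",
         paste(species[bad], collapse = ", "))
  out <- do.call(rbind, lapply(colnames(unique_counts), function(sm) {
    cnt <- unique_counts[, sm]
    norm <- ifelse(sizes > 0, cnt / sizes, 0)
    prop <- if (sum(norm) > 0) 100 * norm / sum(norm) else rep(0, length(norm))
    data.frame(sample_id = sm, species_id = species,
               unique_read_count = as.integer(cnt),
               normalized_abundance = norm, proportion = prop,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(metadata)) out <- merge(out, metadata, by = "sample_id",
                                       sort = FALSE)
  out <- presence_filter(out, threshold)
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Flag species presence by the abundance threshold
#'
#' A community member is called present in a sample when its proportion is at
#' least `threshold` percent (inclusive).  The conventional cutoff, 0.003%,
#' reflects the rate at which reads spuriously assign to genomes of species
#' known to be absent.  Sub-threshold proportions are retained (flagged
#' absent), not zeroed.
#'
#' @param table An `abundance_table` (needs a `proportion` column).
#' @param threshold Percent cutoff, default 0.003.
#' @return The table with a logical `present` column.
#' @export
presence_filter <- function(table, threshold = 0.003) {
  stopifnot(threshold >= 0, "proportion" %in% names(table))
  table$present <- table$proportion >= threshold
  table
}

#' Percentage of maximum achieved (PoMA)
#'
#' Rescales each species' proportional abundance trajectory within each
#' animal to the maximum proportion that species attains across the animal's
#' time-points, putting strongly and weakly represented members on a common
#' 0-100 response scale.
#'
#' @param table An `abundance_table` with `animal`, `day`, `species_id`,
#'   `proportion` columns.
#' @return Data frame (`poma_table`) with `animal`, `species_id`, `day`,
#'   `poma`.  An all-zero (animal, species) series yields NA with a warning.
#' @export
poma <- function(table) {
  stopifnot(all(c("animal", "day", "species_id", "proportion") %in%
                  names(table)))
  key <- interaction(table$animal, table$species_id, drop = TRUE)
  mx <- stats::ave(table$proportion, key, FUN = max)
  pm <- ifelse(mx > 0, 100 * table$proportion / mx, NA_real_)
  if (anyNA(pm))
    warning("PoMA undefined for all-zero (animal, species) series; NA emitted")
  out <- data.frame(animal = table$animal, species_id = table$species_id,
                    day = table$day, poma = pm, stringsAsFactors = FALSE)
  class(out) <- c("poma_table", "data.frame")
  out
}

#' Hellinger-distance principal coordinates analysis
#'
#' Computes pairwise Hellinger distances between samples,
#' \eqn{d(p,q) = \sqrt{\sum_i (\sqrt{p_i} - \sqrt{q_i})^2}} on proportions
#' rescaled to sum 1, then classical metric scaling (PCoA) of the
#' double-centred squared-distance matrix.  Negative eigenvalues are
#' reported but excluded from the percent-variance denominators.
#'
#' @param table An `abundance_table`, or a samples x species matrix of
#'   proportions.
#' @param n_axes Number of ordination axes requested.
#' @return List with `coordinates` (samples x axes), `eigenvalues`,
#'   `percent_variance` (per retained axis), `distances` (a `dist`).
#' @export
hellinger_pcoa <- function(table, n_axes = 2L) {
  if (is.data.frame(table)) {
    m <- stats::xtabs(proportion ~ sample_id + species_id, data = table)
    m <- matrix(m, nrow(m), ncol(m), dimnames = dimnames(m))
  } else m <- as.matrix(table)
  if (nrow(m) < 3) stop("ordination needs at least 3 samples")
  p <- m / rowSums(m)
  d <- stats::dist(sqrt(p))
  max_axes <- nrow(m) - 1L
  if (n_axes > max_axes) {
    warning("fewer samples than requested axes; reducing")
    n_axes <- max_axes
  }
  sc <- stats::cmdscale(d, k = n_axes, eig = TRUE)
  eig <- sc$eig
  pos <- eig[eig > 0]
  pv <- 100 * eig[seq_len(n_axes)] / sum(pos)
  colnames(sc$points) <- paste0("PCo", seq_len(ncol(sc$points)))
  list(coordinates = sc$points, eigenvalues = eig,
       percent_variance = pv, distances = d)
}

#' Cross-timepoint predictiveness of community composition
#'
#' Squared Pearson correlation, across species, between the proportion
#' vectors measured at two time-points (e.g. the ends of two like-diet
#' phases): how well one configuration predicts the other.
#'
#' @param props_day_a,props_day_b Per-species proportion vectors over the
#'   same species set (length >= 3).
#' @return R-squared (scalar).
#' @export
predictiveness_r2 <- function(props_day_a, props_day_b) {
  if (length(props_day_a) != length(props_day_b) || length(props_day_a) < 3)
    stop("need matched proportion vectors over >= 3 species")
  if (stats::sd(props_day_a) == 0 || stats::sd(props_day_b) == 0)
    stop("zero variance in a proportion vector; R^2 undefined")
  stats::cor(props_day_a, props_day_b)^2
}
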