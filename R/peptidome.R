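# Theoretical peptidome: in-silico tryptic digestion, monoisotopic peptide
# masses, uniqueness classification against a composite protein database
# (community + host + distractors + contaminants), and summaries.

# monoisotopic residue masses (Da)
MONO_MASS <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
               V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
               I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
               K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
               F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_MONO <- 18.01056

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water (18.01056 Da);
#' unmodified peptides only.
#'
#' @param sequence Peptide sequence(s), standard 20-letter alphabet.
#' @return Mass(es) in Da.
#' @examples
#' peptide_mass("AK")   # 217.1426
#' @export
peptide_mass <- function(sequence) {
  if (any(!nzchar(sequence))) stop("empty peptide sequence")
  vapply(strsplit(sequence, "", fixed = TRUE), function(ch) {
    m <- MONO_MASS[ch]
    if (anyNA(m))
      stop("non-standard residue: ", paste(ch[is.na(m)], collapse = ","))
    sum(m) + WATER_MONO
  }, numeric(1))
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R, suppressed when the next residue is P (the
#' classical trypsin rule), and returns every fragment containing 0 to
#' `max_missed` internal (missed) cleavage sites, with 1-based start
#' positions.
#'
#' @param protein Amino-acid string (standard 20-letter alphabet).
#' @param max_missed Maximum internal missed cleavages.
#' @return Data frame: `sequence`, `start`, `missed_cleavages`.
#' @examples
#' digest("AKRGGK", max_missed = 1)
#' @export
digest <- function(protein, max_missed = 1L) {
  if (!nzchar(protein)) stop("empty protein")
  ch <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- which(!ch %in% names(MONO_MASS))
  if (length(bad))
    stop("non-standard residue '", ch[bad[1]], "' at position ", bad[1])
  n <- length(ch)
  # cleavage after position i: K/R at i, not P at i+1
  cut_after <- which(ch %in% c("K", "R") & c(ch[-1], "") != "P")
  cut_after <- cut_after[cut_after < n]
  bounds <- c(0L, cut_after, n)  # base fragments: (bounds[i], bounds[i+1]]
  nf <- length(bounds) - 1L
  out <- list()
  for (m in 0:min(max_missed, nf - 1L)) {
    i <- seq_len(nf - m)
    out[[m + 1L]] <- data.frame(
      sequence = substring(protein, bounds[i] + 1L, bounds[i + 1L + m]),
      start = bounds[i] + 1L,
      missed_cleavages = m,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a theoretical peptidome over a composite protein database
#'
#' Digests every protein, drops fragments outside the mass window (inclusive)
#' or exceeding `max_missed`, and merges identical peptide sequences across
#' proteins into single entries with pooled occurrences.  The defaults (600
#' to 4890 Da, at most one missed cleavage) are the conventional settings
#' for theoretical-peptidome uniqueness accounting; note they are distinct
#' from typical database *search* settings (which may allow up to four
#' missed cleavages).
#'
#' @param proteomes Named character vector of protein sequences
#'   (protein_id -> sequence), or a list of such vectors.  Duplicate protein
#'   ids are rejected.
#' @param mass_min,mass_max Mass window in Da (inclusive).
#' @param max_missed Maximum missed cleavages.
#' @return A `peptidome_index`: list with `peptides` (data frame: sequence,
#'   mass, missed_cleavages, n_occurrences, unique) and `occurrences` (data
#'   frame: sequence, protein_id, start).
#' @export
build_theoretical_peptidome <- function(proteomes, mass_min = 600,
                                        mass_max = 4890, max_missed = 1L) {
  if (is.list(proteomes)) proteomes <- unlist(proteomes)
  if (length(proteomes) < 1) stop("need at least one proteome")
  stopifnot(mass_min > 0, mass_max > mass_min, max_missed >= 0)
  if (anyDuplicated(names(proteomes)))
    stop("duplicate protein_id across proteome files")
  frag <- lapply(seq_along(proteomes), function(i) {
    d <- digest(proteomes[i], max_missed = max_missed)
    d$protein_id <- names(proteomes)[i]
    d
  })
  occ <- do.call(rbind, frag)
  occ$mass <- peptide_mass(occ$sequence)
  occ <- occ[occ$mass >= mass_min & occ$mass <= mass_max, , drop = FALSE]
  # a sequence reachable with and without missed cleavage keeps the minimum
  agg_n <- table(occ$sequence)
  seqs <- names(agg_n)
  first <- occ[!duplicated(occ$sequence), ]
  mc_min <- tapply(occ$missed_cleavages, occ$sequence, min)
  peptides <- data.frame(sequence = seqs,
                         mass = first$mass[match(seqs, first$sequence)],
                         missed_cleavages = as.integer(mc_min[seqs]),
                         n_occurrences = as.integer(agg_n),
                         stringsAsFactors = FALSE)
  peptides$unique <- peptides$n_occurrences == 1L
  rownames(peptides) <- NULL
  structure(list(peptides = peptides,
                 occurrences = occ[, c("sequence", "protein_id", "start",
                                       "missed_cleavages")],
                 mass_min = mass_min, mass_max = mass_max,
                 max_missed = as.integer(max_missed)),
            class = "peptidome_index")
}

#' @export
print.peptidome_index <- function(x, ...) {
  cat(sprintf("Theoretical peptidome: %d peptides (%.1f%% unique), mass %g-%g Da, <=%d missed cleavages\n",
              nrow(x$peptides), 100 * mean(x$peptides$unique),
              x$mass_min, x$mass_max, x$max_missed))
  invisible(x)
}

#' Classify peptide uniqueness within the composite database
#'
#' A peptide is unique when its sequence occurs exactly once in the whole
#' database, i.e. it is specific to a single protein; everything else is
#' nonunique.  Under the default protein-occurrence reading, a peptide found
#' at two loci of the *same* protein is nonunique; set
#' `collapse_within_protein = TRUE` for the alternative per-protein reading
#' (unique iff found in exactly one protein, however many loci).
#'
#' @param index A `peptidome_index`.
#' @param collapse_within_protein Collapse multiple loci within one protein
#'   to a single occurrence before counting.
#' @return The index with the `unique` flag recomputed.
#' @export
classify_uniqueness <- function(index, collapse_within_protein = FALSE) {
  stopifnot(inherits(index, "peptidome_index"))
  occ <- index$occurrences
  if (collapse_within_protein)
    occ <- occ[!duplicated(occ[, c("sequence", "protein_id")]), ]
  n <- table(occ$sequence)
  index$peptides$n_occurrences <-
    as.integer(n[index$peptides$sequence])
  index$peptides$unique <- index$peptides$n_occurrences == 1L
  index
}

#' Per-species and per-category uniqueness summaries
#'
#' For each species (or database source), the fraction of its theoretical
#' peptides that are unique within the composite database, and its
#' contribution to the pool of unique peptides; optionally the unique
#' fraction per functional category.  Peptides occurring in several species
#' count toward each of them (and are by construction nonunique).
#'
#' @param index A `peptidome_index`.
#' @param species_map Named character vector protein_id -> species/source;
#'   every protein in the index must be mapped.
#' @param category_map Optional named vector protein_id -> category.
#' @return List with `per_species` (data frame: species, n_peptides,
#'   fraction_unique, contribution_to_unique_metaproteome in percent summing
#'   to 100) and `per_category` (or NULL).
#' @export
uniqueness_summaries <- function(index, species_map, category_map = NULL) {
  stopifnot(inherits(index, "peptidome_index"))
  occ <- index$occurrences
  unmapped <- setdiff(occ$protein_id, names(species_map))
  if (length(unmapped))
    stop("unmapped protein(s): ", paste(utils::head(unmapped), collapse = ", "))
  uniq <- stats::setNames(index$peptides$unique, index$peptides$sequence)
  occ$species <- species_map[occ$protein_id]
  # peptide-species pairs (a peptide counts once per species it occurs in)
  ps <- unique(occ[, c("sequence", "species")])
  ps$unique <- uniq[ps$sequence]
  n_pep <- table(ps$species)
  n_uni <- tapply(ps$unique, ps$species, sum)
  species <- names(n_pep)
  total_unique <- sum(index$peptides$unique)
  per_species <- data.frame(
    species = species,
    n_peptides = as.integer(n_pep),
    fraction_unique = as.numeric(n_uni[species] / n_pep),
    contribution_to_unique_metaproteome =
      if (total_unique > 0) 100 * as.numeric(n_uni[species]) / total_unique
      else rep(0, length(species)),
    stringsAsFactors = FALSE)
  per_category <- NULL
  if (!is.null(category_map)) {
    occ$category <- category_map[occ$protein_id]
    pc <- unique(occ[!is.na(occ$category), c("sequence", "category")])
    pc$unique <- uniq[pc$sequence]
    per_category <- data.frame(
      category = names(table(pc$category)),
      n_peptides = as.integer(table(pc$category)),
      fraction_unique = as.numeric(
        tapply(pc$unique, pc$category, mean)[names(table(pc$category))]),
      stringsAsFactors = FALSE)
  }
  list(per_species = per_species, per_category = per_category)
}
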