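# Label-free spectral-count analysis: community (NBC) and species (NBS)
# normalization, presence and valid-run rules, Mann-Whitney + q-value
# differential calls with the median-difference rule, and RNA-protein
# fold-change correlation.

#' Normalize spectral counts by community or by species
#'
#' NBC divides each protein's count in a run by the total microbial spectra
#' collected in that run; NBS divides by the total spectra of the protein's
#' species in that run.  A species absent from a run has no NBS denominator:
#' those values are missing (NA), not zero.
#'
#' @param table Long-format data frame: `protein_id`, `species_id`,
#'   `sample_id`, `run_id`, `count` (raw spectral counts).
#' @param mode `"NBC"` or `"NBS"`.
#' @return The table with a `normalized` column (per-run fractions).
#' @export
normalize_spectra <- function(table, mode = c("NBC", "NBS")) {
  mode <- match.arg(mode)
  stopifnot(all(c("protein_id", "species_id", "sample_id", "run_id",
                  "count") %in% names(table)))
  run_key <- interaction(table$sample_id, table$run_id, drop = TRUE)
  if (mode == "NBC") {
    tot <- stats::ave(table$count, run_key, FUN = sum)
    if (any(tot == 0)) stop("a run has zero total spectra")
    table$normalized <- table$count / tot
  } else {
    key <- interaction(table$species_id, run_key, drop = TRUE)
    tot <- stats::ave(table$count, key, FUN = sum)
    table$normalized <- ifelse(tot > 0, table$count / tot, NA_real_)
  }
  attr(table, "normalization") <- mode
  table
}

#' Presence call from a sample's technical runs
#'
#' A protein is detected ("present") in a sample when at least four raw
#' spectral counts are assigned to it when aggregating the sample's
#' technical runs.
#'
#' @param run_counts Integer vector of the sample's run counts for one
#'   protein.
#' @param min_total Inclusive threshold on the summed counts (default 4).
#' @return Logical.
#' @examples
#' presence_call(c(3, 2))  # TRUE
#' presence_call(c(2, 1))  # FALSE
#' @export
presence_call <- function(run_counts, min_total = 4L) {
  sum(run_counts) >= min_total
}

#' Eligibility for differential testing
#'
#' p- and q-values are only computed for proteins with at least `min_valid`
#' valid runs, where a valid run has strictly more than `valid_gt` spectral
#' counts.
#'
#' @param run_counts Integer vector of counts across all runs.
#' @param valid_gt A run is valid when its count exceeds this (strictly).
#' @param min_valid Minimum number of valid runs.
#' @return Logical.
#' @examples
#' eligibility(c(6, 6, 6, 0))  # TRUE
#' eligibility(c(6, 6, 5, 5))  # FALSE: 5 is not > 5
#' @export
eligibility <- function(run_counts, valid_gt = 5L, min_valid = 3L) {
  sum(run_counts > valid_gt) >= min_valid
}

#' Storey q-values with smoother pi0 estimation
#'
#' Estimates the null proportion pi0 on a lambda grid (0.05 to 0.95) with a
#' cubic-smoother extrapolation at the right end, then computes
#' q(i) = min over j >= i of pi0 * m * p(j) / j on the sorted p-values
#' (monotone in p).  With fewer than 20 p-values, pi0 is fixed at 1, which
#' reduces to Benjamini-Hochberg.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param pi0 Optional fixed pi0 (e.g. 1 for BH behaviour).
#' @return q-values in the order of `p`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 20) {
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Differential spectral-count calls (UP / DOWN / NULL)
#'
#' For each eligible protein, a two-sided exact Mann-Whitney p-value on the
#' normalized values between the two treatment groups, q-values over the
#' tested set (all proteins under NBC; each species' set separately under
#' NBS), and a call: UP when p < 0.05, q < 0.05 and the group-median
#' spectral-count difference exceeds `median_gt` (DOWN symmetric); NULL
#' otherwise.  Ineligible proteins are reported without a call.
#'
#' @param table A table from [normalize_spectra()], plus a `group` column
#'   (two levels, e.g. the diets) on samples.
#' @param median_gt Strict threshold on |median difference| in counts
#'   (default 5).
#' @param alpha Significance level for p and q (default 0.05).
#' @return A `protein_calls` data frame: `protein_id`, `species_id`,
#'   `eligible`, `p`, `q`, `median_diff` (group B minus group A, raw
#'   counts), `median_diff_normalized`, `call`.
#' @export
diff_call <- function(table, median_gt = 5, alpha = 0.05) {
  stopifnot(all(c("protein_id", "species_id", "sample_id", "run_id",
                  "count", "normalized", "group") %in% names(table)))
  mode <- attr(table, "normalization")
  lv <- unique(table$group)
  if (length(lv) != 2) stop("group must have exactly two levels")
  prot <- unique(table[, c("protein_id", "species_id")])
  n <- nrow(prot)
  eligible <- logical(n); p <- rep(NA_real_, n)
  md <- rep(NA_real_, n); mdn <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rows <- table[table$protein_id == prot$protein_id[i], ]
    eligible[i] <- eligibility(rows$count)
    # samples are the statistical unit: aggregate runs within sample
    agg_c <- tapply(rows$count, rows$sample_id, sum)
    agg_n <- tapply(rows$normalized, rows$sample_id, mean)
    grp <- tapply(rows$group, rows$sample_id, function(g) g[1])
    a <- names(grp)[grp == lv[1]]; b <- names(grp)[grp == lv[2]]
    md[i] <- stats::median(agg_c[b]) - stats::median(agg_c[a])
    mdn[i] <- stats::median(agg_n[b], na.rm = TRUE) -
      stats::median(agg_n[a], na.rm = TRUE)
    if (eligible[i] && !anyNA(agg_n))
      p[i] <- mann_whitney_exact(agg_n[a], agg_n[b])
  }
  q <- rep(NA_real_, n)
  if (identical(mode, "NBS")) {
    for (s in unique(prot$species_id)) {
      idx <- which(prot$species_id == s & !is.na(p))
      if (length(idx)) q[idx] <- qvalues(p[idx])
    }
  } else {
    idx <- which(!is.na(p))
    if (length(idx)) q[idx] <- qvalues(p[idx])
  }
  call <- rep(NA_character_, n)
  tested <- !is.na(p) & !is.na(q)
  call[tested] <- "NULL"
  up <- tested & p < alpha & q < alpha & md > median_gt
  down <- tested & p < alpha & q < alpha & md < -median_gt
  call[up] <- "UP"; call[down] <- "DOWN"
  res <- data.frame(prot, eligible = eligible, p = p, q = q,
                    median_diff = md, median_diff_normalized = mdn,
                    call = call, stringsAsFactors = FALSE)
  class(res) <- c("protein_calls", "data.frame")
  res
}

#' Correlation of RNA and protein diet responses
#'
#' Pearson correlation of paired log-transformed diet fold-changes measured
#' at the RNA and protein level, overall and within each functional category
#' with at least three genes.  Only genes detected in both assays on both
#' diets should be supplied (undetected genes are excluded upstream).
#'
#' @param rna_logfc,protein_logfc Named numeric vectors (gene -> log fold
#'   change); the intersection of names is used.
#' @param category_map Optional named vector gene -> category.
#' @return List with `overall` (r, n) and `per_category` data frame.
#' @export
rna_protein_correlation <- function(rna_logfc, protein_logfc,
                                    category_map = NULL) {
  genes <- intersect(names(rna_logfc), names(protein_logfc))
  if (length(genes) < 3) stop("need >= 3 paired genes")
  x <- rna_logfc[genes]; y <- protein_logfc[genes]
  overall <- list(r = stats::cor(x, y), n = length(genes))
  per_category <- NULL
  if (!is.null(category_map)) {
    cats <- category_map[genes]
    rows <- lapply(unique(cats[!is.na(cats)]), function(cc) {
      g <- genes[!is.na(cats) & cats == cc]
      if (length(g) < 3)
        return(data.frame(category = cc, r = NA_real_, n = length(g)))
      data.frame(category = cc, r = stats::cor(x[g], y[g]), n = length(g))
    })
    per_category <- do.call(rbind, rows)
  }
  list(overall = overall, per_category = per_category)
}
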