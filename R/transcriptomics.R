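# Metatranscriptome analysis: dual-level normalization, EC-number functional
# binning, exact count tests, response kinetics, masking detection,
# bootstrapped clustering, and array-style present/differential calls.

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median, over features with
#' nonzero counts in every sample, of the ratio of the feature's count to
#' its geometric mean across samples.  When no feature is nonzero in all
#' samples the function falls back to library-size ratios (scaled to
#' geometric mean 1) with a warning.
#'
#' @param counts Integer matrix, features x samples (or a `count_matrix`).
#' @return Named numeric vector of per-sample size factors.
#' @examples
#' size_factors(cbind(s1 = c(2, 4), s2 = c(4, 8)))
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  counts <- as.matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    warning("no feature is nonzero in all samples; using library-size ratios")
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  lg <- log(counts[keep, , drop = FALSE])
  gm <- rowMeans(lg)
  exp(apply(lg - gm, 2, stats::median))  # median taken on the log scale
}

#' Normalize a count matrix at community or species level
#'
#' Community-level normalization computes one median-of-ratios size-factor
#' set from all features together; species-level normalization computes size
#' factors independently within each species' feature subset and applies
#' them only there.  The two levels answer different questions: community
#' scaling preserves each species' share of the whole metatranscriptome,
#' while species scaling removes shifts in a species' total output and
#' exposes regulation *within* the species.  Normalizing twice is rejected.
#'
#' @param matrix A raw `count_matrix`.
#' @param level `"community"` or `"species"`.
#' @return The `count_matrix` with normalized `counts`, the new `state`, and
#'   `size_factors` (community: per sample; species: species x sample
#'   matrix).
#' @export
normalize <- function(matrix, level = c("community", "species")) {
  stopifnot(inherits(matrix, "count_matrix"))
  level <- match.arg(level)
  if (matrix$state != "raw")
    stop("matrix is already normalized (state: ", matrix$state, ")")
  raw <- matrix$counts
  if (level == "community") {
    sf <- size_factors(raw)
    matrix$counts <- sweep(raw, 2, sf, "/")
    matrix$size_factors <- sf
    matrix$state <- "community_normalized"
  } else {
    sp <- matrix$features$species_id
    sf_mat <- NULL
    norm <- raw
    for (s in unique(sp)) {
      idx <- which(sp == s)
      sub <- raw[idx, , drop = FALSE]
      sf <- if (length(idx) < 2) {
        warning("species ", s, " has <2 features; library-size fallback")
        ls <- colSums(sub)
        ls / exp(mean(log(ls)))
      } else size_factors(sub)
      norm[idx, ] <- sweep(sub, 2, sf, "/")
      sf_mat <- rbind(sf_mat, sf)
      rownames(sf_mat)[nrow(sf_mat)] <- s
    }
    matrix$counts <- norm
    matrix$size_factors <- sf_mat
    matrix$state <- "species_normalized"
  }
  matrix
}

#' Collapse raw gene counts into EC-number functional bins
#'
#' Sums the raw counts of all genes annotated with each Enzyme Commission
#' number, per sample.  Genes without an EC annotation contribute to no bin;
#' a gene carrying several EC numbers (separated by `;`) contributes its
#' full count to each.
#'
#' @param matrix A raw `count_matrix` whose `features` include an `ec`
#'   column.
#' @return A `count_matrix` of EC x sample raw totals; `features` carries
#'   the EC ids and the dominant-contributor species per EC (the species
#'   contributing the most counts overall, used by [detect_masking()]).
#' @export
bin_by_ec <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (matrix$state != "raw") stop("EC binning expects raw counts")
  ec <- matrix$features$ec
  keep <- !is.na(ec) & nzchar(ec)
  idx <- which(keep)
  ec_list <- strsplit(ec[idx], ";", fixed = TRUE)
  rows <- rep(idx, lengths(ec_list))
  ecs <- trimws(unlist(ec_list))
  agg <- rowsum(matrix$counts[rows, , drop = FALSE], group = ecs)
  sp_tot <- rowsum(rowSums(matrix$counts[rows, , drop = FALSE]),
                   group = paste(ecs, matrix$features$species_id[rows],
                                 sep = "\r"))
  key <- do.call(rbind, strsplit(rownames(sp_tot), "\r", fixed = TRUE))
  dom <- vapply(rownames(agg), function(e) {
    i <- key[, 1] == e
    key[i, 2][which.max(sp_tot[i, 1])]
  }, character(1))
  structure(list(counts = agg, samples = matrix$samples,
                 features = data.frame(ec = rownames(agg),
                                       dominant_species = unname(dom),
                                       stringsAsFactors = FALSE),
                 assay = matrix$assay, state = "raw"),
            class = "count_matrix")
}

# conditional exact NB/Poisson test of equal means for one feature:
# group sums ya, yb over na, nb samples; shared dispersion phi
.exact_count_p <- function(ya, yb, na, nb, phi) {
  n <- ya + yb
  if (n == 0) return(1)
  j <- 0:n
  if (phi <= 1e-8) {
    pr <- stats::dbinom(j, n, na / (na + nb))
  } else {
    mu <- n / (na + nb)
    fa <- stats::dnbinom(j, size = na / phi, mu = na * mu)
    fb <- stats::dnbinom(n - j, size = nb / phi, mu = nb * mu)
    pr <- fa * fb
    pr <- pr / sum(pr)
  }
  obs <- pr[ya + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Exact negative-binomial test for two-group count differences
#'
#' Per-feature two-sided exact test of equal means between two sample
#' groups, conditioning on the feature's total: group sums follow negative
#' binomials with a per-feature dispersion estimated by method of moments on
#' normalized counts (pooled within groups, floored at 1e-8).  Because a
#' per-feature moment estimate from few samples is noisy enough to make the
#' test anti-conservative, each feature's dispersion is additionally floored
#' at the median dispersion across all features (a deliberately conservative
#' moderation).  Dispersion zero degenerates to the binomial
#' (Poisson-conditional) exact test.  With unequal size factors the test is
#' applied to rounded group sums of normalized counts.
#'
#' @param ec_matrix A raw `count_matrix` (typically EC bins).
#' @param group_a,group_b Character vectors of sample ids (>= 2 each).
#' @param sf Optional named per-sample size factors; default
#'   [size_factors()] of the matrix.
#' @return A `diff_result` data frame: `feature_id`, `statistic` (log2 fold
#'   change B over A), `p`, `q`, `fold_change`, `direction`.
#' @export
nb_exact_test <- function(ec_matrix, group_a, group_b, sf = NULL) {
  stopifnot(inherits(ec_matrix, "count_matrix"))
  if (ec_matrix$state != "raw") stop("nb_exact_test expects raw counts")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("need >= 2 samples per group")
  cnt <- ec_matrix$counts
  if (is.null(sf)) sf <- size_factors(cnt)
  sf <- sf[c(group_a, group_b)]
  z <- sweep(cnt[, c(group_a, group_b), drop = FALSE], 2, sf, "/")
  na <- length(group_a); nb <- length(group_b)
  ia <- seq_len(na); ib <- na + seq_len(nb)
  # per-feature MoM dispersion (pooled within groups), then the median
  # floor that keeps the test from being anti-conservative
  phi <- apply(z, 1, function(zi) {
    m <- mean(zi)
    if (m == 0) return(1e-8)
    v <- (sum((zi[ia] - mean(zi[ia]))^2) + sum((zi[ib] - mean(zi[ib]))^2)) /
      (na + nb - 2)
    max((v - m) / m^2, 1e-8)
  })
  phi <- pmax(phi, stats::median(phi))
  p <- fc <- numeric(nrow(z))
  for (i in seq_len(nrow(z))) {
    zi <- z[i, ]
    if (mean(zi) == 0) { p[i] <- 1; fc[i] <- 1; next }
    ya <- round(sum(zi[ia])); yb <- round(sum(zi[ib]))
    p[i] <- .exact_count_p(ya, yb, na, nb, phi[i])
    fc[i] <- (mean(zi[ib]) + 1) / (mean(zi[ia]) + 1)
  }
  res <- data.frame(feature_id = rownames(z),
                    statistic = log2(fc), p = p, q = qvalues(p),
                    fold_change = fc,
                    direction = ifelse(fc > 1, "up",
                                       ifelse(fc < 1, "down", "none")),
                    stringsAsFactors = FALSE)
  class(res) <- c("diff_result", "data.frame")
  res
}

#' Exact two-sided Mann-Whitney U test
#'
#' For combined sample sizes up to 12 without ties, the p-value is computed
#' by full enumeration of all group labelings of the observed values; with
#' ties or larger samples, midranks are used and the labeling enumeration is
#' performed on the ranks (falling back to the normal approximation with tie
#' correction when the enumeration exceeds `max_enum` labelings).
#'
#' @param values_a,values_b Numeric vectors (no missing values).
#' @param max_enum Enumeration cap on `choose(n, n_a)`.
#' @return Two-sided p-value.
#' @examples
#' mann_whitney_exact(1:4, 5:8)   # 2/70
#' @export
mann_whitney_exact <- function(values_a, values_b, max_enum = 2e5) {
  if (anyNA(values_a) || anyNA(values_b)) stop("missing values not allowed")
  na <- length(values_a); nb <- length(values_b)
  if (na < 1 || nb < 1) stop("both groups need >= 1 value")
  x <- c(values_a, values_b)
  if (length(unique(x)) == 1) return(1)
  r <- rank(x)  # midranks
  u_from <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_from(seq_len(na))
  dev_obs <- abs(u_obs - na * nb / 2)
  if (choose(na + nb, na) <= max_enum) {
    combs <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    return(mean(abs(u_all - na * nb / 2) >= dev_obs - 1e-9))
  }
  # normal approximation with tie correction
  ties <- table(r)
  n <- na + nb
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  zst <- (dev_obs - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-zst))
}

#' Classify the kinetics of a diet response
#'
#' Given an expression trajectory spanning a diet phase, the net change is
#' the difference between the phase-end and switch-day values.  Responses
#' smaller than `response_floor` are labelled `none`.  Otherwise a response
#' is `rapid` when at least 2/3 of the net change is attained within two
#' days of the switch, `delayed` when at most 1/3 is attained early and at
#' least 2/3 of the change accrues in the final inter-sample interval, and
#' `gradual` otherwise.
#'
#' @param trajectory Named numeric vector (names = days).
#' @param switch_day,phase_end_day Days delimiting the phase.
#' @param response_floor Absolute change below which the label is `none`;
#'   default a quarter of the trajectory's dynamic range.
#' @return List: `label` in rapid/gradual/delayed/none and
#'   `fraction_of_change_by_day2`.
#' @export
classify_kinetics <- function(trajectory, switch_day, phase_end_day,
                              response_floor = NULL) {
  days <- as.numeric(names(trajectory))
  if (is.null(response_floor))
    response_floor <- 0.25 * diff(range(trajectory))
  early_days <- days[days > switch_day & days <= switch_day + 2]
  if (!(switch_day %in% days) || !(phase_end_day %in% days) ||
      length(early_days) == 0)
    stop("trajectory must include the switch day, a day within 2 d after it, and the phase end day")
  v0 <- trajectory[as.character(switch_day)]
  v_end <- trajectory[as.character(phase_end_day)]
  net <- v_end - v0
  early <- trajectory[as.character(max(early_days))] - v0
  frac_early <- if (net == 0) 0 else early / net
  if (abs(net) < response_floor)
    return(list(label = "none", fraction_of_change_by_day2 = unname(frac_early)))
  in_phase <- days[days >= switch_day & days <= phase_end_day]
  last_prev <- in_phase[length(in_phase) - 1L]
  final_accrual <- (v_end - trajectory[as.character(last_prev)]) / net
  label <- if (abs(early) >= 2 / 3 * abs(net)) "rapid"
  else if (frac_early <= 1 / 3 && final_accrual >= 2 / 3) "delayed"
  else "gradual"
  list(label = label, fraction_of_change_by_day2 = unname(frac_early))
}

#' Detect community-level masking of species-level responses
#'
#' A feature is masked when the community-normalized and species-normalized
#' analyses both call it significant but in opposite fold-change directions
#' (the community-level trend hides, or inverts, the regulation occurring
#' within the dominant contributing species - typically because that
#' species' share of the whole metatranscriptome shifted between diets).
#'
#' @param community_results,species_results `diff_result` data frames over
#'   the same features (community- and species-normalized analyses).
#' @param alpha Significance level applied at both levels.
#' @return Data frame of flagged features with both directions and p-values;
#'   features absent at one level are skipped with a note attribute.
#' @export
detect_masking <- function(community_results, species_results, alpha = 0.05) {
  common <- intersect(community_results$feature_id,
                      species_results$feature_id)
  skipped <- setdiff(union(community_results$feature_id,
                           species_results$feature_id), common)
  cm <- community_results[match(common, community_results$feature_id), ]
  sp <- species_results[match(common, species_results$feature_id), ]
  flag <- cm$p < alpha & sp$p < alpha &
    cm$direction != "none" & sp$direction != "none" &
    cm$direction != sp$direction
  out <- data.frame(feature_id = common,
                    community_direction = cm$direction, community_p = cm$p,
                    species_direction = sp$direction, species_p = sp$p,
                    stringsAsFactors = FALSE)[flag, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

# leaf-label sets of every internal node of an hclust tree
.node_leafsets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    members <- integer(0)
    for (j in 1:2) {
      m <- hc$merge[i, j]
      members <- c(members, if (m < 0) -m else NULL)
      if (m > 0) members <- c(members, attr(sets[[m]], "idx"))
    }
    s <- sort(hc$labels[members])
    attr(s, "idx") <- members
    sets[[i]] <- s
  }
  sets
}

#' Hierarchical clustering with bootstrap support
#'
#' Average-linkage hierarchical clustering of columns on correlation
#' distance (1 - Pearson r), with per-cluster support computed as the
#' fraction of feature-resampled bootstrap trees that contain the same leaf
#' set (ordinary bootstrap proportions).  Clusters with support above 0.95
#' are conventionally considered strongly supported.
#'
#' @param matrix Numeric matrix (features x samples), typically
#'   log-transformed and mean-centred.
#' @param n_boot Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @return List with `hclust` (the dendrogram), `clusters` (list of leaf
#'   sets per internal node) and `support` (numeric vector per node).
#' @export
cluster_with_bootstrap <- function(matrix, n_boot = 100L, seed = 1L) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) < 3) stop("need >= 3 columns")
  if (n_boot < 1) stop("n_boot must be >= 1")
  set.seed(seed)
  cordist <- function(m) stats::as.dist(1 - stats::cor(m))
  hc <- stats::hclust(cordist(matrix), method = "average")
  sets <- .node_leafsets(hc)
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  hits <- numeric(length(keys))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(matrix), replace = TRUE)
    mb <- matrix[idx, , drop = FALSE]
    sd0 <- apply(mb, 2, stats::sd)
    if (any(sd0 == 0)) next  # degenerate resample: correlation undefined
    hb <- stats::hclust(cordist(mb), method = "average")
    kb <- vapply(.node_leafsets(hb), paste, character(1), collapse = "\r")
    hits <- hits + (keys %in% kb)
  }
  list(hclust = hc, clusters = lapply(sets, as.character),
       support = hits / n_boot)
}

# Cyber-T-style regularized t: per-gene variance shrunk toward the mean
# variance of a window of genes with similar mean expression
.regularized_t <- function(a_mat, b_mat, window = 101L, prior_df = 10) {
  na <- ncol(a_mat); nb <- ncol(b_mat)
  ma <- rowMeans(a_mat); mb <- rowMeans(b_mat)
  va <- apply(a_mat, 1, stats::var); vb <- apply(b_mat, 1, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  o <- order((ma + mb) / 2)
  half <- window %/% 2L
  n <- length(sp2)
  prior <- numeric(n)
  ss <- sp2[o]
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    prior[o[i]] <- mean(ss[lo:hi])
  }
  df <- na + nb - 2
  s2 <- (prior_df * prior + df * sp2) / (prior_df + df)
  tstat <- (mb - ma) / sqrt(s2 * (1 / na + 1 / nb))
  pt2 <- 2 * stats::pt(-abs(tstat), df = prior_df + df)
  list(t = tstat, p = pt2)
}

#' Array-style present and differential-expression calls
#'
#' A gene is `present` when detected in at least 5 of 7 animals on at least
#' one diet (for other group sizes, the threshold is `ceiling(5/7 * n)`).
#' Among present genes, differential expression between the two diets
#' requires `p < 0.01` and `|fold change| >= 2` (and posterior probability
#' of differential expression >= 0.99 when such a value is supplied).  The
#' p-value comes from a regularized t-statistic whose per-gene variance is
#' shrunk toward the mean variance of genes with similar mean expression.
#'
#' @param expr Genes x samples matrix of (normalized) expression values.
#' @param detect_flags Logical genes x samples matrix of per-sample
#'   detection calls.
#' @param groups Factor/character vector over samples with two diet levels.
#' @param ppde Optional per-gene posterior probabilities of differential
#'   expression.
#' @return List with `present` (logical per gene) and `results` (a
#'   `diff_result` for present genes: p, q, fold_change, direction, `de`).
#' @export
present_and_de_calls <- function(expr, detect_flags, groups, ppde = NULL) {
  expr <- as.matrix(expr); detect_flags <- as.matrix(detect_flags)
  stopifnot(identical(dim(expr), dim(detect_flags)))
  groups <- as.factor(groups)
  lv <- levels(groups)
  if (length(lv) != 2) stop("groups must have exactly two levels")
  ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
  thr_a <- ceiling(5 / 7 * length(ia)); thr_b <- ceiling(5 / 7 * length(ib))
  present <- rowSums(detect_flags[, ia, drop = FALSE]) >= thr_a |
    rowSums(detect_flags[, ib, drop = FALSE]) >= thr_b
  res <- NULL
  if (min(length(ia), length(ib)) >= 2 && any(present)) {
    a <- expr[present, ia, drop = FALSE]
    b <- expr[present, ib, drop = FALSE]
    rt <- .regularized_t(a, b)
    eps <- 1e-8
    fc <- (rowMeans(b) + eps) / (rowMeans(a) + eps)
    fc_signed <- ifelse(fc >= 1, fc, -1 / fc)  # symmetric |FC| scale
    de <- rt$p < 0.01 & abs(fc_signed) >= 2
    if (!is.null(ppde)) de <- de & ppde[present] >= 0.99
    res <- data.frame(feature_id = rownames(expr)[present],
                      statistic = rt$t, p = rt$p, q = qvalues(rt$p),
                      fold_change = fc_signed,
                      direction = ifelse(fc > 1, "up",
                                         ifelse(fc < 1, "down", "none")),
                      de = de, stringsAsFactors = FALSE)
    class(res) <- c("diff_result", "data.frame")
  }
  list(present = present, results = res)
}
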