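# OD600 growth-curve phenotyping: extrema-based summaries (total growth
# A_tot = A_max - A_min, rate = A_tot / (t_max - t_min)), growth calls,
# replicate aggregation and cross-substrate ranking.

#' Summarize one growth curve
#'
#' Computes A_max, A_min (with the times at which they are first attained),
#' total growth A_tot = A_max - A_min and rate = A_tot / (t_max - t_min).
#' When the extrema coincide in time the rate is 0 (flagged).  An optional
#' centred moving average can be applied before locating extrema
#' (default off: the statistics are defined on the raw readings).
#'
#' @param time Numeric vector of times (h), strictly increasing.
#' @param od Numeric vector of OD600 readings (>= 0), same length.
#' @param smoothing_window Odd window size in points for a moving average;
#'   0 or 1 disables smoothing.
#' @return A `growth_summary` list: `A_max`, `A_min`, `t_max`, `t_min`,
#'   `A_tot`, `rate`, `degenerate` (TRUE when t_max == t_min).
#' @examples
#' summarize_curve(c(0, 10), c(0.05, 0.90))
#' @export
summarize_curve <- function(time, od, smoothing_window = 0L) {
  if (length(time) < 2 || length(od) != length(time))
    stop("need >= 2 matched time/OD points")
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(od < 0)) stop("OD600 must be >= 0")
  if (smoothing_window > 1) {
    w <- as.integer(smoothing_window)
    if (w %% 2L == 0L) w <- w + 1L
    od <- stats::filter(od, rep(1 / w, w), sides = 2)
    keep <- !is.na(od)
    od <- as.numeric(od[keep]); time <- time[keep]
  }
  i_min <- which.min(od)  # earliest attaining index (which.min tie rule)
  i_max <- which.max(od)
  A_min <- od[i_min]; A_max <- od[i_max]
  t_min <- time[i_min]; t_max <- time[i_max]
  A_tot <- A_max - A_min
  degenerate <- t_max == t_min
  rate <- if (degenerate) 0 else A_tot / (t_max - t_min)
  structure(list(A_max = A_max, A_min = A_min, t_max = t_max, t_min = t_min,
                 A_tot = A_tot, rate = rate, degenerate = degenerate),
            class = "growth_summary")
}

#' @export
print.growth_summary <- function(x, ...) {
  cat(sprintf("A_tot = %.3f OD (A_max %.3f @ %.1f h, A_min %.3f @ %.1f h), rate = %.4f OD/h\n",
              x$A_tot, x$A_max, x$t_max, x$A_min, x$t_min, x$rate))
  invisible(x)
}

#' Growth / no-growth call
#'
#' A culture grew when its total growth reaches the OD threshold
#' (inclusive; default 0.1 OD600 units).
#'
#' @param summary A `growth_summary` (or anything with an `A_tot` field).
#' @param threshold_od Threshold in OD units.
#' @return Logical.
#' @export
growth_call <- function(summary, threshold_od = 0.1) {
  summary$A_tot >= threshold_od
}

#' Aggregate replicate growth summaries
#'
#' Arithmetic mean and sample standard deviation (n - 1) of A_tot and rate
#' across replicates; with a single replicate the SD is absent (NA).
#'
#' @param summaries List of `growth_summary` objects (replicates of one
#'   substrate/species).
#' @return List: `n`, `A_tot_mean`, `A_tot_sd`, `rate_mean`, `rate_sd`.
#' @export
aggregate_replicates <- function(summaries) {
  at <- vapply(summaries, function(s) s$A_tot, numeric(1))
  rt <- vapply(summaries, function(s) s$rate, numeric(1))
  n <- length(at)
  list(n = n,
       A_tot_mean = mean(at),
       A_tot_sd = if (n >= 2) stats::sd(at) else NA_real_,
       rate_mean = mean(rt),
       rate_sd = if (n >= 2) stats::sd(rt) else NA_real_)
}

#' Summarize a simulated growth-curve set
#'
#' Convenience wrapper: applies [summarize_curve()] to every (substrate,
#' replicate) series of a long-format curve table and aggregates replicates.
#'
#' @param curves A `growth_curve_set` (long data frame: substrate,
#'   replicate, time_h, od600), optionally with a `species` column.
#' @param threshold_od Growth-call threshold passed to [growth_call()].
#' @return Data frame per substrate: n, A_tot mean/sd, rate mean/sd,
#'   `grew` (call on the mean A_tot).
#' @export
summarize_growth_set <- function(curves, threshold_od = 0.1) {
  key <- interaction(curves$substrate, curves$replicate, drop = TRUE)
  summaries <- lapply(split(curves, key), function(d)
    c(list(substrate = d$substrate[1]),
      summarize_curve(d$time_h, d$od600)))
  subs <- vapply(summaries, function(s) s$substrate, character(1))
  out <- do.call(rbind, lapply(unique(subs), function(sb) {
    ag <- aggregate_replicates(summaries[subs == sb])
    data.frame(substrate = sb, n = ag$n,
               A_tot_mean = ag$A_tot_mean, A_tot_sd = ag$A_tot_sd,
               rate_mean = ag$rate_mean, rate_sd = ag$rate_sd,
               grew = ag$A_tot_mean >= threshold_od,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Rank species by growth rate across substrates
#'
#' For each substrate, the species with the highest mean rate among those
#' that grew; ties are reported jointly.  Also tallies how many substrates
#' each species wins.
#'
#' @param aggregates Data frame with `species`, `substrate`, `rate_mean`,
#'   `grew` columns.
#' @return List with `winners` (per substrate: character vector of winning
#'   species, empty when nothing grew) and `tallies` (named counts; ties
#'   credit every tied species).
#' @export
rank_species <- function(aggregates) {
  stopifnot(all(c("species", "substrate", "rate_mean", "grew") %in%
                  names(aggregates)))
  winners <- lapply(split(aggregates, aggregates$substrate), function(d) {
    d <- d[d$grew, , drop = FALSE]
    if (!nrow(d)) return(character(0))
    d$species[d$rate_mean == max(d$rate_mean)]
  })
  tal <- table(unlist(winners))
  all_sp <- unique(aggregates$species)
  tallies <- stats::setNames(integer(length(all_sp)), all_sp)
  tallies[names(tal)] <- as.integer(tal)
  list(winners = winners, tallies = tallies)
}
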