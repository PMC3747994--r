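make_spec_table <- function(counts_by_run, species = "S01") {
  # counts_by_run: matrix proteins x (sample:run) with dimnames
  long <- expand.grid(protein_id = rownames(counts_by_run),
                      col = colnames(counts_by_run),
                      stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(long$col, ":"))
  data.frame(protein_id = long$protein_id,
             species_id = if (length(species) == 1) species else
               species[long$protein_id],
             sample_id = parts[, 1], run_id = parts[, 2],
             count = as.vector(counts_by_run),
             stringsAsFactors = FALSE)
}

test_that("NBC and NBS normalization divide by the right totals", {
  m <- rbind(p1 = c(10, 20), p2 = c(990, 180))
  colnames(m) <- c("s1:r1", "s1:r2")
  tab <- make_spec_table(m)
  nbc <- normalize_spectra(tab, "NBC")
  expect_equal(nbc$normalized[nbc$protein_id == "p1" & nbc$run_id == "r1"],
               10 / 1000)
  # NBC sums to 1 per run
  expect_equal(as.vector(tapply(nbc$normalized,
                                interaction(nbc$sample_id, nbc$run_id),
                                sum)), c(1, 1))
  # two species: NBS sums to 1 within species x run; absent species is NA
  m2 <- rbind(p1 = c(10, 20), p2 = c(30, 40), q1 = c(0, 5))
  colnames(m2) <- c("s1:r1", "s1:r2")
  tab2 <- make_spec_table(m2, species = c(p1 = "SA", p2 = "SA", q1 = "SB"))
  nbs <- normalize_spectra(tab2, "NBS")
  expect_equal(nbs$normalized[nbs$protein_id == "p1" & nbs$run_id == "r1"],
               10 / 40)
  expect_true(is.na(nbs$normalized[nbs$protein_id == "q1" &
                                     nbs$run_id == "r1"]))
  # NBC and NBS coincide for a single-species community
  nbc1 <- normalize_spectra(tab, "NBC")
  nbs1 <- normalize_spectra(tab, "NBS")
  expect_equal(nbc1$normalized, nbs1$normalized)
})

test_that("presence and eligibility rules apply their thresholds exactly", {
  expect_true(presence_call(c(3, 2)))
  expect_false(presence_call(c(2, 1)))
  expect_true(presence_call(c(4, 0)))    # inclusive "at least four"
  expect_true(eligibility(c(6, 6, 6, 0)))
  expect_false(eligibility(c(6, 6, 5, 5)))  # 5 is not > 5
  expect_false(eligibility(c(0, 0, 0, 0)))
  # monotonicity: adding counts never flips present -> absent
  set.seed(20)
  for (i in 1:50) {
    rc <- rpois(4, 3)
    more <- rc + rpois(4, 2)
    expect_true(!presence_call(rc) || presence_call(more))
    expect_true(!eligibility(rc) || eligibility(more))
  }
})

test_that("q-values reduce to Benjamini-Hochberg at pi0 = 1", {
  set.seed(8)
  p <- c(runif(60), rbeta(40, 0.2, 5))
  expect_equal(qvalues(p, pi0 = 1), p.adjust(p, "BH"), tolerance = 1e-12)
  expect_equal(qvalues(0.05, pi0 = 1), 0.05)
  expect_equal(qvalues(numeric(0)), numeric(0))
  # monotone in p
  q <- qvalues(sort(p))
  expect_true(all(diff(q) >= -1e-12))
  # estimated pi0 is at most 1 and q-values stay in [0, 1]
  qf <- qvalues(p)
  expect_true(all(qf >= 0 & qf <= 1))
  # fewer than 20 p-values: BH fallback
  expect_equal(qvalues(p[1:10]), p.adjust(p[1:10], "BH"), tolerance = 1e-12)
})

test_that("differential calls follow the p/q/median-difference rule", {
  # 4 samples per diet, 2 runs each; 30 of 60 proteins shift by +12 counts.
  # With the exact 4-vs-4 Mann-Whitney the smallest attainable p is 2/70,
  # so q < 0.05 needs a sizeable set of concordant discoveries - as here.
  set.seed(30)
  prots <- paste0("p", 1:60)
  shifted <- paste0("p", 1:30)
  rows <- list()
  for (pr in prots) {
    shift <- if (pr %in% shifted) 12 else 0
    for (g in c("A", "B")) {
      for (s in 1:4) {
        cnt <- 12 + if (g == "B") shift else 0
        for (r in 1:2) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = pr, species_id = "S01",
            sample_id = paste0(g, s), run_id = paste0("r", r),
            count = cnt + rpois(1, 1), group = g)
        }
      }
    }
  }
  tab <- normalize_spectra(do.call(rbind, rows), "NBC")
  calls <- diff_call(tab)
  expect_s3_class(calls, "protein_calls")
  up <- calls[calls$protein_id %in% shifted, ]
  expect_true(all(up$eligible))
  expect_true(all(up$call == "UP"))
  expect_true(all(up$median_diff > 5))
  expect_true(all(up$p < 0.05 & up$q < 0.05))
  # unchanged proteins: raw median difference near 0, so NULL, never NA
  # (their *share* of community spectra drops, a normalization shift the
  # raw-count median-difference rule is deliberately insensitive to)
  null_calls <- calls$call[!calls$protein_id %in% shifted & calls$eligible]
  expect_false(anyNA(null_calls))
  expect_true(all(null_calls == "NULL"))
})

test_that("median-difference threshold is strict and direction-symmetric", {
  # a steady background protein keeps community normalization meaningful
  mk <- function(a_counts, b_counts) {
    rows <- list()
    for (i in seq_along(a_counts)) {
      for (r in 1:2) {
        for (pr in c("p1", "bg")) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = pr, species_id = "S01",
            sample_id = paste0("A", i), run_id = paste0("r", r),
            count = if (pr == "bg") 1000 else a_counts[i], group = "A")
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = pr, species_id = "S01",
            sample_id = paste0("B", i), run_id = paste0("r", r),
            count = if (pr == "bg") 1000 else b_counts[i], group = "B")
        }
      }
    }
    normalize_spectra(do.call(rbind, rows), "NBC")
  }
  up <- diff_call(mk(c(10, 11, 12, 13), c(30, 31, 32, 33)))
  dn <- diff_call(mk(c(30, 31, 32, 33), c(10, 11, 12, 13)))
  expect_equal(up$call[up$protein_id == "p1"], "UP")
  expect_equal(dn$call[dn$protein_id == "p1"], "DOWN")
  expect_equal(up$median_diff[up$protein_id == "p1"],
               -dn$median_diff[dn$protein_id == "p1"])
  # the shifted background share moves too, but its raw median difference
  # is 0, so it stays NULL
  expect_equal(up$call[up$protein_id == "bg"], "NULL")
  # |median diff| of exactly 2 fails the > 5 rule even at small p
  small <- diff_call(mk(c(10, 10, 10, 10), c(12, 12, 12, 12)))
  expect_equal(small$call[small$protein_id == "p1"], "NULL")
})

test_that("null spectral data produce few UP/DOWN calls", {
  set.seed(44)
  rows <- list()
  for (pr in paste0("p", 1:200)) {
    mu <- 12
    for (g in c("A", "B")) for (s in 1:4) {
      cnt <- rpois(1, mu)
      for (r in 1:2) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pr, species_id = "S01",
          sample_id = paste0(g, s), run_id = paste0("r", r),
          count = cnt + rpois(1, 2), group = g)
      }
    }
  }
  tab <- normalize_spectra(do.call(rbind, rows), "NBC")
  calls <- diff_call(tab)
  frac <- mean(calls$call[calls$eligible] != "NULL", na.rm = TRUE)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("RNA-protein correlation matches the covariance formula", {
  x <- c(a = 1, b = 2, c = 4, d = 3, e = 5)
  y <- c(a = 2, b = 1, c = 5, d = 3, e = 4)
  r <- rna_protein_correlation(x, y)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r$overall$r, manual, tolerance = 1e-12)
  expect_equal(rna_protein_correlation(x, x)$overall$r, 1)
  expect_equal(rna_protein_correlation(x, -x)$overall$r, -1)
  cats <- c(a = "carb", b = "carb", c = "carb", d = "transl", e = "transl")
  rc <- rna_protein_correlation(x, y, cats)
  expect_equal(rc$per_category$r[rc$per_category$category == "carb"],
               cor(x[1:3], y[1:3]))
  expect_true(is.na(rc$per_category$r[rc$per_category$category == "transl"]))
})
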