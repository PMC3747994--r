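make_cm <- function(counts, species = NULL, ec = NULL, diets = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  structure(list(
    counts = counts,
    samples = data.frame(sample_id = colnames(counts),
                         animal = colnames(counts),
                         diet = diets %||% rep("A", ncol(counts))),
    features = data.frame(gene_id = rownames(counts),
                          species_id = species %||% rep("S01", nrow(counts)),
                          ec = ec %||% rep(NA_character_, nrow(counts)),
                          stringsAsFactors = FALSE),
    assay = "rnaseq", state = "raw"), class = "count_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("size factors follow the median-of-ratios closed forms", {
  expect_equal(unname(size_factors(cbind(s1 = c(2, 4), s2 = c(4, 8)))),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)
  m <- cbind(a = c(10, 20, 5), b = c(10, 20, 5))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- cbind(a = c(10, 20, 5), b = 2 * c(10, 20, 5))
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-9)
  # fallback when no feature is present everywhere
  m3 <- cbind(a = c(5, 0), b = c(0, 5))
  expect_warning(sf3 <- size_factors(m3), "library-size")
  expect_equal(unname(sf3), c(1, 1))
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(3)
  m <- matrix(rnbinom(200, mu = 50, size = 5) + 1, 40, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("community vs species normalization differ exactly as designed", {
  counts <- rbind(a1 = c(10, 20), a2 = c(30, 60), b1 = c(10, 10),
                  b2 = c(50, 50))
  cm <- make_cm(counts, species = c("SA", "SA", "SB", "SB"))
  comm <- normalize(cm, "community")
  spec <- normalize(cm, "species")
  # single-species matrix: both levels identical
  cm1 <- make_cm(counts[1:2, , drop = FALSE])
  expect_equal(normalize(cm1, "community")$counts,
               normalize(cm1, "species")$counts)
  # species A doubles in sample 2, B constant: species factors restore B
  expect_equal(unname(spec$counts[c("b1", "b2"), 1]),
               unname(spec$counts[c("b1", "b2"), 2]))
  expect_false(isTRUE(all.equal(comm$counts["b1", 1], comm$counts["b1", 2])))
  # renormalizing is rejected
  expect_error(normalize(comm, "community"), "already normalized")
})

test_that("EC binning equals a group-by-sum oracle and conserves totals", {
  counts <- rbind(g1 = c(5, 1), g2 = c(7, 2), g3 = c(100, 3), g4 = c(9, 4))
  cm <- make_cm(counts, ec = c("1.1.1.1", "1.1.1.1", NA, "2.2.2.2"))
  ec <- bin_by_ec(cm)
  expect_equal(ec$counts["1.1.1.1", ], c(s1 = 12, s2 = 3))
  expect_equal(ec$counts["2.2.2.2", ], c(s1 = 9, s2 = 4))
  expect_false("g3" %in% rownames(ec$counts))
  # oracle: aggregate() on the long table
  long <- data.frame(ec = rep(c("1.1.1.1", "1.1.1.1", "2.2.2.2"), 2),
                     sample = rep(c("s1", "s2"), each = 3),
                     n = c(5, 7, 9, 1, 2, 4))
  or <- aggregate(n ~ ec + sample, long, sum)
  for (i in seq_len(nrow(or)))
    expect_equal(unname(ec$counts[or$ec[i], or$sample[i]]), or$n[i])
  # collapsing-then-summing equals summing annotated genes per sample
  expect_equal(unname(colSums(ec$counts)),
               unname(colSums(counts[c(1, 2, 4), ])))
  # multi-EC genes contribute full counts to each bin
  cm2 <- make_cm(rbind(g1 = c(4, 4)), ec = "1.1.1.1;2.2.2.2")
  ec2 <- bin_by_ec(cm2)
  expect_equal(unname(ec2$counts["1.1.1.1", ]), c(4, 4))
  expect_equal(unname(ec2$counts["2.2.2.2", ]), c(4, 4))
})

test_that("the exact NB test degenerates to the binomial oracle", {
  cm <- make_cm(rbind(e1 = c(0, 0, 10, 10)))
  cm$features$ec <- "e"
  res <- nb_exact_test(cm, c("s1", "s2"), c("s3", "s4"),
                       sf = setNames(rep(1, 4), paste0("s", 1:4)))
  expect_equal(res$p, oracle_binom_p(0, 20, 0.5), tolerance = 1e-9)
  # identical groups: p = 1
  cm2 <- make_cm(rbind(e1 = c(5, 7, 5, 7)))
  res2 <- nb_exact_test(cm2, c("s1", "s2"), c("s3", "s4"),
                        sf = setNames(rep(1, 4), paste0("s", 1:4)))
  expect_equal(res2$p, 1)
  # all-zero feature: p = 1
  cm3 <- make_cm(rbind(e1 = c(0, 0, 0, 0), e2 = c(1, 2, 3, 4)))
  res3 <- nb_exact_test(cm3, c("s1", "s2"), c("s3", "s4"),
                        sf = setNames(rep(1, 4), paste0("s", 1:4)))
  expect_equal(res3$p[1], 1)
})

test_that("the exact NB test holds its size on null simulations", {
  set.seed(77)
  n_feat <- 1000
  counts <- matrix(rnbinom(n_feat * 8, mu = 60, size = 1 / 0.1), n_feat, 8,
                   dimnames = list(paste0("f", 1:n_feat), paste0("s", 1:8)))
  cm <- make_cm(counts)
  res <- nb_exact_test(cm, paste0("s", 1:4), paste0("s", 5:8),
                       sf = setNames(rep(1, 8), paste0("s", 1:8)))
  rate <- mean(res$p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("exact Mann-Whitney agrees with brute-force enumeration", {
  expect_equal(mann_whitney_exact(1:4, 5:8), 2 / 70, tolerance = 1e-12)
  expect_equal(mann_whitney_exact(c(2, 2, 3), c(2, 2, 3)), 1)
  set.seed(9)
  for (na in 1:5) {
    for (nb in na:(10 - na)) {
      a <- round(rnorm(na), 2); b <- round(rnorm(nb, 0.5), 2)
      expect_equal(mann_whitney_exact(a, b), oracle_mwu(a, b),
                   tolerance = 1e-9,
                   info = sprintf("na=%d nb=%d", na, nb))
    }
  }
  # with ties (midranks)
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  expect_equal(mann_whitney_exact(a, b), oracle_mwu(a, b), tolerance = 1e-9)
})

test_that("kinetics classification follows the rapid/gradual/delayed rules", {
  days <- c(13, 14, 15, 20, 27)
  step <- setNames(c(1, 9, 10, 10, 10), days)       # done by day 14
  ramp <- setNames(c(1, 1.6, 2.3, 5.5, 10), days)   # steady accrual
  late <- setNames(c(1, 1, 1, 1.2, 10), days)       # jump at the end
  flat <- setNames(c(1, 1.3, 1.0, 1.3, 1.01), days) # wobble, no net change
  expect_equal(classify_kinetics(step, 13, 27)$label, "rapid")
  expect_equal(classify_kinetics(ramp, 13, 27)$label, "gradual")
  expect_equal(classify_kinetics(late, 13, 27)$label, "delayed")
  expect_equal(classify_kinetics(flat, 13, 27)$label, "none")
  expect_error(classify_kinetics(setNames(c(1, 2), c(13, 27)), 13, 27),
               "within 2 d")
})

test_that("masking detection flags opposite significant directions only", {
  cm <- data.frame(feature_id = c("e1", "e2", "e3"),
                   p = c(0.03, 0.03, 0.5),
                   direction = c("down", "up", "down"))
  sp <- data.frame(feature_id = c("e1", "e2", "e4"),
                   p = c(0.03, 0.03, 0.01),
                   direction = c("up", "up", "up"))
  fl <- detect_masking(cm, sp, alpha = 0.05)
  expect_equal(fl$feature_id, "e1")
  expect_setequal(attr(fl, "skipped"), c("e3", "e4"))
})

test_that("the synthetic masking scenario is flagged end to end", {
  r <- run_masking_scenario(seed = 101)
  expect_identical(r$flagged$feature_id, r$target_ec)
  tc <- r$community[r$community$feature_id == r$target_ec, ]
  ts <- r$species[r$species$feature_id == r$target_ec, ]
  expect_equal(tc$direction, "down")
  expect_equal(ts$direction, "up")
  expect_equal(tc$p, 2 / 70, tolerance = 1e-12)
  expect_equal(ts$p, 2 / 70, tolerance = 1e-12)
})

test_that("bootstrap support is 1 for forced topology and reproducible", {
  set.seed(2)
  x <- rnorm(40); y <- rnorm(40)
  m <- cbind(A1 = x + rnorm(40, sd = 0.05), A2 = x + rnorm(40, sd = 0.05),
             B1 = y + rnorm(40, sd = 0.05), B2 = y + rnorm(40, sd = 0.05))
  cb <- cluster_with_bootstrap(m, n_boot = 50, seed = 10)
  key <- vapply(cb$clusters, paste, "", collapse = ",")
  expect_equal(cb$support[key == "A1,A2"], 1)
  expect_equal(cb$support[key == "B1,B2"], 1)
  cb2 <- cluster_with_bootstrap(m, n_boot = 50, seed = 10)
  expect_identical(cb$support, cb2$support)
  expect_error(cluster_with_bootstrap(m, n_boot = 0), "n_boot")
  # pure noise columns: nontrivial clusters are weakly supported
  set.seed(4)
  noise <- matrix(rnorm(40 * 6), 40, 6,
                  dimnames = list(NULL, paste0("n", 1:6)))
  cbn <- cluster_with_bootstrap(noise, n_boot = 60, seed = 3)
  nontrivial <- lengths(cbn$clusters) < 6
  expect_lt(median(cbn$support[nontrivial]), 0.95)
})

test_that("present/DE calls apply the 5-of-7 and p/FC criteria", {
  set.seed(6)
  n <- 60
  expr <- matrix(rlnorm(n * 14, meanlog = 3), n, 14,
                 dimnames = list(paste0("g", 1:n), paste0("s", 1:14)))
  groups <- rep(c("A", "B"), each = 7)
  det <- matrix(TRUE, n, 14, dimnames = dimnames(expr))
  det[1, ] <- c(rep(TRUE, 5), rep(FALSE, 2), rep(FALSE, 7))   # 5/7 on A
  det[2, ] <- c(rep(TRUE, 4), rep(FALSE, 3), rep(TRUE, 4), rep(FALSE, 3))
  out <- present_and_de_calls(expr, det, groups)
  expect_true(out$present[1])    # 5 of 7 on one diet suffices
  expect_false(out$present[2])   # 4 of 7 on both diets fails
  # a strong true effect is called DE; FC below 2 is not
  expr2 <- expr
  expr2["g3", 1:7] <- rnorm(7, 100, 5)   # clear up-regulation, tight groups
  expr2["g3", 8:14] <- rnorm(7, 800, 5)
  expr2["g4", 1:7] <- rnorm(7, 100, 5)   # sub-threshold fold change
  expr2["g4", 8:14] <- rnorm(7, 150, 5)
  det2 <- matrix(TRUE, n, 14, dimnames = dimnames(expr))
  out2 <- present_and_de_calls(expr2, det2, groups)
  r3 <- out2$results[out2$results$feature_id == "g3", ]
  r4 <- out2$results[out2$results$feature_id == "g4", ]
  expect_true(r3$de)
  expect_false(r4$de)
  expect_lt(abs(r4$fold_change), 2)
})
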