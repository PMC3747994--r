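test_that("informative sizes match a brute-force k-mer dictionary", {
  g <- fixture_genomes(seed = 17, n_species = 3, len = 400)
  k <- 5
  is5 <- compute_informative_sizes(g, k = k)
  # oracle: canonical k-mers by hand, counted in one dictionary
  canon <- function(s) {
    n <- nchar(s) - k + 1
    km <- substring(s, 1:n, 1:n + k - 1)
    pmin(km, oracle_revcomp(km))
  }
  all_km <- unlist(lapply(g$sequences, canon))
  cnt <- table(all_km)
  expected <- vapply(g$sequences, function(s)
    sum(cnt[canon(s)] == 1), numeric(1))
  expect_equal(unname(is5$sizes), unname(expected))
  expect_true(all(is5$sizes <= 400 - k + 1))
})

test_that("identical genomes have zero informative size", {
  d <- synthetic_design(
    n_species = 2, genome_length_per_species = 500, genes_per_species = 2,
    homology_blocks = list(list(pair = c(1, 2), shared_fraction = 1,
                                percent_identity = 100)), seed = 4)
  g <- generate_genomes(d)
  expect_equal(unname(compute_informative_sizes(g, k = 25)$sizes), c(0, 0))
})

test_that("a genome with all-distinct canonical k-mers scores L - k + 1", {
  # fixed sequence whose canonical 5-mers are all distinct
  seqs <- c(S01 = "ATGACAGGCCGGAAACCCCGAGAAAACAAC")
  g <- structure(list(species_id = "S01", sequences = seqs,
                      genes = data.frame(), proteins = character(),
                      aux_proteins = character()),
                 class = "community_genomes")
  k <- 5
  km <- substring(seqs, 1:(nchar(seqs) - k + 1), k:nchar(seqs))
  canon <- pmin(km, oracle_revcomp(km))
  expect_equal(anyDuplicated(canon), 0L)
  expect_equal(unname(compute_informative_sizes(g, k = k)$sizes),
               unname(nchar(seqs)) - k + 1)
})

test_that("read assignment matches the exhaustive substring oracle", {
  shared <- list(list(pair = c(1, 2), shared_fraction = 0.3,
                      percent_identity = 100))
  g <- fixture_genomes(seed = 31, n_species = 3, len = 600, shared = shared)
  r <- simulate_shotgun_reads(g, c(0.4, 0.4, 0.2), 300, seed = 12)
  a <- assign_reads(r, g, k = 25)
  hits <- oracle_assign(r$sequence, g$sequences)
  n_hits <- rowSums(hits)
  expect_equal(a$unassigned, sum(n_hits == 0))
  expect_equal(a$ambiguous, sum(n_hits > 1))
  uc <- colSums(hits[n_hits == 1, , drop = FALSE])
  expect_equal(unname(a$unique_counts), unname(uc))
  # conservation invariant
  expect_equal(sum(a$unique_counts) + a$ambiguous + a$unassigned, a$total)
})

test_that("reads from a fully shared block are ambiguous, private reads unique", {
  shared <- list(list(pair = c(1, 2), shared_fraction = 0.4,
                      percent_identity = 100))
  g <- fixture_genomes(seed = 7, n_species = 2, len = 500, shared = shared)
  block_reads <- data.frame(
    sequence = substring(g$sequences[1], c(1, 50, 100), c(25, 74, 124)))
  a <- assign_reads(block_reads, g, k = 25)
  expect_equal(a$ambiguous, 3L)
  private <- data.frame(
    sequence = substring(g$sequences[1], c(300, 400), c(324, 424)))
  a2 <- assign_reads(private, g, k = 25)
  expect_equal(unname(a2$unique_counts["S01"]), 2L)
  # empty read set: empty result, not an error
  a0 <- assign_reads(data.frame(sequence = character()), g, k = 25)
  expect_equal(a0$total, 0L)
})

test_that("quantification normalizes by informative size", {
  q <- quantify(c(A = 100, B = 100), c(A = 1000, B = 500))
  expect_equal(q$proportion, c(100 / 3, 200 / 3), tolerance = 1e-6)
  expect_equal(sum(q$proportion), 100, tolerance = 1e-9)
  # equal informative sizes: proportions equal raw count fractions
  q2 <- quantify(c(A = 30, B = 70), c(A = 500, B = 500))
  expect_equal(q2$proportion, c(30, 70))
  # scale invariance
  q3 <- quantify(c(A = 300, B = 700), c(A = 500, B = 500))
  expect_equal(q2$proportion, q3$proportion)
  # informative size 0 with nonzero count is a named error
  expect_error(quantify(c(A = 5, B = 1), c(A = 0, B = 10)), "A")
})

test_that("presence threshold is inclusive at 0.003%", {
  tab <- data.frame(sample_id = "s", species_id = c("a", "b", "c"),
                    proportion = c(0.002, 0.003, 0))
  out <- presence_filter(tab)
  expect_equal(out$present, c(FALSE, TRUE, FALSE))
})

test_that("PoMA rescales trajectories to each animal's maximum", {
  tab <- data.frame(animal = "m1", species_id = "S01", day = c(1, 2, 3),
                    proportion = c(10, 40, 20))
  expect_equal(poma(tab)$poma, c(25, 100, 50))
  # constant series: all 100; ties: both 100
  tab2 <- data.frame(animal = "m1", species_id = "S01", day = 1:3,
                     proportion = c(5, 5, 5))
  expect_equal(poma(tab2)$poma, c(100, 100, 100))
  tab3 <- data.frame(animal = "m1", species_id = "S01", day = 1:3,
                     proportion = c(7, 3, 7))
  expect_equal(poma(tab3)$poma, c(100, 300 / 7, 100))
  # invariance to rescaling a whole trajectory
  tab4 <- tab; tab4$proportion <- tab$proportion * 3.7
  expect_equal(poma(tab4)$poma, poma(tab)$poma)
  # all-zero series: NA with warning
  tab5 <- data.frame(animal = "m1", species_id = "S01", day = 1:2,
                     proportion = c(0, 0))
  expect_warning(p5 <- poma(tab5), "undefined")
  expect_true(all(is.na(p5$poma)))
})

test_that("Hellinger PCoA reproduces closed-form distances and coordinates", {
  m <- rbind(s1 = c(1, 0), s2 = c(0, 1), s3 = c(0.5, 0.5))
  res <- hellinger_pcoa(m, n_axes = 2)
  d <- as.matrix(res$distances)
  expect_equal(d["s1", "s2"], sqrt(2), tolerance = 1e-9)
  # identical samples coincide
  m2 <- rbind(a = c(2, 1), b = c(2, 1), c = c(1, 5))
  r2 <- hellinger_pcoa(m2, n_axes = 2)
  expect_equal(as.matrix(r2$distances)["a", "b"], 0, tolerance = 1e-12)
  # Gower property: Hellinger distances are Euclidean-embeddable, so all
  # eigenvalues are nonnegative and coordinate distances reproduce the input
  set.seed(1)
  m3 <- matrix(runif(5 * 4), 5, dimnames = list(paste0("s", 1:5), NULL))
  r3 <- hellinger_pcoa(m3, n_axes = 4)
  expect_true(all(r3$eigenvalues > -1e-8))
  expect_equal(as.matrix(dist(r3$coordinates)), as.matrix(r3$distances),
               tolerance = 1e-8)
})

test_that("predictiveness R^2 behaves at its boundary cases", {
  expect_equal(predictiveness_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(predictiveness_r2(c(1, 2, 3), c(3, 2, 1)), 1)
  expect_error(predictiveness_r2(c(1, 1, 1), c(1, 2, 3)), "variance")
  # null expectation ~ 1/(n-1) for independent vectors of 12 species
  set.seed(5)
  r2s <- replicate(400, predictiveness_r2(runif(12), runif(12)))
  expect_lt(abs(mean(r2s) - 1 / 11), 0.03)
})

test_that("simulated community proportions are recovered by quantification", {
  g <- fixture_genomes(seed = 23, n_species = 3, len = 2000)
  r <- simulate_shotgun_reads(g, c(0.5, 0.3, 0.2), 20000, seed = 4)
  a <- assign_reads(r, g, k = 25)
  is25 <- compute_informative_sizes(g, k = 25)
  q <- quantify(a$unique_counts, is25)
  expect_lt(max(abs(q$proportion - c(50, 30, 20))), 1.5)
})
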