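# Independent brute-force oracles used across the suite.  Each oracle takes
# a different computational route from the implementation it checks.

# reverse complement without Biostrings
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# exhaustive substring-scan read assignment: a read hits a species iff the
# read or its reverse complement occurs anywhere in the genome
oracle_assign <- function(read_seqs, genome_seqs) {
  t(vapply(read_seqs, function(r) {
    rc <- oracle_revcomp(r)
    vapply(genome_seqs, function(g) {
      grepl(r, g, fixed = TRUE) || grepl(rc, g, fixed = TRUE)
    }, logical(1))
  }, logical(length(genome_seqs))))
}

# regex-based tryptic digestion: split after K/R not before P, then join
# consecutive base fragments for missed cleavages
oracle_digest <- function(protein, max_missed) {
  base <- strsplit(protein, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
  nf <- length(base)
  out <- character(0)
  for (m in 0:max_missed) {
    if (m >= nf) break
    for (i in seq_len(nf - m)) {
      out <- c(out, paste(base[i:(i + m)], collapse = ""))
    }
  }
  out
}

# Mann-Whitney two-sided exact p by pair-counting U over all labelings
oracle_mwu <- function(a, b) {
  x <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    av <- x[idx]; bv <- x[-idx]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  dev_obs <- abs(u_of(seq_len(na)) - na * length(b) / 2)
  combs <- utils::combn(length(x), na)
  devs <- abs(apply(combs, 2, u_of) - na * length(b) / 2)
  mean(devs >= dev_obs - 1e-9)
}

# exact binomial two-sided p (sum of outcome probabilities <= observed)
oracle_binom_p <- function(ya, n, prob) {
  d <- stats::dbinom(0:n, n, prob)
  sum(d[d <= d[ya + 1] * (1 + 1e-10)])
}

# tiny two-species community with a designed 100%-identity shared block
fixture_genomes <- function(seed = 11, n_species = 3, len = 1000,
                            shared = NULL) {
  synthetic_design(
    n_species = n_species, genome_length_per_species = len,
    genes_per_species = 3,
    homology_blocks = if (is.null(shared)) list() else shared,
    seed = seed) |> generate_genomes()
}
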