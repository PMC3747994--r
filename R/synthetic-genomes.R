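AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")
rand_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

substitute_chars <- function(seq, rate, alphabet) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(alphabet, ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Generate synthetic community genomes, annotations and proteomes
#'
#' Builds a `community_genomes` object from a [synthetic_design()]: one random
#' DNA genome per species with non-overlapping gene models, functional
#' annotations (EC numbers, CAZy families, susC/susD roles with PUL ids, KEGG
#' categories), one random protein per gene, and auxiliary proteomes (host,
#' distractor species, contaminants) for composite-database searches.
#'
#' Inter-species homology is modelled as blocks copied from a donor genome to
#' an acceptor at the designed percent identity (point substitutions at
#' `100 - identity` percent of positions); proteins of acceptor genes lying
#' fully inside a copied block are likewise copied from the corresponding
#' donor genes.  Overlapping blocks on one acceptor genome are rejected.
#'
#' @param design A [synthetic_design()].
#' @param ec_pool Number of distinct EC numbers to draw from.
#' @param frac_ec,frac_cazy Fraction of genes given an EC number / CAZy family.
#' @param puls_per_species Number of susC/susD marker pairs (PULs) per species.
#' @param n_host_proteins,n_distractor_species,n_distractor_proteins,n_contaminants
#'   Sizes of the auxiliary proteomes.
#' @return A `community_genomes` object: list with `sequences` (named DNA
#'   strings), `genes` (annotation data frame), `proteins` (named amino-acid
#'   strings for every gene), `protein_sources` (protein to source map
#'   including auxiliaries) and `aux_proteins`.
#' @examples
#' g <- generate_genomes(synthetic_design(n_species = 2,
#'        genome_length_per_species = 1500, genes_per_species = 4, seed = 7))
#' names(g$sequences)
#' @export
generate_genomes <- function(design,
                             ec_pool = 20L,
                             frac_ec = 0.6,
                             frac_cazy = 0.2,
                             puls_per_species = 2L,
                             n_host_proteins = 40L,
                             n_distractor_species = 3L,
                             n_distractor_proteins = 20L,
                             n_contaminants = 5L) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  ns <- design$n_species
  L <- design$genome_length_per_species
  ng <- design$genes_per_species
  species_id <- sprintf("S%02d", seq_len(ns))

  sequences <- vapply(seq_len(ns), function(i) rand_dna(L), character(1))
  names(sequences) <- species_id

  # evenly spaced non-overlapping gene models; lengths are multiples of 3
  gene_len <- max(30L, 3L * (floor(0.6 * L / ng) %/% 3L))
  gap <- floor((L - ng * gene_len) / (ng + 1))
  if (gap < 0) stop("genes do not fit in the genome; reduce genes_per_species")
  starts <- gap + (seq_len(ng) - 1L) * (gene_len + gap) + 1L

  ecs <- apply(matrix(sample(1:9, 4 * ec_pool, replace = TRUE), ncol = 4), 1,
               paste, collapse = ".")
  cazys <- paste0(sample(c("GH", "PL", "CE", "GT"), 12, replace = TRUE),
                  sample(1:99, 12))
  keggs <- c("Translation", "Carbohydrate metabolism", "Energy metabolism",
             "Amino acid metabolism", "Other")

  genes <- do.call(rbind, lapply(seq_len(ns), function(i) {
    gid <- sprintf("%s_g%03d", species_id[i], seq_len(ng))
    ec <- ifelse(stats::runif(ng) < frac_ec, sample(ecs, ng, replace = TRUE),
                 NA_character_)
    cazy <- ifelse(stats::runif(ng) < frac_cazy,
                   sample(cazys, ng, replace = TRUE), NA_character_)
    sus <- rep("none", ng)
    pul <- rep(NA_character_, ng)
    npul <- min(puls_per_species, ng %/% 2L)
    if (npul > 0) {
      anchors <- seq(1L, by = max(2L, ng %/% max(1L, npul)),
                     length.out = npul)
      for (p in seq_len(npul)) {
        a <- anchors[p]
        sus[a] <- "susC"; sus[a + 1L] <- "susD"
        pul[c(a, a + 1L)] <- sprintf("%s_PUL%d", species_id[i], p)
      }
    }
    data.frame(gene_id = gid, species_id = species_id[i],
               start = starts, end = starts + gene_len - 1L,
               strand = rep_len(c("+", "-"), ng),
               ec = ec, cazy = cazy, sus_role = sus, pul = pul,
               kegg = sample(keggs, ng, replace = TRUE,
                             prob = c(0.15, 0.25, 0.15, 0.15, 0.3)),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  prot_len <- gene_len %/% 3L
  proteins <- vapply(seq_len(nrow(genes)), function(i) rand_aa(prot_len),
                     character(1))
  names(proteins) <- genes$gene_id

  # homology blocks: copy DNA (and covered proteins) donor -> acceptor
  used <- vector("list", ns)
  for (hb in design$homology_blocks) {
    don <- hb$pair[1]; acc <- hb$pair[2]
    if (don < 1 || don > ns || acc < 1 || acc > ns || don == acc)
      stop("homology block pair indices out of range")
    blen <- round(hb$shared_fraction * L)
    if (blen < 1) next
    bstart <- if (is.null(hb$start)) 1L else as.integer(hb$start)
    bend <- bstart + blen - 1L
    if (bend > L) stop("homology block extends past genome end")
    for (iv in used[[acc]]) {
      if (bstart <= iv[2] && bend >= iv[1])
        stop("overlapping homology blocks on one genome")
    }
    used[[acc]] <- c(used[[acc]], list(c(bstart, bend)))
    sub_rate <- (100 - hb$percent_identity) / 100
    block <- substr(sequences[don], bstart, bend)
    block <- substitute_chars(block, sub_rate, c("A", "C", "G", "T"))
    s <- sequences[acc]
    sequences[acc] <- paste0(substr(s, 1, bstart - 1L), block,
                             substr(s, bend + 1L, L))
    covered <- genes$species_id == species_id[acc] &
      genes$start >= bstart & genes$end <= bend
    donor_genes <- genes$gene_id[genes$species_id == species_id[don]]
    for (idx in which(covered)) {
      j <- match(genes$start[idx],
                 genes$start[genes$species_id == species_id[don]])
      if (!is.na(j)) {
        proteins[genes$gene_id[idx]] <-
          substitute_chars(proteins[donor_genes[j]], sub_rate, AA20)
      }
    }
  }

  host <- vapply(seq_len(n_host_proteins), function(i) rand_aa(250),
                 character(1))
  names(host) <- sprintf("host_p%03d", seq_len(n_host_proteins))
  distract <- list()
  for (d in seq_len(n_distractor_species)) {
    ps <- vapply(seq_len(n_distractor_proteins), function(i) rand_aa(200),
                 character(1))
    names(ps) <- sprintf("distractor%d_p%03d", d,
                         seq_len(n_distractor_proteins))
    distract[[sprintf("distractor%d", d)]] <- ps
  }
  contam <- vapply(seq_len(n_contaminants), function(i) rand_aa(300),
                   character(1))
  names(contam) <- sprintf("contam_p%02d", seq_len(n_contaminants))

  aux <- c(host, unlist(unname(distract)), contam)
  protein_sources <- data.frame(
    protein_id = c(names(proteins), names(aux)),
    source = c(genes$species_id,
               rep("host", length(host)),
               rep(names(distract), each = n_distractor_proteins),
               rep("contaminant", length(contam))),
    stringsAsFactors = FALSE)

  structure(list(
    species_id = species_id,
    sequences = sequences,
    genes = genes,
    proteins = proteins,
    aux_proteins = aux,
    protein_sources = protein_sources,
    design = design
  ), class = "community_genomes")
}

#' @export
print.community_genomes <- function(x, ...) {
  cat(sprintf("Community genome set: %d species, %d genes, %d proteins (+%d auxiliary)\n",
              length(x$species_id), nrow(x$genes), length(x$proteins),
              length(x$aux_proteins)))
  invisible(x)
}

#' Genome lengths of a community genome set
#' @param genomes A `community_genomes` object.
#' @return Named integer vector of genome lengths (bp).
#' @export
genome_lengths <- function(genomes) {
  stopifnot(inherits(genomes, "community_genomes"))
  vapply(genomes$sequences, nchar, integer(1))
}
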