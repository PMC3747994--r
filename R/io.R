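# Readers/writers for the pipeline's on-disk formats: FASTA genomes and
# proteomes, GFF3 + TSV annotation sidecar, FASTQ reads, TSV count/abundance
# tables, JSON designs.

#' Write community genomes as FASTA (and proteomes)
#'
#' @param genomes A `community_genomes` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: `genomes.fasta`,
#'   `proteome_community.fasta`, `proteome_auxiliary.fasta`.
#' @export
write_community_fasta <- function(genomes, dir) {
  stopifnot(inherits(genomes, "community_genomes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("genomes.fasta", "proteome_community.fasta",
                            "proteome_auxiliary.fasta"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genomes$sequences), paths[1])
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(genomes$proteins), paths[2])
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(genomes$aux_proteins), paths[3])
  invisible(paths)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @param type `"dna"` or `"protein"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write gene annotations as GFF3 plus a TSV sidecar
#'
#' @param genomes A `community_genomes` object.
#' @param dir Output directory.
#' @return Invisibly the paths (`annotation.gff3`, `annotation.tsv`).
#' @export
write_annotation <- function(genomes, dir) {
  stopifnot(inherits(genomes, "community_genomes"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- genomes$genes
  gff <- file.path(dir, "annotation.gff3")
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  attrs <- paste0("ID=", g$gene_id,
                  ifelse(is.na(g$ec), "", paste0(";ec_number=", g$ec)),
                  ifelse(is.na(g$pul), "", paste0(";pul=", g$pul)))
  writeLines(paste(g$species_id, "syncomics", "gene", g$start, g$end, ".",
                   g$strand, ".", attrs, sep = "\t"), con)
  close(con)
  tsv <- file.path(dir, "annotation.tsv")
  utils::write.table(g, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(gff, tsv))
}

#' Read the annotation TSV sidecar
#' @param path TSV path written by [write_annotation()].
#' @return Annotation data frame.
#' @export
read_annotation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a read set as FASTQ
#'
#' Qualities are constant (the simulator carries no quality model).
#'
#' @param reads A `read_set`.
#' @param path Output FASTQ path.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$sequence,
                                                reads$read_id))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Read a FASTA/FASTQ read file as a `read_set`
#' @param path Reads path.
#' @param format `"fastq"` or `"fasta"`.
#' @return A `read_set` data frame (true_species NA).
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  res <- data.frame(read_id = names(x), sequence = as.character(x),
                    true_species = NA_character_, stringsAsFactors = FALSE)
  class(res) <- c("read_set", "data.frame")
  res
}

#' Write a count matrix (counts + sample metadata) as TSV
#' @param matrix A `count_matrix`.
#' @param dir Output directory; writes `counts.tsv`, `samples.tsv`,
#'   `features.tsv` (and run tables for spectral assays).
#' @export
write_count_matrix <- function(matrix, dir) {
  stopifnot(inherits(matrix, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(feature_id = rownames(matrix$counts),
                                matrix$counts, check.names = FALSE),
                     file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(matrix$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(matrix$features, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix$runs)) {
    for (r in names(matrix$runs)) {
      utils::write.table(
        data.frame(feature_id = rownames(matrix$runs[[r]]),
                   matrix$runs[[r]], check.names = FALSE),
        file.path(dir, paste0("counts_", r, ".tsv")), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Read a count matrix written by [write_count_matrix()]
#' @param dir Directory containing counts.tsv / samples.tsv / features.tsv.
#' @param assay Assay tag for the reconstructed object.
#' @return A raw `count_matrix`.
#' @export
read_count_matrix <- function(dir, assay = "rnaseq") {
  cts <- utils::read.delim(file.path(dir, "counts.tsv"),
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts[[1]]
  structure(list(counts = m,
                 samples = utils::read.delim(file.path(dir, "samples.tsv"),
                                             stringsAsFactors = FALSE),
                 features = utils::read.delim(file.path(dir, "features.tsv"),
                                              stringsAsFactors = FALSE),
                 assay = assay, state = "raw"),
            class = "count_matrix")
}

#' Write a long-format TSV table
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format TSV table
#' @param path TSV path.
#' @return Data frame.
#' @export
read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Write / read a synthetic design as JSON
#' @param design A [synthetic_design()].
#' @param path JSON path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "synthetic_design"))
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$diet_labels <- unlist(x$diet_labels)
  x$phase_schedule <- lapply(x$phase_schedule, function(p)
    list(phase = p$phase, diet = p$diet, days = unlist(p$days)))
  x$homology_blocks <- lapply(x$homology_blocks, function(hb) {
    hb$pair <- unlist(hb$pair)
    hb
  })
  do.call(synthetic_design, lapply(x, function(v)
    if (is.list(v)) v else unlist(v)))
}
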