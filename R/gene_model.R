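# Genome container: ordered gene models with coordinates, exon structure and
# sequences. Internal coordinates are 0-based half-open; GFF3 conversion
# (1-based inclusive) happens only at the I/O boundary.

#' Construct a genome object
#'
#' A genome bundles a gene table (one row per gene model, with 0-based
#' half-open coordinates, strand, exon structure and per-chromosome rank by
#' start position) with its protein and CDS sequences.
#'
#' @param genome_id short genome identifier.
#' @param species species name.
#' @param clade clade label.
#' @param ploidy positive integer ploidy level.
#' @param genes data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` and a list-column `exons` of two-column matrices
#'   (start, end; 0-based half-open CDS segments sorted by start).
#' @param protein named character vector of protein sequences.
#' @param cds named character vector of CDS nucleotide sequences.
#' @param validate run invariant checks (translation, exon arithmetic).
#' @return an object of class `fam_genome`.
#' @export
new_genome <- function(genome_id, species = genome_id, clade = "unknown",
                       ploidy = 2L, genes, protein, cds, validate = TRUE) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chromosome", "start", "end", "strand")
                %in% names(genes)),
            "exons" %in% names(genes))
  if (anyDuplicated(genes$gene_id))
    stop("duplicated gene_id in genome ", genome_id)
  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ,
                 drop = FALSE]
  # rows are sorted by (chromosome, start), and split() returns chromosome
  # groups in sorted order, so this assigns 0-based positional ranks
  genes$rank <- unlist(lapply(split(seq_len(nrow(genes)), genes$chromosome),
                              function(i) seq_along(i) - 1L),
                       use.names = FALSE)
  rownames(genes) <- NULL
  g <- structure(list(genome_id = genome_id, species = species,
                      clade = clade, ploidy = as.integer(ploidy),
                      genes = genes,
                      protein = protein[genes$gene_id],
                      cds = cds[genes$gene_id]),
                 class = "fam_genome")
  if (validate) validate_genome(g)
  g
}

#' Check the invariants of a genome object
#'
#' Verifies coordinate sanity, exon bookkeeping (non-overlapping, sorted,
#' summed length equal to the CDS length, CDS divisible by 3) and that each
#' CDS translates to the stored protein (terminal stop dropped).
#'
#' @param g a `fam_genome`.
#' @return `g` invisibly; errors describe the first offending gene.
#' @export
validate_genome <- function(g) {
  genes <- g$genes
  for (i in seq_len(nrow(genes))) {
    id <- genes$gene_id[i]
    ex <- genes$exons[[i]]
    if (genes$start[i] >= genes$end[i])
      stop("gene ", id, ": start >= end")
    if (is.unsorted(ex[, 1], strictly = TRUE) && nrow(ex) > 1)
      stop("gene ", id, ": exons not sorted by start")
    if (nrow(ex) > 1 && any(ex[-nrow(ex), 2] > ex[-1, 1]))
      stop("gene ", id, ": overlapping exons")
    clen <- sum(ex[, 2] - ex[, 1])
    if (clen != nchar(g$cds[[id]]))
      stop("gene ", id, ": exon length sum != cds length")
    if (clen %% 3L != 0L)
      stop("gene ", id, ": cds length not divisible by 3")
    if (translate_cds(g$cds[[id]]) != g$protein[[id]])
      stop("gene ", id, ": cds does not translate to protein")
  }
  invisible(g)
}

#' @export
print.fam_genome <- function(x, ...) {
  cat(sprintf("<fam_genome> %s (%s, clade %s, ploidy %d): %d genes on %d chromosomes\n",
              x$genome_id, x$species, x$clade, x$ploidy, nrow(x$genes),
              length(unique(x$genes$chromosome))))
  invisible(x)
}

#' Convert coordinates between internal and GFF3 conventions
#'
#' Internal coordinates are 0-based half-open; GFF3 is 1-based inclusive.
#' The two conversions are mutual inverses.
#'
#' @param start,end coordinate vectors.
#' @return list with converted `start` and `end`.
#' @export
coords_to_gff3 <- function(start, end) list(start = start + 1L, end = end)

#' @rdname coords_to_gff3
#' @export
coords_from_gff3 <- function(start, end) list(start = start - 1L, end = end)

#' Protein sequences of a genome as an AAStringSet
#' @param g a `fam_genome`.
#' @return `Biostrings::AAStringSet` named by gene id.
#' @export
genome_proteins <- function(g) Biostrings::AAStringSet(g$protein)

#' CDS sequences of a genome as a DNAStringSet
#' @param g a `fam_genome`.
#' @return `Biostrings::DNAStringSet` named by gene id.
#' @export
genome_cds <- function(g) Biostrings::DNAStringSet(g$cds)
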