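# Readers/writers for the on-disk formats the pipeline touches: per-genome
# protein/CDS FASTA + GFF3, Newick trees, and canonical TSV artifacts.

#' Read a genome from protein FASTA, CDS FASTA and GFF3
#'
#' Expects a gene -> mRNA -> CDS feature hierarchy in the GFF3. When a gene
#' has several mRNAs, the transcript with the longest summed CDS is kept
#' (ties broken by the lexicographically smallest mRNA ID). FASTA sequences
#' are matched by gene ID or mRNA ID (`id_from`). Records whose CDS length
#' is not divisible by 3 are skipped with a warning; an annotated ID missing
#' from either FASTA is an error.
#'
#' @param fasta_protein path to the protein FASTA.
#' @param fasta_cds path to the CDS FASTA.
#' @param gff3 path to the GFF3 annotation.
#' @param species_row list/one-row data.frame with `genome_id`, and
#'   optionally `species`, `clade`, `ploidy`.
#' @param id_from which feature ID names the FASTA records: "gene" or "mRNA".
#' @return a `fam_genome`.
#' @export
read_genome <- function(fasta_protein, fasta_cds, gff3, species_row,
                        id_from = c("gene", "mRNA")) {
  id_from <- match.arg(id_from)
  prot <- Biostrings::readAAStringSet(fasta_protein)
  cds <- Biostrings::readDNAStringSet(fasta_cds)
  names(prot) <- sub("\\s.*$", "", names(prot))
  names(cds) <- sub("\\s.*$", "", names(cds))
  ann <- as.data.frame(rtracklayer::readGFF(
    gff3, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  ann$Parent <- vapply(ann$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  genes_ann <- ann[ann$type == "gene", , drop = FALSE]
  mrna <- ann[ann$type == "mRNA", , drop = FALSE]
  cds_feat <- ann[ann$type == "CDS", , drop = FALSE]

  rows <- list(); keep_prot <- character(); keep_cds <- character()
  for (i in seq_len(nrow(genes_ann))) {
    gid <- genes_ann$ID[i]
    tx <- mrna[!is.na(mrna$Parent) & mrna$Parent == gid, , drop = FALSE]
    if (nrow(tx) == 0) next
    tx_len <- vapply(tx$ID, function(tid) {
      cf <- cds_feat[cds_feat$Parent == tid, , drop = FALSE]
      sum(cf$end - cf$start + 1L)
    }, integer(1))
    ord <- order(-tx_len, tx$ID)
    tid <- tx$ID[ord[1]]
    cf <- cds_feat[cds_feat$Parent == tid, , drop = FALSE]
    cf <- cf[order(cf$start), , drop = FALSE]
    clen <- sum(cf$end - cf$start + 1L)
    if (clen %% 3L != 0L) {
      warning("gene ", gid, ": CDS length ", clen,
              " not divisible by 3; record skipped")
      next
    }
    key <- if (id_from == "gene") gid else tid
    if (!key %in% names(prot))
      stop("id '", key, "' present in GFF3 but absent from protein FASTA")
    if (!key %in% names(cds))
      stop("id '", key, "' present in GFF3 but absent from CDS FASTA")
    ic <- coords_from_gff3(cf$start, cf$end)
    gc <- coords_from_gff3(genes_ann$start[i], genes_ann$end[i])
    rows[[length(rows) + 1L]] <- list(
      gene_id = gid, chromosome = as.character(genes_ann$seqid[i]),
      start = gc$start, end = gc$end,
      strand = as.character(genes_ann$strand[i]),
      exons = cbind(start = ic$start, end = ic$end),
      prot = as.character(prot[[key]]), cds = as.character(cds[[key]]))
  }
  if (!length(rows)) stop("no usable gene models in ", gff3)
  genes <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    chromosome = vapply(rows, `[[`, character(1), "chromosome"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  genes$exons <- lapply(rows, `[[`, "exons")
  sr <- as.list(species_row)
  new_genome(genome_id = sr$genome_id,
             species = if (!is.null(sr$species)) sr$species else sr$genome_id,
             clade = if (!is.null(sr$clade)) sr$clade else "unknown",
             ploidy = if (!is.null(sr$ploidy)) sr$ploidy else 2L,
             genes = genes,
             protein = setNames(vapply(rows, `[[`, character(1), "prot"),
                                genes$gene_id),
             cds = setNames(vapply(rows, `[[`, character(1), "cds"),
                            genes$gene_id))
}

#' Write a genome as protein FASTA, CDS FASTA and GFF3
#'
#' Emits `<genome_id>.protein.fasta`, `<genome_id>.cds.fasta` and
#' `<genome_id>.gff3` under `dir`, with one mRNA (`<gene>.t1`) per gene and
#' FASTA records named by gene ID. Output is byte-reproducible: genes are
#' written in chromosome/start order.
#'
#' @param g a `fam_genome`.
#' @param dir output directory (created if needed).
#' @return named character vector of the three paths, invisibly.
#' @export
write_genome_files <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, g$genome_id)
  paths <- c(protein = paste0(base, ".protein.fasta"),
             cds = paste0(base, ".cds.fasta"),
             gff3 = paste0(base, ".gff3"))
  Biostrings::writeXStringSet(genome_proteins(g), paths["protein"], width = 70)
  Biostrings::writeXStringSet(genome_cds(g), paths["cds"], width = 70)
  con <- file(paths["gff3"], "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  genes <- g$genes
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    gc <- coords_to_gff3(genes$start[i], genes$end[i])
    chrom <- genes$chromosome[i]; strand <- genes$strand[i]
    writeLines(sprintf("%s\tsynfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       chrom, gc$start, gc$end, strand, gid), con)
    writeLines(sprintf("%s\tsynfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       chrom, gc$start, gc$end, strand, gid, gid), con)
    ex <- genes$exons[[i]]
    phase <- 0L
    ord <- if (strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    for (j in ord) {
      ec <- coords_to_gff3(ex[j, 1], ex[j, 2])
      writeLines(sprintf("%s\tsynfam\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.t1.cds;Parent=%s.t1",
                         chrom, ec$start, ec$end, strand, phase, gid, gid), con)
      phase <- (3L - ((ex[j, 2] - ex[j, 1]) - phase) %% 3L) %% 3L
    }
  }
  invisible(paths)
}

#' Write a synteny edge list as canonical TSV
#'
#' Columns `geneA`, `geneB`, `blockA_chrom`, `blockB_chrom`, `block_id`.
#' Within each row geneA < geneB; rows are sorted lexicographically, so the
#' same edge set always yields a byte-identical file.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `chrom_a`,
#'   `chrom_b`, `block_id` (zero rows allowed).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  out <- data.frame(geneA = character(), geneB = character(),
                    blockA_chrom = character(), blockB_chrom = character(),
                    block_id = character(), stringsAsFactors = FALSE)
  if (nrow(edges)) {
    flip <- edges$gene_a > edges$gene_b
    out <- data.frame(
      geneA = ifelse(flip, edges$gene_b, edges$gene_a),
      geneB = ifelse(flip, edges$gene_a, edges$gene_b),
      blockA_chrom = ifelse(flip, edges$chrom_b, edges$chrom_a),
      blockB_chrom = ifelse(flip, edges$chrom_a, edges$chrom_b),
      block_id = as.character(edges$block_id), stringsAsFactors = FALSE)
    out <- out[order(out$geneA, out$geneB, out$block_id), , drop = FALSE]
    out <- out[!duplicated(out), , drop = FALSE]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Newick tree I/O
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()] that keep
#' branch lengths (to at least 6 decimals) and integer bootstrap supports
#' stored as node labels. Unrooted trees are written with a trifurcating
#' root, as `ape` represents them.
#'
#' @param tree an `ape::phylo` (node labels hold supports, if any).
#' @param path file path.
#' @return `read_newick` returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Read / write simple TSV tables (cluster tables, profile matrices)
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
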