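# Gene-structure summaries per genome (family and family-like separately)
# and copy-number statistics across genomes.

#' Per-genome gene-structure summary
#'
#' For each genome and each class (family, family-like): gene count, mean
#' gene length (genomic span), mean exon number and mean CDS length.
#' Absent classes are reported with the `-` sentinel in the formatted
#' table.
#'
#' @param genomes named list of `fam_genome` objects.
#' @param assignments classification table with `genome_id`, `gene_id`,
#'   `class`.
#' @return data.frame, one row per genome, numeric columns per class
#'   (`NA` when the class is absent); `format_structure_summary()` renders
#'   the `-` sentinel.
#' @export
structure_summary <- function(genomes, assignments) {
  rows <- lapply(genomes, function(g) {
    a <- assignments[assignments$genome_id == g$genome_id, , drop = FALSE]
    one <- function(cls) {
      ids <- a$gene_id[a$class == cls]
      gi <- g$genes[g$genes$gene_id %in% ids, , drop = FALSE]
      if (!nrow(gi))
        return(c(n = 0, gene_len = NA_real_, exon_n = NA_real_,
                 cds_len = NA_real_))
      c(n = nrow(gi),
        gene_len = mean(gi$end - gi$start),
        exon_n = mean(vapply(gi$exons, nrow, integer(1))),
        cds_len = mean(vapply(gi$exons, function(e) sum(e[, 2] - e[, 1]),
                              numeric(1))))
    }
    fam <- one("family"); fl <- one("family_like")
    data.frame(genome_id = g$genome_id,
               family_n = fam["n"], family_gene_length = fam["gene_len"],
               family_exon_number = fam["exon_n"],
               family_cds_length = fam["cds_len"],
               family_like_n = fl["n"],
               family_like_gene_length = fl["gene_len"],
               family_like_exon_number = fl["exon_n"],
               family_like_cds_length = fl["cds_len"],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Render a structure summary with the absence sentinel
#'
#' @param summary output of [structure_summary()].
#' @param digits decimals for the mean columns.
#' @return character data.frame where `NA` means are shown as `-`.
#' @export
format_structure_summary <- function(summary, digits = 2) {
  out <- summary
  for (cl in setdiff(names(out), c("genome_id", "family_n",
                                   "family_like_n"))) {
    v <- round_half_up(out[[cl]], digits)
    out[[cl]] <- ifelse(is.na(v), "-", format(v, trim = TRUE))
  }
  out
}

#' Copy-number statistics across genomes
#'
#' Mean copies and coefficient of variation (100 * sample sd / mean) are
#' computed over genomes carrying at least one copy; the Pearson
#' correlation with ploidy is computed over all genomes, zeros included,
#' with a t-based p-value.
#'
#' @param counts named integer vector of copies per genome.
#' @param ploidies named integer vector of ploidies (same genomes).
#' @return list with `mean`, `cv`, `cor`, `p_value`, `n_genomes_with`.
#' @export
copy_number_stats <- function(counts, ploidies) {
  stopifnot(length(counts) == length(ploidies))
  with_copies <- counts[counts > 0]
  m <- if (length(with_copies)) mean(with_copies) else NA_real_
  cv <- if (length(with_copies) >= 2) 100 * sd(with_copies) / m else NA_real_
  if (length(counts) < 2) {
    co <- NA_real_; pv <- NA_real_
  } else if (sd(counts) == 0 || sd(ploidies) == 0) {
    co <- NA_real_; pv <- NA_real_
  } else {
    ct <- cor.test(as.numeric(counts), as.numeric(ploidies))
    co <- unname(ct$estimate); pv <- ct$p.value
  }
  list(mean = m, cv = cv, cor = co, p_value = pv,
       n_genomes_with = length(with_copies))
}
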