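# Family classification: a gene is a full family member iff both
# diagnostic domains are found, family-like iff exactly one is found.
# Similarity-search support is recorded as confirmatory evidence and
# discordance is flagged, but the class is decided by the domains alone.

#' Assign family / family-like / none classes from domain and similarity
#' evidence
#'
#' @param domain_hits data.frame from [scan_domains_all()] (`gene_id`,
#'   `domain_name`, ...).
#' @param similarity_hits data.frame of similarity hits whose `target`
#'   column names genes with similarity support (may have zero rows).
#' @param gene_ids all gene ids to classify (genes without hits are class
#'   "none").
#' @return data.frame with `gene_id`, `class`, `similarity_support`,
#'   `domains_found` (comma-collapsed), `discordant` (domain evidence and
#'   similarity evidence disagree). Classification is idempotent and
#'   independent of input order.
#' @export
assign_family <- function(domain_hits, similarity_hits = NULL,
                          gene_ids = unique(domain_hits$gene_id)) {
  gene_ids <- sort(unique(gene_ids))
  doms <- lapply(setNames(gene_ids, gene_ids), function(g) {
    sort(unique(domain_hits$domain_name[domain_hits$gene_id == g]))
  })
  n_dom <- lengths(doms)
  class <- ifelse(n_dom >= 2L, "family",
                  ifelse(n_dom == 1L, "family_like", "none"))
  sim <- if (!is.null(similarity_hits) && nrow(similarity_hits))
    gene_ids %in% similarity_hits$target else rep(FALSE, length(gene_ids))
  data.frame(gene_id = gene_ids, class = class,
             similarity_support = sim,
             domains_found = vapply(doms, paste, character(1),
                                    collapse = ","),
             discordant = (class == "family") != sim,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Identify family members across a set of genomes
#'
#' Runs the PSSM domain scan on every protein of every genome, runs the
#' confirmatory similarity search of the query set against each proteome,
#' and classifies each gene by the two-domain rule.
#'
#' @param genomes named list of `fam_genome` objects.
#' @param seed_msas list of two seed alignments (`N`, `C`) for
#'   [build_pssm()].
#' @param queries named character vector of query proteins for the
#'   similarity search; defaults to the first row of each seed alignment.
#' @param config a [run_config()].
#' @return list with `assignments` (one row per gene across all genomes,
#'   plus a `genome_id` column), `domain_hits`, and `pssms`.
#' @export
identify_family <- function(genomes, seed_msas, queries = NULL,
                            config = run_config()) {
  pssms <- list(N = build_pssm(seed_msas$N, "N",
                               cutoff_frac = config$domain_cutoff_frac),
                C = build_pssm(seed_msas$C, "C",
                               cutoff_frac = config$domain_cutoff_frac))
  if (is.null(queries))
    queries <- c(query_N = unname(seed_msas$N[1]),
                 query_C = unname(seed_msas$C[1]))
  hits_all <- list(); assign_all <- list()
  for (g in genomes) {
    prot <- g$protein
    dh <- scan_domains_all(prot, pssms)
    sh <- similarity_search(queries, prot, score_cutoff = config$score_cutoff,
                            prefilter = TRUE)
    a <- assign_family(dh, sh, gene_ids = names(prot))
    a$genome_id <- g$genome_id
    if (nrow(dh)) dh$genome_id <- g$genome_id
    hits_all[[g$genome_id]] <- dh
    assign_all[[g$genome_id]] <- a
  }
  list(assignments = do.call(rbind, c(assign_all, make.row.names = FALSE)),
       domain_hits = do.call(rbind, c(hits_all, make.row.names = FALSE)),
       pssms = pssms)
}
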