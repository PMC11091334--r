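# Phylogenomic profiling of synteny clusters: cluster x genome count
# matrix, Jaccard dissimilarity of species-presence sets, Ward
# clustering, synteny-on-tree overlay, and the summary report.

#' Cluster-by-genome profile matrix
#'
#' Counts each retained cluster's genes per genome; genomes with no
#' members appear as zero columns. Row sums equal cluster sizes.
#'
#' @param clusters data.frame from [detect_communities()] (only rows with
#'   `retained = TRUE` are used).
#' @param gene_genomes named character vector mapping gene id to
#'   genome id.
#' @param genome_ids full genome set (columns).
#' @return integer matrix, rows = cluster ids, columns = genome ids.
#' @export
profile_matrix <- function(clusters, gene_genomes, genome_ids) {
  cl <- clusters[clusters$retained, , drop = FALSE]
  ids <- sort(unique(cl$cluster))
  mat <- matrix(0L, length(ids), length(genome_ids),
                dimnames = list(as.character(ids), genome_ids))
  if (nrow(cl)) {
    g <- unname(gene_genomes[cl$gene_id])
    tab <- table(factor(cl$cluster, levels = ids),
                 factor(g, levels = genome_ids))
    mat[] <- as.integer(tab)
  }
  mat
}

#' Jaccard dissimilarity of two cluster profiles
#'
#' `1 - |A intersect B| / |A union B|` over the sets of genomes with a
#' positive count; two empty profiles have dissimilarity 0.
#'
#' @param profile_a,profile_b count vectors over the same genome set.
#' @return value in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(profile_a, profile_b) {
  sa <- which(profile_a > 0); sb <- which(profile_b > 0)
  u <- length(union(sa, sb))
  if (u == 0) return(0)
  1 - length(intersect(sa, sb)) / u
}

#' Pairwise Jaccard dissimilarity matrix of a profile matrix
#'
#' @param mat cluster x genome count matrix.
#' @return symmetric dissimilarity matrix.
#' @export
jaccard_matrix <- function(mat) {
  k <- nrow(mat)
  D <- matrix(0, k, k, dimnames = list(rownames(mat), rownames(mat)))
  if (k >= 2)
    for (i in seq_len(k - 1)) for (j in (i + 1):k)
      D[i, j] <- D[j, i] <- jaccard_dissimilarity(mat[i, ], mat[j, ])
  D
}

#' Ward hierarchical clustering of cluster profiles
#'
#' Agglomerative clustering with the Lance-Williams ward.D update applied
#' to the dissimilarities as given (not squared), i.e.
#' `stats::hclust(method = "ward.D")`.
#'
#' @param D symmetric zero-diagonal dissimilarity matrix.
#' @return an `hclust` dendrogram (single-leaf input returns a degenerate
#'   one-merge-free structure as a list with the leaf label).
#' @export
ward_cluster <- function(D) {
  if (nrow(D) < 2)
    return(structure(list(labels = rownames(D)), class = "single_leaf"))
  hclust(as.dist(D), method = "ward.D")
}

#' Overlay synteny edges on a phylogeny
#'
#' Keeps edges whose both endpoints are tree leaves (others are counted
#' and dropped) and reports, per cluster, the phylogenetic span: the
#' number of distinct assigned groups its genes touch.
#'
#' @param tree rooted `ape::phylo` of family genes.
#' @param edges edge data.frame (`gene_a`, `gene_b`) with a `cluster`
#'   column.
#' @param groups data.frame from [assign_groups()] (`gene_id`, `group`).
#' @return list with `connections` (leaf_a, leaf_b, cluster), `span`
#'   (cluster, n_groups), `n_dropped`.
#' @export
overlay_synteny_on_tree <- function(tree, edges, groups = NULL) {
  leaves <- tree$tip.label
  ok <- edges$gene_a %in% leaves & edges$gene_b %in% leaves
  conn <- data.frame(leaf_a = edges$gene_a[ok], leaf_b = edges$gene_b[ok],
                     cluster = edges$cluster[ok], stringsAsFactors = FALSE)
  span <- NULL
  if (!is.null(groups)) {
    gmap <- setNames(groups$group, groups$gene_id)
    span <- do.call(rbind, lapply(split(conn, conn$cluster), function(cc) {
      gs <- unique(stats::na.omit(gmap[unique(c(cc$leaf_a, cc$leaf_b))]))
      data.frame(cluster = cc$cluster[1], n_groups = length(gs))
    }))
    if (!is.null(span)) rownames(span) <- NULL
  }
  list(connections = conn, span = span, n_dropped = sum(!ok))
}

#' Headline summary ratios
#'
#' Mean family copies per carrying genome and percentage of syntenic
#' members, both rounded half-up to one decimal.
#'
#' @param total total family genes.
#' @param genomes_with genomes carrying at least one member (>= 1).
#' @param syntenic members present in the synteny network.
#' @return list with `mean_per_genome` and `pct_syntenic`.
#' @export
summary_ratios <- function(total, genomes_with, syntenic) {
  stopifnot(total >= 0, genomes_with >= 1, syntenic >= 0)
  if (syntenic > total) stop("syntenic count exceeds total")
  list(mean_per_genome = round_half_up(total / genomes_with, 1),
       pct_syntenic = round_half_up(100 * syntenic / total, 1))
}

#' Aggregate pipeline summary report
#'
#' Collects per-class totals, genomes carrying members, mean copies,
#' copy-number CV, syntenic member counts and percentages, edge and
#' retained-cluster counts.
#'
#' @param assignments classification table with `genome_id`, `gene_id`,
#'   `class`.
#' @param networks named list of `syn_network`s per class (e.g.
#'   `list(family = , family_like = )`).
#' @param clusters named list of [detect_communities()] outputs per class.
#' @param mapping optional tandem-collapse mapping; collapsed genes count
#'   as syntenic when their representative is.
#' @return nested list (JSON-ready) with one entry per class.
#' @export
summary_report <- function(assignments, networks, clusters = NULL,
                           mapping = NULL) {
  out <- list()
  for (cls in names(networks)) {
    a <- assignments[assignments$class == cls, , drop = FALSE]
    total <- nrow(a)
    counts <- table(a$genome_id)
    net <- networks[[cls]]
    in_net <- a$gene_id %in% net$nodes
    if (!is.null(mapping)) {
      rmap <- setNames(mapping$representative, mapping$gene_id)
      reps <- rmap[a$gene_id]
      in_net <- in_net | (!is.na(reps) & reps %in% net$nodes)
    }
    syntenic <- sum(in_net)
    entry <- list(total = total,
                  genomes_with = length(counts),
                  syntenic = syntenic,
                  edges = nrow(net$edges))
    if (length(counts) >= 1 && total > 0) {
      r <- summary_ratios(total, length(counts), syntenic)
      entry$mean_per_genome <- r$mean_per_genome
      entry$pct_syntenic <- r$pct_syntenic
      entry$copy_cv <- if (length(counts) >= 2)
        round_half_up(100 * sd(counts) / mean(counts), 1) else NA_real_
    }
    if (!is.null(clusters) && !is.null(clusters[[cls]])) {
      cl <- clusters[[cls]]
      kept <- cl[cl$retained, , drop = FALSE]
      entry$clusters <- length(unique(kept$cluster))
      entry$syntelogs <- nrow(kept)
    }
    out[[cls]] <- entry
  }
  out
}

#' Write the summary report as JSON and readable text
#'
#' @param report output of [summary_report()].
#' @param json_path,text_path output files (NULL to skip one).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, json_path = NULL, text_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(text_path)) {
    con <- file(text_path, "w")
    on.exit(close(con))
    for (cls in names(report)) {
      e <- report[[cls]]
      writeLines(sprintf("[%s] total=%d in %d genomes; syntenic=%d (%s%%); edges=%d",
                         cls, e$total, e$genomes_with, e$syntenic,
                         if (!is.null(e$pct_syntenic)) e$pct_syntenic else "NA",
                         e$edges), con)
    }
  }
  invisible(report)
}
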