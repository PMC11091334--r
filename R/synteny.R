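# Microsynteny: top-k homology hits per genome, tandem-array collapse,
# dynamic-programming chaining of collinear anchors into blocks, and the
# gene-level synteny network built from retained blocks.

#' Gene rank context for synteny detection
#'
#' @param genomes named list of `fam_genome` objects.
#' @return data.frame with `gene_id`, `genome_id`, `chromosome`
#'   (globally unique `genome:chromosome`), `rank`.
#' @export
synteny_context <- function(genomes) {
  do.call(rbind, lapply(genomes, function(g) {
    data.frame(gene_id = g$genes$gene_id, genome_id = g$genome_id,
               chromosome = paste0(g$genome_id, ":", g$genes$chromosome),
               rank = g$genes$rank, stringsAsFactors = FALSE)
  }))
}

#' Top-k homology hits per query gene per target genome
#'
#' All proteins are compared with the exact local-alignment search
#' (shared-k-mer candidate filter, banded Smith-Waterman scoring); for
#' each query gene and each target genome (its own included unless
#' `self_synteny` is off) the `top_k` best-scoring hits are kept,
#' self-hits excluded, score ties broken by lexicographically smallest
#' target id.
#'
#' @param genomes named list of `fam_genome` objects.
#' @param config a [run_config()].
#' @param min_shared shared-k-mer threshold of the candidate filter.
#' @param band extra half-width of the scoring band beyond the length
#'   difference.
#' @return data.frame with `query`, `target`, `score`, `query_genome`,
#'   `target_genome`.
#' @export
topk_hits <- function(genomes, config = run_config(), min_shared = 10L,
                      band = 32L) {
  prots <- unlist(lapply(genomes, function(g) g$protein))
  names(prots) <- unlist(lapply(genomes, function(g) names(g$protein)))
  gmap <- unlist(lapply(genomes, function(g)
    setNames(rep(g$genome_id, length(g$protein)), names(g$protein))))
  cand <- kmer_candidates(prots, min_shared = min_shared)
  if (!nrow(cand))
    return(data.frame(query = character(), target = character(),
                      score = numeric(), query_genome = character(),
                      target_genome = character()))
  sub <- blosum62_matrix()
  idx <- lapply(prots, aa_index)
  ia <- match(cand$id_a, names(prots))
  ib <- match(cand$id_b, names(prots))
  score <- vapply(seq_len(nrow(cand)), function(k) {
    a <- idx[[ia[k]]]; b <- idx[[ib[k]]]
    .sw_score(a, b, sub, 11, 1,
              as.integer(abs(length(a) - length(b)) + band))
  }, numeric(1))
  hits <- data.frame(
    query = c(cand$id_a, cand$id_b), target = c(cand$id_b, cand$id_a),
    score = c(score, score), stringsAsFactors = FALSE)
  hits <- hits[hits$score >= config$score_cutoff, , drop = FALSE]
  hits$query_genome <- unname(gmap[hits$query])
  hits$target_genome <- unname(gmap[hits$target])
  if (!config$self_synteny)
    hits <- hits[hits$query_genome != hits$target_genome, , drop = FALSE]
  # top_k per (query, target_genome), ties by lexicographic target id
  hits <- hits[order(hits$query, hits$target_genome, -hits$score,
                     hits$target), , drop = FALSE]
  key <- paste(hits$query, hits$target_genome, sep = "\r")
  pos <- stats::ave(seq_along(key), key, FUN = seq_along)
  out <- hits[pos <= config$top_k, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse tandem arrays to one representative gene
#'
#' Maximal runs of mutually homologous genes at consecutive ranks on the
#' same chromosome are replaced by the member with the highest
#' self-alignment score. Hits are remapped to representatives and gene
#' ranks recomputed on the collapsed order.
#'
#' @param hits hit table from [topk_hits()].
#' @param context rank table from [synteny_context()].
#' @param proteins named character vector covering all genes (for
#'   self-scores).
#' @return list with `hits` (remapped, deduplicated), `context`
#'   (re-ranked, representatives only) and `mapping` (data.frame
#'   `gene_id` -> `representative`).
#' @export
collapse_tandem <- function(hits, context, proteins) {
  ctx <- context[order(context$chromosome, context$rank), , drop = FALSE]
  # adjacent homologous pairs on the same chromosome
  hp <- paste(pmin(hits$query, hits$target),
              pmax(hits$query, hits$target), sep = "\r")
  parent <- setNames(seq_len(nrow(ctx)), ctx$gene_id)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (ch in unique(ctx$chromosome)) {
    rows <- which(ctx$chromosome == ch)
    if (length(rows) < 2) next
    for (k in seq_len(length(rows) - 1)) {
      if (ctx$rank[rows[k + 1]] - ctx$rank[rows[k]] != 1L) next
      a <- ctx$gene_id[rows[k]]; b <- ctx$gene_id[rows[k + 1]]
      if (paste(min(a, b), max(a, b), sep = "\r") %in% hp) {
        ra <- find(rows[k]); rb <- find(rows[k + 1])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  comp <- vapply(seq_len(nrow(ctx)), find, numeric(1))
  selfsc <- vapply(ctx$gene_id, function(g) .self_score(proteins[[g]]),
                   numeric(1))
  rep_of <- character(nrow(ctx))
  for (cmp in unique(comp)) {
    members <- which(comp == cmp)
    rep_of[members] <-
      ctx$gene_id[members[order(-selfsc[members],
                                ctx$gene_id[members])[1]]]
  }
  mapping <- data.frame(gene_id = ctx$gene_id, representative = rep_of,
                        stringsAsFactors = FALSE)
  keep <- ctx$gene_id == rep_of
  new_ctx <- ctx[keep, , drop = FALSE]
  new_ctx$rank <- unlist(lapply(split(seq_len(nrow(new_ctx)),
                                      new_ctx$chromosome),
                                seq_along), use.names = FALSE) - 1L
  rmap <- setNames(mapping$representative, mapping$gene_id)
  h <- hits
  h$query <- unname(rmap[h$query])
  h$target <- unname(rmap[h$target])
  h <- h[h$query != h$target, , drop = FALSE]
  h <- h[order(h$query, h$target, -h$score), , drop = FALSE]
  h <- h[!duplicated(h[, c("query", "target")]), , drop = FALSE]
  rownames(h) <- NULL; rownames(new_ctx) <- NULL
  list(hits = h, context = new_ctx, mapping = mapping)
}

#' Anchor table for one or all chromosome pairs
#'
#' Deduplicates symmetric hits into unordered anchors annotated with
#' chromosome and rank on both sides; `gene_a` is the end on the
#' lexicographically smaller (chromosome, rank).
#'
#' @param hits remapped hit table.
#' @param context rank table (collapsed).
#' @return data.frame with `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `rank_a`, `rank_b`, `score`.
#' @export
anchors_from_hits <- function(hits, context) {
  loc <- context[match(c(hits$query, hits$target), context$gene_id), ]
  n <- nrow(hits)
  a <- data.frame(gene = hits$query, chrom = loc$chromosome[seq_len(n)],
                  rank = loc$rank[seq_len(n)], stringsAsFactors = FALSE)
  b <- data.frame(gene = hits$target, chrom = loc$chromosome[n + seq_len(n)],
                  rank = loc$rank[n + seq_len(n)], stringsAsFactors = FALSE)
  flip <- a$chrom > b$chrom | (a$chrom == b$chrom & a$rank > b$rank)
  anchors <- data.frame(
    gene_a = ifelse(flip, b$gene, a$gene),
    gene_b = ifelse(flip, a$gene, b$gene),
    chrom_a = ifelse(flip, b$chrom, a$chrom),
    chrom_b = ifelse(flip, a$chrom, b$chrom),
    rank_a = ifelse(flip, b$rank, a$rank),
    rank_b = ifelse(flip, a$rank, b$rank),
    score = hits$score, stringsAsFactors = FALSE)
  anchors <- anchors[order(anchors$chrom_a, anchors$chrom_b, anchors$rank_a,
                           anchors$rank_b, -anchors$score), , drop = FALSE]
  anchors <- anchors[!duplicated(anchors[, c("gene_a", "gene_b")]), ,
                     drop = FALSE]
  rownames(anchors) <- NULL
  anchors
}

# forward chain lengths for one orientation over rank-sorted anchors;
# returns the lexicographically smallest maximum-size chain (indices into
# the sorted anchor table)
.best_chain_one <- function(ra, rb, max_gap, inverted) {
  n <- length(ra)
  g1 <- max_gap + 1L
  f <- integer(n)
  for (i in n:1) {
    da <- ra - ra[i]
    db <- rb - rb[i]
    ok <- da > 0L & da <= g1 &
      (if (inverted) db < 0L & db >= -g1 else db > 0L & db <= g1)
    f[i] <- 1L + if (any(ok)) max(f[ok]) else 0L
  }
  Fm <- max(f)
  cur <- which(f == Fm)[1]
  chain <- cur
  while (f[cur] > 1L) {
    da <- ra - ra[cur]
    db <- rb - rb[cur]
    ok <- da > 0L & da <= g1 &
      (if (inverted) db < 0L & db >= -g1 else db > 0L & db <= g1) &
      f == f[cur] - 1L
    cur <- which(ok)[1]
    chain <- c(chain, cur)
  }
  chain
}

#' Chain collinear anchors into synteny blocks
#'
#' Dynamic-programming longest-chain extraction for one chromosome pair.
#' Anchors are sorted by (rank_a, rank_b); a chain may extend from one
#' anchor to the next when `0 < delta_rank_a <= max_gap + 1` and
#' `0 < delta_rank_b <= max_gap + 1` (same orientation) or
#' `-(max_gap + 1) <= delta_rank_b < 0` (inverted). Chain score is the
#' anchor count. Maximal chains are extracted iteratively (used anchors
#' removed); among equal-sized chains the same orientation is preferred,
#' then the lexicographically smallest index sequence (which starts at
#' the earliest rank_a). Chains shorter than `min_match` are discarded.
#'
#' @param anchors data.frame for one chromosome pair with `rank_a`,
#'   `rank_b` (plus any id columns, carried through).
#' @param min_match minimum block size.
#' @param max_gap maximum rank gap.
#' @return list of blocks; each is the anchor subset (original columns)
#'   with attribute `orientation` ("same"/"inverted").
#' @export
chain_anchors <- function(anchors, min_match = 3L, max_gap = 25L) {
  blocks <- list()
  work <- anchors[order(anchors$rank_a, anchors$rank_b), , drop = FALSE]
  while (nrow(work) > 0) {
    same <- .best_chain_one(work$rank_a, work$rank_b, max_gap, FALSE)
    inv <- .best_chain_one(work$rank_a, work$rank_b, max_gap, TRUE)
    pick <- if (length(same) >= length(inv)) list(same, "same")
            else list(inv, "inverted")
    chain <- pick[[1]]
    if (length(chain) < min_match) break
    blk <- work[chain, , drop = FALSE]
    rownames(blk) <- NULL
    attr(blk, "orientation") <- pick[[2]]
    blocks[[length(blocks) + 1L]] <- blk
    work <- work[-chain, , drop = FALSE]
  }
  blocks
}

#' Detect synteny blocks across all chromosome pairs
#'
#' Groups anchors by chromosome pair and chains each group.
#'
#' @param anchors full anchor table from [anchors_from_hits()].
#' @param min_match,max_gap chaining parameters.
#' @return data.frame of block anchors with a `block_id` column
#'   (`<chromA>|<chromB>|<k>`) and an `orientation` column.
#' @export
detect_blocks <- function(anchors, min_match = 3L, max_gap = 25L) {
  out <- list()
  key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "|")
  for (kp in sort(unique(key))) {
    sub <- anchors[key == kp, , drop = FALSE]
    bl <- chain_anchors(sub, min_match, max_gap)
    for (k in seq_along(bl)) {
      b <- bl[[k]]
      b$block_id <- paste(kp, k, sep = "|")
      b$orientation <- attr(b, "orientation")
      out[[length(out) + 1L]] <- b
    }
  }
  if (!length(out)) {
    anchors$block_id <- character(0)
    anchors$orientation <- character(0)
    return(anchors[0, , drop = FALSE])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the gene-level synteny network from retained blocks
#'
#' Every anchor inside a retained block becomes an edge between its two
#' genes, annotated with the block id.
#'
#' @param block_anchors output of [detect_blocks()].
#' @param context collapsed rank table (defines the node set).
#' @return list of class `syn_network` with `nodes` (character) and
#'   `edges` (data.frame `gene_a`, `gene_b`, `chrom_a`, `chrom_b`,
#'   `block_id`).
#' @export
build_network <- function(block_anchors, context) {
  edges <- block_anchors[, c("gene_a", "gene_b", "chrom_a", "chrom_b",
                             "block_id"), drop = FALSE]
  edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(unique(context$gene_id)), edges = edges),
            class = "syn_network")
}

#' Extract the family (or family-like) subnetwork
#'
#' Keeps exactly the edges whose BOTH endpoints carry the requested class.
#'
#' @param network a `syn_network`.
#' @param assignments classification table (`gene_id`, `class`).
#' @param which class required at both ends.
#' @return a `syn_network` whose nodes are the incident genes.
#' @export
extract_family_subnetwork <- function(network, assignments,
                                      which = "family") {
  cls <- setNames(assignments$class, assignments$gene_id)
  e <- network$edges
  keep <- !is.na(cls[e$gene_a]) & !is.na(cls[e$gene_b]) &
    cls[e$gene_a] == which & cls[e$gene_b] == which
  e <- e[keep, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = sort(unique(c(e$gene_a, e$gene_b))), edges = e),
            class = "syn_network")
}

#' @export
print.syn_network <- function(x, ...) {
  cat(sprintf("<syn_network> %d nodes, %d edges in %d blocks\n",
              length(x$nodes), nrow(x$edges),
              length(unique(x$edges$block_id))))
  invisible(x)
}
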