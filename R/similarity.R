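# Protein similarity search: exact Smith-Waterman local alignment with
# affine gaps (open 11, extend 1) over BLOSUM62, with a shared-k-mer
# pre-filter so genome-scale all-vs-all searches stay tractable. The
# filter mirrors the seeding step of the usual heuristic search tools;
# scoring itself is always the exact local alignment.

.kmer_codes <- function(protein, k = 5L) {
  idx <- aa_index(protein) - 1L           # 0..20; 20 = unknown
  L <- length(idx)
  if (L < k) return(integer())
  code <- integer(L - k + 1L)
  bad <- logical(L - k + 1L)
  for (j in 0:(k - 1L)) {
    s <- idx[(1L + j):(L - k + 1L + j)]
    code <- code + s * 20L^j
    bad <- bad | s >= 20L
  }
  sort(unique(code[!bad]))
}

#' Candidate homolog pairs by shared k-mers
#'
#' Returns pairs of sequences sharing at least `min_shared` distinct
#' k-mers; k-mers present in more than `max_group` sequences are ignored.
#' Used to restrict exact alignment to plausible homologs.
#'
#' @param proteins named character vector.
#' @param k k-mer length.
#' @param min_shared minimum shared distinct k-mers.
#' @param max_group low-complexity guard.
#' @return data.frame with `id_a`, `id_b`, `shared`.
#' @export
kmer_candidates <- function(proteins, k = 5L, min_shared = 10L,
                            max_group = 200L) {
  kl <- lapply(proteins, .kmer_codes, k = k)
  pr <- .kmer_shared_pairs(kl, as.integer(max_group), as.integer(min_shared))
  data.frame(id_a = names(proteins)[pr$i], id_b = names(proteins)[pr$j],
             shared = pr$shared, stringsAsFactors = FALSE)
}

#' Smith-Waterman score of one sequence pair
#'
#' @param a,b protein strings.
#' @param gap_open,gap_ext affine gap parameters (a gap of length L costs
#'   `gap_open + L * gap_ext`).
#' @param band half-width of the alignment band (0 = full matrix).
#' @return numeric score.
#' @export
sw_score <- function(a, b, gap_open = 11, gap_ext = 1, band = 0L) {
  .sw_score(aa_index(a), aa_index(b), blosum62_matrix(), gap_open, gap_ext,
            as.integer(band))
}

#' Smith-Waterman alignment with identity statistics
#'
#' @inheritParams sw_score
#' @return list with `score`, `nid` (identical positions), `ncol` (aligned
#'   columns including gaps), `pident` (percent identity over aligned
#'   columns) and the aligned spans.
#' @export
sw_align <- function(a, b, gap_open = 11, gap_ext = 1) {
  r <- .sw_align(aa_index(a), aa_index(b), blosum62_matrix(), gap_open,
                 gap_ext)
  r$pident <- if (r$ncol > 0) 100 * r$nid / r$ncol else 0
  r
}

#' Local-alignment similarity search between protein sets
#'
#' Every query is aligned against every candidate target that shares at
#' least `min_shared` k-mers with it (all pairs when `prefilter = FALSE`);
#' hits with Smith-Waterman score >= `score_cutoff` are reported with
#' percent identity over aligned columns.
#'
#' @param queries,targets named character vectors of proteins.
#' @param score_cutoff minimum alignment score.
#' @param gap_open,gap_ext affine gap parameters over BLOSUM62.
#' @param prefilter use the shared-k-mer candidate filter.
#' @param min_shared k-mer filter threshold.
#' @return data.frame with `query`, `target`, `score`, `pident`.
#' @export
similarity_search <- function(queries, targets, score_cutoff = 50,
                              gap_open = 11, gap_ext = 1, prefilter = FALSE,
                              min_shared = 10L) {
  stopifnot(length(queries) > 0, length(targets) > 0)
  pairs <- if (prefilter) {
    pool <- c(queries, targets[setdiff(names(targets), names(queries))])
    cand <- kmer_candidates(pool, min_shared = min_shared)
    both <- rbind(cand[, 1:2],
                  setNames(cand[, 2:1], names(cand)[1:2]))
    both <- both[both$id_a %in% names(queries) &
                   both$id_b %in% names(targets), , drop = FALSE]
    unique(both)
  } else {
    expand.grid(id_a = names(queries), id_b = names(targets),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }
  if (!nrow(pairs))
    return(data.frame(query = character(), target = character(),
                      score = numeric(), pident = numeric()))
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- sw_align(queries[[pairs$id_a[i]]], targets[[pairs$id_b[i]]],
                  gap_open, gap_ext)
    c(score = r$score, pident = r$pident)
  })
  res <- do.call(rbind, res)
  out <- data.frame(query = pairs$id_a, target = pairs$id_b,
                    score = res[, "score"], pident = res[, "pident"],
                    stringsAsFactors = FALSE)
  out <- out[out$score >= score_cutoff, , drop = FALSE]
  out[order(out$query, -out$score, out$target), , drop = FALSE]
}

# self-alignment score: sum of diagonal substitution values
.self_score <- function(protein) {
  idx <- aa_index(protein)
  sum(diag(blosum62_matrix())[idx])
}
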