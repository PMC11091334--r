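# Multiple sequence alignment: deterministic progressive alignment with a
# UPGMA guide tree on 3-mer cosine distances and profile-profile global
# alignment (affine gaps, BLOSUM62), plus alignment-column trimming.

.kmer3_counts <- function(protein) {
  idx <- aa_index(protein) - 1L
  L <- length(idx)
  if (L < 3L) return(integer())
  code <- idx[1:(L - 2L)] + 20L * idx[2:(L - 1L)] + 400L * idx[3:L]
  ok <- idx[1:(L - 2L)] < 20L & idx[2:(L - 1L)] < 20L & idx[3:L] < 20L
  table(code[ok])
}

.cosine_dist <- function(ca, cb) {
  if (!length(ca) || !length(cb)) return(1)
  shared <- intersect(names(ca), names(cb))
  dot <- sum(as.numeric(ca[shared]) * as.numeric(cb[shared]))
  1 - dot / sqrt(sum(as.numeric(ca)^2) * sum(as.numeric(cb)^2))
}

.profile_freq <- function(mat) {
  # columns x 20 residue frequencies; gaps carry zero weight so gap-rich
  # columns score weakly against everything
  n <- nrow(mat)
  f <- matrix(0, ncol(mat), 20)
  for (a in seq_along(AA20))
    f[, a] <- colSums(mat == AA20[a]) / n
  f
}

.align_profiles <- function(ma, mb, gap_open, gap_ext) {
  fa <- .profile_freq(ma)
  fb <- .profile_freq(mb)
  B <- blosum62_matrix()[1:20, 1:20]
  S <- fa %*% B %*% t(fb)
  r <- .nw_profile(S, gap_open, gap_ext)
  ncols <- length(r$ai)
  out <- matrix("-", nrow(ma) + nrow(mb), ncols)
  out[seq_len(nrow(ma)), r$ai != 0] <- ma[, r$ai[r$ai != 0], drop = FALSE]
  out[nrow(ma) + seq_len(nrow(mb)), r$bi != 0] <-
    mb[, r$bi[r$bi != 0], drop = FALSE]
  rownames(out) <- c(rownames(ma), rownames(mb))
  out
}

#' Progressive multiple alignment of proteins
#'
#' Guide tree: UPGMA (average-linkage `hclust`) on pairwise 3-mer cosine
#' distances. Merges use profile-profile global alignment with affine gaps
#' (open 10, extend 0.5) over BLOSUM62; profile column scores are the
#' frequency-weighted average substitution score, with gaps carrying zero
#' weight. Fully deterministic.
#'
#' @param proteins named character vector (>= 1 sequence).
#' @param gap_open,gap_ext affine gap parameters.
#' @return named character vector of aligned rows (an `Msa`), in the input
#'   order; un-gapping any row recovers its input sequence.
#' @export
progressive_align <- function(proteins, gap_open = 10, gap_ext = 0.5) {
  n <- length(proteins)
  if (n == 0) stop("no sequences")
  if (n == 1) return(proteins)
  if (n == 2) {
    mats <- lapply(proteins, function(s)
      matrix(strsplit(s, "", fixed = TRUE)[[1]], nrow = 1))
    rownames(mats[[1]]) <- names(proteins)[1]
    rownames(mats[[2]]) <- names(proteins)[2]
    m <- .align_profiles(mats[[1]], mats[[2]], gap_open, gap_ext)
    return(apply(m, 1, paste, collapse = "")[names(proteins)])
  }
  counts <- lapply(proteins, .kmer3_counts)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- .cosine_dist(counts[[i]], counts[[j]])
  hc <- hclust(as.dist(D), method = "average")
  mats <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(proteins[[i]], "", fixed = TRUE)[[1]], nrow = 1)
    rownames(m) <- names(proteins)[i]
    m
  })
  merged <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) mats[[-x]] else merged[[x]]
    merged[[k]] <- .align_profiles(pick(hc$merge[k, 1]),
                                   pick(hc$merge[k, 2]), gap_open, gap_ext)
  }
  m <- merged[[length(merged)]]
  apply(m, 1, paste, collapse = "")[names(proteins)]
}

#' Trim alignment columns by coverage and conservation
#'
#' A column's coverage is its fraction of non-gap residues; its similarity
#' is the frequency of the modal non-gap residue among non-gap residues
#' (1.0 when the column holds at most one residue). Columns with coverage
#' >= `gt` and similarity >= `st` are kept. If fewer than `cons`% of the
#' original columns survive, dropped columns are added back - highest
#' coverage first, ties broken by higher similarity then left-most
#' position - until exactly `ceiling(cons/100 * width)` columns remain.
#' Column order is always preserved.
#'
#' @param msa named character vector of equal-length aligned rows.
#' @param gt coverage threshold in `[0, 1]`.
#' @param st similarity threshold in `[0, 1]`.
#' @param cons minimum percentage of columns retained.
#' @return trimmed `Msa`; `attr(, "kept_columns")` holds the retained
#'   original column indices.
#' @export
trim_alignment <- function(msa, gt = 0.8, st = 0.001, cons = 60) {
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  w <- ncol(mat)
  if (w == 0) return(msa)
  cover <- colMeans(mat != "-")
  simil <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) <= 1) 1 else max(table(col)) / length(col)
  })
  keep <- cover >= gt & simil >= st
  target <- ceiling(cons / 100 * w)
  if (sum(keep) < target) {
    dropped <- which(!keep)
    ord <- dropped[order(-cover[dropped], -simil[dropped], dropped)]
    keep[ord[seq_len(target - sum(keep))]] <- TRUE
  }
  idx <- which(keep)
  out <- apply(mat[, idx, drop = FALSE], 1, paste, collapse = "")
  out <- setNames(out, names(msa))
  attr(out, "kept_columns") <- idx
  out
}
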