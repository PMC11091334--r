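# Position-specific scoring matrices for the two diagnostic domains, and
# the ungapped sliding-window scan that locates them in proteins.

#' Build a position-specific scoring matrix from a seed alignment
#'
#' Columns with >= 50% gaps are dropped, then per-column residue
#' probabilities are `(count + pseudocount) / (n_nongap + 20 * pseudocount)`
#' and scores are log-odds against a uniform background of 1/20, in bits.
#' An unknown residue scores `log2(0.05 / 0.05) = 0` bits minus a 0.5-bit
#' penalty, so runs of `X` cannot accumulate into a hit. The default hit
#' cutoff is `cutoff_frac` times the consensus self-score (the sum of the
#' per-column maxima).
#'
#' @param seed_msa named character vector of aligned sequences (gap `-`),
#'   at least 3 rows.
#' @param domain_name label, conventionally "N" or "C".
#' @param pseudocount added per residue per column.
#' @param cutoff_frac fraction of the consensus self-score used as
#'   `bit_cutoff`.
#' @return object of class `fam_pssm` with elements `domain_name`, `width`,
#'   `scores` (width x 21 matrix, column 21 = unknown), `probs`,
#'   `background`, `max_score`, `bit_cutoff`.
#' @export
build_pssm <- function(seed_msa, domain_name = "N", pseudocount = 0.5,
                       cutoff_frac = 0.6) {
  if (length(seed_msa) == 0) stop("empty seed alignment")
  if (length(seed_msa) < 3) stop("seed alignment needs >= 3 sequences")
  rows <- strsplit(seed_msa, "", fixed = TRUE)
  if (length(unique(lengths(rows))) != 1)
    stop("seed alignment rows differ in length")
  m <- do.call(rbind, rows)
  gap_frac <- colMeans(m == "-")
  m <- m[, gap_frac < 0.5, drop = FALSE]
  w <- ncol(m)
  if (w < 5) stop("alignment has fewer than 5 usable columns")
  probs <- matrix(0, nrow = w, ncol = 20, dimnames = list(NULL, AA20))
  for (j in seq_len(w)) {
    col <- m[, j]
    col <- col[col != "-"]
    cnt <- table(factor(col, levels = AA20))
    probs[j, ] <- (as.numeric(cnt) + pseudocount) /
      (length(col) + 20 * pseudocount)
  }
  scores <- log2(probs / 0.05)
  scores <- cbind(scores, X = rep(-0.5, w))
  max_score <- sum(apply(scores[, 1:20, drop = FALSE], 1, max))
  structure(list(domain_name = domain_name, width = w, scores = scores,
                 probs = probs, background = rep(0.05, 20),
                 max_score = max_score,
                 bit_cutoff = cutoff_frac * max_score),
            class = "fam_pssm")
}

#' @export
print.fam_pssm <- function(x, ...) {
  cat(sprintf("<fam_pssm> domain %s: width %d, consensus self-score %.1f bits, cutoff %.1f\n",
              x$domain_name, x$width, x$max_score, x$bit_cutoff))
  invisible(x)
}

#' Scan a protein for ungapped PSSM hits
#'
#' Slides the matrix over every window, keeps windows scoring at least
#' `bit_cutoff`, and reports non-overlapping hits greedily by descending
#' score (ties: smallest start). Coordinates are 0-based half-open.
#'
#' @param protein a protein string (or named character vector; each scanned
#'   independently via [scan_domains_all()]).
#' @param pssm a `fam_pssm`.
#' @param bit_cutoff override for the stored cutoff.
#' @return data.frame with `domain_name`, `start`, `end`, `bitscore`.
#' @export
scan_domains <- function(protein, pssm, bit_cutoff = pssm$bit_cutoff) {
  idx <- aa_index(protein)
  sc <- .pssm_scores(idx, pssm$scores)
  empty <- data.frame(domain_name = character(), start = integer(),
                      end = integer(), bitscore = numeric())
  if (!length(sc)) return(empty)
  cand <- which(sc >= bit_cutoff)
  if (!length(cand)) return(empty)
  ord <- cand[order(-sc[cand], cand)]
  taken <- rep(FALSE, length(idx))
  keep <- integer()
  for (o in ord) {
    span <- o:(o + pssm$width - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      keep <- c(keep, o)
    }
  }
  keep <- sort(keep)
  data.frame(domain_name = pssm$domain_name, start = keep - 1L,
             end = keep - 1L + pssm$width, bitscore = sc[keep])
}

#' Scan every protein of a set against both domain PSSMs
#'
#' @param proteins named character vector of proteins.
#' @param pssms list of `fam_pssm` objects (typically `list(N = , C = )`).
#' @return data.frame of hits with a `gene_id` column.
#' @export
scan_domains_all <- function(proteins, pssms) {
  out <- list()
  for (gid in names(proteins)) {
    for (p in pssms) {
      h <- scan_domains(proteins[[gid]], p)
      if (nrow(h)) {
        h$gene_id <- gid
        out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out))
    return(data.frame(domain_name = character(), start = integer(),
                      end = integer(), bitscore = numeric(),
                      gene_id = character()))
  do.call(rbind, out)
}
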