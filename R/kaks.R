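# Selection-pressure estimation: reciprocal within-genome homolog pairing,
# back-translated codon alignment, and Nei-Gojobori (1986) Ka/Ks with
# Jukes-Cantor multiple-hit correction.

#' Reciprocal within-genome homolog pairs
#'
#' A pair of family genes is kept iff each is among the other's similarity
#' hits and their global alignment identity (identical positions over all
#' alignment columns) exceeds `identity_threshold`. Each unordered pair is
#' reported once.
#'
#' @param genome a `fam_genome`.
#' @param assignments classification table with `gene_id` and `class`.
#' @param identity_threshold percent identity cutoff (exclusive).
#' @param score_cutoff minimum local-alignment score for a hit.
#' @param class which class to pair ("family" by default).
#' @return data.frame with `gene_a`, `gene_b`, `identity` (Ka/Ks columns
#'   unset); zero rows when fewer than 2 such genes exist.
#' @export
find_homolog_pairs <- function(genome, assignments, identity_threshold = 50,
                               score_cutoff = 50, class = "family") {
  ids <- assignments$gene_id[assignments$class == class &
                               assignments$gene_id %in% names(genome$protein)]
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      identity = numeric())
  if (length(ids) < 2) return(empty)
  prot <- genome$protein[ids]
  rows <- list()
  for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
    loc <- sw_align(prot[[i]], prot[[j]])
    if (loc$score < score_cutoff) next   # not reciprocal hits
    ga <- global_identity(prot[[i]], prot[[j]])
    if (ga > identity_threshold)
      rows[[length(rows) + 1L]] <- data.frame(gene_a = ids[i],
                                              gene_b = ids[j],
                                              identity = ga)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Global alignment percent identity of two proteins
#'
#' Needleman-Wunsch (affine gaps over BLOSUM62, via the profile aligner on
#' single sequences); identity is identical positions over all alignment
#' columns, gap columns included.
#'
#' @param a,b protein strings.
#' @return percent identity.
#' @export
global_identity <- function(a, b) {
  al <- align_pair_global(a, b)
  va <- strsplit(al[[1]], "", fixed = TRUE)[[1]]
  vb <- strsplit(al[[2]], "", fixed = TRUE)[[1]]
  100 * sum(va == vb & va != "-") / length(va)
}

#' Global pairwise protein alignment
#'
#' @param a,b protein strings.
#' @param gap_open,gap_ext affine gap parameters.
#' @return character vector of the two aligned rows.
#' @export
align_pair_global <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  al <- progressive_align(c(a = a, b = b), gap_open, gap_ext)
  unname(al)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each protein column expands to one codon column; protein gaps become
#' `---`. Each CDS must be exactly 3x its ungapped protein (terminal stop
#' removed beforehand) and must translate to it, otherwise the offending
#' position is reported.
#'
#' @param cds_a,cds_b CDS strings (no terminal stop).
#' @param protein_alignment character vector of the two aligned protein
#'   rows.
#' @return character vector of the two aligned codon rows.
#' @export
codon_align <- function(cds_a, cds_b, protein_alignment) {
  expand_one <- function(cds, aln_row, which) {
    aa <- strsplit(aln_row, "", fixed = TRUE)[[1]]
    ungapped <- aa[aa != "-"]
    if (nchar(cds) != 3L * length(ungapped))
      stop("sequence ", which, ": CDS length ", nchar(cds),
           " does not match 3 x ", length(ungapped), " aligned residues")
    trans <- translate_cds(cds)
    tv <- strsplit(trans, "", fixed = TRUE)[[1]]
    mism <- which(tv != ungapped)
    if (length(mism))
      stop("sequence ", which, ": CDS translation differs from protein at ",
           "position ", mism[1])
    codons <- substring(cds, 3L * seq_along(tv) - 2L, 3L * seq_along(tv))
    out <- character(length(aa))
    out[aa == "-"] <- "---"
    out[aa != "-"] <- codons
    paste(out, collapse = "")
  }
  c(expand_one(cds_a, protein_alignment[1], "a"),
    expand_one(cds_b, protein_alignment[2], "b"))
}

# per-codon synonymous/nonsynonymous site counts; changes to stop codons
# are excluded from the per-position denominator
.ng86_sites <- function(codon, ct) {
  v <- strsplit(codon, "", fixed = TRUE)[[1]]
  aa <- ct[[codon]]
  s <- 0
  for (pos in 1:3) {
    alts <- setdiff(DNA4, v[pos])
    syn <- 0L; ok <- 0L
    for (b in alts) {
      w <- v; w[pos] <- b
      alt_aa <- ct[[paste(w, collapse = "")]]
      if (alt_aa == "*") next
      ok <- ok + 1L
      if (alt_aa == aa) syn <- syn + 1L
    }
    if (ok > 0) s <- s + syn / ok
  }
  c(S = s, N = 3 - s)
}

# observed synonymous/nonsynonymous differences between two codons,
# averaged over all minimal mutation pathways; pathways passing through a
# stop codon are excluded (unless every pathway does)
.ng86_diffs <- function(ca, cb, ct) {
  va <- strsplit(ca, "", fixed = TRUE)[[1]]
  vb <- strsplit(cb, "", fixed = TRUE)[[1]]
  pos <- which(va != vb)
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  perms <- if (length(pos) == 1) list(pos)
           else if (length(pos) == 2) list(pos, rev(pos))
           else {
             p <- pos
             out <- list()
             for (x in seq_along(p)) for (y in seq_along(p)) for (z in seq_along(p))
               if (length(unique(c(x, y, z))) == 3)
                 out[[length(out) + 1L]] <- p[c(x, y, z)]
             out
           }
  walk <- function(order) {
    cur <- va
    sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- vb[p]
      a1 <- ct[[paste(cur, collapse = "")]]
      a2 <- ct[[paste(nxt, collapse = "")]]
      if (a2 == "*" && !identical(nxt, vb)) return(NULL)  # via a stop
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(res)) res <- Filter(Negate(is.null), lapply(perms, function(o) {
    cur <- va; sd <- 0; nd <- 0
    for (p in o) {
      nxt <- cur; nxt[p] <- vb[p]
      if (ct[[paste(cur, collapse = "")]] == ct[[paste(nxt, collapse = "")]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }))
  m <- do.call(rbind, res)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

#' Nei-Gojobori (1986) Ka/Ks from an aligned codon pair
#'
#' Synonymous site fractions are counted per codon by enumerating the nine
#' single-base changes (standard genetic code; changes to stop codons are
#' excluded from the denominator) and averaged over both sequences.
#' Multi-difference codons average their synonymous/nonsynonymous
#' difference counts over all minimal mutation pathways, excluding
#' pathways through stop codons. Proportions are corrected with
#' Jukes-Cantor `d = -(3/4) ln(1 - 4p/3)`. Codon columns containing gaps,
#' stops or ambiguous bases are skipped.
#'
#' @param aligned_codons character vector of the two aligned codon rows
#'   (from [codon_align()]).
#' @return list with `Ka`, `Ks`, `ratio` (NA when Ks == 0), `S`, `N`,
#'   `Sd`, `Nd` and a `saturated` flag (`p >= 3/4` leaves the corrected
#'   value `NaN`).
#' @export
ng86 <- function(aligned_codons) {
  ct <- codon_table()
  n_col <- nchar(aligned_codons[1]) %/% 3L
  starts <- 3L * seq_len(n_col) - 2L
  ca <- substring(aligned_codons[1], starts, starts + 2L)
  cb <- substring(aligned_codons[2], starts, starts + 2L)
  usable <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    ca %in% names(ct) & cb %in% names(ct) &
    ct[ca] != "*" & ct[cb] != "*"
  ca <- ca[usable]; cb <- cb[usable]
  if (!length(ca)) stop("no comparable codon pairs")
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(ca)) {
    sa <- .ng86_sites(ca[k], ct)
    sb <- .ng86_sites(cb[k], ct)
    S <- S + (sa["S"] + sb["S"]) / 2
    N <- N + (sa["N"] + sb["N"]) / 2
    d <- .ng86_diffs(ca[k], cb[k], ct)
    Sd <- Sd + d["Sd"]; Nd <- Nd + d["Nd"]
  }
  jc <- function(p) {
    # p is NaN when a sequence offers no sites of that type (e.g. S = 0)
    if (!is.finite(p) || p >= 0.75) return(NaN)
    -0.75 * log(1 - 4 * p / 3)
  }
  ps <- Sd / S; pn <- Nd / N
  Ks <- jc(ps); Ka <- jc(pn)
  saturated <- is.nan(Ks) || is.nan(Ka)
  ratio <- if (saturated) NaN else if (Ks == 0) NA_real_ else Ka / Ks
  list(Ka = unname(Ka), Ks = unname(Ks), ratio = unname(ratio),
       S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       saturated = saturated)
}

#' Ka/Ks for all reciprocal family pairs of a genome
#'
#' Convenience wrapper: [find_homolog_pairs()], global protein alignment,
#' [codon_align()] (terminal stops stripped), [ng86()].
#'
#' @inheritParams find_homolog_pairs
#' @return data.frame of `HomologPair`s: `gene_a`, `gene_b`, `identity`,
#'   `Ka`, `Ks`, `ratio`, `saturated`.
#' @export
kaks_pairs <- function(genome, assignments, identity_threshold = 50,
                       score_cutoff = 50, class = "family") {
  pairs <- find_homolog_pairs(genome, assignments, identity_threshold,
                              score_cutoff, class)
  if (!nrow(pairs)) {
    pairs$Ka <- numeric(); pairs$Ks <- numeric(); pairs$ratio <- numeric()
    pairs$saturated <- logical()
    return(pairs)
  }
  strip_stop <- function(cds) {
    last <- substr(cds, nchar(cds) - 2L, nchar(cds))
    if (codon_table()[[last]] == "*") substr(cds, 1L, nchar(cds) - 3L)
    else cds
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    pal <- align_pair_global(genome$protein[[a]], genome$protein[[b]])
    cal <- codon_align(strip_stop(genome$cds[[a]]),
                       strip_stop(genome$cds[[b]]), pal)
    ng86(cal)
  })
  pairs$Ka <- vapply(res, `[[`, numeric(1), "Ka")
  pairs$Ks <- vapply(res, `[[`, numeric(1), "Ks")
  pairs$ratio <- vapply(res, `[[`, numeric(1), "ratio")
  pairs$saturated <- vapply(res, `[[`, logical(1), "saturated")
  pairs
}
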