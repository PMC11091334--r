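# Distance phylogeny: Kimura-corrected protein distances, Saitou-Nei
# neighbor joining with explicit tie-breaking, column-bootstrap supports,
# outgroup rooting and seed-based group extraction.

#' Kimura-corrected protein distance matrix
#'
#' For each sequence pair, `p` is the proportion of differing positions
#' over columns where both rows are non-gap, corrected as
#' `d = -ln(1 - p - p^2/5)`. When the correction is undefined
#' (`1 - p - p^2/5 <= 0`), `saturation = "cap"` substitutes `cap_value`
#' and `"na"` leaves `NaN` (which [nj_tree()] rejects by name).
#'
#' @param msa named character vector of aligned rows.
#' @param saturation how to handle saturated pairs.
#' @param cap_value distance substituted when capping.
#' @return symmetric distance matrix with zero diagonal.
#' @export
protein_distance <- function(msa, saturation = c("cap", "na"),
                             cap_value = 5) {
  saturation <- match.arg(saturation)
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- mat[i, ] != "-" & mat[j, ] != "-"
    p <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0
    arg <- 1 - p - p^2 / 5
    d <- if (arg > 0) -log(arg)
         else if (saturation == "cap") cap_value else NaN
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Classic NJ with two determinism rules: ties in the Q criterion are
#' broken by the smallest (i, j) index pair, and a negative branch length
#' is clamped to zero with the deficit moved to its sister branch. Exact
#' on additive distance matrices. The result is unrooted (trifurcating
#' root node).
#'
#' @param D symmetric numeric matrix with zero diagonal, labelled rows.
#' @return an unrooted `ape::phylo`.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  bad <- which(!is.finite(D) | is.nan(D), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite distance between '", labels[bad[1, 1]], "' and '",
         labels[bad[1, 2]], "'")
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")

  ids <- seq_len(n)                   # active node ids; tips are 1..n
  next_id <- n + 1L
  edges <- list()
  add_edge <- function(p, c, l) edges[[length(edges) + 1L]] <<- c(p, c, l)
  Dm <- D
  while (length(ids) > 3L) {
    m <- length(ids)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    hit <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    u <- next_id; next_id <- next_id + 1L
    add_edge(u, ids[i], li)
    add_edge(u, ids[j], lj)
    duk <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], duk[keep]),
                c(duk[keep], 0))
    ids <- c(ids[keep], u)
  }
  # resolve the final three by the three-point formulas
  a <- Dm[1, 2]; b <- Dm[1, 3]; cc <- Dm[2, 3]
  l1 <- (a + b - cc) / 2; l2 <- (a + cc - b) / 2; l3 <- (b + cc - a) / 2
  root <- next_id
  add_edge(root, ids[1], max(l1, 0))
  add_edge(root, ids[2], max(l2, 0))
  add_edge(root, ids[3], max(l3, 0))

  em <- do.call(rbind, edges)
  # renumber internal nodes: root first, then breadth-first
  internal <- unique(em[, 1])
  ord <- root
  queue <- root
  while (length(queue)) {
    node <- queue[1]; queue <- queue[-1]
    kids <- em[em[, 1] == node, 2]
    ik <- kids[kids > n]
    ord <- c(ord, ik)
    queue <- c(queue, ik)
  }
  remap <- setNames(n + seq_along(ord), ord)
  e1 <- remap[as.character(em[, 1])]
  e2 <- ifelse(em[, 2] > n, remap[as.character(em[, 2])], em[, 2])
  phy <- list(edge = cbind(as.integer(e1), as.integer(e2)),
              edge.length = em[, 3], tip.label = labels,
              Nnode = length(ord))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}

# canonical bipartition keys of a tree's internal edges (excluding the
# root edge of the basal trifurcation); sides are canonicalized so the key
# never contains the reference tip (the alphabetically smallest label)
.bipart_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  ref <- sort(labs)[1]
  all_tips <- labs
  keys <- vapply(pp, function(tips) {
    side <- labs[tips]
    if (ref %in% side) side <- setdiff(all_tips, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  # drop trivial partitions (whole set or single tips)
  sizes <- vapply(strsplit(keys, "|", fixed = TRUE), length, integer(1))
  keys[sizes >= 2 & sizes <= length(labs) - 2]
}

#' Column-bootstrap supports for a neighbor-joining tree
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times, rebuilds the tree, and scores
#' each internal bipartition of the main tree by the percentage of
#' replicate trees containing it. Deterministic given `seed`.
#'
#' @param msa named character vector of aligned rows (>= 4 sequences).
#' @param n_reps bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @return the main tree with integer supports (0-100) in `node.label`
#'   (empty label on the basal node).
#' @export
bootstrap_supports <- function(msa, n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1)
  mat <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  rownames(mat) <- names(msa)
  main <- nj_tree(protein_distance(msa))
  keys <- .bipart_keys(main)
  counts <- setNames(rep(0L, length(keys)), keys)
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    rep_msa <- setNames(apply(mat[, cols, drop = FALSE], 1, paste,
                              collapse = ""), rownames(mat))
    rk <- .bipart_keys(nj_tree(protein_distance(rep_msa)))
    hit <- keys %in% rk
    counts[hit] <- counts[hit] + 1L
  }
  support <- round(100 * counts / n_reps)
  # attach supports to the internal node defining each bipartition
  pp <- ape::prop.part(main)
  labs <- attr(pp, "labels")
  ref <- sort(labs)[1]
  node_keys <- vapply(pp, function(tips) {
    side <- labs[tips]
    if (ref %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  main$node.label <- ifelse(node_keys %in% names(support),
                            as.character(support[node_keys]), "")
  main
}

#' Root a tree on the outgroup's pendant edge
#'
#' Places the root at the midpoint of the edge leading to the outgroup
#' leaf. Re-rooting an already-rooted tree at the same outgroup is a
#' no-op.
#'
#' @param tree an `ape::phylo`.
#' @param outgroup_gene_id leaf label to root at.
#' @return rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup_gene_id) {
  if (!outgroup_gene_id %in% tree$tip.label)
    stop("outgroup '", outgroup_gene_id, "' is not a leaf of the tree")
  tip <- which(tree$tip.label == outgroup_gene_id)
  if (ape::is.rooted(tree)) {
    root <- length(tree$tip.label) + 1L
    kids <- tree$edge[tree$edge[, 1] == root, 2]
    if (tip %in% kids && length(kids) == 2) return(tree)
    tree <- ape::unroot(tree)
  }
  rooted <- ape::root(tree, outgroup = outgroup_gene_id,
                      resolve.root = TRUE)
  root <- length(rooted$tip.label) + 1L
  re <- which(rooted$edge[, 1] == root)
  # after resolve.root the root has two children: the outgroup pendant
  # edge and a zero-length edge to the ingroup; split the total evenly
  total <- sum(rooted$edge.length[re])
  rooted$edge.length[re] <- total / 2
  rooted
}

#' Assign leaves to groups by seed-defined clades
#'
#' Each group is the smallest clade of the rooted tree containing all of
#' its seed leaves. Resulting clades must be non-overlapping; leaves in no
#' group are "unassigned".
#'
#' @param tree rooted `ape::phylo`.
#' @param seed_sets named list of character vectors of leaf labels.
#' @return data.frame with `gene_id`, `group`.
#' @export
assign_groups <- function(tree, seed_sets) {
  stopifnot(ape::is.rooted(tree))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  members <- list()
  for (gname in names(seed_sets)) {
    seeds <- seed_sets[[gname]]
    missing <- setdiff(seeds, tree$tip.label)
    if (length(missing))
      stop("seed gene(s) missing from tree: ", paste(missing, collapse = ", "))
    node <- if (length(seeds) == 1) which(tree$tip.label == seeds)
            else ape::getMRCA(tree, seeds)
    if (node == root)
      stop("seed set '", gname, "' spans the root (seeds: ",
           paste(seeds, collapse = ", "), "); no proper clade contains it")
    tips <- if (node <= ntip) tree$tip.label[node]
            else ape::extract.clade(tree, node)$tip.label
    members[[gname]] <- tips
  }
  for (a in seq_along(members)) for (b in seq_len(a - 1L)) {
    ov <- intersect(members[[a]], members[[b]])
    if (length(ov))
      stop("groups '", names(members)[a], "' and '", names(members)[b],
           "' overlap via seeds; offending leaves: ",
           paste(head(ov, 5), collapse = ", "))
  }
  grp <- setNames(rep("unassigned", ntip), tree$tip.label)
  for (gname in names(members)) grp[members[[gname]]] <- gname
  data.frame(gene_id = tree$tip.label, group = unname(grp[tree$tip.label]),
             stringsAsFactors = FALSE)
}
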