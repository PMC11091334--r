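# Two-level map-equation community detection for undirected networks:
# the description length L(M) = q H(Q) + sum_i p_i H(P_i) of a random
# walk under a two-level module partition, minimized by seeded greedy
# node moving with module aggregation (merge passes), repeated until no
# move improves L.

.plogp <- function(x) ifelse(x > 0, x * log2(x), 0)

#' Two-level map-equation description length
#'
#' Node visit rates are degree-proportional (`p = deg / 2m`); module exit
#' rates are cut-edge fractions. Lower is better; the one-module
#' partition scores the entropy of the visit rates.
#'
#' @param edges two-column integer matrix of node indices (undirected,
#'   no duplicates).
#' @param membership integer module id per node.
#' @param n_nodes number of nodes.
#' @return description length in bits.
#' @export
map_equation_L <- function(edges, membership, n_nodes) {
  m <- nrow(edges)
  if (m == 0) return(0)
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_nodes)
  p <- deg / (2 * m)
  mods <- sort(unique(membership))
  memb <- match(membership, mods)
  cut <- tabulate(c(memb[edges[, 1]][memb[edges[, 1]] != memb[edges[, 2]]],
                    memb[edges[, 2]][memb[edges[, 1]] != memb[edges[, 2]]]),
                  nbins = length(mods))
  q <- cut / (2 * m)
  psum <- as.numeric(tapply(p, memb, sum))
  sum(.plogp(sum(q))) - 2 * sum(.plogp(q)) + sum(.plogp(q + psum)) -
    sum(.plogp(p))
}

.sweep_once <- function(edges, memb, n, adj, L_fun, order_v) {
  improved <- FALSE
  for (v in order_v) {
    nb <- adj[[v]]
    if (!length(nb)) next
    cand <- unique(c(memb[nb], max(memb) + 1L))
    cand <- setdiff(cand, memb[v])
    if (!length(cand)) next
    cur_L <- L_fun(memb)
    best_L <- cur_L; best_m <- memb[v]
    for (cm in cand) {
      trial <- memb
      trial[v] <- cm
      tl <- L_fun(trial)
      if (tl < best_L - 1e-12) { best_L <- tl; best_m <- cm }
    }
    if (best_m != memb[v]) { memb[v] <- best_m; improved <- TRUE }
  }
  list(memb = memb, improved = improved)
}

.merge_once <- function(edges, memb, L_fun) {
  improved <- FALSE
  repeat {
    mods <- unique(memb)
    linked <- unique(t(apply(cbind(memb[edges[, 1]], memb[edges[, 2]]), 1,
                             sort)))
    linked <- linked[linked[, 1] != linked[, 2], , drop = FALSE]
    if (!nrow(linked)) break
    cur_L <- L_fun(memb)
    best <- NULL; best_L <- cur_L
    for (r in seq_len(nrow(linked))) {
      trial <- memb
      trial[trial == linked[r, 2]] <- linked[r, 1]
      tl <- L_fun(trial)
      if (tl < best_L - 1e-12) { best_L <- tl; best <- linked[r, ] }
    }
    if (is.null(best)) break
    memb[memb == best[2]] <- best[1]
    improved <- TRUE
  }
  list(memb = memb, improved = improved)
}

#' Detect synteny communities by map-equation minimization
#'
#' Greedy two-level map-equation optimizer: nodes start as singletons;
#' sweeps move nodes to neighboring modules while L decreases, alternating
#' with module-merge passes, until no move improves L. Several seeded
#' sweep orders are tried (the first is ascending node id) and the best
#' partition kept, so the result is deterministic given `seed`. Clusters
#' smaller than `min_size` are reported but flagged as not retained.
#'
#' @param subnetwork a `syn_network` (possibly disconnected).
#' @param seed RNG seed for the extra sweep orders.
#' @param min_size minimum retained cluster size.
#' @param n_restarts seeded restarts beyond the ascending-order run.
#' @return data.frame with `gene_id`, `cluster` (1..K, numbered by each
#'   cluster's smallest member), `retained`; `attr(,"L")` holds the
#'   achieved description length.
#' @export
detect_communities <- function(subnetwork, seed = 1L, min_size = 3L,
                               n_restarts = 8L) {
  nodes <- subnetwork$nodes
  n <- length(nodes)
  if (n == 0)
    return(structure(data.frame(gene_id = character(), cluster = integer(),
                                retained = logical()), L = 0))
  e <- subnetwork$edges
  ei <- cbind(match(e$gene_a, nodes), match(e$gene_b, nodes))
  ei <- ei[ei[, 1] != ei[, 2], , drop = FALSE]
  ei <- unique(t(apply(ei, 1, sort)))
  if (is.null(dim(ei))) ei <- matrix(ei, ncol = 2)
  adj <- lapply(seq_len(n), function(v)
    c(ei[ei[, 1] == v, 2], ei[ei[, 2] == v, 1]))
  L_fun <- function(memb) map_equation_L(ei, memb, n)
  run_from <- function(order_v) {
    memb <- seq_len(n)
    repeat {
      any_change <- FALSE
      repeat {
        s <- .sweep_once(ei, memb, n, adj, L_fun, order_v)
        memb <- s$memb
        if (!s$improved) break
        any_change <- TRUE
      }
      mg <- .merge_once(ei, memb, L_fun)
      memb <- mg$memb
      if (mg$improved) any_change <- TRUE
      if (!any_change) break
    }
    memb
  }
  set.seed(seed)
  orders <- c(list(seq_len(n)),
              lapply(seq_len(n_restarts), function(i) sample.int(n)))
  best <- NULL; best_L <- Inf
  for (ov in orders) {
    memb <- run_from(ov)
    L <- L_fun(memb)
    if (L < best_L - 1e-12) { best_L <- L; best <- memb }
  }
  # canonical labels: clusters numbered by their smallest member index
  first <- tapply(seq_len(n), best, min)
  relabel <- match(best, as.integer(names(sort(first))))
  sizes <- tabulate(relabel)
  structure(data.frame(gene_id = nodes, cluster = relabel,
                       retained = sizes[relabel] >= min_size,
                       stringsAsFactors = FALSE),
            L = best_L)
}
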