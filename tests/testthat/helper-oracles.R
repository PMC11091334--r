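# Independent reference implementations used to cross-check the package's
# algorithms on small inputs. Deliberately written in a different style
# (direct enumeration / textbook formulas) from the implementations they
# check.

# ---- Nei-Gojobori oracle ----------------------------------------------

.oracle_gc <- as.character(Biostrings::GENETIC_CODE)
names(.oracle_gc) <- names(Biostrings::GENETIC_CODE)

# synonymous site count of one codon, stop mutations excluded from the
# per-position denominator
oracle_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  v <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    cands <- vapply(setdiff(bases, v[pos]), function(b) {
      w <- v; w[pos] <- b
      .oracle_gc[[paste(w, collapse = "")]]
    }, character(1))
    cands <- cands[cands != "*"]
    if (length(cands))
      s <- s + sum(cands == .oracle_gc[[codon]]) / length(cands)
  }
  s
}

# all orderings of a vector (n <= 3 here)
.perm_all <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .perm_all(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

oracle_diffs <- function(ca, cb, allow_stop = FALSE) {
  va <- strsplit(ca, "")[[1]]
  vb <- strsplit(cb, "")[[1]]
  pos <- which(va != vb)
  if (!length(pos)) return(c(0, 0))
  paths <- list()
  for (ord in .perm_all(pos)) {
    cur <- va; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- vb[p]
      now <- paste(cur, collapse = "")
      if (!allow_stop && .oracle_gc[[now]] == "*" && now != cb) {
        blocked <- TRUE
        break
      }
      if (.oracle_gc[[prev]] == .oracle_gc[[now]]) sd <- sd + 1
      else nd <- nd + 1
    }
    if (!blocked) paths[[length(paths) + 1L]] <- c(sd, nd)
  }
  if (!length(paths)) return(oracle_diffs(ca, cb, allow_stop = TRUE))
  colMeans(do.call(rbind, paths))
}

oracle_ng86 <- function(codons_a, codons_b) {
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (k in seq_along(codons_a)) {
    sk <- (oracle_sites(codons_a[k]) + oracle_sites(codons_b[k])) / 2
    S <- S + sk
    N <- N + 3 - sk
    d <- oracle_diffs(codons_a[k], codons_b[k])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  jc <- function(p) if (!is.finite(p) || p >= 0.75) NaN
        else -0.75 * log(1 - 4 * p / 3)
  list(Ka = jc(Nd / N), Ks = jc(Sd / S), S = S, N = N, Sd = Sd, Nd = Nd)
}

# random sense codon pair with at most max_diff differing positions
random_codon_pair <- function(max_diff = 2) {
  sense <- names(.oracle_gc)[.oracle_gc != "*"]
  repeat {
    ca <- sample(sense, 1)
    v <- strsplit(ca, "")[[1]]
    nd <- sample(0:max_diff, 1)
    if (nd > 0) {
      pos <- sample(1:3, nd)
      for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    }
    cb <- paste(v, collapse = "")
    if (.oracle_gc[[cb]] != "*") return(c(ca, cb))
  }
}

# ---- chain oracle ------------------------------------------------------

# enumerate every valid chain over rank-sorted anchors by depth-first
# extension; returns the best chain under the implementation's selection
# order (max size, same orientation first, lexicographic index sequence)
oracle_best_chain <- function(ra, rb, max_gap) {
  n <- length(ra)
  g1 <- max_gap + 1
  best <- NULL
  better <- function(x, y) {   # TRUE if chain/orient pair x beats y
    if (is.null(y)) return(TRUE)
    if (length(x$chain) != length(y$chain))
      return(length(x$chain) > length(y$chain))
    if (x$orient != y$orient) return(x$orient == "same")
    for (k in seq_along(x$chain)) {
      if (x$chain[k] != y$chain[k]) return(x$chain[k] < y$chain[k])
    }
    FALSE
  }
  succ_ok <- function(i, j, orient) {
    da <- ra[j] - ra[i]; db <- rb[j] - rb[i]
    da > 0 && da <= g1 &&
      ((orient == "same" && db > 0 && db <= g1) ||
         (orient == "inverted" && db < 0 && db >= -g1))
  }
  grow <- function(chain, orient) {
    cand <- list(chain = chain, orient = orient)
    if (better(cand, best)) best <<- cand
    last <- chain[length(chain)]
    for (j in seq_len(n)) {
      if (j > last && succ_ok(last, j, orient)) grow(c(chain, j), orient)
    }
  }
  for (orient in c("same", "inverted"))
    for (i in seq_len(n)) grow(i, orient)
  best
}

oracle_chain_blocks <- function(anchors, min_match, max_gap) {
  work <- anchors[order(anchors$rank_a, anchors$rank_b), , drop = FALSE]
  blocks <- list()
  while (nrow(work) > 0) {
    b <- oracle_best_chain(work$rank_a, work$rank_b, max_gap)
    if (length(b$chain) < min_match) break
    blk <- work[b$chain, , drop = FALSE]
    rownames(blk) <- NULL
    attr(blk, "orientation") <- b$orient
    blocks[[length(blocks) + 1L]] <- blk
    work <- work[-b$chain, , drop = FALSE]
  }
  blocks
}

# ---- map-equation oracle ----------------------------------------------

# textbook entropy form of the two-level description length
oracle_map_L <- function(edges, membership, n_nodes) {
  m <- nrow(edges)
  if (m == 0) return(0)
  H <- function(p) {
    p <- p[p > 0]
    if (!length(p)) return(0)
    -sum(p * log2(p))
  }
  deg <- rep(0, n_nodes)
  for (r in seq_len(m)) {
    deg[edges[r, 1]] <- deg[edges[r, 1]] + 1
    deg[edges[r, 2]] <- deg[edges[r, 2]] + 1
  }
  p <- deg / (2 * m)
  mods <- unique(membership)
  q <- numeric(length(mods))
  term <- 0
  for (k in seq_along(mods)) {
    inmod <- membership == mods[k]
    cut <- sum(xor(inmod[edges[, 1]], inmod[edges[, 2]]))
    q[k] <- cut / (2 * m)
    pi_circ <- q[k] + sum(p[inmod])
    if (pi_circ > 0)
      term <- term + pi_circ * H(c(q[k], p[inmod]) / pi_circ)
  }
  qt <- sum(q)
  qt * H(q / max(qt, .Machine$double.eps)) * (qt > 0) + term
}

# all set partitions of 1..n as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, mx) {
    k <- length(memb) + 1L
    if (k > n) {
      out[[length(out) + 1L]] <<- memb
      return()
    }
    for (v in seq_len(mx + 1L)) rec(c(memb, v), max(mx, v))
  }
  rec(integer(), 0L)
  out
}

oracle_min_map_L <- function(edges, n_nodes) {
  best <- Inf
  for (memb in all_partitions(n_nodes)) {
    L <- oracle_map_L(edges, memb, n_nodes)
    if (L < best) best <- L
  }
  best
}

# ---- Ward (Lance-Williams ward.D) oracle ------------------------------

oracle_ward_heights <- function(D) {
  n <- nrow(D)
  size <- rep(1, n)
  act <- seq_len(n)
  Dm <- D
  heights <- numeric(0)
  while (length(act) > 1) {
    m <- length(act)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (Dm[i, j] < best[1] - 1e-12) best <- c(Dm[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    ni <- size[i]; nj <- size[j]
    newd <- vapply(seq_len(m), function(k) {
      if (k == i || k == j) return(NA_real_)
      nk <- size[k]
      ((ni + nk) * Dm[i, k] + (nj + nk) * Dm[j, k] - nk * Dm[i, j]) /
        (ni + nj + nk)
    }, numeric(1))
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    size <- c(size[keep], ni + nj)
    act <- seq_len(m - 1)
  }
  heights
}

# ---- misc --------------------------------------------------------------

random_protein <- function(n) {
  paste(sample(synfam:::AA20, n, replace = TRUE), collapse = "")
}
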