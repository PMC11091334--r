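make_anchors <- function(ra, rb) {
  data.frame(gene_a = paste0("a", seq_along(ra)),
             gene_b = paste0("b", seq_along(ra)),
             chrom_a = "x", chrom_b = "y",
             rank_a = as.integer(ra), rank_b = as.integer(rb),
             score = 100, stringsAsFactors = FALSE)
}

test_that("chaining respects the minimum size and gap bounds", {
  # three collinear anchors form one same-orientation block
  b1 <- chain_anchors(make_anchors(0:2, 0:2), min_match = 3, max_gap = 25)
  expect_length(b1, 1L)
  expect_identical(nrow(b1[[1]]), 3L)
  expect_identical(attr(b1[[1]], "orientation"), "same")
  # two anchors are below the minimum match size
  expect_length(chain_anchors(make_anchors(0:1, 0:1), 3, 25), 0L)
  # a rank gap beyond max_gap + 1 breaks the chain
  expect_length(chain_anchors(make_anchors(c(0, 1, 28), c(0, 1, 2)), 3, 25),
                0L)
  # inverted blocks chain on descending rank_b
  b2 <- chain_anchors(make_anchors(0:3, c(9, 8, 7, 6)), 3, 25)
  expect_length(b2, 1L)
  expect_identical(attr(b2[[1]], "orientation"), "inverted")
})

test_that("chaining equals the exhaustive best-chain oracle (spot sweep)", {
  set.seed(111)
  for (rep in 1:60) {
    n <- sample(4:10, 1)
    anc <- make_anchors(sample(0:14, n, replace = TRUE),
                        sample(0:14, n, replace = TRUE))
    anc <- anc[!duplicated(anc[, c("rank_a", "rank_b")]), ]
    mm <- sample(2:3, 1); mg <- sample(1:5, 1)
    got <- chain_anchors(anc, mm, mg)
    want <- oracle_chain_blocks(anc, mm, mg)
    expect_identical(length(got), length(want))
    for (k in seq_along(got)) {
      expect_identical(got[[k]][, c("rank_a", "rank_b")],
                       want[[k]][, c("rank_a", "rank_b")])
      expect_identical(attr(got[[k]], "orientation"),
                       attr(want[[k]], "orientation"))
    }
  }
})

test_that("every reported block satisfies its own invariants", {
  set.seed(121)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    anc <- make_anchors(sample(0:20, n, replace = TRUE),
                        sample(0:20, n, replace = TRUE))
    anc <- anc[!duplicated(anc[, c("rank_a", "rank_b")]), ]
    for (b in chain_anchors(anc, 3, 4)) {
      expect_gte(nrow(b), 3L)
      da <- diff(b$rank_a); db <- diff(b$rank_b)
      expect_true(all(da >= 1 & da <= 5))
      if (attr(b, "orientation") == "same")
        expect_true(all(db >= 1 & db <= 5))
      else expect_true(all(db <= -1 & db >= -5))
    }
  }
})

test_that("top-k keeps k best hits per target genome with the tie rule", {
  sim <- small_sim()
  cfg <- run_config(top_k = 2)
  hits <- topk_hits(sim$genomes, cfg)
  key <- paste(hits$query, hits$target_genome)
  expect_lte(max(table(key)), 2L)
  expect_true(all(hits$query != hits$target))
  # ties break toward the lexicographically smallest target id
  tied <- hits[duplicated(key) | duplicated(key, fromLast = TRUE), ]
  for (k in unique(paste(tied$query, tied$target_genome))) {
    sub <- tied[paste(tied$query, tied$target_genome) == k, ]
    if (nrow(sub) == 2 && sub$score[1] == sub$score[2])
      expect_true(sub$target[1] < sub$target[2])
  }
})

test_that("tandem arrays collapse to their best self-scoring member", {
  ctx <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                    genome_id = "G", chromosome = "G:c1",
                    rank = 0:3, stringsAsFactors = FALSE)
  prot <- c(g1 = "MKLV", g2 = "MKLVW", g3 = "MKLV", g4 = "AAAA")
  # g1-g2 adjacent homologs; g3 adjacent to g2; g4 unrelated
  hits <- data.frame(query = c("g1", "g2"), target = c("g2", "g3"),
                     score = c(20, 20), query_genome = "G",
                     target_genome = "G", stringsAsFactors = FALSE)
  col <- collapse_tandem(hits, ctx, prot)
  # run {g1,g2,g3} collapses to g2 (longest, highest self-score)
  expect_identical(sort(unique(col$mapping$representative[
    col$mapping$gene_id %in% c("g1", "g2", "g3")])), "g2")
  expect_identical(col$context$gene_id, c("g2", "g4"))
  expect_identical(col$context$rank, c(0L, 1L))
  # separated paralogs stay distinct
  ctx2 <- ctx; ctx2$rank <- c(0L, 3L, 6L, 9L)
  col2 <- collapse_tandem(hits, ctx2, prot)
  expect_identical(col2$mapping$representative, col2$mapping$gene_id)
})

test_that("network edges come from blocks and subnetworks filter by class", {
  anc <- make_anchors(0:3, 0:3)
  anc$gene_a <- c("f1", "b1", "b2", "f2")
  anc$gene_b <- c("f3", "b3", "b4", "b5")
  bl <- detect_blocks(anc, 3, 25)
  ctx <- data.frame(gene_id = unique(c(anc$gene_a, anc$gene_b)),
                    genome_id = "G", chromosome = "x", rank = 0L)
  net <- build_network(bl, ctx)
  expect_identical(nrow(net$edges), 4L)
  asg <- data.frame(gene_id = c("f1", "f2", "f3", "b1", "b2", "b3", "b4",
                                "b5"),
                    class = c("family", "family", "family", rep("none", 5)))
  sub <- extract_family_subnetwork(net, asg, "family")
  # only the f1-f3 edge has two family endpoints
  expect_identical(nrow(sub$edges), 1L)
  expect_setequal(sub$nodes, c("f1", "f3"))
  expect_true(all(sub$edges$gene_a %in% net$edges$gene_a))
  # no family genes -> empty subnetwork
  sub2 <- extract_family_subnetwork(net, transform(asg, class = "none"),
                                    "family")
  expect_identical(nrow(sub2$edges), 0L)
})

test_that("community detection matches the planted two-clique structure", {
  cl <- function(nodes) t(combn(nodes, 2))
  e <- rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4)),
             c("a1", "b1"))
  net <- structure(list(nodes = sort(unique(c(e))),
                        edges = data.frame(gene_a = e[, 1], gene_b = e[, 2],
                                           stringsAsFactors = FALSE)),
                   class = "syn_network")
  res <- detect_communities(net, seed = 1, min_size = 3)
  split_a <- unique(res$cluster[grepl("^a", res$gene_id)])
  split_b <- unique(res$cluster[grepl("^b", res$gene_id)])
  expect_length(split_a, 1L)
  expect_length(split_b, 1L)
  expect_false(split_a == split_b)
  expect_true(all(res$retained))
  # the achieved partition attains the exhaustive optimum
  nodes <- net$nodes
  ei <- cbind(match(e[, 1], nodes), match(e[, 2], nodes))
  expect_equal(attr(res, "L"), oracle_min_map_L(ei, length(nodes)),
               tolerance = 1e-9)
})

test_that("cluster size gating: triangles retained, edges dropped", {
  net <- structure(list(
    nodes = c("t1", "t2", "t3", "u1", "u2"),
    edges = data.frame(gene_a = c("t1", "t2", "t3", "u1"),
                       gene_b = c("t2", "t3", "t1", "u2"),
                       stringsAsFactors = FALSE)), class = "syn_network")
  res <- detect_communities(net, seed = 1, min_size = 3)
  tri <- res[res$gene_id %in% c("t1", "t2", "t3"), ]
  expect_length(unique(tri$cluster), 1L)
  expect_true(all(tri$retained))
  pair <- res[res$gene_id %in% c("u1", "u2"), ]
  expect_false(any(pair$retained))
})

test_that("relabeling nodes permutes labels but not the partition", {
  set.seed(131)
  e <- data.frame(gene_a = c("n1", "n2", "n3", "n5", "n6", "n7", "n1"),
                  gene_b = c("n2", "n3", "n1", "n6", "n7", "n5", "n5"),
                  stringsAsFactors = FALSE)
  net1 <- structure(list(nodes = paste0("n", 1:7), edges = e),
                    class = "syn_network")
  perm <- setNames(paste0("m", sample(7)), paste0("n", 1:7))
  e2 <- data.frame(gene_a = unname(perm[e$gene_a]),
                   gene_b = unname(perm[e$gene_b]), stringsAsFactors = FALSE)
  net2 <- structure(list(nodes = sort(unname(perm)), edges = e2),
                    class = "syn_network")
  r1 <- detect_communities(net1, seed = 2)
  r2 <- detect_communities(net2, seed = 2)
  # compare partitions through the permutation map
  canon <- function(part, map = identity)
    unname(sort(vapply(part, function(x) paste(sort(map(x)), collapse = ","),
                       character(1))))
  inv <- setNames(names(perm), perm)
  expect_identical(canon(split(r1$gene_id, r1$cluster)),
                   canon(split(r2$gene_id, r2$cluster),
                         function(x) unname(inv[x])))
})
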