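test_that("progressive alignment handles identical, gapped and edge cases", {
  al <- progressive_align(c(a = "MKLV", b = "MKLV"))
  expect_identical(unname(al), c("MKLV", "MKLV"))
  al2 <- progressive_align(c(x = "ACDEFG", y = "ACEFG"))
  expect_identical(unname(al2), c("ACDEFG", "AC-EFG"))
  expect_identical(progressive_align(c(solo = "MK")), c(solo = "MK"))
  # width >= longest input; ungapping recovers inputs
  set.seed(51)
  prots <- setNames(vapply(1:6, function(i) random_protein(sample(30:60, 1)),
                           character(1)), paste0("p", 1:6))
  al3 <- progressive_align(prots)
  expect_true(all(nchar(al3) == nchar(al3[1])))
  expect_gte(nchar(al3[1]), max(nchar(prots)))
  expect_identical(gsub("-", "", al3), prots)
})

test_that("trimming drops low-coverage columns and keeps conserved ones", {
  # 10 rows; column 1 has 3 gaps (coverage 0.7 < 0.8) -> dropped
  msa <- setNames(c(rep("AAC", 7), rep("-AC", 3)), paste0("s", 1:10))
  tr <- trim_alignment(msa, gt = 0.8, st = 0.001, cons = 0)
  expect_identical(attr(tr, "kept_columns"), 2:3)
  # an all-identical column survives any gt, st <= 1
  tr2 <- trim_alignment(msa, gt = 1, st = 1, cons = 0)
  expect_true(2L %in% attr(tr2, "kept_columns"))
})

test_that("the cons floor adds columns back to exactly the target width", {
  # 10 columns; only 5 pass gt -> cons 60 forces exactly 6
  rows <- c(paste0("AAAAA", "-----"), paste0("AAAAA", "A----"),
            paste0("AAAAA", "AA---"), paste0("AAAAA", "AAA--"))
  msa <- setNames(rows, paste0("s", 1:4))
  tr <- trim_alignment(msa, gt = 0.8, st = 0.001, cons = 60)
  kept <- attr(tr, "kept_columns")
  expect_length(kept, 6L)
  expect_identical(kept[1:5], 1:5)
  # the added-back column is the highest-coverage dropped one (column 6)
  expect_identical(kept[6], 6L)
  # order preserved, never reordered
  expect_identical(kept, sort(kept))
})

test_that("neighbor joining is exact on an additive 4-taxon matrix", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):1);")
  D <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  nt <- nj_tree(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nt)), 0)
  expect_lt(max(abs(ape::cophenetic.phylo(nt)[LETTERS[1:4], LETTERS[1:4]] -
                      D)), 1e-12)
})

test_that("three taxa resolve by the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nt <- nj_tree(D)
  expect_identical(nt$Nnode, 1L)
  len <- setNames(nt$edge.length, nt$tip.label[nt$edge[, 2]])
  expect_equal(unname(len[c("A", "B", "C")]), c(1, 2, 3))
})

test_that("input order does not change the NJ tree", {
  set.seed(61)
  tr <- ape::rtree(7)
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(D))
  n1 <- nj_tree(D)
  n2 <- nj_tree(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(n1, n2)), 0)
})

test_that("NJ agrees with the reference implementation away from ties", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    D <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
    v <- stats::runif(n * (n - 1) / 2, 0.5, 2)
    D[upper.tri(D)] <- v
    D <- D + t(D)
    expect_equal(as.numeric(ape::dist.topo(nj_tree(D), ape::nj(D))), 0)
  }
})

test_that("NaN distances are rejected naming the offending pair", {
  D <- matrix(c(0, 1, NaN, 1, 0, 1, NaN, 1, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_error(nj_tree(D), "a.*c|c.*a")
})

test_that("bootstrap supports are deterministic and bounded", {
  set.seed(81)
  prots <- setNames(vapply(1:5, function(i) random_protein(50),
                           character(1)), paste0("s", 1:5))
  al <- progressive_align(prots)
  b1 <- bootstrap_supports(al, n_reps = 1, seed = 5)
  sup <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  b2 <- bootstrap_supports(al, n_reps = 25, seed = 5)
  b3 <- bootstrap_supports(al, n_reps = 25, seed = 5)
  expect_identical(b2$node.label, b3$node.label)
})

test_that("clearly separated clusters get high central support", {
  set.seed(91)
  base1 <- random_protein(120); base2 <- random_protein(120)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    p <- sample(length(v), k)
    v[p] <- vapply(v[p], function(a) sample(setdiff(synfam:::AA20, a), 1),
                   character(1))
    paste(v, collapse = "")
  }
  prots <- c(a1 = mut(base1, 3), a2 = mut(base1, 3),
             b1 = mut(base2, 3), b2 = mut(base2, 3))
  al <- progressive_align(prots)
  bt <- bootstrap_supports(al, n_reps = 100, seed = 2)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95)
})

test_that("outgroup rooting is midpoint-on-pendant-edge and idempotent", {
  tr <- ape::read.tree(text = "(A:1,B:1,(C:1,D:1):1);")
  r <- root_at_outgroup(tr, "A")
  expect_true(ape::is.rooted(r))
  root <- length(r$tip.label) + 1L
  re <- which(r$edge[, 1] == root)
  expect_equal(r$edge.length[re], c(0.5, 0.5))
  r2 <- root_at_outgroup(r, "A")
  expect_identical(ape::write.tree(r2), ape::write.tree(r))
  expect_error(root_at_outgroup(tr, "nope"), "not a leaf")
})

test_that("groups are extracted as smallest seed-containing clades", {
  tr <- ape::read.tree(
    text = "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  g <- assign_groups(tr, list(I = "A", II = "C", III = "E", IV = "G"))
  expect_identical(g$group[g$gene_id %in% c("A")], "I")
  expect_identical(sort(unique(g$group)),
                   sort(c("I", "II", "III", "IV", "unassigned")))
  g2 <- assign_groups(tr, list(I = c("A", "B"), II = c("E", "F", "G", "H")))
  expect_identical(g2$group[g2$gene_id == "H"], "II")
  expect_identical(g2$group[g2$gene_id == "C"], "unassigned")
  # seeds spanning the root have no proper clade
  expect_error(assign_groups(tr, list(I = c("A", "H"))), "root")
  # overlapping clades are rejected
  expect_error(assign_groups(tr, list(I = c("A", "B"), II = c("A", "D"))),
               "overlap")
  expect_error(assign_groups(tr, list(I = "ZZ")), "missing")
})

test_that("same-origin family copies are monophyletic with good support", {
  sim <- small_sim()
  idf <- small_identify()
  fam <- idf$assignments[idf$assignments$class == "family", ]
  prots <- unlist(lapply(sim$genomes, function(g)
    g$protein[names(g$protein) %in% fam$gene_id]))
  names(prots) <- sub("^g[A-D]\\.", "", names(prots))
  al <- trim_alignment(progressive_align(prots))
  bt <- bootstrap_supports(al, n_reps = 50, seed = 3)
  og <- setNames(sim$truth$ortholog_group, sim$truth$gene_id)[bt$tip.label]
  # each ancestral copy with >= 2 descendants forms a clade
  for (o in unique(og)) {
    tips <- names(og)[og == o]
    if (length(tips) < 2 || length(tips) >= length(bt$tip.label) - 1) next
    expect_true(ape::is.monophyletic(bt, tips))
  }
})
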