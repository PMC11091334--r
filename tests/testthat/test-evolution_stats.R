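test_that("NG86 reproduces hand-derived values on worked codon pairs", {
  r <- ng86(c("ATTGGG", "ATCGGG"))
  expect_equal(r$S, 5 / 3, tolerance = 1e-12)
  expect_equal(r$N, 13 / 3, tolerance = 1e-12)
  expect_equal(r$Sd, 1); expect_equal(r$Nd, 0)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, -0.75 * log(0.2), tolerance = 1e-12)
  expect_equal(r$ratio, 0)
  # Lys -> Arg at position 2: nonsynonymous only, Ks = 0, ratio undefined
  r2 <- ng86(c("ATGAAA", "ATGAGA"))
  expect_equal(r2$Sd, 0); expect_equal(r2$Nd, 1)
  expect_gt(r2$Ka, 0); expect_equal(r2$Ks, 0)
  expect_true(is.na(r2$ratio))
  # identical sequences
  r3 <- ng86(c("ATGGCT", "ATGGCT"))
  expect_equal(r3$Ka, 0); expect_equal(r3$Ks, 0)
  expect_true(is.na(r3$ratio))
})

test_that("NG86 is symmetric and invariant under codon duplication", {
  set.seed(101)
  for (i in 1:20) {
    p <- c(random_codon_pair(2), random_codon_pair(2))
    a <- paste0(p[1], p[3]); b <- paste0(p[2], p[4])
    r1 <- ng86(c(a, b)); r2 <- ng86(c(b, a))
    expect_equal(r1$Ka, r2$Ka, tolerance = 1e-12)
    expect_equal(r1$Ks, r2$Ks, tolerance = 1e-12)
    # duplicating the alignment leaves per-site values unchanged
    r3 <- ng86(c(paste0(a, a), paste0(b, b)))
    expect_equal(r3$Ka, r1$Ka, tolerance = 1e-12)
    expect_equal(r3$Ks, r1$Ks, tolerance = 1e-12)
  }
})

test_that("gapped and stop codon columns are excluded from counting", {
  r <- ng86(c("ATT---GGGTAA", "ATTGCC---TAA"))
  # only the first codon column is comparable
  expect_equal(r$S + r$N, 3, tolerance = 1e-12)
  expect_error(ng86(c("---", "---")), "no comparable")
})

test_that("codon alignment back-translates and round-trips exactly", {
  cds_a <- "ATGGCTAAA"  # M A K
  cds_b <- "ATGAAA"     # M K
  pal <- c("MAK", "M-K")
  cal <- codon_align(cds_a, cds_b, pal)
  expect_identical(cal, c("ATGGCTAAA", "ATG---AAA"))
  expect_identical(gsub("-", "", cal), c(cds_a, cds_b))
  # gap-free alignment returns the CDS unchanged
  cal2 <- codon_align("ATGAAA", "ATGAGA", c("MK", "MR"))
  expect_identical(cal2, c("ATGAAA", "ATGAGA"))
  # translation mismatch errors with the position
  expect_error(codon_align("ATGGGT", "ATGAAA", c("MK", "MK")), "position 2")
  expect_error(codon_align("ATGAAAGGG", "ATGAAA", c("MK", "MK")),
               "does not match")
})

test_that("reciprocal pairing honors the identity threshold", {
  sim <- small_sim()
  idf <- small_identify()
  g <- sim$genomes$gA
  a <- idf$assignments[idf$assignments$genome_id == "gA", ]
  pairs <- find_homolog_pairs(g, a, identity_threshold = 50)
  if (nrow(pairs)) expect_true(all(pairs$identity > 50))
  # three mutually near-identical paralogs give three pairs
  prot <- c(p1 = "MKLVWAAC", p2 = "MKLVWAAC", p3 = "MKLVWAAC")
  cds <- setNames(vapply(prot, function(p) synfam:::.back_translate(p),
                         character(1)), names(prot))
  genes <- data.frame(gene_id = names(prot), chromosome = "c1",
                      start = c(0L, 100L, 200L), end = c(24L, 124L, 224L),
                      strand = "+", stringsAsFactors = FALSE)
  genes$exons <- lapply(seq_len(3), function(i)
    cbind(start = genes$start[i], end = genes$start[i] + 24L))
  set.seed(3)
  toy <- new_genome("toy", genes = genes, protein = prot, cds = cds,
                    validate = FALSE)
  asg <- data.frame(gene_id = names(prot), class = "family")
  p3 <- find_homolog_pairs(toy, asg, identity_threshold = 50,
                           score_cutoff = 10)
  expect_identical(nrow(p3), 3L)
  expect_equal(p3$identity, rep(100, 3))
  # a pair at ~40% identity is excluded at threshold 50
  lowa <- random_protein(100)
  expect_lt(global_identity(lowa, random_protein(100)), 50)
})

test_that("full family Ka/Ks pipeline flags saturation and undefined ratios", {
  sim <- small_sim()
  idf <- small_identify()
  got_pairs <- FALSE
  for (g in sim$genomes) {
    a <- idf$assignments[idf$assignments$genome_id == g$genome_id, ]
    kk <- kaks_pairs(g, a)
    if (!nrow(kk)) next
    got_pairs <- TRUE
    expect_true(all(kk$Ka >= 0 | is.nan(kk$Ka)))
    expect_true(all(is.na(kk$ratio[kk$Ks == 0])))
  }
  expect_true(got_pairs)
})

test_that("protein characteristics match closed-form values", {
  g <- protein_profile("G")
  expect_equal(g$mw, 57.0519 + 18.0153, tolerance = 1e-6)
  expect_equal(protein_profile("I")$gravy, 4.5)
  # GG: only termini ionize; pI is the pKa midpoint 6.1
  expect_equal(protein_profile("GG")$pi, 6.1, tolerance = 2e-3)
  p <- protein_profile("MKWVTFISLLLLFSSAYS")
  expect_true(p$pi > 0 && p$pi < 14)
  expect_true(p$gravy >= -4.5 && p$gravy <= 4.5)
  expect_error(protein_profile("MKX"), "X")
})

test_that("structure summaries average the right quantities", {
  sim <- small_sim()
  idf <- small_identify()
  ss <- structure_summary(sim$genomes, idf$assignments)
  g <- sim$genomes$gA
  a <- idf$assignments[idf$assignments$genome_id == "gA" &
                         idf$assignments$class == "family", ]
  gi <- g$genes[g$genes$gene_id %in% a$gene_id, ]
  expect_equal(ss$family_n[ss$genome_id == "gA"], nrow(gi))
  expect_equal(ss$family_gene_length[ss$genome_id == "gA"],
               mean(gi$end - gi$start))
  expect_equal(ss$family_cds_length[ss$genome_id == "gA"],
               mean(vapply(gi$exons, function(e) sum(e[, 2] - e[, 1]),
                           numeric(1))))
  # absence sentinel
  fake <- structure_summary(sim$genomes[1],
                            idf$assignments[0, , drop = FALSE])
  fmt <- format_structure_summary(fake)
  expect_identical(fmt$family_gene_length, "-")
})

test_that("copy-number statistics: mean, CV and ploidy correlation", {
  counts <- c(a = 2L, b = 2L, c = 2L, d = 0L)
  plo <- c(a = 2L, b = 4L, c = 6L, d = 8L)
  s <- copy_number_stats(counts, plo)
  expect_equal(s$mean, 2)
  expect_equal(s$cv, 0)
  expect_equal(s$n_genomes_with, 3L)
  # copies exactly equal to ploidy -> correlation 1
  s2 <- copy_number_stats(plo, plo)
  expect_equal(s2$cor, 1)
  s3 <- copy_number_stats(c(a = 1L), c(a = 2L))
  expect_true(is.na(s3$cor))
})
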