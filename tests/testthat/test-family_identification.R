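test_that("PSSM probabilities and log-odds follow the stated formula", {
  msa <- setNames(rep(strrep("ACDEF", 4), 4), paste0("s", 1:4))
  p <- build_pssm(msa, "N", pseudocount = 0.5)
  # all-A column, n = 4, pseudocount 0.5: P(A) = 4.5/14
  expect_equal(unname(p$probs[1, "A"]), 4.5 / 14, tolerance = 1e-12)
  expect_equal(unname(p$scores[1, "A"]), log2((4.5 / 14) / 0.05), tolerance = 1e-12)
  expect_equal(sum(p$probs[1, ]), 1, tolerance = 1e-12)
  # uniform column: equal scores
  rows <- vapply(1:20, function(i)
    paste(synfam:::AA20[c(i, i, i, i, i)], collapse = ""), character(1))
  pu <- build_pssm(setNames(rows, paste0("r", 1:20)), "N")
  expect_lt(diff(range(pu$scores[1, 1:20])), 1e-12)
  # large pseudocount drives scores to 0 bits
  pb <- build_pssm(msa, "N", pseudocount = 1e9)
  expect_lt(max(abs(pb$scores[, 1:20])), 1e-6)
  expect_error(build_pssm(character(0)), "empty")
})

test_that("scan finds the consensus at its planted offset only", {
  set.seed(21)
  msa <- setNames(replicate(6, random_protein(30)), paste0("x", 1:6))
  # make columns conserved: all rows equal to the first
  msa[] <- msa[1]
  p <- build_pssm(msa, "N")
  cons <- msa[[1]]
  # consensus scans to a single maximal hit at offset 0
  h <- scan_domains(cons, p)
  expect_identical(h$start, 0L)
  expect_equal(h$bitscore, p$max_score, tolerance = 1e-9)
  # embedded at offset 7 inside random flanks: brute-force oracle agrees
  flank1 <- random_protein(7); flank2 <- random_protein(11)
  prot <- paste0(flank1, cons, flank2)
  h2 <- scan_domains(prot, p)
  expect_identical(h2$start, 7L)
  idx <- synfam:::aa_index(prot)
  brute <- vapply(seq_len(nchar(prot) - p$width + 1), function(o)
    sum(p$scores[cbind(seq_len(p$width), idx[o:(o + p$width - 1)])]),
    numeric(1))
  expect_identical(which.max(brute) - 1L, 7L)
  expect_equal(h2$bitscore, max(brute), tolerance = 1e-9)
  # unknown residues cannot form hits
  expect_identical(nrow(scan_domains(strrep("X", 60), p)), 0L)
  # short protein: empty result
  expect_identical(nrow(scan_domains("MK", p)), 0L)
})

test_that("local alignment scores match an independent implementation", {
  suppressWarnings(library(Biostrings, quietly = TRUE))
  set.seed(31)
  for (i in 1:20) {
    a <- random_protein(sample(40:250, 1))
    b <- random_protein(sample(40:250, 1))
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    expect_equal(sw_score(a, b), Biostrings::score(ref))
    # banded score on similar-length pairs equals the full score
    expect_equal(sw_score(a, b, band = max(nchar(a), nchar(b))),
                 Biostrings::score(ref))
  }
})

test_that("similarity search reports identity and honors its cutoff", {
  set.seed(41)
  q <- random_protein(100)
  hits <- similarity_search(c(q = q), c(t = q), score_cutoff = 10)
  expect_equal(hits$pident, 100)
  expect_equal(hits$score, synfam:::.self_score(q))
  # single substitution in 100 aa -> 99% identity
  v <- strsplit(q, "")[[1]]
  v[50] <- setdiff(synfam:::AA20, v[50])[1]
  h2 <- similarity_search(c(q = q), c(t = paste(v, collapse = "")),
                          score_cutoff = 10)
  expect_equal(h2$pident, 99)
  # unrelated random sequences fall below the default cutoff: empirical null
  nulls <- vapply(1:100, function(i)
    sw_score(random_protein(300),
             paste(rev(strsplit(random_protein(300), "")[[1]]),
                   collapse = "")), numeric(1))
  expect_lt(max(nulls), synfam:::.self_score(q))  # far below self-score
  expect_lt(stats::quantile(nulls, 0.99), 80)
})

test_that("class follows the two-domain rule; similarity is confirmatory", {
  dh <- data.frame(gene_id = c("g1", "g1", "g2", "g4", "g4", "g4"),
                   domain_name = c("N", "C", "C", "N", "N", "C"),
                   start = 0L, end = 10L, bitscore = 50)
  sh <- data.frame(query = "q", target = c("g2", "g3"), score = 99,
                   pident = 60)
  a <- assign_family(dh, sh, gene_ids = c("g1", "g2", "g3", "g4"))
  expect_identical(a$class, c("family", "family_like", "none", "family"))
  # g1: both domains but no similarity support -> flagged discordant
  expect_true(a$discordant[a$gene_id == "g1"])
  expect_false(a$similarity_support[a$gene_id == "g1"])
  # g2: one domain only
  expect_identical(a$domains_found[a$gene_id == "g2"], "C")
  # idempotent and order-independent
  a2 <- assign_family(dh[sample(nrow(dh)), ], sh,
                      gene_ids = c("g4", "g2", "g3", "g1"))
  expect_identical(a, a2)
})

test_that("classification recovers the planted truth on the small clade", {
  sim <- small_sim()
  idf <- small_identify()
  tab <- merge(idf$assignments, sim$truth, by = c("genome_id", "gene_id"))
  fam_pred <- tab$class == "family"
  fam_true <- tab$label == "family"
  expect_gte(sum(fam_pred & fam_true) / sum(fam_pred), 0.95)
  expect_gte(sum(fam_pred & fam_true) / sum(fam_true), 0.95)
  fl <- tab[tab$label == "family_like", ]
  expect_gte(mean(fl$class == "family_like"), 0.9)
})

test_that("decoy one-domain genes classify as family-like, not family", {
  cfg <- sim_config(species_tree = "(gA:0.01,gB:0.01);",
                    chromosomes = 1L, genes_per_chromosome = 12L,
                    family_seed_count = 2L, decoy_families = 1L,
                    rng_seed = 13L)
  sim <- simulate_clade(cfg)
  idf <- identify_family(sim$genomes, sim$seed_msas)
  tab <- merge(idf$assignments, sim$truth, by = c("genome_id", "gene_id"))
  dec <- tab[grepl("^c", tab$ortholog_group) & tab$label == "family_like", ]
  expect_gt(nrow(dec), 0)
  expect_true(all(dec$class == "family_like"))
})
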