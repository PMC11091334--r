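# Synthetic clade simulator. Generates toy genomes descending from a common
# ancestor that carries a planted multi-copy two-domain gene family, with
# per-branch whole-genome duplication (WGD), tandem duplication,
# transposition, gene loss and domain loss, plus K2P-style point
# substitutions. Every emitted gene carries a ground-truth label so each
# downstream pipeline stage can be scored against the truth.

# default 12-leaf species tree; branch lengths are substitutions/site
.default_species_tree <- paste0(
  "(((g01:0.012,g02:0.012):0.014,(g03:0.011,g04:0.011):0.015):0.02,",
  "((g05:0.013,g06:0.013):0.015,((g07:0.010,g08:0.010):0.011,",
  "(g09:0.012,(g10:0.009,(g11:0.007,g12:0.007):0.004):0.005):0.008):0.009)",
  ":0.016);")

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic clade: species tree,
#' genome layout, planted family size, per-branch event probabilities and
#' the substitution process. Defaults describe a 12-genome clade with 2
#' chromosomes of 200 genes each and 6 ancestral family copies; event rates
#' are per family gene per branch (WGD is per branch), chosen to yield a
#' handful of each event type across the clade.
#'
#' @param species_tree Newick string with branch lengths in
#'   substitutions/site.
#' @param chromosomes chromosomes in the ancestral genome.
#' @param genes_per_chromosome background gene slots per chromosome.
#' @param family_seed_count ancestral two-domain family copies.
#' @param wgd_prob probability of a whole-genome duplication per branch.
#' @param tandem_rate per family gene per branch tandem-duplication
#'   probability.
#' @param transposition_rate per family gene per branch probability of a
#'   synteny-breaking relocation.
#' @param loss_rate per family gene per branch deletion probability.
#' @param domain_loss_rate per family gene per branch probability of losing
#'   one of the two domains (the gene becomes family-like).
#' @param sub_rate substitutions per site per unit branch length.
#' @param linker_indel_rate per family gene per branch probability of a
#'   small in-frame indel in the inter-domain linker.
#' @param purifying_domains model purifying selection on family proteins:
#'   amino-acid-changing substitutions are always rejected inside intact
#'   domains and rejected with probability 0.7 elsewhere in the protein.
#' @param decoy_families number of extra background families carrying only
#'   the N-terminal domain (exercises the one-domain classification path).
#' @param ploidy_map named integer vector of base ploidies per leaf
#'   (default 2 everywhere); WGDs on the path to a leaf double it.
#' @param rng_seed integer seed; identical configurations give identical
#'   simulations.
#' @param dn_width,dc_width,linker_width,flank_n,flank_c protein segment
#'   widths (aa) of the planted family architecture
#'   `M + flank_n + domainN + linker + domainC + flank_c`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(species_tree = .default_species_tree,
                       chromosomes = 2L, genes_per_chromosome = 200L,
                       family_seed_count = 6L,
                       wgd_prob = 0.12, tandem_rate = 0.08,
                       transposition_rate = 0.03, loss_rate = 0.03,
                       domain_loss_rate = 0.05, sub_rate = 1.0,
                       linker_indel_rate = 0.05, purifying_domains = TRUE,
                       decoy_families = 0L, ploidy_map = NULL,
                       rng_seed = 1L, dn_width = 120L, dc_width = 100L,
                       linker_width = 40L, flank_n = 30L, flank_c = 20L) {
  probs <- c(wgd_prob = wgd_prob, tandem_rate = tandem_rate,
             transposition_rate = transposition_rate, loss_rate = loss_rate,
             domain_loss_rate = domain_loss_rate,
             linker_indel_rate = linker_indel_rate)
  if (any(probs < 0 | probs > 1))
    stop("event probabilities must be in [0, 1]")
  if (sub_rate < 0) stop("sub_rate must be >= 0")
  tree <- ape::read.tree(text = species_tree)
  if (anyDuplicated(tree$tip.label)) stop("species tree leaf names not unique")
  if (is.null(ploidy_map))
    ploidy_map <- setNames(rep(2L, length(tree$tip.label)), tree$tip.label)
  cfg <- list(species_tree = species_tree,
              chromosomes = as.integer(chromosomes),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              family_seed_count = as.integer(family_seed_count),
              wgd_prob = wgd_prob, tandem_rate = tandem_rate,
              transposition_rate = transposition_rate, loss_rate = loss_rate,
              domain_loss_rate = domain_loss_rate, sub_rate = sub_rate,
              linker_indel_rate = linker_indel_rate,
              purifying_domains = isTRUE(purifying_domains),
              decoy_families = as.integer(decoy_families),
              ploidy_map = ploidy_map, rng_seed = as.integer(rng_seed),
              dn_width = as.integer(dn_width), dc_width = as.integer(dc_width),
              linker_width = as.integer(linker_width),
              flank_n = as.integer(flank_n), flank_c = as.integer(flank_c))
  class(cfg) <- "sim_config"
  cfg
}

# ---- sequence helpers --------------------------------------------------

.sense_codons <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ct <- codon_table()
      cache <<- names(ct)[ct != "*"]
    }
    cache
  }
})

.syn_codons <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ct <- codon_table()
      cache <<- split(names(ct)[ct != "*"], ct[ct != "*"])
    }
    cache
  }
})

.random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                     collapse = "")

.back_translate <- function(protein) {
  syn <- .syn_codons()
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  paste(vapply(aa, function(a) {
    cs <- syn[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

# K2P-style substitutions (transition/transversion rate ratio 2, so a
# mutating site transitions with probability 1/2). Mutations creating a
# premature stop are rejected. Purifying selection: amino-acid changes in
# `purify_codons` (the intact domains) are always rejected; elsewhere in a
# constrained gene they are rejected with probability `soft_reject`. The
# terminal stop codon is never touched.
.mutate_cds <- function(cds, p, purify_codons = integer(), soft_reject = 0) {
  if (p <= 0) return(cds)
  v <- strsplit(cds, "", fixed = TRUE)[[1]]
  L <- length(v)
  idx <- which(runif(L) < p)
  idx <- idx[idx <= L - 3L]
  if (!length(idx)) return(cds)
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  r <- runif(length(idx))
  cur <- v[idx]
  new <- ifelse(r < 0.5, ts[cur], ifelse(r < 0.75, tv1[cur], tv2[cur]))
  w <- v
  w[idx] <- new
  ct <- codon_table()
  ci <- sort(unique((idx - 1L) %/% 3L))  # 0-based codon indices
  starts <- ci * 3L + 1L
  oldc <- paste0(v[starts], v[starts + 1L], v[starts + 2L])
  newc <- paste0(w[starts], w[starts + 1L], w[starts + 2L])
  nonsyn <- ct[newc] != ct[oldc]
  hard <- (ci + 1L) %in% purify_codons
  soft <- if (soft_reject > 0)
    runif(length(ci)) < soft_reject else rep(FALSE, length(ci))
  revert <- ct[newc] == "*" | (nonsyn & hard) | (nonsyn & !hard & soft)
  for (k in which(revert)) {
    s <- starts[k]
    w[s:(s + 2L)] <- v[s:(s + 2L)]
  }
  paste(w, collapse = "")
}

# ---- ancestor ----------------------------------------------------------

.new_sim_gene <- function(uid, cds, label, og, dn = NULL, dc = NULL) {
  L <- nchar(cds)
  n_ex <- sample.int(5L, 1L)
  cuts <- if (n_ex > 1L) sort(sample.int(L - 1L, n_ex - 1L)) else integer()
  exon_lens <- diff(c(0L, cuts, L))
  introns <- if (n_ex > 1L) sample(100:2000, n_ex - 1L, replace = TRUE)
             else integer()
  list(uid = uid, cds = cds, label = label, og = og,
       dn = dn, dc = dc, exon_lens = as.integer(exon_lens),
       intron_lens = as.integer(introns),
       strand = sample(c("+", "-"), 1L), transposed = FALSE)
}

#' Build the ancestral genome of a simulated clade
#'
#' Creates `chromosomes * genes_per_chromosome` background genes (random
#' CDS of 300-1500 codons) in fixed chromosomal order and plants
#' `family_seed_count` two-domain family genes (plus optional one-domain
#' decoy genes) at random slots. Deterministic under `rng_seed`.
#'
#' @param config a [sim_config()].
#' @return a list with the internal ancestor state (`state`), the domain
#'   consensus proteins (`domains`), and seed alignments for both domains
#'   (`seed_msas`, gapless 8-sequence MSAs at 10% divergence from the
#'   consensus).
#' @export
build_ancestor <- function(config) {
  n_slots <- config$chromosomes * config$genes_per_chromosome
  n_planted <- config$family_seed_count + config$decoy_families
  if (config$family_seed_count < 1L) stop("family_seed_count must be >= 1")
  if (n_planted > n_slots)
    stop("family_seed_count + decoy_families exceeds available gene slots")
  set.seed(config$rng_seed)
  dom_n <- .random_protein(config$dn_width)
  dom_c <- .random_protein(config$dc_width)
  seed_msas <- list(N = .seed_msa(dom_n, "N"), C = .seed_msa(dom_c, "C"))

  fam_slots <- sort(sample.int(n_slots, n_planted))
  fam_type <- c(rep("family", config$family_seed_count),
                rep("decoy", config$decoy_families))[
                  sample.int(n_planted)]
  pool <- list()
  chroms <- list()
  slot <- 0L
  fam_i <- 0L
  for (ch in seq_len(config$chromosomes)) {
    cname <- sprintf("chr%02d", ch)
    uids <- character(config$genes_per_chromosome)
    for (k in seq_len(config$genes_per_chromosome)) {
      slot <- slot + 1L
      uid <- sprintf("c%02dg%04d", ch, k)
      hit <- match(slot, fam_slots)
      if (!is.na(hit)) {
        fam_i <- fam_i + 1L
        type <- fam_type[hit]
        fn <- .random_protein(config$flank_n)
        lk <- .random_protein(config$linker_width)
        fc <- .random_protein(config$flank_c)
        if (type == "family") {
          prot <- paste0("M", fn, dom_n, lk, dom_c, fc)
          dn <- c(2L + config$flank_n,
                  1L + config$flank_n + config$dn_width)
          dc <- c(dn[2] + config$linker_width + 1L,
                  dn[2] + config$linker_width + config$dc_width)
          g <- .new_sim_gene(uid, paste0(.back_translate(prot), "TAA"),
                             "family", og = uid, dn = dn, dc = dc)
        } else {
          # decoy: N domain only, C-sized random tail
          prot <- paste0("M", fn, dom_n, lk, .random_protein(config$dc_width),
                         fc)
          dn <- c(2L + config$flank_n,
                  1L + config$flank_n + config$dn_width)
          g <- .new_sim_gene(uid, paste0(.back_translate(prot), "TAA"),
                             "family_like", og = uid, dn = dn, dc = NULL)
        }
      } else {
        ncod <- sample(300:1500, 1L)
        body <- paste(sample(.sense_codons(), ncod - 2L, replace = TRUE),
                      collapse = "")
        g <- .new_sim_gene(uid, paste0("ATG", body, "TAA"),
                           "background", og = uid)
      }
      pool[[uid]] <- g
      uids[k] <- uid
    }
    chroms[[cname]] <- uids
  }
  state <- list(pool = pool, chroms = chroms, wgd_count = 0L,
                copy_counter = 0L)
  list(state = state, domains = list(N = dom_n, C = dom_c),
       seed_msas = seed_msas)
}

.seed_msa <- function(consensus, name, n = 8L, divergence = 0.1) {
  aa <- strsplit(consensus, "", fixed = TRUE)[[1]]
  seqs <- c(consensus, vapply(seq_len(n - 1L), function(i) {
    mut <- aa
    hit <- which(runif(length(aa)) < divergence)
    if (length(hit)) mut[hit] <- sample(AA20, length(hit), replace = TRUE)
    paste(mut, collapse = "")
  }, character(1)))
  setNames(seqs, sprintf("seed_%s_%02d", name, seq_len(n)))
}

# ---- branch evolution --------------------------------------------------

.evolve_branch <- function(state, branch_len, config, branch_id, events) {
  pool <- state$pool
  chroms <- state$chroms
  rec <- function(type, gene) {
    events[[length(events) + 1L]] <<- list(branch = branch_id, type = type,
                                           gene = gene)
  }
  fam_uids <- function() {
    names(pool)[vapply(pool, function(g) g$label != "background", logical(1))]
  }
  # 1. whole-genome duplication
  if (runif(1) < config$wgd_prob) {
    sfx <- paste0("w", state$wgd_count + 1L)  # unique per successive WGD
    new_chroms <- list()
    for (cname in names(chroms)) {
      uids <- chroms[[cname]]
      dup <- paste0(uids, sfx)
      for (k in seq_along(uids)) {
        g <- pool[[uids[k]]]
        g$uid <- dup[k]
        pool[[dup[k]]] <- g
      }
      new_chroms[[paste0(cname, sfx)]] <- dup
    }
    chroms <- c(chroms, new_chroms)
    state$wgd_count <- state$wgd_count + 1L
    rec("WGD", NA_character_)
  }
  # 2. tandem duplication (adjacent rank)
  for (uid in fam_uids()) {
    if (runif(1) < config$tandem_rate) {
      state$copy_counter <- state$copy_counter + 1L
      g <- pool[[uid]]
      nid <- sprintf("%st%03d", uid, state$copy_counter)
      g$uid <- nid
      pool[[nid]] <- g
      for (cname in names(chroms)) {
        pos <- match(uid, chroms[[cname]])
        if (!is.na(pos)) {
          chroms[[cname]] <- append(chroms[[cname]], nid, after = pos)
          break
        }
      }
      rec("tandem", nid)
    }
  }
  # 3. transposition (synteny-breaking relocation)
  if (length(chroms) > 1L) {
    for (uid in fam_uids()) {
      if (runif(1) < config$transposition_rate) {
        src <- NULL
        for (cname in names(chroms))
          if (uid %in% chroms[[cname]]) { src <- cname; break }
        dest <- sample(setdiff(names(chroms), src), 1L)
        chroms[[src]] <- setdiff(chroms[[src]], uid)
        at <- sample.int(length(chroms[[dest]]) + 1L, 1L) - 1L
        chroms[[dest]] <- append(chroms[[dest]], uid, after = at)
        pool[[uid]]$transposed <- TRUE
        rec("transposition", uid)
      }
    }
  }
  # 4. loss
  had_family <- any(vapply(pool, function(g) g$label == "family", logical(1)))
  for (uid in fam_uids()) {
    if (runif(1) < config$loss_rate) {
      pool[[uid]] <- NULL
      for (cname in names(chroms))
        chroms[[cname]] <- setdiff(chroms[[cname]], uid)
      rec("loss", uid)
    }
  }
  if (had_family &&
      !any(vapply(pool, function(g) g$label == "family", logical(1))))
    warning("all family genes lost on branch ", branch_id)
  # 5. domain loss (family gene keeps exactly one intact domain)
  for (uid in names(pool)) {
    g <- pool[[uid]]
    if (g$label != "family") next
    if (runif(1) < config$domain_loss_rate) {
      side <- sample(c("N", "C"), 1L)
      span <- if (side == "N") g$dn else g$dc
      repl <- .back_translate(.random_protein(span[2] - span[1] + 1L))
      nt0 <- (span[1] - 1L) * 3L + 1L
      nt1 <- span[2] * 3L
      substr(g$cds, nt0, nt1) <- repl
      if (side == "N") g$dn <- NULL else g$dc <- NULL
      g$label <- "family_like"
      pool[[uid]] <- g
      rec("domain_loss", uid)
    }
  }
  # 6. linker indel (in-frame, between the two domains)
  for (uid in names(pool)) {
    g <- pool[[uid]]
    if (g$label != "family" || is.null(g$dn) || is.null(g$dc)) next
    if (runif(1) >= config$linker_indel_rate) next
    len <- 3L * sample.int(3L, 1L)
    lo <- g$dn[2] * 3L + 1L           # first linker nt
    hi <- (g$dc[1] - 1L) * 3L         # last linker nt
    if (hi - lo + 1L < len + 6L) next
    if (runif(1) < 0.5) {             # insertion
      at <- sample(lo:hi, 1L)
      ins <- paste(sample(.sense_codons(), len %/% 3L, replace = TRUE),
                   collapse = "")
      g$cds <- paste0(substr(g$cds, 1L, at - 1L), ins,
                      substr(g$cds, at, nchar(g$cds)))
      g <- .shift_gene_structure(g, at, len)
    } else {                          # deletion
      at <- sample(lo:(hi - len + 1L), 1L)
      g$cds <- paste0(substr(g$cds, 1L, at - 1L),
                      substr(g$cds, at + len, nchar(g$cds)))
      g <- .shift_gene_structure(g, at, -len)
      if (is.null(g)) next            # would not fit one exon; skipped
    }
    pool[[uid]] <- g
    rec("linker_indel", uid)
  }
  # 7. point substitutions
  p <- branch_len * config$sub_rate
  if (p > 0) {
    for (uid in names(pool)) {
      g <- pool[[uid]]
      purify <- integer()
      soft <- 0
      if (config$purifying_domains && g$label != "background") {
        if (!is.null(g$dn)) purify <- c(purify, g$dn[1]:g$dn[2])
        if (!is.null(g$dc)) purify <- c(purify, g$dc[1]:g$dc[2])
        soft <- 0.7
      }
      g$cds <- .mutate_cds(g$cds, p, purify, soft)
      pool[[uid]] <- g
    }
  }
  state$pool <- pool
  state$chroms <- chroms
  list(state = state, events = events)
}

# shift domain coordinates and exon lengths after an indel of `delta` nt
# at CDS position `at` (1-based). Deletions must fit inside one exon.
.shift_gene_structure <- function(g, at, delta) {
  cum <- cumsum(g$exon_lens)
  piece <- which(at <= cum)[1]
  if (delta < 0) {
    within <- at - c(0L, cum)[piece] - 1L    # nt of the piece before `at`
    if (within + (-delta) > g$exon_lens[piece]) return(NULL)
  }
  g$exon_lens[piece] <- g$exon_lens[piece] + delta
  dcod <- delta %/% 3L
  if (!is.null(g$dc) && (g$dc[1] - 1L) * 3L + 1L > at) g$dc <- g$dc + dcod
  g
}

# ---- finalization ------------------------------------------------------

.finalize_genome <- function(state, genome_id, config) {
  pool <- state$pool
  chroms <- state$chroms
  rows <- list()
  for (cname in names(chroms)) {
    pos <- 1000L
    for (uid in chroms[[cname]]) {
      g <- pool[[uid]]
      glen <- sum(g$exon_lens) + sum(g$intron_lens)
      ex_starts <- pos + cumsum(c(0L, head(g$exon_lens, -1L) +
                                    g$intron_lens))
      ex <- cbind(start = as.integer(ex_starts),
                  end = as.integer(ex_starts + g$exon_lens))
      rows[[length(rows) + 1L]] <- list(
        gene_id = paste0(genome_id, "_", uid), chromosome = cname,
        start = pos, end = as.integer(pos + glen), strand = g$strand,
        exons = ex, cds = g$cds, label = g$label,
        og = g$og, transposed = g$transposed,
        dn_intact = !is.null(g$dn), dc_intact = !is.null(g$dc))
      pos <- as.integer(pos + glen + sample(500:3000, 1L))
    }
  }
  genes <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    chromosome = vapply(rows, `[[`, character(1), "chromosome"),
    start = vapply(rows, `[[`, integer(1), "start"),
    end = vapply(rows, `[[`, integer(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  genes$exons <- lapply(rows, `[[`, "exons")
  cds <- setNames(vapply(rows, `[[`, character(1), "cds"), genes$gene_id)
  prot <- setNames(translate_cds(cds), genes$gene_id)
  ploidy <- config$ploidy_map[[genome_id]] * 2L^state$wgd_count
  truth <- data.frame(
    genome_id = genome_id,
    gene_id = genes$gene_id,
    label = vapply(rows, `[[`, character(1), "label"),
    ortholog_group = vapply(rows, `[[`, character(1), "og"),
    transposed = vapply(rows, `[[`, logical(1), "transposed"),
    dn_intact = vapply(rows, `[[`, logical(1), "dn_intact"),
    dc_intact = vapply(rows, `[[`, logical(1), "dc_intact"),
    stringsAsFactors = FALSE)
  list(genome = new_genome(genome_id, species = genome_id, clade = "sim",
                           ploidy = ploidy, genes = genes, protein = prot,
                           cds = cds, validate = FALSE),
       truth = truth)
}

#' Evolve a clade of genomes from a common ancestor
#'
#' Walks the species tree from the root, applying per-branch events in a
#' fixed order (WGD, tandem duplication, transposition, loss, domain loss,
#' linker indels, substitutions), and emits one genome per leaf plus a
#' ground-truth table.
#'
#' @param ancestor result of [build_ancestor()].
#' @param config the same [sim_config()].
#' @return list with `genomes` (named list of `fam_genome`), `truth`
#'   (per-gene labels, ortholog groups and event flags) and `events`
#'   (per-branch event records).
#' @export
evolve_clade <- function(ancestor, config) {
  tree <- ape::read.tree(text = config$species_tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- ancestor$state
  events <- list()
  genomes <- list()
  truths <- list()
  # preorder traversal: parents always precede children in edge order after
  # reorder(); process edges in that order
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    bl <- tr$edge.length[e]
    branch_id <- if (child <= ntip) tr$tip.label[child]
                 else paste0("node", child)
    res <- .evolve_branch(states[[par]], bl, config, branch_id, events)
    events <- res$events
    if (child <= ntip) {
      fin <- .finalize_genome(res$state, tr$tip.label[child], config)
      genomes[[tr$tip.label[child]]] <- fin$genome
      truths[[tr$tip.label[child]]] <- fin$truth
    } else {
      states[[child]] <- res$state
    }
  }
  ev <- if (length(events)) {
    data.frame(branch = vapply(events, `[[`, character(1), "branch"),
               type = vapply(events, `[[`, character(1), "type"),
               gene = vapply(events, `[[`, character(1), "gene"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(branch = character(), type = character(), gene = character())
  }
  genomes <- genomes[tree$tip.label]
  list(genomes = genomes, truth = do.call(rbind, truths[tree$tip.label]),
       events = ev)
}

#' Simulate a full clade with ground truth
#'
#' Convenience wrapper: [build_ancestor()] then [evolve_clade()], returning
#' genomes, truth, event records, the domain consensus proteins and the
#' seed alignments used to build the domain scoring matrices.
#'
#' @param config a [sim_config()].
#' @return list with `genomes`, `truth`, `events`, `domains`, `seed_msas`
#'   and `config`.
#' @export
simulate_clade <- function(config = sim_config()) {
  anc <- build_ancestor(config)
  ev <- evolve_clade(anc, config)
  c(ev, list(domains = anc$domains, seed_msas = anc$seed_msas,
             config = config))
}

#' Plant a target correlation between ploidy and family copy number
#'
#' Draws ploidies from `ploidy_levels` and copy counts whose Pearson
#' correlation with ploidy targets `target_cor`. With `|target_cor| = 1`
#' the copy count is an exact linear function of ploidy (sample correlation
#' exactly +/-1); otherwise counts are rounded, non-negative draws from a
#' Gaussian model calibrated to the target, so the recovered correlation is
#' stochastic around it.
#'
#' @param n_genomes number of genomes (>= 10).
#' @param target_cor target Pearson correlation in `[-1, 1]`.
#' @param seed RNG seed.
#' @param mean_copies,sd_copies marginal mean / sd of the copy counts.
#' @param ploidy_levels ploidies sampled uniformly.
#' @return data.frame with `genome`, `ploidy`, `copies`; the achieved
#'   sample correlation is in `attr(, "correlation")`.
#' @export
plant_ploidy_correlation <- function(n_genomes, target_cor, seed = 1L,
                                     mean_copies = 12, sd_copies = 7,
                                     ploidy_levels = c(2L, 4L, 6L, 8L)) {
  if (n_genomes < 10L) stop("need at least 10 genomes")
  if (abs(target_cor) > 1) stop("target_cor must be in [-1, 1]")
  set.seed(seed)
  ploidy <- sample(ploidy_levels, n_genomes, replace = TRUE)
  while (length(unique(ploidy)) < 2L)
    ploidy <- sample(ploidy_levels, n_genomes, replace = TRUE)
  if (abs(target_cor) == 1) {
    copies <- if (target_cor > 0) 3L * ploidy
              else 3L * (max(ploidy_levels) + 2L) - 3L * ploidy
  } else {
    z <- as.numeric(scale(ploidy))
    y <- target_cor * z + sqrt(1 - target_cor^2) * stats::rnorm(n_genomes)
    copies <- pmax(0, round(mean_copies + sd_copies * y))
  }
  out <- data.frame(genome = sprintf("s%03d", seq_len(n_genomes)),
                    ploidy = ploidy, copies = as.integer(copies))
  attr(out, "correlation") <- cor(out$ploidy, out$copies)
  out
}
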