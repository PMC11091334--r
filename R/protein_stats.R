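# Protein characteristics: molecular weight, isoelectric point and grand
# average of hydropathy. The pKa set is fixed, versioned data; swap it via
# the `pka` argument, never silently.

# average residue masses (Da)
.aa_mass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
              C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
              H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
              M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
              T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.water_mass <- 18.0153

# Kyte-Doolittle hydropathy indices
.kd_index <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

#' Default pKa set for isoelectric-point estimation
#'
#' Terminal and side-chain pKa values used by [protein_profile()].
#' @return named numeric vector.
#' @export
default_pka <- function() {
  c(Cterm = 3.6, Nterm = 8.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1,
    H = 6.5, K = 10.8, R = 12.5)
}

#' Protein characteristics: length, MW, pI, GRAVY
#'
#' MW is the sum of average residue masses plus one water; GRAVY is the
#' mean Kyte-Doolittle index; pI is the bisection root (tolerance 1e-3 pH)
#' of the Henderson-Hasselbalch net charge using the fixed pKa set of
#' [default_pka()]. Only the 20 canonical residues are accepted.
#'
#' @param protein protein string.
#' @param gene_id optional id carried into the output.
#' @param pka pKa set (named as [default_pka()]).
#' @return data.frame with `gene_id`, `length`, `mw`, `pi`, `gravy`.
#' @export
protein_profile <- function(protein, gene_id = NA_character_,
                            pka = default_pka()) {
  v <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(v), names(.aa_mass))
  if (length(bad))
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  n <- table(factor(v, levels = names(.aa_mass)))
  mw <- sum(as.numeric(n) * .aa_mass) + .water_mass
  gravy <- mean(.kd_index[v])
  charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - pka["Nterm"])) +
      n[["H"]] / (1 + 10^(ph - pka["H"])) +
      n[["K"]] / (1 + 10^(ph - pka["K"])) +
      n[["R"]] / (1 + 10^(ph - pka["R"]))
    neg <- 1 / (1 + 10^(pka["Cterm"] - ph)) +
      n[["D"]] / (1 + 10^(pka["D"] - ph)) +
      n[["E"]] / (1 + 10^(pka["E"] - ph)) +
      n[["C"]] / (1 + 10^(pka["C"] - ph)) +
      n[["Y"]] / (1 + 10^(pka["Y"] - ph))
    unname(pos - neg)
  }
  lo <- 0; hi <- 14
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    if (charge(mid) > 0) lo <- mid else hi <- mid
  }
  data.frame(gene_id = gene_id, length = length(v), mw = mw,
             pi = (lo + hi) / 2, gravy = gravy, stringsAsFactors = FALSE)
}

#' Protein characteristics for every gene of a class
#'
#' @param genome a `fam_genome`.
#' @param assignments classification table (`gene_id`, `class`).
#' @param class class to profile.
#' @return data.frame, one row per gene.
#' @export
protein_profiles <- function(genome, assignments, class = "family") {
  ids <- assignments$gene_id[assignments$class == class &
                               assignments$gene_id %in% names(genome$protein)]
  if (!length(ids))
    return(data.frame(gene_id = character(), length = integer(),
                      mw = numeric(), pi = numeric(), gravy = numeric()))
  do.call(rbind, lapply(ids, function(g)
    protein_profile(genome$protein[[g]], g)))
}
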