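# Shared constants and small helpers.

# canonical 20-residue alphabet; index 21 is reserved for unknown residues
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

DNA4 <- c("A", "C", "G", "T")

#' Round half away from zero at a fixed number of decimals
#'
#' Plain decimal rounding in which ties go up (0.05 -> 0.1), matching how
#' summary percentages are conventionally printed. `base::round` rounds
#' half to even, which differs on exact ties.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # nudge by an epsilon scaled to x so binary representation of exact ties
  # (e.g. 0.15 stored as 0.1499...) still rounds up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

aa_index <- function(protein) {
  # residue codes 1..20, unknowns -> 21
  v <- strsplit(protein, "", fixed = TRUE)[[1]]
  i <- match(v, AA20)
  i[is.na(i)] <- 21L
  i
}

#' @importFrom stats setNames
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

translate_cds <- function(cds) {
  # translate a character CDS (length divisible by 3), drop a terminal stop
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# BLOSUM62 over AA20 plus an unknown row/column scoring 0 against anything
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    b <- env$BLOSUM62[AA20, AA20]
    m <- matrix(0, 21, 21, dimnames = list(c(AA20, "X"), c(AA20, "X")))
    m[1:20, 1:20] <- b
    cache <<- m
    m
  }
})

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1 || is.na(x))
    stop(sprintf("'%s' must be a single non-missing value", name))
  invisible(x)
}
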