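# Run configuration: every threshold of the analysis pipeline in one place,
# serialized as a single JSON document. Defaults are the published parameter
# set of the workflow this package implements.

#' Pipeline run configuration
#'
#' Collects all identification, trimming, pairing and synteny thresholds.
#' Defaults: trimming `gt 0.8, st 0.001, cons 60`; reciprocal-pair identity
#' `> 50`; `top_k = 5` homology hits per query per target genome; block
#' chaining with `min_match = 3`, `max_gap = 25`; community `min_size = 3`.
#'
#' @param score_cutoff minimum Smith-Waterman score for a similarity hit.
#' @param domain_cutoff_frac PSSM bit-score cutoff as a fraction of the
#'   domain consensus self-score.
#' @param gt minimum column coverage (fraction non-gap) kept by trimming.
#' @param st minimum column similarity (modal-residue frequency) kept.
#' @param cons minimum percentage of alignment columns retained.
#' @param identity_threshold reciprocal homolog pair identity threshold (%).
#' @param top_k homology hits kept per query gene per target genome.
#' @param min_match minimum anchors per retained synteny block.
#' @param max_gap maximum rank gap between consecutive anchors.
#' @param min_size minimum nodes per retained synteny community.
#' @param self_synteny include same-genome comparisons when building the
#'   synteny network.
#' @param seed integer RNG seed used by seeded pipeline stages.
#' @return a list of class `fam_config`.
#' @export
run_config <- function(score_cutoff = 50, domain_cutoff_frac = 0.6,
                       gt = 0.8, st = 0.001, cons = 60,
                       identity_threshold = 50,
                       top_k = 5L, min_match = 3L, max_gap = 25L,
                       min_size = 3L, self_synteny = TRUE, seed = 1L) {
  cfg <- list(score_cutoff = as.numeric(score_cutoff),
              domain_cutoff_frac = as.numeric(domain_cutoff_frac),
              gt = as.numeric(gt), st = as.numeric(st),
              cons = as.numeric(cons),
              identity_threshold = as.numeric(identity_threshold),
              top_k = as.integer(top_k), min_match = as.integer(min_match),
              max_gap = as.integer(max_gap), min_size = as.integer(min_size),
              self_synteny = isTRUE(self_synteny), seed = as.integer(seed))
  class(cfg) <- "fam_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (gt < 0 || gt > 1) stop("gt must be in [0, 1]")
    if (st < 0 || st > 1) stop("st must be in [0, 1]")
    if (cons < 0 || cons > 100) stop("cons must be in [0, 100]")
    if (top_k < 1) stop("top_k must be >= 1")
    if (min_match < 2) stop("min_match must be >= 2")
    if (max_gap < 1) stop("max_gap must be >= 1")
    if (min_size < 1) stop("min_size must be >= 1")
  })
  cfg
}

#' Read / write a run configuration as JSON
#'
#' @param path file path.
#' @param cfg a `fam_config`.
#' @return `read_config` returns a validated `fam_config`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
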