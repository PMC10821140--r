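# Packaged reference panels (plain-text fixtures under inst/extdata).

#' Published benchmark metric panel
#'
#' Validity / uniqueness / novelty / success-rate rows reported for common
#' SMILES generative models on the MOSES and GuacaMol distribution-learning
#' benchmarks.  Used to regression-test the success-rate product identity.
#'
#' @return data.frame with columns `dataset`, `model`, `validity`,
#'   `uniqueness`, `novelty`, `success_rate`.
#' @export
load_benchmark_panel <- function() {
  path <- system.file("extdata", "generation_benchmarks.csv", package = "molcontrast")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "generation_benchmarks.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Case-study molecule panel
#'
#' Six pairs of drug-like molecules differing by one ring atom (a generated
#' molecule and its nearest test-set neighbour), with reference Tanimoto
#' similarity and QED / SAScore / LogP values for the generated member.
#' Note: the reference QED and SAScore entries of rows 3 and 4 are
#' transposed in the published source; `qed_expected()` in the test helpers
#' documents the mapping actually used for regression checks.
#'
#' @return data.frame with columns `pair`, `generated`, `reference`,
#'   `tanimoto`, `qed`, `sascore`, `logp`.
#' @export
load_case_study_pairs <- function() {
  path <- system.file("extdata", "case_study_pairs.csv", package = "molcontrast")
  if (!nzchar(path)) path <- file.path("inst", "extdata", "case_study_pairs.csv")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
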