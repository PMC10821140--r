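# Distribution-learning metrics for generated molecule sets, molecular
# property profiling and binary classification metrics.

#' Fingerprint specification
#'
#' Default: hashed circular (Morgan) radius-2 COUNT fingerprint, 2048 bins.
#' Count fingerprints (not plain bit vectors) are the package default because
#' they reproduce the reference Tanimoto values of the case-study panel; see
#' the methods vignette.  `"morgan_bits"` gives the binary variant.
#'
#' @param type `"morgan_count"` or `"morgan_bits"`.
#' @param radius circular radius (default 2).
#' @param nbits hash width (default 2048).
#' @export
fingerprint_spec <- function(type = c("morgan_count", "morgan_bits"),
                             radius = 2L, nbits = 2048L) {
  type <- match.arg(type)
  structure(list(type = type, radius = as.integer(radius), nbits = as.integer(nbits)),
            class = "fingerprint_spec")
}

#' Validity of a generated set
#'
#' Fraction of raw strings accepted by the structure parser.
#'
#' @param generated character vector of raw generated strings.
#' @return fraction in \[0, 1\].
#' @export
validity <- function(generated) {
  if (length(generated) == 0) stop("empty generated set")
  mean(validate_smiles(generated))
}

#' Uniqueness among the first K valid molecules
#'
#' Takes the first `min(k, n_valid)` VALID strings in generation order and
#' returns the fraction of distinct canonical forms among them.  With fewer
#' than `k` valid molecules all valid ones are used (MOSES convention).
#'
#' @param generated character vector of raw generated strings.
#' @param k window size (default 10000).
#' @return fraction in \[0, 1\].
#' @export
unique_at_k <- function(generated, k = 10000L) {
  stopifnot(k >= 1)
  ok <- validate_smiles(generated)
  if (!any(ok)) stop("no valid molecules in generated set")
  taken <- utils::head(generated[ok], k)
  canon <- canonicalize_smiles(taken)
  length(unique(canon)) / length(taken)
}

#' Novelty of generated molecules w.r.t. a training set
#'
#' Fraction of distinct generated canonical forms absent from the training
#' set; both arguments must already be canonicalized.
#'
#' @param generated_unique character vector (or set) of canonical generated
#'   SMILES.
#' @param training character vector of canonical training SMILES.
#' @return fraction in \[0, 1\].
#' @export
novelty <- function(generated_unique, training) {
  gen <- unique(generated_unique)
  if (length(gen) == 0) stop("empty generated set")
  length(setdiff(gen, unique(training))) / length(gen)
}

#' Success rate: product of validity, uniqueness and novelty
#' @param v,u,n fractions in \[0, 1\].
#' @export
success_rate <- function(v, u, n) {
  vals <- c(v, u, n)
  if (any(vals < 0 | vals > 1)) stop("all factors must lie in [0, 1]")
  v * u * n
}

## ---- similarity -------------------------------------------------------------

tanimoto_sparse <- function(f1, f2) {
  common <- intersect(f1$idx, f2$idx)
  inter <- sum(pmin(f1$val[match(common, f1$idx)], f2$val[match(common, f2$idx)]))
  union <- sum(f1$val) + sum(f2$val) - inter
  if (union == 0) return(0)
  inter / union
}

#' Tanimoto similarity between two molecules
#'
#' Generalized Jaccard on the fingerprint vectors: `sum(min) / sum(max)`
#' (which reduces to bit-set Jaccard for binary fingerprints).
#'
#' @param s1,s2 valid SMILES strings.
#' @param fp a [fingerprint_spec()].
#' @return value in \[0, 1\].
#' @export
tanimoto <- function(s1, s2, fp = fingerprint_spec()) {
  fps <- chem_fingerprints(c(s1, s2), fp)
  if (any(vapply(fps, is.null, logical(1)))) stop("invalid SMILES")
  tanimoto_sparse(fps[[1]], fps[[2]])
}

#' Pairwise Tanimoto similarity matrix
#' @param smiles character vector of valid SMILES.
#' @inheritParams tanimoto
#' @export
tanimoto_matrix <- function(smiles, fp = fingerprint_spec()) {
  fps <- chem_fingerprints(smiles, fp)
  if (any(vapply(fps, is.null, logical(1)))) stop("invalid SMILES")
  n <- length(fps)
  M <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        M[i, j] <- M[j, i] <- tanimoto_sparse(fps[[i]], fps[[j]])
      }
    }
  }
  M
}

#' Internal diversity of a molecule set
#'
#' `1 - (mean of T(s1,s2)^p over ALL ordered pairs, self-pairs included)^(1/p)`,
#' exactly as the benchmark formula is written (`1/|S|^2` normalization).
#' A set of identical molecules scores 0.
#'
#' @param smiles character vector of valid SMILES (`|S| >= 1`).
#' @param p power (default 1).
#' @inheritParams tanimoto
#' @export
internal_diversity <- function(smiles, p = 1L, fp = fingerprint_spec()) {
  if (length(smiles) == 0) stop("empty set")
  stopifnot(p >= 1)
  M <- tanimoto_matrix(smiles, fp)
  1 - mean(M^p)^(1 / p)
}

## ---- property profiling -----------------------------------------------------

#' Molecular property profile
#'
#' QED (drug-likeness, Bickerton), synthetic-accessibility score
#' (Ertl-Schuffenhauer, 1 easy .. 10 hard), Crippen LogP, Ertl TPSA
#' (Angstrom^2) and molecular weight (Da), one row per molecule.
#'
#' @param smiles character vector of valid SMILES.
#' @return data.frame of class `property_profile` with columns `smiles`,
#'   `qed`, `sascore`, `logp`, `tpsa`, `mw`.
#' @export
property_profile <- function(smiles) {
  if (length(smiles) == 0) stop("empty molecule set")
  df <- chem_descriptors(smiles)
  class(df) <- c("property_profile", class(df))
  df
}

#' Compare property distributions of two molecule sets
#'
#' Aligned histograms (shared bins) plus mean/sd per property; the usual way
#' to check that generated molecules match the property distribution of the
#' training data.
#'
#' @param gen,ref `property_profile` tables.
#' @param bins number of shared histogram bins.
#' @return list of class `property_comparison`, JSON-serializable.
#' @export
compare_property_distributions <- function(gen, ref, bins = 30L) {
  if (nrow(gen) == 0 || nrow(ref) == 0) stop("empty property profile")
  props <- c("qed", "logp", "sascore", "tpsa", "mw")
  out <- lapply(props, function(p) {
    all_vals <- c(gen[[p]], ref[[p]])
    breaks <- seq(min(all_vals), max(all_vals), length.out = bins + 1L)
    if (breaks[1] == breaks[length(breaks)]) breaks <- breaks[1] + c(-0.5, 0.5)
    hg <- graphics::hist(gen[[p]], breaks = breaks, plot = FALSE)
    hr <- graphics::hist(ref[[p]], breaks = breaks, plot = FALSE)
    list(property = p, breaks = breaks,
         gen_counts = hg$counts, ref_counts = hr$counts,
         gen_mean = mean(gen[[p]]), ref_mean = mean(ref[[p]]),
         gen_sd = stats::sd(gen[[p]]), ref_sd = stats::sd(ref[[p]]),
         mean_difference = mean(gen[[p]]) - mean(ref[[p]]))
  })
  names(out) <- props
  structure(out, class = "property_comparison")
}

#' @export
plot.property_comparison <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (p in names(x)) {
    cmp <- x[[p]]
    mids <- (cmp$breaks[-1] + cmp$breaks[-length(cmp$breaks)]) / 2
    graphics::matplot(mids, cbind(cmp$gen_counts, cmp$ref_counts), type = "l",
                      lty = 1, col = c("firebrick", "steelblue"),
                      xlab = p, ylab = "count", main = p)
  }
  invisible(x)
}

## ---- classification ---------------------------------------------------------

#' Precision, recall and F1 from a confusion table
#'
#' Zero-denominator cases (no predicted positives / no actual positives /
#' P + R = 0) report 0 with an `undefined` flag rather than NaN.
#'
#' @param tp,fp,fn,tn non-negative counts.
#' @return list of class `classification_metrics`.
#' @export
classification_metrics <- function(tp, fp, fn, tn = 0L) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero confusion table")
  undefined <- character(0)
  if (tp + fp > 0) precision <- tp / (tp + fp) else { precision <- 0; undefined <- c(undefined, "precision") }
  if (tp + fn > 0) recall <- tp / (tp + fn) else { recall <- 0; undefined <- c(undefined, "recall") }
  if (precision + recall > 0) {
    f1 <- 2 * precision * recall / (precision + recall)
  } else { f1 <- 0; undefined <- c(undefined, "f1") }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 precision = precision, recall = recall, f1 = f1,
                 undefined = undefined),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("precision %.3f  recall %.3f  F1 %.3f  (tp %d fp %d fn %d tn %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn, x$tn))
  if (length(x$undefined)) cat("  undefined (reported as 0):",
                               paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

## ---- full generation report -------------------------------------------------

#' Score a generated set against a training set
#'
#' Computes the five generation metrics (validity, unique@k, novelty,
#' success rate, internal diversity) and echoes counts and settings.
#' Reported values are also rounded to 3 decimals alongside the raw values.
#'
#' @param generated character vector of raw generated strings (invalid ones
#'   allowed; they count against validity).
#' @param training character vector of training SMILES (canonicalized
#'   internally).
#' @param k unique@k window (default 10000).
#' @param p internal-diversity power (default 1).
#' @param fp a [fingerprint_spec()].
#' @param intdiv_max_n cap on molecules entering the pairwise internal-
#'   diversity computation (subsampled deterministically when exceeded).
#' @return list of class `generation_report`.
#' @export
generation_report <- function(generated, training, k = 10000L, p = 1L,
                              fp = fingerprint_spec(), intdiv_max_n = 500L) {
  if (length(generated) == 0) stop("empty generated set")
  ok <- validate_smiles(generated)
  v <- mean(ok)
  if (!any(ok)) stop("no valid molecules in generated set")
  valid <- generated[ok]
  canon_valid <- canonicalize_smiles(valid)
  taken <- utils::head(canon_valid, k)
  u <- length(unique(taken)) / length(taken)
  train_canon <- unique(chem_canonicalize(training))
  train_canon <- train_canon[!is.na(train_canon)]
  gen_unique <- unique(canon_valid)
  nv <- novelty(gen_unique, train_canon)
  sub <- if (length(gen_unique) > intdiv_max_n) {
    gen_unique[round(seq(1, length(gen_unique), length.out = intdiv_max_n))]
  } else gen_unique
  idiv <- internal_diversity(sub, p = p, fp = fp)
  raw <- list(validity = v, unique_at_k = u, novelty = nv,
              success_rate = success_rate(v, u, nv), intdiv = idiv)
  structure(list(
    metrics = raw,
    rounded = lapply(raw, round, 3L),
    counts = list(generated = length(generated), valid = length(valid),
                  unique_valid = length(gen_unique),
                  training = length(train_canon),
                  intdiv_sample = length(sub)),
    settings = list(k = k, p = p, fp = unclass(fp))
  ), class = "generation_report")
}

#' @export
print.generation_report <- function(x, ...) {
  m <- x$rounded
  cat(sprintf("validity %.3f  unique@%d %.3f  novelty %.3f  success %.3f  intdiv%d %.3f\n",
              m$validity, x$settings$k, m$unique_at_k, m$novelty,
              m$success_rate, x$settings$p, m$intdiv))
  invisible(x)
}

#' Write a generation report as JSON
#' @param report a `generation_report`.
#' @param path output file.
#' @export
write_generation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
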