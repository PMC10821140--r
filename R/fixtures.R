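# Synthetic fixture data: drug-like toy SMILES corpora assembled from a
# scaffold/substituent grammar (a desk-scale stand-in for lead-like
# libraries), planted-signal compound-protein tables, plus the dataset
# filters and random splits used throughout.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Pre-training corpus filter
#'
#' Lead-like window: molecular weight in \[250, 350\] Da, LogP at most 3.5
#' and canonical SMILES length at most 100 characters.
#'
#' @param mw_min,mw_max molecular-weight window (Da).
#' @param logp_max LogP ceiling.
#' @param max_smiles_len maximum canonical SMILES length (characters).
#' @export
filter_spec <- function(mw_min = 250, mw_max = 350, logp_max = 3.5,
                        max_smiles_len = 100L) {
  stopifnot(mw_min < mw_max)
  structure(list(mw_min = mw_min, mw_max = mw_max, logp_max = logp_max,
                 max_smiles_len = as.integer(max_smiles_len)),
            class = "filter_spec")
}

#' Filter molecules to the pre-training window
#'
#' Order-preserving; the length criterion is measured on the canonical
#' writing.
#'
#' @param corpus character vector of valid SMILES or molecule records.
#' @param spec a [filter_spec()].
#' @return filtered molecule-record data.frame (possibly empty).
#' @export
filter_pretraining_candidates <- function(corpus, spec = filter_spec()) {
  records <- as_molecule_records(corpus)
  if (!all(records$is_valid)) stop("corpus contains invalid SMILES")
  if (nrow(records) == 0) return(records)
  d <- chem_descriptors(records$canonical)
  keep <- d$mw >= spec$mw_min & d$mw <= spec$mw_max &
    d$logp <= spec$logp_max & nchar(records$canonical) <= spec$max_smiles_len
  records[keep, , drop = FALSE]
}

#' Random dataset split
#'
#' Seeded shuffle followed by a contiguous partition at the given ratios
#' (19:1 for pre-training, 8:1:1 for CPI).  Partitions are disjoint,
#' exhaustive and reproducible per seed.
#'
#' @param records vector, list or data.frame of records.
#' @param ratios positive split ratios, e.g. `c(19, 1)` or `c(8, 1, 1)`.
#' @param seed integer seed.
#' @return list of partitions, same container type as the input.
#' @export
split_dataset <- function(records, ratios = c(8, 1, 1), seed = 0L) {
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n == 0) stop("no records to split")
  stopifnot(all(ratios > 0))
  if (n < length(ratios)) stop("more splits requested than records available")
  ord <- with_seed(seed, sample(n))
  cuts <- round(cumsum(ratios) / sum(ratios) * n)
  cuts[length(cuts)] <- n
  starts <- c(1L, utils::head(cuts, -1) + 1L)
  lapply(seq_along(ratios), function(i) {
    idx <- if (starts[i] > cuts[i]) integer(0) else ord[starts[i]:cuts[i]]
    if (is.data.frame(records)) records[idx, , drop = FALSE] else records[idx]
  })
}

## ---- toy SMILES corpus ------------------------------------------------------

# Two-slot aromatic cores and substituent pools restricted to C/N/O/F/S/Cl
# with rings of at most 7 atoms; sized so that core + substituents usually
# lands in the 250-350 Da lead-like window.  Every candidate is validated by
# the structure parser and deduplicated on canonical form.
.toy_cores <- c(
  "%sc1ccc(%s)cc1",
  "%sc1ccc(%s)nc1",
  "%sc1ccc(%s)cc1F",
  "%sc1cc(%s)no1",
  "%sc1ccc(%s)s1",
  "%sc1ccc(%s)cc1Cl",
  "%sc1ccc(%s)cc1C",
  "%sc1ccc(%s)cc1OC",
  "%sc1cc(%s)ccc1C",
  "%sc1cc(%s)ccn1"
)

.toy_prefix <- c(
  "C", "CC", "CO", "CCO", "CN", "CC(C)", "OC", "N#CC", "FC(F)(F)", "CS",
  "CC(=O)N", "COC", "ClCC", "CCC", "OCC", "CC(=O)", "NC(=O)", "CCN"
)

.toy_inner <- c(
  "NC(=O)N2CCN(C(=O)C3CCCCC3)CC2",
  "NC(=O)N2CCN(C(C)=O)CC2",
  "C(=O)N2CCN(C(=O)C3CCCC3)CC2",
  "NC(=O)C2CCCCC2",
  "N2CCN(C(=O)c3ccccc3)CC2",
  "C(=O)Nc2ccc(F)cc2",
  "NC(=O)N2CCCC2",
  "C(=O)NC2CCN(C)CC2",
  "OCC(=O)N2CCN(C)CC2",
  "NC(=O)c2cccnc2",
  "N2CCN(S(C)(=O)=O)CC2",
  "NC(=O)N2CCC(N3CCOCC3)CC2",
  "CN(C(=O)Nc2ccccc2)C",
  "C(=O)N2CCC(C(N)=O)CC2",
  "NC(=O)COC2CCCCC2",
  "NC(=O)N2CCOCC2",
  "C(=O)N2CCOCC2",
  "CNC(=O)C2CCCCC2"
)

#' Generate a toy drug-like SMILES corpus
#'
#' Seeded combination of aromatic cores with substituent decorations
#' (amides, ureas, piperazines, ethers) chosen so most products fall in the
#' lead-like 250-350 Da window.  Every output is valid and corpora are
#' distinct by canonical form.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @return molecule-record data.frame with `n` rows.
#' @export
make_toy_smiles_corpus <- function(n, seed = 0L) {
  stopifnot(n >= 1)
  space <- length(.toy_cores) * length(.toy_prefix) * length(.toy_inner)
  if (n > space) {
    stop("cannot reach ", n, " distinct molecules; combinatorial space (",
         space, " raw combinations) exhausted")
  }
  seen <- character(0)
  raws <- character(0)
  attempts <- 0L
  batch <- max(64L, min(5000L, 2L * n))
  k <- 0L
  while (length(raws) < n) {
    attempts <- attempts + 1L
    if (attempts > 200L) {
      stop("cannot reach ", n, " distinct molecules; combinatorial space (",
           space, " raw combinations) exhausted")
    }
    cand <- with_seed(derive_seed(seed, attempts), {
      core <- sample(.toy_cores, batch, replace = TRUE)
      pre <- sample(.toy_prefix, batch, replace = TRUE)
      inner <- sample(.toy_inner, batch, replace = TRUE)
      sprintf(core, pre, inner)
    })
    canon <- chem_canonicalize(cand)
    ok <- !is.na(canon) & !duplicated(canon) & !(canon %in% seen)
    add <- which(ok)
    if (length(add)) {
      take <- utils::head(add, n - length(raws))
      raws <- c(raws, canon[take])
      seen <- c(seen, canon[take])
    }
    k <- k + 1L
  }
  data.frame(raw = raws, canonical = raws, is_valid = TRUE,
             stringsAsFactors = FALSE)
}

## ---- planted-signal CPI data ------------------------------------------------

.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# background residues follow natural (Swiss-Prot-like) frequencies, so rare
# residues (W, C) are genuinely rare; the planted motif is deliberately rich
# in them, keeping it statistically detectable at desk-scale sample sizes
.aa_freqs <- c(A = 7.8, C = 1.4, D = 5.3, E = 6.3, F = 3.9, G = 7.2, H = 2.3,
               I = 5.3, K = 5.9, L = 9.1, M = 2.3, N = 4.3, P = 5.2, Q = 3.9,
               R = 5.3, S = 6.8, T = 5.9, V = 6.6, W = 1.1, Y = 3.2)

.cpi_signal <- list(substructure = "F", motif = "WCWHWC")

random_protein <- function(len) {
  paste(sample(names(.aa_freqs), len, replace = TRUE, prob = .aa_freqs),
        collapse = "")
}

insert_motif <- function(protein, motif) {
  pos <- sample(nchar(protein) - nchar(motif) + 1L, 1L)
  paste0(substr(protein, 1, pos - 1L), motif,
         substr(protein, pos + nchar(motif), nchar(protein)))
}

#' Generate a balanced planted-signal CPI dataset
#'
#' Label 1 iff the molecule contains the designated substructure token (a
#' fluorine atom) AND the protein contains a designated k-mer motif; a
#' learnable conjunction rather than a lookup table, so generalization (not
#' memorization) is what a classifier must achieve.  Negatives are spread
#' evenly over the three non-signal combinations.  Proteins are seeded
#' random strings over the 20-letter alphabet with the motif inserted where
#' required.
#'
#' @param n number of records (balanced: n/2 positive).
#' @param seed integer seed.
#' @param noise label-flip probability (default 0).
#' @param protein_len protein sequence length (default 50).
#' @return data.frame with columns `smiles`, `sequence`, `label`; the
#'   planted signal definition is attached as attribute `"signal"`.
#' @export
make_toy_cpi_dataset <- function(n, seed = 0L, noise = 0, protein_len = 50L) {
  if (n < 2) stop("n too small for balanced labels")
  n_pos <- n %/% 2L
  n_neg <- n - n_pos
  corpus <- make_toy_smiles_corpus(max(64L, min(400L, n)), seed = derive_seed(seed, 11L))
  has_f <- grepl("F", corpus$canonical, fixed = TRUE)
  mols_f <- corpus$canonical[has_f]
  mols_nf <- corpus$canonical[!has_f]
  if (!length(mols_f) || !length(mols_nf)) stop("toy corpus lacks signal diversity")

  with_seed(derive_seed(seed, 12L), {
    neg_kind <- rep_len(1:3, n_neg)  # 1: F only, 2: motif only, 3: neither
    smiles <- c(sample(mols_f, n_pos, replace = TRUE),
                ifelse(neg_kind == 1L, sample(mols_f, n_neg, replace = TRUE),
                       sample(mols_nf, n_neg, replace = TRUE)))
    prots <- vapply(seq_len(n), function(i) random_protein(protein_len), character(1))
    motif_in <- c(rep(TRUE, n_pos), neg_kind == 2L)
    prots[motif_in] <- vapply(prots[motif_in], insert_motif, character(1),
                              motif = .cpi_signal$motif)
    label <- c(rep(1L, n_pos), rep(0L, n_neg))
    if (noise > 0) {
      flip <- stats::runif(n) < noise
      label[flip] <- 1L - label[flip]
    }
    ord <- sample(n)
    df <- data.frame(smiles = smiles[ord], sequence = prots[ord],
                     label = label[ord], stringsAsFactors = FALSE)
    attr(df, "signal") <- .cpi_signal
    df
  })
}

#' Rule-based detector of the planted CPI signal
#'
#' Predicts 1 iff both the substructure token and the protein motif are
#' present; on noise-free data this detector scores F1 = 1 by construction,
#' which bounds what a trained classifier can be expected to achieve.
#'
#' @param dataset a CPI data.frame (`smiles`, `sequence`, `label`).
#' @param signal list with `substructure` and `motif`; defaults to the
#'   generator's planted signal.
#' @return integer vector of predictions.
#' @export
cpi_signal_oracle <- function(dataset, signal = NULL) {
  signal <- signal %||% attr(dataset, "signal") %||% .cpi_signal
  as.integer(grepl(signal$substructure, dataset$smiles, fixed = TRUE) &
               grepl(signal$motif, dataset$sequence, fixed = TRUE))
}

## ---- CPI file format --------------------------------------------------------

#' Read / write CPI tables (TSV with smiles, sequence, label)
#'
#' The reader validates both alphabets: SMILES must parse and sequences must
#' use the 20-letter amino-acid alphabet; labels must be 0/1.
#'
#' @param path TSV file path.
#' @export
read_cpi_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("smiles", "sequence", "label")
  if (!all(need %in% names(df))) stop("CPI table must have columns smiles, sequence, label")
  df$smiles <- gsub("[[:space:]]+", "", df$smiles)
  if (!all(validate_smiles(df$smiles))) stop("CPI table contains invalid SMILES")
  if (any(grepl(sprintf("[^%s]", paste(.aa_alphabet, collapse = "")), df$sequence)) ||
      any(!nzchar(df$sequence))) {
    stop("CPI table contains sequences outside the amino-acid alphabet")
  }
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0/1")
  df[need]
}

#' @rdname read_cpi_tsv
#' @param dataset CPI data.frame to write.
#' @export
write_cpi_tsv <- function(dataset, path) {
  utils::write.table(dataset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
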