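#' Validate SMILES strings
#'
#' A string is valid when the chemical structure parser (RDKit) accepts it,
#' i.e. atom valences and aromatic-ring consistency check out.  Malformed
#' input returns `FALSE`, never an error.
#'
#' @param smiles character vector of candidate SMILES strings.
#' @return logical vector, one flag per input.
#' @export
#' @examples \dontrun{validate_smiles(c("CCO", "C1CC", "xyz"))}
validate_smiles <- function(smiles) {
  if (length(smiles) == 0) return(logical(0))
  !is.na(chem_canonicalize(smiles))
}

#' Canonicalize SMILES strings
#'
#' Maps every writing of a molecular graph to its unique canonical writing.
#' Canonical-form string equality is the molecule-identity predicate used
#' throughout the package (uniqueness, novelty, round-trip checks).
#'
#' @param smiles character vector of valid SMILES strings.
#' @return character vector of canonical SMILES.
#' @export
canonicalize_smiles <- function(smiles) {
  out <- chem_canonicalize(smiles)
  if (anyNA(out)) {
    stop("invalid SMILES: ", paste(utils::head(smiles[is.na(out)], 3), collapse = ", "))
  }
  out
}

#' Enumerate randomized SMILES writings of one molecule
#'
#' Randomizes the atom order (hence the DFS traversal start) before writing,
#' producing alternative valid writings of the same molecular graph.  Seeded:
#' the same `(smiles, n, seed)` always returns the same list.
#'
#' @param smiles a single valid SMILES string.
#' @param n number of writings to draw (with replacement from the writing
#'   space; duplicates possible for small molecules).
#' @param seed integer seed.
#' @return character vector of length `n`; every element canonicalizes back
#'   to `canonicalize_smiles(smiles)`.
#' @export
enumerate_smiles <- function(smiles, n, seed = 0L) {
  stopifnot(length(smiles) == 1, n >= 1)
  out <- chem_enumerate(smiles, n = n, seed = seed)[[1]]
  if (is.null(out)) stop("invalid SMILES: ", smiles)
  out
}

#' Draw a contrastive view pair
#'
#' Two independently enumerated writings of the same molecule: the positive
#' pair of the contrastive objective.  The two writings may coincide for
#' small molecules; they are kept, not resampled.
#'
#' @param smiles a single valid SMILES string.
#' @param seed integer seed.
#' @return a `view_pair`: list with `x1`, `x2`, `source_canonical`.
#' @export
sample_view_pair <- function(smiles, seed = 0L) {
  sample_view_pairs(smiles, seed = seed)[[1]]
}

#' @rdname sample_view_pair
#' @param smiles_vec character vector of valid SMILES (batched variant).
#' @export
sample_view_pairs <- function(smiles_vec, seed = 0L) {
  smiles_vec <- as.character(smiles_vec)
  writings <- chem_enumerate(smiles_vec, n = 2L, seed = seed)
  canon <- chem_canonicalize(smiles_vec)
  bad <- vapply(writings, is.null, logical(1))
  if (any(bad)) stop("invalid SMILES: ", paste(utils::head(smiles_vec[bad], 3), collapse = ", "))
  lapply(seq_along(smiles_vec), function(i) {
    structure(
      list(x1 = writings[[i]][1], x2 = writings[[i]][2], source_canonical = canon[i]),
      class = "view_pair"
    )
  })
}

#' Build a molecule-record table
#'
#' The unit of every corpus: raw writing, canonical form and validity flag.
#' Invalid strings are retained with `is_valid = FALSE` and `canonical = NA`.
#'
#' @param raw character vector of SMILES strings.
#' @return data.frame with columns `raw`, `canonical`, `is_valid`.
#' @export
molecule_records <- function(raw) {
  raw <- trimws(as.character(raw))
  canonical <- chem_canonicalize(raw)
  data.frame(raw = raw, canonical = canonical, is_valid = !is.na(canonical),
             stringsAsFactors = FALSE)
}

as_molecule_records <- function(x) {
  if (is.data.frame(x) && all(c("raw", "canonical", "is_valid") %in% names(x))) return(x)
  molecule_records(x)
}

## ---- tokenizer -------------------------------------------------------------

# bracket atoms, two-letter elements and %nn ring closures are single tokens;
# everything else is one character
.smiles_token_re <- "\\[[^]]*\\]|Br|Cl|%[0-9]{2}|."

#' Split a SMILES string into tokens
#' @param smiles character vector.
#' @return list of character vectors.
#' @export
tokenize_smiles_string <- function(smiles) {
  regmatches(smiles, gregexpr(.smiles_token_re, smiles))
}

#' Token vocabulary
#'
#' Dense-id token map with four reserved specials at the front:
#' pad = 0, bos = 1, eos = 2, unk = 3.  Non-special tokens are appended in
#' first-occurrence order over the corpus, so the map is deterministic given
#' corpus order.
#'
#' @param corpus character vector of valid SMILES strings (or any strings if
#'   `tokenizer` is supplied).
#' @param tokenizer function mapping a character vector to a list of token
#'   vectors; defaults to the SMILES tokenizer.
#' @return a `token_vocabulary`.
#' @export
build_vocab <- function(corpus, tokenizer = tokenize_smiles_string) {
  if (length(corpus) == 0) stop("empty corpus")
  toks <- unlist(tokenizer(as.character(corpus)), use.names = FALSE)
  specials <- c("<pad>", "<bos>", "<eos>", "<unk>")
  body <- unique(toks)
  body <- setdiff(body, specials)
  structure(
    list(tokens = c(specials, body),
         pad = 0L, bos = 1L, eos = 2L, unk = 3L,
         size = length(body) + 4L),
    class = "token_vocabulary"
  )
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat("<token_vocabulary> size", x$size, "\n")
  cat("  specials: pad=0 bos=1 eos=2 unk=3\n")
  cat("  tokens:", paste(utils::head(x$tokens[-(1:4)], 12), collapse = " "),
      if (x$size > 16) "..." else "", "\n")
  invisible(x)
}

vocab_id <- function(vocab, tokens) {
  id <- match(tokens, vocab$tokens) - 1L
  id[is.na(id)] <- vocab$unk
  id
}

#' Encode a string as token ids
#'
#' Produces `bos + body + eos`; tokens absent from the vocabulary map to unk.
#'
#' @param smiles single string.
#' @param vocab a `token_vocabulary`.
#' @param max_len maximum sequence length including bos/eos (default 100,
#'   the pre-training corpus filter length).
#' @param tokenizer token splitter, defaults to the SMILES tokenizer.
#' @return a `tokenized_sequence`: list with integer `ids` and `length`.
#' @export
tokenize <- function(smiles, vocab, max_len = 100L, tokenizer = tokenize_smiles_string) {
  stopifnot(inherits(vocab, "token_vocabulary"), length(smiles) == 1)
  body <- vocab_id(vocab, tokenizer(smiles)[[1]])
  ids <- c(vocab$bos, body, vocab$eos)
  if (length(ids) > max_len) {
    stop("sequence of ", length(ids), " tokens exceeds max length ", max_len)
  }
  structure(list(ids = as.integer(ids), length = length(ids)),
            class = "tokenized_sequence")
}

#' Decode token ids back to a string
#'
#' Concatenates token strings between bos and the first eos; specials are
#' dropped and anything after the first eos is ignored.
#'
#' @param x a `tokenized_sequence` or an integer id vector.
#' @param vocab a `token_vocabulary`.
#' @return single string.
#' @export
detokenize <- function(x, vocab) {
  ids <- if (inherits(x, "tokenized_sequence")) x$ids else as.integer(x)
  if (any(ids < 0L | ids >= vocab$size)) stop("token id out of range for vocabulary")
  eos_at <- which(ids == vocab$eos)
  if (length(eos_at)) ids <- ids[seq_len(eos_at[1] - 1L)]
  ids <- ids[!(ids %in% c(vocab$pad, vocab$bos, vocab$eos, vocab$unk))]
  paste(vocab$tokens[ids + 1L], collapse = "")
}

## ---- file formats ----------------------------------------------------------

#' Read / write .smi files
#'
#' One SMILES per line; an optional whitespace-separated name column is
#' ignored on read.  Whitespace inside a field is stripped.
#'
#' @param path file path.
#' @return character vector of SMILES strings.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1L)
}

#' @rdname read_smi
#' @param smiles character vector to write.
#' @export
write_smi <- function(smiles, path) {
  writeLines(as.character(smiles), path)
  invisible(path)
}

#' Read SMILES from a CSV column
#' @param path CSV file path.
#' @param column column name holding the SMILES (default "smiles").
#' @return character vector with internal whitespace stripped.
#' @export
read_smiles_csv <- function(path, column = "smiles") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!column %in% names(df)) stop("no column '", column, "' in ", path)
  gsub("[[:space:]]+", "", as.character(df[[column]]))
}

#' Serialize a vocabulary as plain text (one token per line, line = id + 1)
#' @param vocab a `token_vocabulary`.
#' @param path file path.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  tokens <- readLines(path, warn = FALSE)
  stopifnot(identical(tokens[1:4], c("<pad>", "<bos>", "<eos>", "<unk>")))
  structure(
    list(tokens = tokens, pad = 0L, bos = 1L, eos = 2L, unk = 3L,
         size = length(tokens)),
    class = "token_vocabulary"
  )
}
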