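#' @keywords internal
"_PACKAGE"

# Batched subprocess bridge to RDKit.  One JSON request per call; results for
# pure functions of a SMILES string (canonicalization, descriptors) are
# memoised in a session-level environment so repeated metric calls do not
# respawn Python.

.chem_cache <- new.env(parent = emptyenv())

chem_python <- function() {
  py <- Sys.getenv("MOLCONTRAST_PYTHON", unset = Sys.which("python"))
  if (!nzchar(py)) {
    stop("no 'python' executable found on PATH; RDKit bridge unavailable")
  }
  py
}

chem_tool_path <- function() {
  path <- system.file("python", "chem_tool.py", package = "molcontrast")
  if (!nzchar(path)) {
    # during development (pkgload) inst/ is on the source path
    path <- file.path("inst", "python", "chem_tool.py")
  }
  if (!file.exists(path)) stop("chem_tool.py not found")
  path
}

chem_call <- function(op, payload = list()) {
  req <- c(list(op = op), payload)
  json <- jsonlite::toJSON(req, auto_unbox = TRUE, digits = NA, null = "null")
  out <- suppressWarnings(system2(
    chem_python(), shQuote(chem_tool_path()),
    input = json, stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status")
  resp <- tryCatch(
    jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE),
    error = function(e) NULL
  )
  if (!is.null(resp$error)) stop("RDKit bridge error: ", resp$error)
  if (!is.null(status) && status != 0 || is.null(resp)) {
    stop("RDKit bridge failed (exit status ", status %||% "?", ")")
  }
  resp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical form, NA_character_ for invalid strings; memoised
chem_canonicalize <- function(smiles) {
  smiles <- as.character(smiles)
  key <- paste0("c\x01", smiles)
  hit <- vapply(key, function(k) !is.null(.chem_cache[[k]]), logical(1))
  if (any(!hit)) {
    todo <- unique(smiles[!hit])
    resp <- chem_call("canonicalize", list(smiles = as.list(todo)))
    for (i in seq_along(todo)) {
      v <- resp$canonical[[i]]
      .chem_cache[[paste0("c\x01", todo[i])]] <- if (is.null(v)) NA_character_ else v
    }
  }
  vapply(key, function(k) .chem_cache[[k]], character(1), USE.NAMES = FALSE)
}

chem_enumerate <- function(smiles, n, seed) {
  resp <- chem_call("enumerate", list(
    smiles = as.list(as.character(smiles)), n = as.integer(n), seed = as.integer(seed)
  ))
  lapply(resp$writings, function(w) {
    if (is.null(w)) NULL else vapply(w, identity, character(1))
  })
}

chem_descriptors <- function(smiles) {
  smiles <- as.character(smiles)
  key <- paste0("d\x01", smiles)
  hit <- vapply(key, function(k) !is.null(.chem_cache[[k]]), logical(1))
  if (any(!hit)) {
    todo <- unique(smiles[!hit])
    resp <- chem_call("descriptors", list(smiles = as.list(todo)))
    for (i in seq_along(todo)) {
      row <- resp$rows[[i]]
      .chem_cache[[paste0("d\x01", todo[i])]] <-
        if (is.null(row)) list(NA) else row
    }
  }
  rows <- lapply(key, function(k) .chem_cache[[k]])
  bad <- vapply(rows, function(r) identical(r, list(NA)), logical(1))
  if (any(bad)) {
    stop("invalid SMILES passed to descriptor computation: ",
         paste(utils::head(smiles[bad], 3), collapse = ", "))
  }
  data.frame(
    smiles = smiles,
    qed = vapply(rows, function(r) r$qed, numeric(1)),
    sascore = vapply(rows, function(r) r$sascore, numeric(1)),
    logp = vapply(rows, function(r) r$logp, numeric(1)),
    tpsa = vapply(rows, function(r) r$tpsa, numeric(1)),
    mw = vapply(rows, function(r) r$mw, numeric(1)),
    stringsAsFactors = FALSE
  )
}

chem_fingerprints <- function(smiles, fp = fingerprint_spec()) {
  resp <- chem_call("fingerprints", list(
    smiles = as.list(as.character(smiles)),
    fp = unclass(fp)
  ))
  lapply(resp$fps, function(f) {
    if (is.null(f)) return(NULL)
    list(
      idx = vapply(f$idx, as.integer, integer(1)),
      val = vapply(f$val, as.numeric, numeric(1))
    )
  })
}

# full pairwise Tanimoto matrix computed by RDKit itself -- the independent
# oracle used in tests; the package's own path is tanimoto()/tanimoto_matrix()
chem_tanimoto_oracle <- function(smiles, fp = fingerprint_spec()) {
  resp <- chem_call("tanimoto_oracle", list(
    smiles = as.list(as.character(smiles)), fp = unclass(fp)
  ))
  n <- length(smiles)
  mat <- matrix(0, n, n)
  for (i in seq_len(n)) mat[i, ] <- vapply(resp$matrix[[i]], as.numeric, numeric(1))
  mat
}
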