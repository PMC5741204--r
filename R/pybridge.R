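# Subprocess bridge to the bundled RDKit helper. One python call handles a
# whole batch of structures; results are memoised per session so repeated
# parses of the same string never pay the interpreter start-up cost again.

.sempfinder_env <- new.env(parent = emptyenv())

.python_bin <- function() {
  cached <- .sempfinder_env$python_bin
  if (!is.null(cached)) return(cached)
  for (cand in c("python", "python3")) {
    path <- Sys.which(cand)
    if (nzchar(path)) {
      ok <- suppressWarnings(system2(path, c("-c", shQuote("import rdkit")),
                                     stdout = FALSE, stderr = FALSE))
      if (identical(ok, 0L)) {
        .sempfinder_env$python_bin <- path
        return(path)
      }
    }
  }
  stop("no python interpreter with rdkit found on PATH ",
       "(required for structure parsing)", call. = FALSE)
}

.molparse_script <- function() {
  path <- system.file("python", "molparse.py", package = "sempfinder")
  if (!nzchar(path)) stop("bundled molparse.py not found", call. = FALSE)
  path
}

.parse_cache_key <- function(text, dialect, normalize) {
  paste0(dialect, "\r", normalize, "\r", text)
}

#' Batch-parse structures through the RDKit helper
#'
#' Internal workhorse behind [parse_structure()] and [normalize_mol()].
#' Returns a list parallel to `texts`; each element is either a parsed graph
#' (list with `atoms`/`bonds` data frames) or a condition-style list with an
#' `error` string.
#'
#' @param texts character vector of structure strings.
#' @param dialects character vector, `"InChI"` or `"SMILES"`, recycled.
#' @param normalize logical scalar; apply the normalization pipeline in the
#'   helper (largest fragment, charge removal, aromatic perception, H removal).
#' @keywords internal
#' @noRd
.py_parse_batch <- function(texts, dialects, normalize = FALSE) {
  stopifnot(length(texts) >= 1L)
  dialects <- rep_len(dialects, length(texts))
  keys <- .parse_cache_key(texts, dialects, normalize)
  cache <- .sempfinder_env$parse_cache
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    .sempfinder_env$parse_cache <- cache
  }
  out <- vector("list", length(texts))
  todo <- which(vapply(keys, function(k) is.null(cache[[k]]), logical(1)))
  if (length(todo)) {
    jobs <- lapply(seq_along(todo), function(i) {
      j <- todo[i]
      list(id = i, text = texts[j], dialect = dialects[j],
           normalize = normalize)
    })
    infile <- tempfile(fileext = ".json")
    on.exit(unlink(infile), add = TRUE)
    jsonlite::write_json(jobs, infile, auto_unbox = TRUE)
    raw <- suppressWarnings(system2(
      .python_bin(), c(shQuote(.molparse_script())),
      stdin = infile, stdout = TRUE, stderr = NULL
    ))
    status <- attr(raw, "status")
    if (!is.null(status) && status != 0L) {
      stop("structure-parsing helper failed (exit ", status, ")",
           call. = FALSE)
    }
    res <- jsonlite::fromJSON(paste(raw, collapse = ""),
                              simplifyDataFrame = FALSE,
                              simplifyVector = FALSE)
    for (r in res) {
      j <- todo[[r$id]]
      cache[[keys[j]]] <- r
    }
  }
  for (i in seq_along(texts)) out[[i]] <- cache[[keys[i]]]
  out
}
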