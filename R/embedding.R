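# Pluggable per-residue embedding backends and the positional encoding of a
# variant: the rows of the wild-type and mutated sequence embeddings at the
# variant position, concatenated across two backends.

#' Construct an embedding backend
#'
#' A backend is a deterministic function from a residue sequence to an
#' L x D real matrix, together with its name, output dimension and maximum
#' accepted input length. Sequences longer than `max_length` are windowed
#' by [extract_window()] before the backend sees them. Real protein
#' language-model adapters can be plugged in behind this same contract;
#' nothing in the package requires them.
#'
#' @param name backend name (used in error messages and cache keys).
#' @param dim per-residue embedding dimension D.
#' @param embed function(sequence) returning an `nchar(sequence)` x D matrix.
#' @param max_length maximum sequence length the backend accepts
#'   (`Inf` for unbounded).
#' @return object of class `embedding_backend`.
#' @export
embedding_backend <- function(name, dim, embed, max_length = Inf) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is_count(dim)) sv_stop("savanno_config", "backend dim must be a positive integer")
  stopifnot(is.function(embed))
  structure(list(name = name, dim = as.integer(dim), embed = embed,
                 max_length = max_length),
            class = "embedding_backend")
}

#' @export
print.embedding_backend <- function(x, ...) {
  cat(sprintf("<embedding_backend> %s (dim %d, max_length %s)\n",
              x$name, x$dim,
              if (is.finite(x$max_length)) x$max_length else "unbounded"))
  invisible(x)
}

#' Extract the backend input window around a variant position
#'
#' Sequences within the backend's length limit pass through unchanged.
#' Over-limit sequences are reduced to a fixed-size window centred on the
#' variant position; near the termini the window is shifted (not truncated)
#' so its full length is preserved whenever the sequence allows it.
#'
#' @param sequence residue sequence.
#' @param position 1-based variant position.
#' @param max_length backend length limit.
#' @param window window size used when the limit is exceeded (default 201).
#' @return list with `sequence` (the possibly windowed subsequence) and
#'   `position` (the variant's 1-based index inside it).
#' @export
extract_window <- function(sequence, position, max_length, window = 201L) {
  L <- nchar(sequence)
  if (!is_count(position) || position > L) {
    sv_stop("savanno_position", "position %s out of range 1..%d", position, L)
  }
  position <- as.integer(position)
  if (L <= max_length) {
    return(list(sequence = sequence, position = position))
  }
  w <- as.integer(min(window, max_length, L))
  half <- (w - 1L) %/% 2L
  start <- max(1L, min(position - half, L - w + 1L))
  list(sequence = substr(sequence, start, start + w - 1L),
       position = position - start + 1L)
}

#' Deterministic mock embedding backend
#'
#' Produces pseudo-random but fully reproducible per-residue vectors: the
#' matrix is a pure function of (salt, backend name, sequence content), so
#' equal sequences give equal matrices while changing any single residue
#' changes every row — mimicking the context sensitivity of a protein
#' language model. Values are bounded in [-1, 1].
#'
#' @param name backend name.
#' @param dim embedding dimension.
#' @param seed_salt string salt separating independent mock backends.
#' @param max_length optional length limit (default unbounded).
#' @return an `embedding_backend`.
#' @export
mock_backend <- function(name, dim, seed_salt = "mock", max_length = Inf) {
  force(name); force(dim); force(seed_salt)
  embed <- function(sequence) {
    L <- nchar(sequence)
    seed <- str_seed(paste("mockemb", seed_salt, name, dim, sequence, sep = "\r"))
    with_seed(seed, matrix(runif(L * dim, -1, 1), nrow = L, ncol = dim))
  }
  embedding_backend(name, dim, embed, max_length = max_length)
}

#' Memoising wrapper around a backend
#'
#' Caches embedding matrices keyed by (backend name, subsequence content)
#' so repeated encodings of variants on the same protein do not recompute.
#'
#' @param backend an `embedding_backend`.
#' @return an `embedding_backend` with the same contract.
#' @export
cached_backend <- function(backend) {
  cache <- new.env(parent = emptyenv())
  inner <- backend$embed
  embed <- function(sequence) {
    key <- sequence
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- inner(sequence)
    cache[[key]] <- m
    m
  }
  embedding_backend(backend$name, backend$dim, embed, max_length = backend$max_length)
}

#' Backend over precomputed per-protein embedding matrices
#'
#' Reads tab-separated matrix files `<dir>/<accession>.<name>.tsv` (one row
#' per residue, no header) written by an external embedding run. Because
#' the matrices are keyed by accession, this backend embeds only full
#' wild-type sequences registered at construction; it is the bulk-import
#' path for real language-model embeddings.
#'
#' @param name backend name (also the file suffix).
#' @param dim embedding dimension.
#' @param dir directory holding the matrix files.
#' @param proteins list of [protein_record()] mapping sequences back to
#'   accessions.
#' @param max_length optional length limit.
#' @return an `embedding_backend`.
#' @export
precomputed_backend <- function(name, dim, dir, proteins, max_length = Inf) {
  proteins <- protein_map(proteins)
  seq_to_acc <- stats::setNames(names(proteins),
                                vapply(proteins, function(p) p$sequence, character(1)))
  embed <- function(sequence) {
    acc <- unname(seq_to_acc[sequence])
    if (is.na(acc)) {
      sv_stop("savanno_missing_input",
              "precomputed backend %s: sequence not registered (only full wild-type sequences are available)",
              name)
    }
    path <- file.path(dir, paste0(acc, ".", name, ".tsv"))
    if (!file.exists(path)) {
      sv_stop("savanno_missing_input", "precomputed backend %s: no matrix file %s", name, path)
    }
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != nchar(sequence) || ncol(m) != dim) {
      sv_stop("savanno_schema", "matrix %s: expected %d x %d, found %d x %d",
              path, nchar(sequence), dim, nrow(m), ncol(m))
    }
    m
  }
  embedding_backend(name, dim, embed, max_length = max_length)
}

# Embed with shape validation; errors carry the backend name.
embed_checked <- function(backend, sequence, context = "") {
  m <- tryCatch(backend$embed(sequence), error = function(e) {
    sv_stop("savanno_backend", "backend %s failed%s: %s", backend$name,
            if (nzchar(context)) paste0(" (", context, ")") else "",
            conditionMessage(e))
  })
  if (!is.matrix(m) || nrow(m) != nchar(sequence) || ncol(m) != backend$dim) {
    sv_stop("savanno_backend",
            "backend %s returned wrong shape for a %d-residue input (got %s x %s, want %d x %d)",
            backend$name, nchar(sequence),
            if (is.matrix(m)) nrow(m) else "?", if (is.matrix(m)) ncol(m) else "?",
            nchar(sequence), backend$dim)
  }
  m
}

#' Positional encoding of a variant
#'
#' Applies the single substitution to the wild-type sequence, embeds both
#' sequences with each backend (windowing long sequences per that backend's
#' limit), and concatenates the embedding rows at the variant position in
#' the fixed block order: variant then wild-type for backend one, variant
#' then wild-type for backend two. With the default dimensions (1280 and
#' 1024) the result has 2x1280 + 2x1024 = 4608 components.
#'
#' @param wt_sequence wild-type residue sequence.
#' @param variant one-row `sav_table` or list with `position`, `wt`, `mut`.
#' @param backends list of two `embedding_backend` objects, ordered.
#' @param window window size for over-limit sequences (default 201).
#' @return numeric vector of length `2*dim1 + 2*dim2` with a `layout`
#'   attribute describing the blocks (class `positional_encoding`).
#' @export
encode_variant_positional <- function(wt_sequence, variant, backends, window = 201L) {
  stopifnot(length(backends) == 2L)
  pos <- as.integer(variant$position)
  wt <- as.character(variant$wt)
  mut <- as.character(variant$mut)
  if (pos < 1L || pos > nchar(wt_sequence)) {
    sv_stop("savanno_position", "variant position %d out of range 1..%d",
            pos, nchar(wt_sequence))
  }
  if (substr(wt_sequence, pos, pos) != wt) {
    sv_stop("savanno_wt_mismatch",
            "wild-type mismatch at position %d: sequence has %s, variant says %s",
            pos, substr(wt_sequence, pos, pos), wt)
  }
  if (wt == mut) sv_stop("savanno_schema", "wt and mut residues are identical")
  mut_sequence <- wt_sequence
  substr(mut_sequence, pos, pos) <- mut

  blocks <- list()
  layout <- list()
  for (b in backends) {
    win_mut <- extract_window(mut_sequence, pos, b$max_length, window)
    win_wt <- extract_window(wt_sequence, pos, b$max_length, window)
    m_mut <- embed_checked(b, win_mut$sequence, "variant sequence")
    m_wt <- embed_checked(b, win_wt$sequence, "wild-type sequence")
    blocks[[paste0(b$name, "_variant")]] <- as.numeric(m_mut[win_mut$position, ])
    blocks[[paste0(b$name, "_wildtype")]] <- as.numeric(m_wt[win_wt$position, ])
  }
  values <- unlist(blocks, use.names = FALSE)
  structure(values,
            layout = data.frame(block = names(blocks),
                                dim = vapply(blocks, length, integer(1)),
                                row.names = NULL, stringsAsFactors = FALSE),
            class = "positional_encoding")
}
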