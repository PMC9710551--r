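# Internal helpers: deterministic hashing, RNG isolation, small-file IO.

# Amino-acid alphabet. X marks an ambiguous residue: tolerated in sequences
# (flagged) but variants at X positions are excluded during curation.
AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Xaa = "X"
)

#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash over the UTF-8 code points, reduced modulo
#' 2^31 - 2 and shifted to 1..2^31-2 so it is always a valid `set.seed()`
#' argument. Used to derive reproducible RNG streams from string keys
#' (e.g. backend salt + sequence content).
#'
#' @param x character scalar.
#' @return integer scalar in 1..2147483646.
#' @keywords internal
str_seed <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  codes <- utf8ToInt(x)
  h <- 0
  m <- 2147483646 # 2^31 - 2; products stay < 2^53 so doubles are exact
  for (cc in codes) h <- (h * 131 + cc) %% m
  as.integer(h + 1)
}

# Runs `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards, so deterministic generators behave as
# pure functions and never perturb user-level randomness.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a dependent sub-seed from a base seed and a stream label; stays
# below 2^31 so it is always a legal set.seed() argument.
sub_seed <- function(seed, stream) {
  str_seed(paste0("seed:", seed, "|", stream))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

sv_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "savanno_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

sv_log <- function(level = "INFO", fmt, ...) {
  lev <- getOption("savanno.log_level", "INFO")
  ranks <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)
  if (ranks[[level]] >= ranks[[lev]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}

read_tsv_strict <- function(path, expected = NULL) {
  if (!file.exists(path)) sv_stop("savanno_missing_input", "input file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  if (!is.null(expected) && !all(expected %in% names(df))) {
    sv_stop("savanno_schema",
            "file %s: expected columns {%s}, found {%s}",
            path, paste(expected, collapse = ", "),
            paste(names(df), collapse = ", "))
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
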