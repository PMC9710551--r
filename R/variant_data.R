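# Domain types and curation rules for SAV (single amino acid variant)
# catalogues. Variants arrive as a pre-converted tab-separated dialect of
# HUMSAVAR/ClinVar exports; native formats are out of scope.

#' Create a protein record
#'
#' A protein record is the unit of clustering and annotation: an accession,
#' an upper-case residue sequence over the 20 canonical amino acids (X is
#' tolerated and flagged), and per-sub-ontology GO term sets.
#'
#' @param accession character scalar, unique identifier.
#' @param sequence character scalar, residue sequence (length >= 1).
#' @param go_terms named list with character vectors `MF`, `CC`, `BP`
#'   (missing entries are filled with empty sets).
#' @return an object of class `protein_record`.
#' @export
protein_record <- function(accession, sequence, go_terms = list()) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) {
    sv_stop("savanno_parse", "protein %s: empty sequence", accession)
  }
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(AA_CANONICAL, "X"))
  if (length(bad)) {
    sv_stop("savanno_parse", "protein %s: non amino-acid characters: %s",
            accession, paste(bad, collapse = ""))
  }
  gt <- list(MF = character(0), CC = character(0), BP = character(0))
  for (ns in intersect(names(go_terms), names(gt))) {
    gt[[ns]] <- unique(as.character(go_terms[[ns]]))
  }
  structure(
    list(accession = accession, sequence = sequence, go_terms = gt,
         has_ambiguous = grepl("X", sequence, fixed = TRUE)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa%s; GO: %d MF / %d CC / %d BP)\n",
              x$accession, nchar(x$sequence),
              if (x$has_ambiguous) ", contains X" else "",
              length(x$go_terms$MF), length(x$go_terms$CC),
              length(x$go_terms$BP)))
  invisible(x)
}

# Named list of protein_record keyed by accession; duplicate accessions are
# a structural error because the accession is the dataset-wide key.
protein_map <- function(proteins) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  acc <- vapply(proteins, function(p) p$accession, character(1))
  if (anyDuplicated(acc)) {
    sv_stop("savanno_parse", "duplicate accession(s): %s",
            paste(unique(acc[duplicated(acc)]), collapse = ", "))
  }
  names(proteins) <- acc
  proteins
}

VARIANT_COLS <- c("accession", "position", "wt", "mut", "label",
                  "somatic", "disease_ids", "source")
VARIANT_LABELS <- c("PLP", "BLB", "US")
VARIANT_SOURCES <- c("HUMSAVAR", "CLINVAR", "OTHER")

# Canonical empty variant table.
empty_sav_table <- function() {
  structure(
    data.frame(accession = character(0), position = integer(0),
               wt = character(0), mut = character(0), label = character(0),
               somatic = logical(0), disease_ids = character(0),
               source = character(0), stringsAsFactors = FALSE),
    class = c("sav_table", "data.frame")
  )
}

as_sav_table <- function(df) {
  stopifnot(all(VARIANT_COLS %in% names(df)))
  df <- df[VARIANT_COLS]
  df$position <- as.integer(df$position)
  df$somatic <- as.logical(df$somatic)
  rownames(df) <- NULL
  class(df) <- c("sav_table", "data.frame")
  df
}

# "A123V" -> c(wt, pos, mut); also accepts HGVS protein form "p.Ala123Val".
parse_substitution <- function(token) {
  token <- trimws(token)
  if (grepl("^p\\.", token)) {
    m <- regmatches(token, regexec("^p\\.([A-Z][a-z]{2})(\\d+)([A-Z][a-z]{2})$", token))[[1]]
    if (length(m) != 4L || !all(m[c(2, 4)] %in% names(AA_THREE_TO_ONE))) {
      sv_stop("savanno_parse", "cannot parse substitution token '%s'", token)
    }
    return(list(wt = AA_THREE_TO_ONE[[m[2]]], position = as.integer(m[3]),
                mut = AA_THREE_TO_ONE[[m[4]]]))
  }
  m <- regmatches(token, regexec("^([A-Z])(\\d+)([A-Z])$", token))[[1]]
  if (length(m) != 4L) {
    sv_stop("savanno_parse", "cannot parse substitution token '%s'", token)
  }
  list(wt = m[2], position = as.integer(m[3]), mut = m[4])
}

format_substitution <- function(wt, position, mut) {
  paste0(wt, position, mut)
}

#' Read protein sequences from a FASTA file
#'
#' The first whitespace-delimited token of each header is taken as the
#' accession. Sequences are upper-cased; input order is preserved.
#'
#' @param path path to a FASTA file.
#' @return list of [protein_record()] (GO term sets empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) sv_stop("savanno_missing_input", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(list())
  # Pre-scan for diagnostics with line numbers; Biostrings does the parse.
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    sv_stop("savanno_parse", "%s: line %d: expected FASTA header", path, nonblank[1])
  }
  hdr <- nonblank[startsWith(trimws(lines[nonblank]), ">")]
  for (i in seq_along(hdr)) {
    h <- trimws(lines[hdr[i]])
    if (!nzchar(sub("^>", "", strsplit(h, "\\s+")[[1]][1]))) {
      sv_stop("savanno_parse", "%s: line %d: malformed header '%s'", path, hdr[i], h)
    }
    to <- if (i < length(hdr)) hdr[i + 1] - 1L else length(lines)
    body <- paste(trimws(lines[setdiff(seq(hdr[i] + 1L, length.out = max(0L, to - hdr[i])), hdr)]), collapse = "")
    if (!nzchar(body)) {
      sv_stop("savanno_parse", "%s: line %d: entry with empty sequence", path, hdr[i])
    }
  }
  seqs <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  out <- lapply(seq_along(seqs), function(i) {
    protein_record(acc[i], as.character(seqs[[i]]))
  })
  protein_map(out)
}

#' Write protein records to FASTA
#'
#' @param proteins list of [protein_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(vapply(proteins, function(p) p$sequence, character(1)))
  names(set) <- vapply(proteins, function(p) p$accession, character(1))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a variant table
#'
#' Parses the tab-separated dialect with header
#' `accession substitution label somatic disease_ids source`. The
#' substitution token may be compact (`A123V`) or HGVS protein
#' (`p.Ala123Val`); both parse to the same record. Every variant is
#' cross-checked against the protein sequence: a wild-type mismatch or an
#' out-of-range position raises a distinct error naming the offending row.
#' Records whose accession is absent from `proteins` are, by default,
#' excluded and logged (reason `no_sequence`) rather than raised, because
#' large catalogue merges routinely contain orphans.
#'
#' @param path path to the variant table.
#' @param proteins named list of [protein_record()] keyed by accession.
#' @param on_missing `"exclude"` (default) or `"error"` for unknown accessions.
#' @return a `sav_table` data frame with columns
#'   `accession, position, wt, mut, label, somatic, disease_ids, source`;
#'   excluded orphan rows are attached as `attr(, "excluded")`.
#' @export
read_variant_table <- function(path, proteins, on_missing = c("exclude", "error")) {
  on_missing <- match.arg(on_missing)
  proteins <- protein_map(proteins)
  df <- read_tsv_strict(path, expected = c("accession", "substitution", "label",
                                           "somatic", "disease_ids", "source"))
  excluded <- data.frame(accession = character(0), substitution = character(0),
                         reason = character(0), stringsAsFactors = FALSE)
  if (!nrow(df)) {
    out <- empty_sav_table()
    attr(out, "excluded") <- excluded
    return(out)
  }
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    acc <- as.character(df$accession[i])
    sub <- parse_substitution(as.character(df$substitution[i]))
    lab <- toupper(trimws(as.character(df$label[i])))
    if (!lab %in% VARIANT_LABELS) {
      sv_stop("savanno_schema", "%s row %d: unknown label '%s'", path, i, lab)
    }
    src <- toupper(trimws(as.character(df$source[i])))
    if (!src %in% VARIANT_SOURCES) src <- "OTHER"
    if (!acc %in% names(proteins)) {
      if (on_missing == "error") {
        sv_stop("savanno_unknown_accession", "%s row %d: unknown accession '%s'", path, i, acc)
      }
      excluded <- rbind(excluded, data.frame(
        accession = acc, substitution = as.character(df$substitution[i]),
        reason = "no_sequence", stringsAsFactors = FALSE))
      next
    }
    seqc <- proteins[[acc]]$sequence
    if (sub$position < 1L || sub$position > nchar(seqc)) {
      sv_stop("savanno_position", "%s row %d: position %d out of range for %s (length %d)",
              path, i, sub$position, acc, nchar(seqc))
    }
    have <- substr(seqc, sub$position, sub$position)
    if (have != sub$wt) {
      sv_stop("savanno_wt_mismatch",
              "%s row %d: wild-type mismatch for %s position %d (table says %s, sequence has %s)",
              path, i, acc, sub$position, sub$wt, have)
    }
    if (sub$wt == sub$mut) {
      sv_stop("savanno_schema", "%s row %d: synonymous token '%s' (wt == mut)",
              path, i, as.character(df$substitution[i]))
    }
    rows[[i]] <- data.frame(
      accession = acc, position = sub$position, wt = sub$wt, mut = sub$mut,
      label = lab, somatic = isTRUE(as.logical(df$somatic[i])),
      disease_ids = trimws(as.character(df$disease_ids[i])),
      source = src, stringsAsFactors = FALSE)
  }
  out <- as_sav_table(do.call(rbind, c(list(empty_sav_table()), rows[!vapply(rows, is.null, logical(1))])))
  attr(out, "excluded") <- excluded
  out
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]; positions are rendered 1-based in the
#' compact substitution dialect.
#'
#' @param variants a `sav_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  df <- data.frame(
    accession = variants$accession,
    substitution = format_substitution(variants$wt, variants$position, variants$mut),
    label = variants$label,
    somatic = tolower(as.character(variants$somatic)),
    disease_ids = variants$disease_ids,
    source = variants$source,
    stringsAsFactors = FALSE)
  write_tsv(df, path)
}

variant_key <- function(variants) {
  paste(variants$accession, variants$position, variants$wt, variants$mut, sep = "|")
}

#' Curate a merged variant catalogue
#'
#' Applies the dataset-construction rules for merged clinical catalogues:
#' benign (B/LB) records are kept; pathogenic (P/LP) records are kept only
#' when they carry at least one disease identifier (OMIM/MONDO); uncertain
#' (US) and somatic records are dropped; any unique
#' (accession, position, wt, mut) key asserted both P/LP and B/LB across
#' sources is dropped entirely as a conflict; concordant duplicates collapse
#' to one record. Variants located on an ambiguous (X) residue are dropped,
#' as are records lacking a sequence. Every exclusion is logged with a
#' reason, never raised.
#'
#' Rule order per key: `no_sequence`, `ambiguous_residue`, `somatic`,
#' `uncertain`, `conflict` (evaluated on the surviving germline P/B
#' assertions), `no_disease_id`, then `duplicate` collapsing.
#'
#' @param variants a `sav_table` (possibly with duplicates across sources).
#' @param proteins named list of [protein_record()]; used for the
#'   `no_sequence` and `ambiguous_residue` checks.
#' @return an object of class `curated_dataset`: list with `proteins`,
#'   `variants` (a `sav_table` with labels in {PLP, BLB} only) and
#'   `exclusions` (data frame `accession, substitution, reason`).
#' @export
curate <- function(variants, proteins) {
  proteins <- protein_map(proteins)
  n <- nrow(variants)
  if (n == 0L) {
    return(structure(list(proteins = proteins, variants = empty_sav_table(),
                          exclusions = data.frame(accession = character(0),
                                                  substitution = character(0),
                                                  reason = character(0),
                                                  stringsAsFactors = FALSE)),
                     class = "curated_dataset"))
  }
  reason <- rep(NA_character_, n)
  subtok <- format_substitution(variants$wt, variants$position, variants$mut)

  known <- variants$accession %in% names(proteins)
  reason[!known] <- "no_sequence"

  at_x <- rep(FALSE, n)
  ki <- which(known)
  if (length(ki)) {
    at_x[ki] <- unname(mapply(function(a, p) {
      substr(proteins[[a]]$sequence, p, p) == "X"
    }, variants$accession[ki], variants$position[ki]))
  }
  reason[is.na(reason) & at_x] <- "ambiguous_residue"

  reason[is.na(reason) & variants$somatic] <- "somatic"
  reason[is.na(reason) & variants$label == "US"] <- "uncertain"

  # Conflicts among surviving germline P/B assertions for the same SAV key.
  alive <- is.na(reason)
  key <- variant_key(variants)
  lab_by_key <- tapply(variants$label[alive], key[alive], function(l) length(unique(l)))
  conflicted <- names(lab_by_key)[lab_by_key > 1L]
  reason[alive & key %in% conflicted] <- "conflict"

  no_dis <- is.na(reason) & variants$label == "PLP" & !nzchar(variants$disease_ids)
  reason[no_dis] <- "no_disease_id"

  idx <- which(is.na(reason))
  reason[idx[duplicated(key[idx])]] <- "duplicate"

  kept <- as_sav_table(variants[is.na(reason), , drop = FALSE])
  excl <- data.frame(accession = variants$accession[!is.na(reason)],
                     substitution = subtok[!is.na(reason)],
                     reason = reason[!is.na(reason)],
                     stringsAsFactors = FALSE)
  structure(list(proteins = proteins, variants = kept, exclusions = excl),
            class = "curated_dataset")
}

#' @export
print.curated_dataset <- function(x, ...) {
  cat(sprintf("<curated_dataset> %d proteins, %d variants (%d P/LP, %d B/LB), %d exclusions\n",
              length(x$proteins), nrow(x$variants),
              sum(x$variants$label == "PLP"), sum(x$variants$label == "BLB"),
              nrow(x$exclusions)))
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    cat("  exclusions by reason:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an exclusion log
#'
#' @param exclusions data frame `accession, substitution, reason` as
#'   produced by [curate()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(exclusions, path) {
  write_tsv(exclusions, path)
}
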