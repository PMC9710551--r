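# GO ontology handling: a subset OBO parser, ancestor closure over
# is_a/part_of, redundancy removal by leaf filtering, and per-sub-ontology
# averaging of precomputed term vectors into a fixed-length function
# encoding.

GO_NAMESPACES <- c(molecular_function = "MF", cellular_component = "CC",
                   biological_process = "BP")

#' Parse a Gene Ontology OBO file (subset)
#'
#' Reads the stanza fields `id`, `namespace`, `is_a`, `relationship:
#' part_of`, `is_obsolete` and `alt_id`; everything else is ignored.
#' Obsolete terms are retained but flagged. Cross-namespace parent edges
#' are dropped with a warning log; a cyclic input is an error reporting one
#' offending cycle.
#'
#' @param path path to an OBO file.
#' @return object of class `go_dag`: list with `namespace` (named MF/CC/BP
#'   vector), `obsolete` (named logical), `parents_isa` / `parents_partof`
#'   (named lists of parent ids) and `alt` (alt_id -> primary id map).
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) sv_stop("savanno_missing_input", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <<- cur
  }
  for (ln in lines) {
    ln <- sub("\\s*!.*$", "", trimws(ln)) # strip OBO comments
    if (ln == "[Term]") { flush(); cur <- list(isa = character(0), partof = character(0), alt = character(0), obsolete = FALSE); in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
    else if (startsWith(ln, "namespace:")) cur$ns <- trimws(sub("^namespace:", "", ln))
    else if (startsWith(ln, "is_a:")) cur$isa <- c(cur$isa, trimws(sub("^is_a:", "", ln)))
    else if (startsWith(ln, "relationship:")) {
      rel <- strsplit(trimws(sub("^relationship:", "", ln)), "\\s+")[[1]]
      if (length(rel) >= 2L && rel[1] == "part_of") cur$partof <- c(cur$partof, rel[2])
    }
    else if (startsWith(ln, "alt_id:")) cur$alt <- c(cur$alt, trimws(sub("^alt_id:", "", ln)))
    else if (startsWith(ln, "is_obsolete:")) cur$obsolete <- identical(trimws(sub("^is_obsolete:", "", ln)), "true")
  }
  flush()
  if (!length(terms)) {
    return(structure(list(namespace = character(0), obsolete = logical(0),
                          parents_isa = list(), parents_partof = list(),
                          alt = character(0)),
                     class = "go_dag"))
  }
  ids <- names(terms)
  ns <- vapply(terms, function(t) {
    v <- GO_NAMESPACES[t$ns %||% ""]
    if (is.na(v)) NA_character_ else unname(v)
  }, character(1))
  if (anyNA(ns)) {
    sv_stop("savanno_parse", "OBO term(s) without a recognised namespace: %s",
            paste(ids[is.na(ns)], collapse = ", "))
  }
  obsolete <- vapply(terms, function(t) t$obsolete, logical(1))
  keep_same_ns <- function(id, parents) {
    known <- parents[parents %in% ids]
    dropped <- known[ns[known] != ns[[id]]]
    if (length(dropped)) {
      sv_log("WARN", "dropping cross-namespace edge(s) %s -> %s", id,
             paste(dropped, collapse = ","))
    }
    known[ns[known] == ns[[id]]]
  }
  parents_isa <- lapply(ids, function(id) keep_same_ns(id, terms[[id]]$isa))
  parents_partof <- lapply(ids, function(id) keep_same_ns(id, terms[[id]]$partof))
  names(parents_isa) <- names(parents_partof) <- ids
  alt <- unlist(lapply(ids, function(id) {
    a <- terms[[id]]$alt
    stats::setNames(rep(id, length(a)), a)
  }))
  alt <- if (is.null(alt)) character(0) else alt
  dag <- structure(list(namespace = ns, obsolete = obsolete,
                        parents_isa = parents_isa,
                        parents_partof = parents_partof, alt = alt),
                   class = "go_dag")
  cyc <- find_cycle(dag)
  if (!is.null(cyc)) {
    sv_stop("savanno_parse", "OBO graph is cyclic: %s", paste(cyc, collapse = " -> "))
  }
  dag
}

# Kahn topological check; returns one cycle (vector of ids) or NULL.
find_cycle <- function(dag) {
  ids <- names(dag$namespace)
  par <- lapply(ids, function(id) union(dag$parents_isa[[id]], dag$parents_partof[[id]]))
  names(par) <- ids
  indeg <- stats::setNames(integer(length(ids)), ids) # edges child -> parent
  for (id in ids) for (p in par[[id]]) indeg[[p]] <- indeg[[p]] + 1L
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (p in par[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk parents from an unresolved node until a repeat closes the cycle
  v <- ids[indeg > 0L][1L]
  path <- v
  repeat {
    nxt <- intersect(par[[v]], ids[indeg > 0L])[1L]
    if (nxt %in% path) return(c(path[which(path == nxt):length(path)], nxt))
    path <- c(path, nxt)
    v <- nxt
  }
}

#' Resolve a GO identifier to its primary id
#'
#' @param dag a `go_dag`.
#' @param id GO identifier (primary or alt_id).
#' @return the primary id, or `NA_character_` when unknown.
#' @export
resolve_term <- function(dag, id) {
  if (id %in% names(dag$namespace)) return(id)
  if (id %in% names(dag$alt)) return(unname(dag$alt[[id]]))
  NA_character_
}

#' Ancestor set of a GO term
#'
#' Transitive closure over `is_a` (and, by default, `part_of`) parent
#' edges; the term itself is not included.
#'
#' @param dag a `go_dag`.
#' @param id primary GO identifier.
#' @param use_part_of include `part_of` edges (default TRUE).
#' @return character vector of ancestor ids.
#' @export
go_ancestors <- function(dag, id, use_part_of = TRUE) {
  out <- character(0)
  queue <- id
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    par <- dag$parents_isa[[v]]
    if (use_part_of) par <- union(par, dag$parents_partof[[v]])
    new <- setdiff(par, out)
    out <- c(out, new)
    queue <- c(queue, new)
  }
  setdiff(out, id)
}

#' Remove redundant (ancestor) annotations, keeping only leaf terms
#'
#' Drops every annotated term that is a proper ancestor of another term in
#' the same set; each namespace is handled independently (edges never cross
#' namespaces, so filtering the pooled set is equivalent). Unknown terms
#' are excluded with a warning log, not raised.
#'
#' @param terms character vector of GO ids (primary or alt).
#' @param dag a `go_dag`.
#' @param use_part_of include `part_of` edges in ancestor closure.
#' @return character vector of retained leaf terms (primary ids, input
#'   order preserved).
#' @export
leaf_filter <- function(terms, dag, use_part_of = TRUE) {
  if (!length(terms)) return(character(0))
  resolved <- vapply(terms, function(t) resolve_term(dag, t), character(1))
  unknown <- terms[is.na(resolved)]
  if (length(unknown)) {
    sv_log("WARN", "leaf_filter: unknown GO term(s) excluded: %s",
           paste(unknown, collapse = ", "))
  }
  resolved <- unique(resolved[!is.na(resolved)])
  if (!length(resolved)) return(character(0))
  anc <- unique(unlist(lapply(resolved, go_ancestors, dag = dag,
                              use_part_of = use_part_of)))
  resolved[!resolved %in% anc]
}

#' Read a GO term-vector table
#'
#' Tab-separated `go_id v1 ... vK` with header; all rows must share one
#' vector length (default tables use K = 200).
#'
#' @param path path to the table.
#' @return numeric matrix, one row per term, rownames = GO ids
#'   (class `term_vector_table`).
#' @export
read_term_vectors <- function(path) {
  df <- read_tsv_strict(path)
  if (names(df)[1] != "go_id") {
    sv_stop("savanno_schema", "%s: first column must be 'go_id'", path)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$go_id
  colnames(m) <- NULL
  if (anyNA(m)) sv_stop("savanno_schema", "%s: non-numeric vector entries", path)
  class(m) <- c("term_vector_table", class(m))
  m
}

#' Write a GO term-vector table
#'
#' @param table numeric matrix with GO ids as rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_vectors <- function(table, path) {
  df <- data.frame(go_id = rownames(table), unclass(table),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("go_id", paste0("v", seq_len(ncol(table))))
  write_tsv(df, path)
}

#' Averaged, leaf-filtered GO function encoding of a protein
#'
#' Per sub-ontology (MF, CC, BP in that fixed order): resolve the protein's
#' annotated terms, drop obsolete terms, keep only leaf terms, drop terms
#' missing from the vector table (logged), and average the remaining term
#' vectors. A sub-ontology with no usable term contributes a zero block, so
#' the layout is constant: 3 x K components (600 with the default K = 200).
#'
#' @param protein a [protein_record()] with `go_terms` filled in.
#' @param dag a `go_dag`.
#' @param table a `term_vector_table`.
#' @param use_part_of include `part_of` edges in leaf determination.
#' @return numeric vector of length `3 * ncol(table)` with a `layout`
#'   attribute (class `function_encoding`).
#' @export
encode_go <- function(protein, dag, table, use_part_of = TRUE) {
  k <- ncol(table)
  blocks <- lapply(c("MF", "CC", "BP"), function(nsname) {
    terms <- protein$go_terms[[nsname]]
    leaves <- leaf_filter(terms, dag, use_part_of = use_part_of)
    leaves <- leaves[!dag$obsolete[leaves]]
    missing <- leaves[!leaves %in% rownames(table)]
    if (length(missing)) {
      sv_log("WARN", "encode_go(%s/%s): term(s) missing from vector table: %s",
             protein$accession, nsname, paste(missing, collapse = ", "))
    }
    leaves <- setdiff(leaves, missing)
    if (!length(leaves)) return(numeric(k))
    colMeans(table[leaves, , drop = FALSE])
  })
  values <- unlist(blocks, use.names = FALSE)
  structure(values,
            layout = data.frame(block = c("MF", "CC", "BP"),
                                dim = rep(k, 3L), stringsAsFactors = FALSE),
            class = "function_encoding")
}

#' Read a protein -> GO annotation file
#'
#' Tab-separated `accession go_id`; `go_id` may be a single id or a
#' semicolon-separated list. Terms are assigned to the sub-ontology the
#' ontology declares for them; unknown terms are dropped with a warning.
#'
#' @param path path to the annotation table.
#' @param proteins named list of [protein_record()].
#' @param dag a `go_dag`.
#' @return the protein list with `go_terms` populated.
#' @export
read_annotations <- function(path, proteins, dag) {
  proteins <- protein_map(proteins)
  df <- read_tsv_strict(path, expected = c("accession", "go_id"))
  for (i in seq_len(nrow(df))) {
    acc <- as.character(df$accession[i])
    if (!acc %in% names(proteins)) {
      sv_log("WARN", "annotations: unknown accession %s (skipped)", acc)
      next
    }
    terms <- trimws(strsplit(as.character(df$go_id[i]), ";")[[1]])
    terms <- terms[nzchar(terms)]
    for (t in terms) {
      pt <- resolve_term(dag, t)
      if (is.na(pt)) {
        sv_log("WARN", "annotations: unknown GO term %s for %s (skipped)", t, acc)
        next
      }
      nsname <- unname(dag$namespace[[pt]])
      proteins[[acc]]$go_terms[[nsname]] <-
        unique(c(proteins[[acc]]$go_terms[[nsname]], pt))
    }
  }
  proteins
}

#' Write annotations of a protein set
#'
#' One row per protein with a semicolon-joined term list (proteins with no
#' annotation are omitted).
#'
#' @param proteins named list of [protein_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(proteins, path) {
  rows <- lapply(proteins, function(p) {
    terms <- unlist(p$go_terms, use.names = FALSE)
    if (!length(terms)) return(NULL)
    data.frame(accession = p$accession, go_id = paste(terms, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df)) df <- data.frame(accession = character(0), go_id = character(0))
  write_tsv(df, path)
}

#' Serialize a `go_dag` back to OBO
#'
#' Writes the subset of fields the parser reads; round-tripping a parsed
#' ontology reproduces the same DAG.
#'
#' @param dag a `go_dag`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  inv_ns <- stats::setNames(names(GO_NAMESPACES), GO_NAMESPACES)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (id in names(dag$namespace)) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("namespace: ", inv_ns[[dag$namespace[[id]]]]), con)
    for (a in names(dag$alt)[dag$alt == id]) writeLines(paste0("alt_id: ", a), con)
    for (p in dag$parents_isa[[id]]) writeLines(paste0("is_a: ", p), con)
    for (p in dag$parents_partof[[id]]) writeLines(paste0("relationship: part_of ", p), con)
    if (isTRUE(dag$obsolete[[id]])) writeLines("is_obsolete: true", con)
  }
  invisible(path)
}
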