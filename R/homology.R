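# Homology-aware partitioning: similarity edges, connected-component
# clustering and balanced blind/CV fold assignment. The goal is that no
# pair of proteins sharing detectable sequence similarity ever straddles a
# training/testing boundary.

#' Build pairwise similarity edges between proteins
#'
#' Aligns every unordered pair with a Smith-Waterman local alignment
#' (BLOSUM62, gap open 11 / extend 1) and emits an edge when both
#' thresholds are met. Identity is matches over aligned columns (gap
#' columns included); coverage is the aligned span of the shorter sequence
#' over the shorter sequence's length. Intended for test/toy scale (up to a
#' few hundred sequences); real-scale workflows supply a precomputed edge
#' file from a dedicated clustering tool instead (see [read_edge_file()]).
#'
#' @param proteins list of [protein_record()].
#' @param min_identity minimum identity fraction (default 0.25).
#' @param min_coverage minimum coverage fraction (default 0.40).
#' @return data frame `accession_a, accession_b, identity, coverage`
#'   (class `similarity_edges`), one row per retained pair.
#' @export
build_edges <- function(proteins, min_identity = 0.25, min_coverage = 0.40) {
  proteins <- protein_map(proteins)
  acc <- names(proteins)
  n <- length(acc)
  rows <- list()
  if (n >= 2L) {
    aas <- lapply(proteins, function(p) Biostrings::AAString(chartr("X", "A", p$sequence)))
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        aln <- Biostrings::pairwiseAlignment(
          aas[[i]], aas[[j]], type = "local",
          substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
        cols <- Biostrings::nchar(aln) # aligned columns, gaps included
        if (cols == 0L) next
        ident <- Biostrings::nmatch(aln) / cols
        len_i <- nchar(proteins[[i]]$sequence)
        len_j <- nchar(proteins[[j]]$sequence)
        # span of the alignment in the shorter sequence's coordinates
        span <- if (len_i <= len_j) {
          Biostrings::width(Biostrings::pattern(aln))
        } else {
          Biostrings::width(Biostrings::subject(aln))
        }
        cov <- span / min(len_i, len_j)
        if (ident >= min_identity && cov >= min_coverage) {
          rows[[length(rows) + 1L]] <- data.frame(
            accession_a = acc[i], accession_b = acc[j],
            identity = ident, coverage = cov, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession_a = character(0), accession_b = character(0),
               identity = numeric(0), coverage = numeric(0),
               stringsAsFactors = FALSE)
  class(out) <- c("similarity_edges", "data.frame")
  out
}

#' Read a precomputed similarity edge file
#'
#' Tab-separated `accession_a accession_b identity coverage`, the interface
#' for plugging in any external clustering tool's pairwise output.
#'
#' @param path path to the edge file.
#' @param min_identity,min_coverage rows below either threshold are dropped.
#' @return a `similarity_edges` data frame.
#' @export
read_edge_file <- function(path, min_identity = 0.25, min_coverage = 0.40) {
  df <- read_tsv_strict(path, expected = c("accession_a", "accession_b",
                                           "identity", "coverage"))
  df$identity <- as.numeric(df$identity)
  df$coverage <- as.numeric(df$coverage)
  df <- df[df$identity >= min_identity & df$coverage >= min_coverage, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("similarity_edges", "data.frame")
  df
}

#' Connected-component clustering of the similarity graph
#'
#' Union-find over the retained edges: if two proteins are each similar to a
#' third, all three land in one cluster. Isolated proteins become singleton
#' clusters. Cluster ids are assigned deterministically: components are
#' numbered 1, 2, ... by the lexicographically smallest member accession.
#'
#' @param accessions character vector of all accessions to partition.
#' @param edges a `similarity_edges` data frame (possibly empty).
#' @return named integer vector mapping accession to cluster id
#'   (class `cluster_assignment`).
#' @export
connected_components <- function(accessions, edges) {
  accessions <- as.character(accessions)
  if (anyDuplicated(accessions)) {
    sv_stop("savanno_schema", "duplicate accessions in clustering input")
  }
  idx <- seq_along(accessions)
  names(idx) <- accessions
  unknown <- setdiff(unique(c(edges$accession_a, edges$accession_b)), accessions)
  if (length(unknown)) {
    sv_stop("savanno_schema", "edge references unknown accession(s): %s",
            paste(unknown, collapse = ", "))
  }
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]] # path halving
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    ia <- idx[edges$accession_a]
    ib <- idx[edges$accession_b]
    for (k in seq_along(ia)) {
      ra <- find(ia[k]); rb <- find(ib[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(idx, find, integer(1))
  # deterministic ids: order components by smallest member accession
  smallest <- tapply(accessions, root, min)
  ord <- order(smallest)
  id_of_root <- integer(max(root))
  id_of_root[as.integer(names(smallest))[ord]] <- seq_along(ord)
  out <- id_of_root[root]
  names(out) <- accessions
  class(out) <- "cluster_assignment"
  out
}

#' Assign clusters to a blind set and k cross-validation folds
#'
#' Greedy balanced bin packing at cluster granularity: clusters are sorted
#' by decreasing variant count (ties shuffled by `seed`), the blind bin is
#' filled first up to `blind_fraction` of all variants, and every remaining
#' cluster goes to the fold that minimises a deviation score over the
#' running total variant count and P/LP count. Clusters are never split, so
#' a giant cluster may force imbalance; the imbalance is reported, not
#' hidden.
#'
#' @param clusters a `cluster_assignment` from [connected_components()].
#' @param variants a `sav_table`; every accession must be clustered.
#' @param blind_fraction target fraction of variants held out entirely
#'   (default 0.10; 0.20 is a supported alternative).
#' @param k number of CV folds (default 10).
#' @param seed integer seed controlling tie shuffling.
#' @return object of class `fold_assignment`: list with `fold` (named
#'   character vector cluster_id -> "BLIND" or "F1".."Fk"), `by_accession`
#'   (named character vector), `seed`, and a `summary` data frame of per-bin
#'   variant and P/LP counts.
#' @export
assign_folds <- function(clusters, variants, blind_fraction = 0.10, k = 10L, seed = 1L) {
  if (!is_count(k) || k < 2) sv_stop("savanno_config", "k must be an integer >= 2")
  if (!is.numeric(blind_fraction) || blind_fraction <= 0 || blind_fraction >= 0.5) {
    sv_stop("savanno_config", "blind_fraction must lie in (0, 0.5)")
  }
  missing_acc <- setdiff(unique(variants$accession), names(clusters))
  if (length(missing_acc)) {
    sv_stop("savanno_schema", "variants reference unclustered accession(s): %s",
            paste(missing_acc, collapse = ", "))
  }
  cl_of_var <- unclass(clusters)[variants$accession]
  all_ids <- sort(unique(unclass(clusters)))
  nvar <- table(factor(cl_of_var, levels = all_ids))
  npos <- table(factor(cl_of_var[variants$label == "PLP"], levels = all_ids))
  total <- nrow(variants)
  total_pos <- sum(variants$label == "PLP")

  ord <- with_seed(sub_seed(seed, "assign_folds"), {
    # canonical order first so input permutation cannot change the result
    jitter <- runif(length(all_ids))
    order(-as.integer(nvar), jitter)
  })
  ids <- all_ids[ord]

  bins <- c("BLIND", paste0("F", seq_len(k)))
  bin_var <- stats::setNames(numeric(k + 1L), bins)
  bin_pos <- bin_var
  fold_of <- stats::setNames(rep(NA_character_, length(all_ids)), all_ids)

  blind_target <- blind_fraction * total
  fold_target <- (total - blind_target) / k
  pos_frac <- if (total > 0) total_pos / total else 0

  for (id in ids) {
    v <- as.numeric(nvar[as.character(id)])
    p <- as.numeric(npos[as.character(id)])
    if (bin_var[["BLIND"]] + v <= blind_target ||
        (bin_var[["BLIND"]] < blind_target &&
         abs(bin_var[["BLIND"]] + v - blind_target) < abs(bin_var[["BLIND"]] - blind_target))) {
      pick <- "BLIND"
    } else {
      # least-loaded-first packing; the label term breaks near-ties toward
      # the bin whose P/LP share stays closest to the global fraction
      scores <- vapply(bins[-1L], function(b) {
        sz <- bin_var[[b]] + v
        pp <- abs((bin_pos[[b]] + p) - pos_frac * sz)
        sz + pp
      }, numeric(1))
      pick <- bins[-1L][which.min(scores)]
    }
    bin_var[[pick]] <- bin_var[[pick]] + v
    bin_pos[[pick]] <- bin_pos[[pick]] + p
    fold_of[[as.character(id)]] <- pick
  }

  by_acc <- fold_of[as.character(unclass(clusters))]
  names(by_acc) <- names(clusters)
  summary <- data.frame(bin = bins,
                        n_variants = as.numeric(bin_var),
                        n_plp = as.numeric(bin_pos),
                        stringsAsFactors = FALSE)
  structure(list(fold = fold_of, by_accession = by_acc, seed = seed,
                 k = as.integer(k), blind_fraction = blind_fraction,
                 summary = summary),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("<fold_assignment> %d clusters -> BLIND + %d folds (seed %d)\n",
              length(x$fold), x$k, x$seed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Audit a fold assignment for homology leakage
#'
#' Returns the (expected-empty) set of similarity edges whose endpoints sit
#' in different bins. Because folds are assigned at cluster granularity and
#' clusters are edge-closed, any crossing edge indicates a corrupted
#' assignment.
#'
#' @param folds a `fold_assignment`.
#' @param edges a `similarity_edges` data frame.
#' @param clusters the `cluster_assignment` the folds were built from.
#' @return data frame of crossing edges with the two bins appended;
#'   zero rows when the assignment is leak-free.
#' @export
audit_leakage <- function(folds, edges, clusters) {
  fold_a <- folds$by_accession[edges$accession_a]
  fold_b <- folds$by_accession[edges$accession_b]
  bad <- which(is.na(fold_a) | is.na(fold_b) | fold_a != fold_b)
  out <- edges[bad, , drop = FALSE]
  out$bin_a <- unname(fold_a[bad])
  out$bin_b <- unname(fold_b[bad])
  rownames(out) <- NULL
  out
}

#' Write / read fold assignments
#'
#' Tab-separated `accession cluster_id fold`.
#'
#' @param folds a `fold_assignment`.
#' @param clusters the matching `cluster_assignment`.
#' @param path output path.
#' @return `path` invisibly, or for the reader a list with `by_accession`
#'   and `clusters`.
#' @export
write_fold_file <- function(folds, clusters, path) {
  df <- data.frame(accession = names(clusters),
                   cluster_id = as.integer(unclass(clusters)),
                   fold = unname(folds$by_accession[names(clusters)]),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_fold_file
#' @export
read_fold_file <- function(path) {
  df <- read_tsv_strict(path, expected = c("accession", "cluster_id", "fold"))
  by_acc <- stats::setNames(as.character(df$fold), df$accession)
  clusters <- stats::setNames(as.integer(df$cluster_id), df$accession)
  class(clusters) <- "cluster_assignment"
  list(by_accession = by_acc, clusters = clusters)
}

#' Write / read a cluster assignment file
#'
#' Tab-separated `accession cluster_id`.
#'
#' @param clusters a `cluster_assignment`.
#' @param path file path.
#' @return `path` invisibly; the reader returns a `cluster_assignment`.
#' @export
write_cluster_file <- function(clusters, path) {
  df <- data.frame(accession = names(clusters),
                   cluster_id = as.integer(unclass(clusters)),
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_cluster_file
#' @export
read_cluster_file <- function(path) {
  df <- read_tsv_strict(path, expected = c("accession", "cluster_id"))
  out <- stats::setNames(as.integer(df$cluster_id), df$accession)
  class(out) <- "cluster_assignment"
  out
}

#' Write a similarity edge file
#'
#' @param edges a `similarity_edges` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_file <- function(edges, path) {
  write_tsv(as.data.frame(edges), path)
}
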