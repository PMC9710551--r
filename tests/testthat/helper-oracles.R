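# Independent reference implementations used as oracles; deliberately
# simple and distinct from the package's algorithms.

# Breadth-first-search connected components; returns cluster ids numbered
# by smallest member accession, matching the package's convention.
bfs_components <- function(accessions, edges) {
  adj <- stats::setNames(vector("list", length(accessions)), accessions)
  for (i in seq_len(nrow(edges))) {
    a <- edges$accession_a[i]; b <- edges$accession_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(accessions)), accessions)
  groups <- list()
  for (s in accessions) {
    if (!is.na(comp[[s]])) next
    queue <- s
    members <- character(0)
    comp[[s]] <- 0L
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members <- c(members, v)
      for (w in adj[[v]]) if (is.na(comp[[w]])) { comp[[w]] <- 0L; queue <- c(queue, w) }
    }
    groups[[length(groups) + 1L]] <- members
  }
  mins <- vapply(groups, min, character(1))
  ord <- order(mins)
  for (r in seq_along(ord)) comp[groups[[ord[r]]]] <- r
  comp
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  acc <- sprintf("N%03d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- which(runif(ncol(pairs)) < p)
  edges <- data.frame(accession_a = acc[pairs[1, keep]],
                      accession_b = acc[pairs[2, keep]],
                      identity = rep(0.5, length(keep)),
                      coverage = rep(0.9, length(keep)),
                      stringsAsFactors = FALSE)
  class(edges) <- c("similarity_edges", "data.frame")
  list(accessions = acc, edges = edges)
}

# Random DAG over one namespace: edges only from higher to lower index,
# guaranteeing acyclicity. Returns a go_dag-shaped object.
random_dag <- function(n_terms, p_edge, seed, ns = "MF") {
  set.seed(seed)
  ids <- sprintf("GO:9%06d", seq_len(n_terms))
  parents <- lapply(seq_len(n_terms), function(i) {
    if (i == 1L) return(character(0))
    cand <- ids[seq_len(i - 1L)]
    cand[runif(i - 1L) < p_edge]
  })
  names(parents) <- ids
  structure(list(namespace = stats::setNames(rep(ns, n_terms), ids),
                 obsolete = stats::setNames(rep(FALSE, n_terms), ids),
                 parents_isa = parents,
                 parents_partof = stats::setNames(rep(list(character(0)), n_terms), ids),
                 alt = character(0)),
            class = "go_dag")
}

# Transitive closure by boolean matrix powering (reachability to parents).
closure_ancestors <- function(dag, id) {
  ids <- names(dag$namespace)
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (v in ids) {
    for (p in union(dag$parents_isa[[v]], dag$parents_partof[[v]])) A[v, p] <- TRUE
  }
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  ids[R[id, ]]
}

# Exact-arithmetic MCC at count scales where doubles are exact integers.
mcc_exact <- function(tp, tn, fp, fn) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NA_real_)
  num / den
}

# All-pairs ROC-AUC (ties count one half).
auc_pairs <- function(scores, y) {
  pos <- scores[y == "PLP"]; neg <- scores[y == "BLB"]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Small in-memory toy dataset used across files.
toy_proteins <- function() {
  list(protein_record("P1", "MKVLWAALLG"),
       protein_record("P2", "ACDEFGHIKL"),
       protein_record("P3", "MKVLWAXLLG"))
}

make_variant_row <- function(acc, pos, wt, mut, label = "BLB", somatic = FALSE,
                             disease = "", source = "OTHER") {
  data.frame(accession = acc, position = as.integer(pos), wt = wt, mut = mut,
             label = label, somatic = somatic, disease_ids = disease,
             source = source, stringsAsFactors = FALSE)
}

as_sav <- function(...) {
  df <- do.call(rbind, list(...))
  class(df) <- c("sav_table", "data.frame")
  df
}
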