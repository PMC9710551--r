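# Similarity edges, connected-component clustering, fold assignment and
# the leakage audit.

no_edges <- function() {
  structure(data.frame(accession_a = character(0), accession_b = character(0),
                       identity = numeric(0), coverage = numeric(0),
                       stringsAsFactors = FALSE),
            class = c("similarity_edges", "data.frame"))
}

edge_df <- function(a, b) {
  structure(data.frame(accession_a = a, accession_b = b,
                       identity = 0.5, coverage = 0.9, stringsAsFactors = FALSE),
            class = c("similarity_edges", "data.frame"))
}

test_that("connected components: singletons, chains, unknown accessions", {
  cc <- connected_components(c("A", "B", "C"), no_edges())
  expect_identical(unname(unclass(cc)), 1:3)

  cc2 <- connected_components(c("A", "B", "C"), edge_df(c("A", "B"), c("B", "C")))
  expect_true(length(unique(unclass(cc2))) == 1L)

  expect_error(connected_components(c("A"), edge_df("A", "Z")),
               class = "savanno_schema")
})

test_that("union-find matches the BFS oracle on random graphs", {
  for (seed in 1:30) {
    g <- random_graph(n = sample(2:50, 1), p = runif(1, 0, 0.15), seed = seed)
    ours <- connected_components(g$accessions, g$edges)
    ref <- bfs_components(g$accessions, g$edges)
    expect_identical(unclass(ours)[g$accessions], ref[g$accessions])
  }
})

test_that("build_edges scores identity and coverage as documented", {
  p1 <- protein_record("A", "MKVLWAALLGHHEEDDKKRRMKVLWAALLG")
  p2 <- protein_record("B", p1$sequence)
  e <- build_edges(list(p1, p2))
  expect_identical(nrow(e), 1L)
  expect_equal(e$identity, 1.0)
  expect_equal(e$coverage, 1.0)

  # 50-residue shared segment inside two otherwise unrelated 500-mers:
  # local identity is perfect but coverage 50/500 = 0.10 < 0.40 -> no edge
  set.seed(21)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  core <- paste(sample(aa, 50, TRUE), collapse = "")
  q1 <- protein_record("A", paste0(paste(sample(aa, 225, TRUE), collapse = ""), core,
                                   paste(sample(aa, 225, TRUE), collapse = "")))
  q2 <- protein_record("B", paste0(paste(sample(aa, 225, TRUE), collapse = ""), core,
                                   paste(sample(aa, 225, TRUE), collapse = "")))
  expect_identical(nrow(build_edges(list(q1, q2))), 0L)
})

test_that("independent random 100-mers rarely meet both thresholds", {
  set.seed(31)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  hits <- 0L
  n_draws <- 200L
  for (i in seq_len(n_draws)) {
    pair <- list(protein_record("A", paste(sample(aa, 100, TRUE), collapse = "")),
                 protein_record("B", paste(sample(aa, 100, TRUE), collapse = "")))
    if (nrow(build_edges(pair)) > 0L) hits <- hits + 1L
  }
  expect_lte(hits / n_draws, 0.05)
})

singleton_clusters <- function(n) {
  acc <- sprintf("S%03d", seq_len(n))
  connected_components(acc, no_edges())
}

test_that("assign_folds: pigeonhole, giant clusters, balance", {
  # 11 singleton variants, blind 10%, k = 10 -> one variant everywhere
  cl <- singleton_clusters(11)
  v <- do.call(as_sav, lapply(seq_len(11), function(i) {
    make_variant_row(sprintf("S%03d", i), 1, "M", "K",
                     label = if (i %% 2) "PLP" else "BLB", disease = "OMIM:1")
  }))
  f <- assign_folds(cl, v, blind_fraction = 0.10, k = 10, seed = 3)
  expect_identical(sort(unname(f$fold)), sort(c("BLIND", paste0("F", 1:10))))

  # a giant cluster is never split
  accs <- sprintf("S%03d", 1:20)
  giant_edges <- edge_df(rep("S001", 7), sprintf("S%03d", 2:8))
  cl2 <- connected_components(accs, giant_edges)
  v2 <- do.call(as_sav, lapply(seq_len(20), function(i) {
    make_variant_row(accs[i], 1, "M", "K", label = "BLB")
  }))
  f2 <- assign_folds(cl2, v2, blind_fraction = 0.10, k = 5, seed = 1)
  giant_id <- as.character(unclass(cl2)[["S001"]])
  member_bins <- unique(f2$by_accession[sprintf("S%03d", 1:8)])
  expect_identical(unname(member_bins), unname(f2$fold[[giant_id]]))
  expect_length(member_bins, 1L)
})

test_that("fold label balance stays within 5 points on 200 clusters", {
  set.seed(17)
  n_prot <- 200
  acc <- sprintf("C%03d", seq_len(n_prot))
  cl <- connected_components(acc, no_edges())
  rows <- lapply(seq_len(n_prot), function(i) {
    nv <- sample(1:8, 1)
    do.call(rbind, lapply(seq_len(nv), function(j) {
      make_variant_row(acc[i], j, "M", "K",
                       label = if (runif(1) < 0.6) "PLP" else "BLB")
    }))
  })
  v <- as_sav(do.call(rbind, rows))
  f <- assign_folds(cl, v, blind_fraction = 0.10, k = 10, seed = 9)
  global <- mean(v$label == "PLP")
  per_bin <- f$summary
  folds_only <- per_bin[per_bin$bin != "BLIND", ]
  frac <- folds_only$n_plp / folds_only$n_variants
  expect_true(all(abs(frac - global) <= 0.05))
  # blind holds roughly 10% of variants
  expect_lt(abs(per_bin$n_variants[per_bin$bin == "BLIND"] / nrow(v) - 0.10), 0.05)
})

test_that("assign_folds is deterministic and order-insensitive", {
  cl <- singleton_clusters(30)
  v <- do.call(as_sav, lapply(1:60, function(i) {
    make_variant_row(sprintf("S%03d", (i %% 30) + 1), i, "M", "K",
                     label = if (i %% 3) "BLB" else "PLP")
  }))
  f1 <- assign_folds(cl, v, seed = 42, k = 5)
  f2 <- assign_folds(cl, v, seed = 42, k = 5)
  expect_identical(f1$fold, f2$fold)
  perm <- v[sample(nrow(v)), ]
  f3 <- assign_folds(cl, perm, seed = 42, k = 5)
  expect_identical(f1$fold, f3$fold)
  expect_error(assign_folds(cl, v, k = 1), class = "savanno_config")
  expect_error(assign_folds(cl, v, blind_fraction = 0.7), class = "savanno_config")
})

test_that("audit_leakage agrees with a brute-force scan on fuzzed inputs", {
  cl <- singleton_clusters(3)
  v <- do.call(as_sav, lapply(1:3, function(i) {
    make_variant_row(sprintf("S%03d", i), 1, "M", "K", label = "BLB")
  }))
  f <- assign_folds(cl, v, k = 2, blind_fraction = 0.2, seed = 1)
  expect_identical(nrow(audit_leakage(f, no_edges(), cl)), 0L)

  # hand-built corrupt assignment splitting a linked pair
  g <- random_graph(10, 0.3, seed = 5)
  cc <- connected_components(g$accessions, g$edges)
  fake <- list(by_accession = stats::setNames(
    rep(c("F1", "F2"), length.out = 10), g$accessions))
  class(fake) <- "fold_assignment"
  report <- audit_leakage(fake, g$edges, cc)
  brute <- sum(fake$by_accession[g$edges$accession_a] !=
                 fake$by_accession[g$edges$accession_b])
  expect_identical(nrow(report), as.integer(brute))
})

test_that("edge/cluster/fold files round-trip", {
  g <- random_graph(8, 0.3, seed = 2)
  cc <- connected_components(g$accessions, g$edges)
  v <- do.call(as_sav, lapply(seq_along(g$accessions), function(i) {
    make_variant_row(g$accessions[i], 1, "M", "K", label = "BLB")
  }))
  f <- assign_folds(cc, v, k = 3, blind_fraction = 0.2, seed = 1)
  d <- withr::local_tempdir()
  write_edge_file(g$edges, file.path(d, "e.tsv"))
  write_cluster_file(cc, file.path(d, "c.tsv"))
  write_fold_file(f, cc, file.path(d, "f.tsv"))
  expect_equal(as.data.frame(read_edge_file(file.path(d, "e.tsv"))),
               as.data.frame(g$edges))
  expect_identical(read_cluster_file(file.path(d, "c.tsv")), cc)
  back <- read_fold_file(file.path(d, "f.tsv"))
  expect_identical(back$by_accession[g$accessions],
                   f$by_accession[g$accessions])
})
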