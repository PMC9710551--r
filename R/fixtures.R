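# Self-contained synthetic data with controllable class signal, so every
# stage and the end-to-end pipeline are testable without downloads. The
# generator states a small world: random sequences carrying variants whose
# mutated-sequence embeddings are shifted (P/LP only) inside a random
# low-dimensional latent subspace, plus a toy GO DAG whose leaf pools are
# label-biased.

#' Specification of a synthetic fixture
#'
#' `embedding_separation` is the per-latent-dimension shift between class
#' means, in pooled-standard-deviation units, applied across a
#' `latent_dim`-dimensional random subspace of each backend's embedding
#' space (so the total mean separation is `separation * sqrt(latent_dim)`
#' pooled SDs). `go_signal` is the probability that a protein's GO terms
#' are drawn from the term pool biased toward its variants' class.
#'
#' @param n_proteins,mean_length,n_variants,plp_fraction dataset shape;
#'   the P/LP count is exactly `round(plp_fraction * n_variants)`.
#' @param embedding_separation class signal in the sequence embeddings.
#' @param go_signal class signal in the GO annotation, in [0, 1].
#' @param seed master seed; all randomness derives from it.
#' @param esm_dim,t5_dim mock backend dimensions (the first backend gets a
#'   1024-residue length limit, mirroring the real constraint).
#' @param go_dim term-vector dimension.
#' @param latent_dim dimension of the latent signal subspace.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 30L, mean_length = 80L, n_variants = 100L,
                         plp_fraction = 0.4, embedding_separation = 0,
                         go_signal = 0, seed = 1L,
                         esm_dim = 32L, t5_dim = 24L, go_dim = 16L,
                         latent_dim = 10L) {
  stopifnot(is_count(n_proteins), is_count(mean_length), is_count(n_variants),
            plp_fraction >= 0, plp_fraction <= 1,
            embedding_separation >= 0, go_signal >= 0, go_signal <= 1,
            is_count(esm_dim), is_count(t5_dim), is_count(go_dim),
            is_count(latent_dim))
  structure(as.list(environment()), class = "fixture_spec")
}

# Toy three-namespace GO DAG: per namespace one root, two mid terms and
# eight leaves (the first mid also part_of the root), 33 nodes in all.
build_toy_godag <- function() {
  ns <- character(0); isa <- list(); partof <- list()
  counter <- 0L
  gid <- function() { counter <<- counter + 1L; sprintf("GO:%07d", counter) }
  leaves <- list()
  for (nsname in c("MF", "CC", "BP")) {
    root <- gid(); mids <- c(gid(), gid()); lv <- vapply(1:8, function(i) gid(), character(1))
    ids <- c(root, mids, lv)
    ns[ids] <- nsname
    isa[[root]] <- character(0); partof[[root]] <- character(0)
    isa[[mids[1]]] <- root; partof[[mids[1]]] <- character(0)
    isa[[mids[2]]] <- character(0); partof[[mids[2]]] <- root
    for (i in seq_along(lv)) {
      isa[[lv[i]]] <- mids[(i %% 2L) + 1L]
      partof[[lv[i]]] <- character(0)
    }
    leaves[[nsname]] <- lv
  }
  dag <- structure(list(namespace = ns,
                        obsolete = stats::setNames(rep(FALSE, length(ns)), names(ns)),
                        parents_isa = isa, parents_partof = partof,
                        alt = character(0)),
                   class = "go_dag")
  attr(dag, "leaves") <- leaves
  dag
}

random_sequence <- function(len) {
  paste(sample(AA_CANONICAL, len, replace = TRUE), collapse = "")
}

# Mock backend wrapped with a class-signal injector: sequences registered
# in `signal_env` get `shift` added to the embedding row at the recorded
# variant position.
signal_backend <- function(base, signal_env, shift) {
  inner <- base$embed
  embed <- function(sequence) {
    m <- inner(sequence)
    pos <- signal_env[[sequence]]
    if (!is.null(pos)) m[pos, ] <- m[pos, ] + shift
    m
  }
  embedding_backend(base$name, base$dim, embed, max_length = base$max_length)
}

#' Generate a synthetic fixture
#'
#' Builds random proteins, exact-count labelled variants placed at valid
#' positions, a toy GO DAG with label-biased leaf pools, a term-vector
#' table, and two mock embedding backends that inject the class-conditional
#' shift at variant positions of P/LP variants. Fully deterministic given
#' `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @return list with `proteins`, `variants`, `dag`, `term_table`,
#'   `backends` (list of two), and `spec`.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  seed <- spec$seed

  proteins <- with_seed(sub_seed(seed, "sequences"), {
    lens <- pmax(30L, as.integer(round(rnorm(spec$n_proteins, spec$mean_length,
                                             spec$mean_length / 6))))
    lapply(seq_len(spec$n_proteins), function(i) {
      protein_record(sprintf("SYN%04d", i), random_sequence(lens[i]))
    })
  })
  proteins <- protein_map(proteins)

  n_plp <- round(spec$plp_fraction * spec$n_variants)
  labels <- c(rep("PLP", n_plp), rep("BLB", spec$n_variants - n_plp))
  # label-grouped host assignment keeps proteins (mostly) class-pure, so
  # protein-level GO signal aligns with variant labels
  n_dis <- max(1L, min(spec$n_proteins - 1L, round(spec$n_proteins * spec$plp_fraction)))
  hosts <- character(spec$n_variants)
  if (n_plp > 0) hosts[seq_len(n_plp)] <- names(proteins)[rep_len(seq_len(n_dis), n_plp)]
  if (n_plp < spec$n_variants) {
    hosts[seq(n_plp + 1L, spec$n_variants)] <-
      names(proteins)[n_dis + rep_len(seq_len(spec$n_proteins - n_dis),
                                      spec$n_variants - n_plp)]
  }

  variants <- with_seed(sub_seed(seed, "variants"), {
    used <- new.env(parent = emptyenv())
    rows <- lapply(seq_len(spec$n_variants), function(i) {
      acc <- hosts[i]
      L <- nchar(proteins[[acc]]$sequence)
      taken <- used[[acc]] %||% integer(0)
      pos <- sample(setdiff(seq_len(L), taken), 1L)
      used[[acc]] <- c(taken, pos)
      wt <- substr(proteins[[acc]]$sequence, pos, pos)
      mut <- sample(setdiff(AA_CANONICAL, wt), 1L)
      data.frame(accession = acc, position = pos, wt = wt, mut = mut,
                 label = labels[i], somatic = FALSE,
                 disease_ids = if (labels[i] == "PLP") "OMIM:000001" else "",
                 source = "OTHER", stringsAsFactors = FALSE)
    })
    as_sav_table(do.call(rbind, rows))
  })

  dag <- build_toy_godag()
  leaves <- attr(dag, "leaves")

  # term vectors: disease-pool leaves offset +0.5, benign-pool -0.5
  term_table <- with_seed(sub_seed(seed, "term_vectors"), {
    ids <- names(dag$namespace)
    m <- matrix(runif(length(ids) * spec$go_dim, -1, 1), nrow = length(ids))
    rownames(m) <- ids
    for (nsname in names(leaves)) {
      lv <- leaves[[nsname]]
      m[lv[1:4], ] <- m[lv[1:4], ] + 0.5
      m[lv[5:8], ] <- m[lv[5:8], ] - 0.5
    }
    class(m) <- c("term_vector_table", class(m))
    m
  })

  host_bias <- tapply(variants$label, variants$accession,
                      function(l) if (mean(l == "PLP") >= 0.5) "PLP" else "BLB")
  proteins <- with_seed(sub_seed(seed, "annotations"), {
    for (acc in names(proteins)) {
      bias <- if (acc %in% names(host_bias)) host_bias[[acc]] else "BLB"
      for (nsname in c("MF", "CC", "BP")) {
        lv <- leaves[[nsname]]
        pool <- if (runif(1) < spec$go_signal) {
          if (bias == "PLP") lv[1:4] else lv[5:8]
        } else lv
        terms <- sample(pool, 2L)
        # occasionally annotate a redundant ancestor; leaf filtering absorbs it
        if (runif(1) < 0.3) terms <- c(terms, dag$parents_isa[[terms[1]]])
        proteins[[acc]]$go_terms[[nsname]] <- unique(terms)
      }
    }
    proteins
  })

  sigma_unif <- 1 / sqrt(3) # sd of U(-1, 1), the mock backend's base noise
  backends <- with_seed(sub_seed(seed, "backends"), {
    base <- list(mock_backend("esm_mock", spec$esm_dim, seed_salt = paste0("esm", seed),
                              max_length = 1024L),
                 mock_backend("t5_mock", spec$t5_dim, seed_salt = paste0("t5", seed)))
    signal_env <- new.env(parent = emptyenv())
    plp <- variants[variants$label == "PLP", , drop = FALSE]
    for (i in seq_len(nrow(plp))) {
      seqc <- proteins[[plp$accession[i]]]$sequence
      substr(seqc, plp$position[i], plp$position[i]) <- plp$mut[i]
      signal_env[[seqc]] <- plp$position[i]
    }
    lapply(base, function(b) {
      k <- min(spec$latent_dim, b$dim)
      basis <- qr.Q(qr(matrix(rnorm(b$dim * k), nrow = b$dim)))
      shift <- as.numeric(basis %*% rep(spec$embedding_separation * sigma_unif, k))
      signal_backend(b, signal_env, shift)
    })
  })

  list(proteins = proteins, variants = variants, dag = dag,
       term_table = term_table, backends = backends, spec = spec)
}

#' Write a fixture to the on-disk formats the pipeline reads
#'
#' Emits `proteins.fasta`, `variants.tsv`, `ontology.obo`,
#' `annotations.tsv` and `term_vectors.tsv` under `dir`.
#'
#' @param fixture result of [make_fixture()].
#' @param dir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             variants = file.path(dir, "variants.tsv"),
             obo = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             term_vectors = file.path(dir, "term_vectors.tsv"))
  write_fasta(fixture$proteins, paths[["fasta"]])
  write_variant_table(fixture$variants, paths[["variants"]])
  write_obo(fixture$dag, paths[["obo"]])
  write_annotations(fixture$proteins, paths[["annotations"]])
  write_term_vectors(fixture$term_table, paths[["term_vectors"]])
  invisible(paths)
}

#' Small end-to-end smoke bundle
#'
#' About 50 proteins and 500 variants with moderate embedding and GO
#' signal: enough rows for a stable train/evaluate chain that still runs
#' in well under a minute with the mock backends.
#'
#' @param seed master seed.
#' @return a fixture list, as [make_fixture()].
#' @export
make_paper_scale_smoke <- function(seed = 1L) {
  make_fixture(fixture_spec(n_proteins = 50L, mean_length = 60L,
                            n_variants = 500L, plp_fraction = 0.4,
                            embedding_separation = 1.5, go_signal = 0.7,
                            seed = seed))
}
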