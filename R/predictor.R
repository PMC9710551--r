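# Predictor assembly: feature vector construction, hyperparameter search,
# pipeline training (PCA -> RBF-SVM -> isotonic calibration) and
# prediction with a reliability index.

#' Assemble the per-variant feature vector
#'
#' Concatenates the positional encoding (variant/wild-type rows from two
#' backends) with the GO function encoding, in that fixed order. With the
#' default dimensions this yields 2x1280 + 2x1024 + 3x200 = 5208 features.
#'
#' @param pos a `positional_encoding` from [encode_variant_positional()].
#' @param func a `function_encoding` from [encode_go()].
#' @return numeric vector with a `layout` attribute (class
#'   `feature_vector`).
#' @export
assemble_features <- function(pos, func) {
  for (nm in c("positional", "functional")) {
    v <- if (nm == "positional") pos else func
    if (!all(is.finite(v))) {
      sv_stop("savanno_schema", "non-finite values in the %s block", nm)
    }
  }
  lay_pos <- attr(pos, "layout")
  lay_fun <- attr(func, "layout")
  layout <- rbind(
    data.frame(block = paste0("positional_", lay_pos$block), dim = lay_pos$dim,
               stringsAsFactors = FALSE),
    data.frame(block = paste0("go_", lay_fun$block), dim = lay_fun$dim,
               stringsAsFactors = FALSE))
  structure(c(as.numeric(pos), as.numeric(func)),
            layout = layout, class = "feature_vector")
}

#' Slice an assembled feature vector back into its blocks
#'
#' @param fv a `feature_vector`.
#' @return named list of numeric blocks following the layout descriptor.
#' @export
split_features <- function(fv) {
  layout <- attr(fv, "layout")
  ends <- cumsum(layout$dim)
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- lapply(seq_len(nrow(layout)), function(i) {
    as.numeric(fv)[starts[i]:ends[i]]
  })
  names(out) <- layout$block
  out
}

#' Encode a set of variants into a feature matrix
#'
#' Runs [encode_variant_positional()] and [encode_go()] for every variant
#' and stacks the assembled vectors. Backends are memoised per protein so
#' repeated variants on one sequence do not recompute embeddings.
#'
#' @param variants a `sav_table`.
#' @param proteins named list of [protein_record()] (GO terms populated).
#' @param backends ordered list of two `embedding_backend`s.
#' @param dag a `go_dag`.
#' @param table a `term_vector_table`.
#' @param window over-limit window size (default 201).
#' @return numeric matrix (one row per variant) with attributes `layout`
#'   and `variant_key`.
#' @export
encode_features <- function(variants, proteins, backends, dag, table,
                            window = 201L) {
  proteins <- protein_map(proteins)
  backends <- lapply(backends, cached_backend)
  go_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(variants))
  layout <- NULL
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    p <- proteins[[v$accession]]
    if (is.null(p)) {
      sv_stop("savanno_unknown_accession", "no sequence for accession %s", v$accession)
    }
    pos <- encode_variant_positional(p$sequence, v, backends, window = window)
    func <- go_cache[[v$accession]]
    if (is.null(func)) {
      func <- encode_go(p, dag, table)
      go_cache[[v$accession]] <- func
    }
    fv <- assemble_features(pos, func)
    if (is.null(layout)) layout <- attr(fv, "layout")
    rows[[i]] <- as.numeric(fv)
  }
  X <- do.call(rbind, rows)
  if (is.null(X)) X <- matrix(numeric(0), nrow = 0, ncol = 0)
  attr(X, "layout") <- layout
  attr(X, "variant_key") <- variant_key(variants)
  X
}

#' Pipeline configuration
#'
#' Defaults follow the reference architecture: 2400 PCA components, RBF
#' kernel, decision threshold 0 (score >= 0 means P/LP), standardisation
#' before PCA, unweighted classes. The hyperparameter grid is a design
#' default, exposed for [grid_search_cv()].
#'
#' @param pca_components projected dimension (default 2400); capped at the
#'   training rank at fit time.
#' @param svm_C SVM cost parameter.
#' @param svm_gamma RBF width or `"scale"`.
#' @param grid named list of candidate vectors `pca_components`, `C`,
#'   `gamma` for the grid search.
#' @param seed integer seed for all stochastic steps.
#' @param decision_threshold raw-score classification threshold.
#' @param standardize standardise features before PCA.
#' @param class_weight optional `c(PLP=, BLB=)` cost multipliers.
#' @param calibration_folds folds used for out-of-fold calibration when no
#'   fold assignment is supplied to [train_pipeline()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(pca_components = 2400L, svm_C = 1, svm_gamma = "scale",
                            grid = list(pca_components = c(1200L, 2400L),
                                        C = c(1, 10, 100),
                                        gamma = list("scale", 1e-3, 1e-4)),
                            seed = 1L, decision_threshold = 0,
                            standardize = TRUE, class_weight = NULL,
                            calibration_folds = 5L) {
  if (!is_count(pca_components)) {
    sv_stop("savanno_config", "pca_components must be a positive integer")
  }
  structure(list(pca_components = as.integer(pca_components), svm_C = svm_C,
                 svm_gamma = svm_gamma, grid = grid, seed = as.integer(seed),
                 decision_threshold = decision_threshold,
                 standardize = isTRUE(standardize), class_weight = class_weight,
                 calibration_folds = as.integer(calibration_folds)),
            class = "pipeline_config")
}

# Fit PCA+SVM on training rows only; returns the pair.
fit_stage <- function(X, y, config) {
  k <- min(config$pca_components, nrow(X) - 1L, ncol(X))
  pca <- fit_pca(X, k, standardize = config$standardize)
  Z <- apply_pca(pca, X)
  svm <- svm_fit(Z, y, C = config$svm_C, gamma = config$svm_gamma,
                 class_weight = config$class_weight)
  list(pca = pca, svm = svm)
}

stage_scores <- function(stage, X) {
  svm_decision(stage$svm, apply_pca(stage$pca, X))
}

#' Hyperparameter grid search over cross-validation folds
#'
#' For every grid point, trains on each fold's complement (PCA refitted on
#' the training part every time) and scores the held-out fold; the point
#' with the best mean validation MCC wins. Ties break toward fewer PCA
#' components, then smaller C.
#'
#' @param X feature matrix.
#' @param y labels (`PLP`/`BLB`).
#' @param folds character/integer vector of fold ids per row (>= 2 distinct).
#' @param grid named list with `pca_components`, `C`, `gamma` candidates.
#' @param config base [pipeline_config()] supplying fixed settings.
#' @return list with `best` (a `pipeline_config`) and `results` (data frame
#'   of per-point mean MCC).
#' @export
grid_search_cv <- function(X, y, folds, grid = NULL, config = pipeline_config()) {
  grid <- grid %||% config$grid
  if (!length(grid$pca_components) || !length(grid$C) || !length(grid$gamma)) {
    sv_stop("savanno_config", "empty hyperparameter grid")
  }
  fold_ids <- unique(folds)
  if (length(fold_ids) < 2L) sv_stop("savanno_config", "grid search needs >= 2 folds")
  combos <- expand.grid(pi = seq_along(grid$pca_components),
                        ci = seq_along(grid$C),
                        gi = seq_along(grid$gamma))
  res <- lapply(seq_len(nrow(combos)), function(r) {
    pc <- grid$pca_components[[combos$pi[r]]]
    cc <- grid$C[[combos$ci[r]]]
    gg <- grid$gamma[[combos$gi[r]]]
    cfg <- modifyList(unclass(config),
                      list(pca_components = as.integer(pc), svm_C = cc, svm_gamma = gg))
    class(cfg) <- "pipeline_config"
    mccs <- vapply(fold_ids, function(f) {
      tr <- folds != f
      stage <- fit_stage(X[tr, , drop = FALSE], y[tr], cfg)
      sc <- stage_scores(stage, X[!tr, , drop = FALSE])
      pred <- ifelse(sc >= cfg$decision_threshold, "PLP", "BLB")
      m <- classification_metrics(confusion_counts(y[!tr], pred))
      if (is.na(m$mcc)) 0 else m$mcc
    }, numeric(1))
    data.frame(pca_components = pc, C = cc,
               gamma = if (identical(gg, "scale")) NA_real_ else gg,
               gamma_is_scale = identical(gg, "scale"),
               mean_mcc = mean(mccs), stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)
  ord <- order(-results$mean_mcc, results$pca_components, results$C)
  best_row <- ord[1L]
  gg <- grid$gamma[[combos$gi[best_row]]]
  best <- modifyList(unclass(config),
                     list(pca_components = as.integer(results$pca_components[best_row]),
                          svm_C = results$C[best_row], svm_gamma = gg))
  class(best) <- "pipeline_config"
  list(best = best, results = results)
}

#' Train the full prediction pipeline
#'
#' Fits standardisation + PCA + SVM on all supplied rows, then fits the
#' isotonic calibrator on pooled out-of-fold decision scores: each fold is
#' scored by a model trained on the remaining folds, so the calibrator
#' never sees scores produced by a model trained on the same rows. When no
#' fold assignment is given, seeded stratified folds are drawn internally
#' (`config$calibration_folds`); supplying the homology-aware folds is
#' preferred.
#'
#' @param X feature matrix.
#' @param y labels (`PLP`/`BLB`), both classes required.
#' @param config a [pipeline_config()].
#' @param folds optional per-row fold ids for calibration.
#' @return object of class `trained_pipeline`.
#' @export
train_pipeline <- function(X, y, config = pipeline_config(), folds = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) {
    sv_stop("savanno_single_class", "training labels contain a single class")
  }
  if (is.null(folds)) {
    folds <- with_seed(sub_seed(config$seed, "calibration_folds"), {
      f <- integer(length(y))
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        f[idx] <- rep_len(seq_len(config$calibration_folds), length(idx))
      }
      f
    })
  }
  stage <- fit_stage(X, y, config)
  oof <- rep(NA_real_, length(y))
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) {
      sv_log("WARN", "calibration fold %s: training complement single-class, skipped", f)
      next
    }
    st <- fit_stage(X[tr, , drop = FALSE], y[tr], config)
    oof[!tr] <- stage_scores(st, X[!tr, , drop = FALSE])
  }
  usable <- is.finite(oof)
  calibrator <- fit_isotonic(oof[usable], as.numeric(y[usable] == "PLP"))
  layout <- attr(X, "layout")
  structure(list(pca = stage$pca, svm = stage$svm, calibrator = calibrator,
                 config = config, feature_dim = ncol(X), layout = layout,
                 checksum = pipeline_checksum(ncol(X), layout),
                 version = "savanno-pipeline/1"),
            class = "trained_pipeline")
}

pipeline_checksum <- function(feature_dim, layout) {
  desc <- paste(feature_dim,
                if (is.null(layout)) "" else paste(layout$block, layout$dim, collapse = ";"))
  str_seed(desc)
}

#' @export
print.trained_pipeline <- function(x, ...) {
  cat(sprintf("<trained_pipeline> %d features -> PCA %d -> RBF-SVM (%d SV) -> isotonic (%d knots)\n",
              x$feature_dim, x$pca$k, nrow(x$svm$sv), length(x$calibrator$x)))
  invisible(x)
}

#' Reliability index of a calibrated probability
#'
#' `RI = round(20 * |p - 0.5|)` with half-away-from-zero rounding: 0 at
#' p = 0.5 (a coin-flip prediction) up to 10 at p = 0 or 1 (certain).
#' Symmetric in p and 1 - p.
#'
#' @param p probabilities in [0, 1] (vectorised).
#' @return integer vector in 0..10.
#' @export
reliability_index <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    sv_stop("savanno_config", "probabilities must lie in [0, 1]")
  }
  # epsilon guards the half-away-from-zero boundary against float error in
  # |p - 0.5|, keeping RI(p) == RI(1 - p) exactly
  as.integer(floor(20 * abs(p - 0.5) + 0.5 + 1e-9))
}

#' Predict variants with a trained pipeline
#'
#' @param pipeline a `trained_pipeline`.
#' @param X feature matrix (or single `feature_vector`) matching the
#'   pipeline's layout.
#' @param variants optional `sav_table` aligned with the rows of `X`; its
#'   identifying columns are prepended to the output.
#' @return data frame with `score` (raw SVM decision value), `probability`
#'   (calibrated P/LP probability), `label` (`PLP` iff score >= threshold)
#'   and `reliability_index`.
#' @export
predict_pipeline <- function(pipeline, X, variants = NULL) {
  if (inherits(X, "feature_vector")) X <- matrix(as.numeric(X), nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != pipeline$feature_dim) {
    sv_stop("savanno_schema",
            "feature length mismatch: pipeline expects %d, received %d",
            pipeline$feature_dim, ncol(X))
  }
  score <- stage_scores(pipeline, X)
  prob <- pmin(1, pmax(0, predict_isotonic(pipeline$calibrator, score)))
  label <- ifelse(score >= pipeline$config$decision_threshold, "PLP", "BLB")
  out <- data.frame(score = score, probability = prob, label = label,
                    reliability_index = reliability_index(prob),
                    stringsAsFactors = FALSE)
  if (!is.null(variants)) {
    out <- cbind(data.frame(accession = variants$accession,
                            substitution = format_substitution(
                              variants$wt, variants$position, variants$mut),
                            stringsAsFactors = FALSE),
                 out)
  }
  out
}

#' Persist / restore a trained pipeline
#'
#' The archive embeds a format version and a feature-layout checksum that
#' is verified on load, so a model can never silently be applied to a
#' different feature layout.
#'
#' @param pipeline a `trained_pipeline`.
#' @param path file path for the model archive.
#' @return `path` invisibly; `load_pipeline()` returns the pipeline.
#' @export
save_pipeline <- function(pipeline, path) {
  saveRDS(unclass(pipeline), path)
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  if (!file.exists(path)) sv_stop("savanno_missing_input", "model file not found: %s", path)
  obj <- readRDS(path)
  if (!identical(obj$version, "savanno-pipeline/1")) {
    sv_stop("savanno_schema", "unsupported model archive version: %s", obj$version %||% "<none>")
  }
  if (!identical(obj$checksum, pipeline_checksum(obj$feature_dim, obj$layout))) {
    sv_stop("savanno_schema", "model archive failed its layout checksum")
  }
  class(obj) <- "trained_pipeline"
  obj
}
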