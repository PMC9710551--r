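# R interface to the SMO-based RBF C-SVC in src/smo.cpp.

#' Fit an RBF-kernel support vector classifier
#'
#' Binary C-SVC solved by sequential minimal optimisation with
#' maximal-violating-pair working-set selection (dense kernel; intended for
#' up to a few thousand training rows). The positive class is P/LP.
#'
#' @param X numeric matrix, rows = examples.
#' @param y labels: character/factor with values `PLP`/`BLB`, or a numeric
#'   vector in {-1, +1}.
#' @param C cost parameter (> 0).
#' @param gamma RBF width; a positive number or `"scale"` for
#'   `1 / (ncol(X) * var(X))` over all matrix entries.
#' @param class_weight optional named vector `c(PLP = , BLB = )` of
#'   per-class multipliers on `C` (default unweighted).
#' @param eps KKT stopping tolerance (default 1e-3).
#' @param max_iter cap on SMO pair updates.
#' @return object of class `savanno_svm` with support vectors, dual
#'   coefficients, intercept and kernel parameters.
#' @export
svm_fit <- function(X, y, C = 1, gamma = "scale", class_weight = NULL,
                    eps = 1e-3, max_iter = 1000000L) {
  X <- as.matrix(X)
  yy <- svm_labels_to_pm1(y)
  if (length(unique(yy)) < 2L) {
    sv_stop("savanno_single_class", "training data contains a single class")
  }
  if (!is.numeric(C) || C <= 0) sv_stop("savanno_config", "C must be positive")
  g <- resolve_gamma(gamma, X)
  w_pos <- w_neg <- 1
  if (!is.null(class_weight)) {
    w_pos <- class_weight[["PLP"]] %||% 1
    w_neg <- class_weight[["BLB"]] %||% 1
  }
  fit <- .smo_fit(X, yy, C * w_pos, C * w_neg, g, eps, as.integer(max_iter))
  if (!fit$converged) {
    sv_log("WARN", "SMO stopped at max_iter with KKT gap %.3g", fit$gap)
  }
  structure(list(sv = fit$sv, coef = as.numeric(fit$coef), rho = fit$rho,
                 gamma = g, C = C, dim = ncol(X),
                 iterations = fit$iterations, converged = fit$converged),
            class = "savanno_svm")
}

svm_labels_to_pm1 <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) sv_stop("savanno_schema", "numeric labels must be -1/+1")
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("PLP", "BLB"))) {
    sv_stop("savanno_schema", "labels must be PLP or BLB")
  }
  ifelse(y == "PLP", 1, -1)
}

resolve_gamma <- function(gamma, X) {
  if (identical(gamma, "scale")) {
    v <- stats::var(as.numeric(X))
    if (!is.finite(v) || v <= 0) v <- 1
    return(1 / (ncol(X) * v))
  }
  if (!is.numeric(gamma) || gamma <= 0) {
    sv_stop("savanno_config", "gamma must be positive or \"scale\"")
  }
  gamma
}

#' Decision scores of a fitted SVC
#'
#' Signed distance-like score; the classification rule is P/LP when the
#' score is >= 0.
#'
#' @param model a `savanno_svm`.
#' @param X numeric matrix of rows to score.
#' @return numeric vector of decision scores.
#' @export
svm_decision <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$dim) {
    sv_stop("savanno_schema", "feature dimension mismatch: model %d, input %d",
            model$dim, ncol(X))
  }
  .smo_decision(model$sv, model$coef, model$rho, model$gamma, X)
}

#' @export
print.savanno_svm <- function(x, ...) {
  cat(sprintf("<savanno_svm> RBF C-SVC: %d support vectors, C=%g, gamma=%.4g%s\n",
              nrow(x$sv), x$C, x$gamma,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}
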