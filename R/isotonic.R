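# Isotonic (monotone non-decreasing) regression by weighted pool-adjacent-
# violators, used to map SVM decision scores to calibrated probabilities.

#' Fit an isotonic calibration map
#'
#' Ties in `x` are pooled (weighted mean of `y`) before the
#' pool-adjacent-violators pass, so the fit is invariant to input order.
#' Prediction interpolates linearly between knots and clamps outside the
#' fitted score range.
#'
#' @param x numeric scores.
#' @param y numeric targets in [0, 1] (binary labels for calibration).
#' @return object of class `savanno_isotonic` with knot positions and
#'   fitted values.
#' @export
fit_isotonic <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1L)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  ux <- unique(x)
  w <- as.numeric(table(match(x, ux)))
  ym <- as.numeric(tapply(y, match(x, ux), mean))
  # weighted PAVA over (ux, ym, w)
  n <- length(ux)
  val <- numeric(n); wt <- numeric(n); from <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- ym[i]; wt[top] <- w[i]; from[top] <- i
    while (top > 1L && val[top - 1L] > val[top]) {
      pooled_w <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (val[top - 1L] * wt[top - 1L] + val[top] * wt[top]) / pooled_w
      wt[top - 1L] <- pooled_w
      top <- top - 1L
    }
  }
  fitted <- numeric(n)
  bounds <- c(from[seq_len(top)], n + 1L)
  for (b in seq_len(top)) {
    fitted[seq(bounds[b], bounds[b + 1L] - 1L)] <- val[b]
  }
  structure(list(x = ux, y = fitted), class = "savanno_isotonic")
}

#' Apply an isotonic calibration map
#'
#' @param model a `savanno_isotonic`.
#' @param x numeric scores.
#' @return calibrated values, clamped to the fitted range outside it.
#' @export
predict_isotonic <- function(model, x) {
  if (length(model$x) == 1L) return(rep(model$y, length(x)))
  stats::approx(model$x, model$y, xout = x, method = "linear", rule = 2)$y
}
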