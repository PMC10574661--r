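#' Confusion counts for binary predictions
#'
#' Labels follow the high(positive)/weak(negative) convention: `high` (or 1)
#' is the positive class.
#'
#' @param y_true,y_pred vectors of equal length; factors with levels
#'   high/weak, or 0/1 numerics (1 = positive).
#' @return list of class `confusion_counts` with TP, TN, FP, FN.
#' @export
confusion <- function(y_true, y_pred) {
  t1 <- as_binary(y_true)
  p1 <- as_binary(y_pred)
  if (length(t1) != length(p1)) stop("length mismatch")
  structure(list(TP = sum(t1 == 1 & p1 == 1),
                 TN = sum(t1 == 0 & p1 == 0),
                 FP = sum(t1 == 0 & p1 == 1),
                 FN = sum(t1 == 1 & p1 == 0)),
            class = "confusion_counts")
}

as_binary <- function(y) {
  if (inherits(y, "confusion_counts")) stop("expected label vector")
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    bad <- !y %in% c("high", "weak")
    if (any(bad)) stop("labels must be 'high' or 'weak'")
    as.integer(y == "high")
  } else {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
    as.integer(y)
  }
}

#' Classification accuracy Q (percent)
#'
#' `Q = 100 * (TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param c a `confusion_counts` object.
#' @return accuracy in percent, in \[0, 100\].
#' @export
q_accuracy <- function(c) {
  n <- c$TP + c$TN + c$FP + c$FN
  if (n == 0) stop("empty confusion counts")
  100 * (c$TP + c$TN) / n
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; if any
#' factor of the denominator is zero (e.g. all predictions in one class),
#' the coefficient is defined as 0.
#'
#' @param c a `confusion_counts` object.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(c) {
  n <- c$TP + c$TN + c$FP + c$FN
  if (n == 0) stop("empty confusion counts")
  den <- (c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
  if (den == 0) return(0)
  ((c$TP * c$TN) - (c$FP * c$FN)) / sqrt(den)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y observed values (non-constant).
#' @param y_hat predicted values.
#' @return R-squared (can be negative for predictors worse than the mean).
#' @export
r2 <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  if (length(y) < 2L) stop("need n >= 2")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("R-squared undefined for constant y")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Root mean squared error
#'
#' `RMSE = sqrt(mean((y - yhat)^2))`.
#'
#' @inheritParams r2
#' @return non-negative RMSE.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch")
  sqrt(mean((y - y_hat)^2))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d  (Q=%.1f%%, MCC=%.3f)\n",
              x$TP, x$TN, x$FP, x$FN, q_accuracy(x), mcc(x)))
  invisible(x)
}
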