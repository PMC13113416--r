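#' Regression metrics: mean squared error and coefficient of determination
#'
#' `mse(y, yhat)` is the mean of squared residuals. `r_squared(y, yhat)` is
#' `1 - SSres / SStot` with the total sum of squares taken about the
#' observed mean of `y`; it equals 1 for perfect prediction, 0 for the
#' mean predictor, and is negative when the model does worse than
#' predicting the mean. A constant `y` leaves the denominator undefined
#' and is an error.
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return A single number.
#' @examples
#' mse(c(1, 2, 3), c(2, 2, 2))        # 2/3
#' r_squared(c(1, 2, 3), c(3, 2, 1))  # -3
#' @export
mse <- function(y, yhat) {
  if (length(y) != length(yhat) || !length(y))
    stop("y and yhat must have equal, nonzero length", call. = FALSE)
  mean((y - yhat)^2)
}

#' @rdname mse
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat) || !length(y))
    stop("y and yhat must have equal, nonzero length", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0)
    stop("r_squared is undefined for constant y", call. = FALSE)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Pearson correlation implied by a coefficient of determination
#'
#' For a least-squares fit, the magnitude of the Pearson correlation
#' between observations and predictions equals the square root of the
#' coefficient of determination; this converts a reported positive
#' R-squared to that implied correlation.
#'
#' @param r2 Nonnegative coefficient of determination.
#' @return `sqrt(r2)`.
#' @examples
#' pearson_from_r2(0.49)
#' @export
pearson_from_r2 <- function(r2) {
  stopifnot(is.numeric(r2), r2 >= 0)
  sqrt(r2)
}
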