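#' Round half away from zero
#'
#' Display rounding used for the movement tables: ties are rounded away from
#' zero (so 0.0005 -> 0.001), unlike [base::round()]'s round-half-even.
#' Internal arithmetic is never rounded; this is applied only when a value is
#' shown at table precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # tiny relative nudge so values that are exact ties after binary roundoff
  # (e.g. 0.0585 stored as 0.05849999...) still round away from zero
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Von Mises stress from Voigt stress components
#'
#' @param sigma numeric matrix with 6 columns in Voigt order
#'   (xx, yy, zz, xy, yz, zx), or a length-6 vector.
#' @return numeric vector of von Mises equivalent stresses (same units).
#' @export
von_mises <- function(sigma) {
  if (is.null(dim(sigma))) sigma <- matrix(sigma, nrow = 1)
  sqrt(0.5 * ((sigma[, 1] - sigma[, 2])^2 +
              (sigma[, 2] - sigma[, 3])^2 +
              (sigma[, 3] - sigma[, 1])^2) +
       3 * (sigma[, 4]^2 + sigma[, 5]^2 + sigma[, 6]^2))
}

#' Maximum principal stress from Voigt stress components
#'
#' @inheritParams von_mises
#' @return numeric vector of largest principal stresses.
#' @export
max_principal <- function(sigma) {
  if (is.null(dim(sigma))) sigma <- matrix(sigma, nrow = 1)
  vapply(seq_len(nrow(sigma)), function(i) {
    s <- sigma[i, ]
    m <- matrix(c(s[1], s[4], s[6],
                  s[4], s[2], s[5],
                  s[6], s[5], s[3]), 3, 3)
    max(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
}

# unit vector, erroring on zero length
unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalise a zero-length vector")
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
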