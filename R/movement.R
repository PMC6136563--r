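#' Quadratic stress-to-movement law
#'
#' Monthly tooth movement Y (mm) as a quadratic function of the stress
#' invariant X (N/mm^2) sampled at a root landmark:
#' `Y = a X^2 + b X + c`.
#'
#' @param a quadratic coefficient (mm per (N/mm^2)^2).
#' @param b linear coefficient (mm per (N/mm^2)).
#' @param c intercept (mm).
#' @return a `quadratic_law`.
#' @export
quadratic_law <- function(a, b, c) {
  co <- c(a = a, b = b, c = c)
  if (any(!is.finite(co))) stop("law coefficients must be finite")
  structure(list(a = a, b = b, c = c), class = "quadratic_law")
}

#' The calibrated movement law for canine retraction under 1 N
#'
#' The quadratic law obtained from the first patient's calibration data,
#' with coefficients a = 2960, b = -254.56, c = 5.667.  Used by default to
#' predict the second patient's monthly movement.
#'
#' @return a `quadratic_law`.
#' @export
calibrated_movement_law <- function() quadratic_law(2960, -254.56, 5.667)

#' @export
print.quadratic_law <- function(x, ...) {
  cat(sprintf("quadratic_law: Y = %g X^2 + %g X + %g  (Y mm, X N/mm^2)\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Predict tooth movement from stress
#'
#' Evaluates the quadratic law, unrounded.  Use
#' [round_half_away()]`(*, 3)` for table display at 3 decimals.  Negative
#' predictions (outside the calibrated stress range) trigger a warning.
#'
#' @param law a [quadratic_law()].
#' @param X stress values (N/mm^2).
#' @return predicted movement (mm), unrounded.
#' @export
predict_movement <- function(law, X) {
  stopifnot(inherits(law, "quadratic_law"), all(is.finite(X)))
  y <- law$a * X^2 + law$b * X + law$c
  if (any(y < 0))
    warning("negative predicted movement: stress outside calibration range")
  y
}

#' @export
predict.quadratic_law <- function(object, X, ...) predict_movement(object, X)

#' Fit a quadratic movement law by ordinary least squares
#'
#' Fits `movement ~ stress + stress^2` by QR-based OLS on calibration
#' points, optionally excluding a landmark (the first patient's C1M series
#' is the documented candidate for exclusion).
#'
#' @param points data.frame with columns `stress` and `movement`
#'   (and optionally `landmark`).
#' @param exclude optional landmark id(s) to drop before fitting.
#' @return a list with the fitted `law`, `rmse`, per-point `residuals`,
#'   coefficient standard errors `se`, and the underlying `lm` fit.
#' @export
fit_movement_law <- function(points, exclude = NULL) {
  stopifnot(is.data.frame(points),
            all(c("stress", "movement") %in% names(points)))
  if (!is.null(exclude)) {
    if (!"landmark" %in% names(points))
      stop("cannot exclude by landmark: no landmark column")
    points <- points[!points$landmark %in% exclude, , drop = FALSE]
  }
  if (length(unique(points$stress)) < 3)
    stop("rank-deficiency error: need >= 3 distinct stress values for a ",
         "quadratic fit")
  fit <- stats::lm(movement ~ stress + I(stress^2), data = points)
  cf <- stats::coef(fit)
  law <- quadratic_law(a = unname(cf["I(stress^2)"]),
                       b = unname(cf["stress"]),
                       c = unname(cf["(Intercept)"]))
  res <- stats::residuals(fit)
  # summary.lm warns on noiseless (interpolating) input; the zero standard
  # errors it returns are exactly what we want to report there
  se <- withCallingHandlers(
    summary(fit)$coefficients[, "Std. Error"],
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(law = law,
       rmse = sqrt(mean(res^2)),
       residuals = res,
       se = c(a = unname(se["I(stress^2)"]), b = unname(se["stress"]),
              c = unname(se["(Intercept)"])),
       fit = fit)
}

# ---- rigid superimposition --------------------------------------------------

#' Rigid transform (rotation + translation)
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation (mm).
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(R, t) {
  if (max(abs(crossprod(R) - diag(3))) > 1e-10 || det(R) < 0)
    stop("R must be a proper rotation (orthonormal, det +1)")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

is_identity_transform <- function(tr, tol = 1e-12) {
  max(abs(tr$R - diag(3))) < tol && max(abs(tr$t)) < tol
}

#' Apply a rigid transform to points
#'
#' @param transform a `rigid_transform`.
#' @param pts n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
transform_points <- function(transform, pts) {
  pts <- matrix(pts, ncol = 3, dimnames = dimnames(pts))
  sweep(pts %*% t(transform$R), 2, -transform$t)
}

# composition: first apply `first`, then `second`
compose_transforms <- function(second, first) {
  rigid_transform(second$R %*% first$R,
                  as.numeric(second$R %*% first$t) + second$t)
}

#' Best-fit rigid superimposition (Kabsch)
#'
#' Finds the rigid transform (rotation + translation, no scaling) mapping
#' `moving` onto `fixed` with minimum root-mean-square deviation, via SVD of
#' the cross-covariance (Kabsch/Procrustes).  This emulates best-fit
#' superimposition of serial dental models on a stable palatal patch.
#'
#' @param fixed n x 3 reference points.
#' @param moving n x 3 points to superimpose (row-wise correspondence).
#' @return a `rigid_transform` with attributes `rmsd` (post-fit RMSD, mm).
#' @export
rigid_superimpose <- function(fixed, moving) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (nrow(fixed) != nrow(moving) || nrow(fixed) < 3)
    stop("need >= 3 corresponding points")
  cf <- colMeans(fixed); cm <- colMeans(moving)
  F0 <- sweep(fixed, 2, cf); M0 <- sweep(moving, 2, cm)
  H <- crossprod(M0, F0)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300))
    stop("degeneracy error: points are collinear or coincident")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cf - as.numeric(R %*% cm)
  tr <- rigid_transform(R, t)
  moved <- transform_points(tr, moving)
  attr(tr, "rmsd") <- sqrt(mean(rowSums((moved - fixed)^2)))
  tr
}

#' Landmark displacement after superimposition
#'
#' Applies the superimposition transform to the post-period landmarks and
#' returns the Euclidean distance of each from its pre-period position
#' (the clinical tooth-movement measurement).
#'
#' @param transform `rigid_transform` from superimposing the stable
#'   reference patch of the post-period model onto the pre-period model.
#' @param landmarks_before,landmarks_after matrices with matching row names.
#' @return named numeric vector of displacements (mm).
#' @export
landmark_displacement <- function(transform, landmarks_before,
                                  landmarks_after) {
  ib <- rownames(landmarks_before); ia <- rownames(landmarks_after)
  if (is.null(ib) || is.null(ia) || !setequal(ib, ia))
    stop("landmark id mismatch between before/after sets")
  after <- transform_points(transform, landmarks_after)[ib, , drop = FALSE]
  d <- sqrt(rowSums((after - landmarks_before)^2))
  stats::setNames(d, ib)
}

#' Dahlberg method error
#'
#' `sqrt(sum(d_i^2) / (2 n))` over paired repeated measurements, the
#' standard method-error estimate for duplicated distance measurements.
#'
#' @param first,second equal-length numeric vectors of paired measurements.
#' @return method error (same units as the inputs).
#' @export
dahlberg_error <- function(first, second) {
  if (length(first) != length(second))
    stop("paired measurement vectors must have equal length")
  if (length(first) < 1) stop("need at least one pair")
  d <- first - second
  sqrt(sum(d^2) / (2 * length(d)))
}

# ---- validation -------------------------------------------------------------

#' Build movement records from a law and a validation table
#'
#' For each row, the unrounded prediction F is computed from the law at the
#' row's stress, and compared against the printed clinical movement C:
#' `diff = |F - C|`, `percent = 100 |F - C| / F` (denominator is the
#' unrounded prediction).  Display columns are rounded half-away-from-zero
#' to 3 (mm) and 2 (percent) decimals.
#'
#' @param law a [quadratic_law()].
#' @param table data.frame with columns `landmark`, `period`, `stress`,
#'   `clinical`.
#' @return data.frame of movement records.
#' @export
movement_records <- function(law, table) {
  stopifnot(all(c("landmark", "period", "stress", "clinical") %in%
                names(table)))
  F_ <- predict_movement(law, table$stress)
  diff <- abs(F_ - table$clinical)
  pct <- 100 * diff / F_
  data.frame(landmark = table$landmark, period = table$period,
             stress = table$stress,
             predicted = F_,
             predicted_display = round_half_away(F_, 3),
             clinical = table$clinical,
             diff = diff,
             diff_display = round_half_away(diff, 3),
             percent = pct,
             percent_display = round_half_away(pct, 2),
             stringsAsFactors = FALSE)
}

#' Validation summary over movement records
#'
#' @param records data.frame from [movement_records()] (columns `diff` and
#'   `percent` required).
#' @return a `validation_summary`: min/max absolute difference (mm) and
#'   percent difference, at display rounding (3 dp / 2 dp), plus the
#'   per-row table.
#' @export
validate_records <- function(records) {
  if (nrow(records) < 1) stop("need at least one record")
  structure(list(
    min_diff = round_half_away(min(records$diff), 3),
    max_diff = round_half_away(max(records$diff), 3),
    min_percent = round_half_away(min(records$percent), 2),
    max_percent = round_half_away(max(records$percent), 2),
    min_predicted = round_half_away(min(records$predicted), 3),
    max_predicted = round_half_away(max(records$predicted), 3),
    records = records
  ), class = "validation_summary")
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("validation_summary\n")
  cat(sprintf("  |F - C| range: %.3f to %.3f mm\n", x$min_diff, x$max_diff))
  cat(sprintf("  percent range: %.2f to %.2f %%\n",
              x$min_percent, x$max_percent))
  cat(sprintf("  predicted range: %.3f to %.3f mm\n",
              x$min_predicted, x$max_predicted))
  invisible(x)
}
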