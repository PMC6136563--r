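test_that("quadratic law evaluates the calibrated coefficients correctly", {
  law <- calibrated_movement_law()
  # printed table values at 3 decimals
  expect_equal(round_half_away(predict_movement(law, 0.063), 3), 1.378)
  expect_equal(round_half_away(predict_movement(law, 0.030), 3), 0.694)
  expect_equal(round_half_away(predict_movement(law, 0.048), 3), 0.268)
  # intercept at zero stress
  expect_equal(predict_movement(law, 0), 5.667)
  # predict() S3 method agrees
  expect_equal(predict(law, c(0.03, 0.063)),
               predict_movement(law, c(0.03, 0.063)))
})

test_that("every predicted cell of the validation table matches at 3 dp", {
  val <- load_validation_table()
  F_ <- predict_movement(calibrated_movement_law(), val$stress)
  expect_equal(round_half_away(F_, 3), val$calculated)
})

test_that("quadratic fit recovers exact coefficients and matches the
           normal-equations oracle", {
  # noiseless interpolation
  x <- c(0.1, 0.2, 0.3, 0.4)
  y <- 2 * x^2 + 3 * x + 1
  fit <- fit_movement_law(data.frame(stress = x, movement = y))
  expect_equal(fit$law$a, 2, tolerance = 1e-9)
  expect_equal(fit$law$b, 3, tolerance = 1e-9)
  expect_equal(fit$law$c, 1, tolerance = 1e-9)
  expect_lt(fit$rmse, 1e-10)

  # calibration table: QR-based fit vs independent dense normal equations
  cal <- load_calibration_table()
  fit2 <- fit_movement_law(data.frame(stress = cal$stress,
                                      movement = cal$movement))
  oracle <- quad_fit_oracle(cal$stress, cal$movement)
  expect_equal(fit2$law$c, oracle[1], tolerance = 1e-6)
  expect_equal(fit2$law$b, oracle[2], tolerance = 1e-6)
  expect_equal(fit2$law$a, oracle[3], tolerance = 1e-6)
})

test_that("fit errors on rank-deficient input", {
  expect_error(fit_movement_law(data.frame(stress = c(0.1, 0.2),
                                           movement = c(1, 2))),
               "rank-deficiency")
  expect_error(fit_movement_law(data.frame(stress = rep(0.1, 5),
                                           movement = runif(5))),
               "rank-deficiency")
})

test_that("fit/predict round trip and noisy parameter recovery", {
  law <- quadratic_law(1500, -120, 3.2)
  x <- seq(0.02, 0.08, length.out = 12)
  fit <- fit_movement_law(data.frame(stress = x,
                                     movement = predict_movement(law, x)))
  expect_equal(fit$law$a, law$a, tolerance = 1e-9)
  expect_equal(fit$law$b, law$b, tolerance = 1e-9)
  expect_equal(fit$law$c, law$c, tolerance = 1e-9)

  set.seed(42)
  n <- 50
  x <- runif(n, 0.02, 0.08)
  y <- predict_movement(law, x) + rnorm(n, sd = 0.05)
  fitn <- fit_movement_law(data.frame(stress = x, movement = y))
  expect_lt(abs(fitn$law$a - law$a), 3 * fitn$se["a"])
  expect_lt(abs(fitn$law$b - law$b), 3 * fitn$se["b"])
  expect_lt(abs(fitn$law$c - law$c), 3 * fitn$se["c"])
})

test_that("rigid superimposition recovers constructed transforms", {
  set.seed(7)
  cloud <- matrix(rnorm(30), ncol = 3)
  # identity
  tr0 <- rigid_superimpose(cloud, cloud)
  expect_equal(tr0$R, diag(3), tolerance = 1e-12)
  expect_equal(tr0$t, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(attr(tr0, "rmsd"), 1e-12)
  # 90 degrees about z + translation
  R <- rotation_matrix(c(0, 0, 1), pi / 2)
  moved <- cloud %*% t(R) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  tr <- rigid_superimpose(fixed = moved, moving = cloud)
  expect_equal(tr$R, R, tolerance = 1e-10)
  expect_equal(tr$t, c(1, 2, 3), tolerance = 1e-10)
  # permutation invariance of corresponding pairs
  perm <- sample(nrow(cloud))
  trp <- rigid_superimpose(moved[perm, ], cloud[perm, ])
  expect_equal(trp$R, tr$R, tolerance = 1e-10)
  expect_equal(trp$t, tr$t, tolerance = 1e-10)
})

test_that("rigid superimposition is optimal against random rigid transforms", {
  set.seed(11)
  cloud <- matrix(rnorm(24), ncol = 3)
  noisy <- cloud + matrix(rnorm(24, sd = 0.01), ncol = 3)
  tr <- rigid_superimpose(fixed = noisy, moving = cloud)
  best <- attr(tr, "rmsd")
  # brute-force sampling oracle: no random rigid transform does better
  for (i in 1:1000) {
    R <- rotation_matrix(rnorm(3), rnorm(1, sd = 0.05))
    t <- rnorm(3, sd = 0.02)
    moved <- cloud %*% t(R) + matrix(t, nrow(cloud), 3, byrow = TRUE)
    rmsd <- sqrt(mean(rowSums((moved - noisy)^2)))
    expect_gte(rmsd, best - 1e-12)
  }
})

test_that("rigid superimposition rejects degenerate point sets", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(rigid_superimpose(line, line), "degeneracy|collinear")
  expect_error(rigid_superimpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               ">= 3")
})

test_that("landmark displacement measures Euclidean movement", {
  lm0 <- matrix(rnorm(9), 3, 3, dimnames = list(c("C1D", "C2D", "C1M"), NULL))
  id <- rigid_transform(diag(3), c(0, 0, 0))
  expect_equal(unname(landmark_displacement(id, lm0, lm0)), rep(0, 3))
  # 3-4-5 translation
  after <- sweep(lm0, 2, -c(0.3, 0.4, 0))
  expect_equal(unname(landmark_displacement(id, lm0, after)), rep(0.5, 3))
  # pure 0.5 mm distal translation
  after2 <- sweep(lm0, 2, -c(0.5, 0, 0))
  expect_equal(unname(landmark_displacement(id, lm0, after2)), rep(0.5, 3))
  # id mismatch
  bad <- after
  rownames(bad) <- c("C1D", "C2D", "XX")
  expect_error(landmark_displacement(id, lm0, bad), "mismatch")
})

test_that("Dahlberg method error matches direct summation", {
  expect_equal(dahlberg_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dahlberg_error(c(1, 1), c(0, 0)), sqrt(2 / 4),
               tolerance = 1e-12)
  set.seed(3)
  a <- rnorm(25); b <- rnorm(25)
  expect_equal(dahlberg_error(a, b), dahlberg_oracle(a, b),
               tolerance = 1e-12)
  expect_error(dahlberg_error(1:3, 1:4), "equal length")
})

test_that("validation ranges over the packaged table match the printed
           summary", {
  val <- load_validation_table()
  recs <- movement_records(calibrated_movement_law(),
                           data.frame(landmark = val$landmark,
                                      period = val$movement_period,
                                      stress = val$stress,
                                      clinical = val$clinical))
  s <- validate_records(recs)
  expect_equal(s$min_diff, 0.003)
  expect_equal(s$max_diff, 0.085)
  expect_equal(s$min_percent, 0.36)
  expect_equal(s$max_percent, 8.96)
  # per-cell percent agrees with the printed cells within 0.06 points
  expect_true(all(abs(recs$percent_display - val$percent_printed) <= 0.06))
  # records with F == C give zero differences
  recs0 <- movement_records(calibrated_movement_law(),
                            data.frame(landmark = "C1D", period = "T0-1",
                                       stress = 0.05,
                                       clinical = predict_movement(
                                         calibrated_movement_law(), 0.05)))
  expect_equal(recs0$diff, 0)
  expect_equal(recs0$percent, 0)
})

test_that("display rounding is half-away-from-zero", {
  expect_equal(round_half_away(0.0005, 3), 0.001)
  expect_equal(round_half_away(-0.0005, 3), -0.001)
  expect_equal(round_half_away(2.675, 2), 2.68)
  expect_equal(round_half_away(1.3784999, 3), 1.378)
})
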