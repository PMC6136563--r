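# Independent dense oracle for the tet4 element stiffness: textbook
# B-matrix/D-matrix computation written without reusing package internals.
tet4_stiffness_oracle <- function(X, E, nu) {
  # shape N_i = a_i + b_i x + c_i y + d_i z via inversion of the nodal matrix
  A <- cbind(1, X)
  C <- solve(A)                       # rows: coefficients of each monomial
  grads <- t(C[2:4, ])                # per node: (b_i, c_i, d_i)
  V <- abs(det(A)) / 6
  B <- matrix(0, 6, 12)
  for (i in 1:4) {
    b <- grads[i, 1]; c_ <- grads[i, 2]; d <- grads[i, 3]
    B[, (3 * i - 2):(3 * i)] <-
      rbind(c(b, 0, 0), c(0, c_, 0), c(0, 0, d),
            c(c_, b, 0), c(0, d, c_), c(d, 0, b))
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  V * t(B) %*% D %*% B
}

test_that("element stiffness matches an independent dense computation", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mesh <- orthofem:::new_volume_mesh(X, matrix(1:4, 1), "tooth")
  for (prm in list(c(1, 0), c(200, 0.3), c(0.68, 0.49))) {
    sys <- assemble(mesh, material_table("tooth", prm[1], prm[2]))
    Ke <- as.matrix(sys$K)
    Ko <- tet4_stiffness_oracle(X, prm[1], prm[2])
    expect_lt(max(abs(Ke - Ko)), 1e-12 * max(abs(Ko)))
  }
  # a randomly distorted tet as well
  set.seed(1)
  X2 <- X + matrix(runif(12, -0.2, 0.2), 4, 3)
  mesh2 <- orthofem:::new_volume_mesh(X2, matrix(1:4, 1), "tooth")
  sys2 <- assemble(mesh2, material_table("tooth", 50, 0.25))
  expect_lt(max(abs(as.matrix(sys2$K) - tet4_stiffness_oracle(X2, 50, 0.25))),
            1e-11 * max(abs(as.matrix(sys2$K))))
})

test_that("stiffness is symmetric with a rigid-body null space", {
  mesh <- tet_mesh_box(c(1, 1, 1), c(2, 2, 2))
  sys <- assemble(mesh, material_table("tooth", 100, 0.3))
  K <- sys$K
  expect_lt(max(abs(K - Matrix::t(K))), 1e-12 * max(abs(K)))
  n <- nrow(mesh$nodes)
  # three translations and one rotation
  modes <- list(rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n),
                as.numeric(t(cbind(-mesh$nodes[, 2], mesh$nodes[, 1], 0))))
  for (m in modes)
    expect_lt(max(abs(K %*% m)) / max(abs(K)), 1e-10)
})

test_that("missing material for a region tag raises a configuration error", {
  mesh <- tet_mesh_box(c(1, 1, 1), c(1, 1, 1), region = "pdl")
  expect_error(assemble(mesh, material_table("tooth", 100, 0.3)),
               "no material.*pdl")
})

test_that("patch test: linear boundary displacement reproduces constant
           strain to machine precision", {
  mesh <- tet_mesh_box(c(1, 1, 1), c(3, 3, 3))
  E <- 120; nu <- 0.31
  sys <- assemble(mesh, material_table("tooth", E, nu))
  A <- matrix(c(0.01, 0.002, 0.001,
                0.003, -0.005, 0.002,
                0.001, 0.004, -0.002), 3, 3, byrow = TRUE)
  uexact <- mesh$nodes %*% t(A)
  bnodes <- sort(unique(unlist(mesh$node_sets)))
  spec <- load_boundary_spec(force_magnitude = 0, fixed_nodes = integer(),
                             prescribed_nodes = bnodes,
                             prescribed_u = uexact[bnodes, , drop = FALSE])
  res <- solve_fem(sys, spec)
  expect_lt(max(abs(res$u - uexact)), 1e-12)
  eps <- (A + t(A)) / 2
  sig <- orthofem:::elasticity_matrix(E, nu) %*%
    c(diag(eps), 2 * eps[1, 2], 2 * eps[2, 3], 2 * eps[3, 1])
  expect_lt(max(abs(sweep(res$stress, 2, as.numeric(sig)))), 1e-12)
})

test_that("uniaxial bar reproduces sigma = F/A and equilibrium", {
  mesh <- tet_mesh_box(c(1, 1, 5), c(2, 2, 10))
  sys <- assemble(mesh, material_table("tooth", 1000, 0.0))
  spec <- load_boundary_spec(force_magnitude = 1,
                             bracket_nodes = mesh$node_sets$zmax,
                             force_direction = c(0, 0, 1),
                             fixed_nodes = mesh$node_sets$zmin)
  res <- solve_fem(sys, spec)
  # F = 1 N over A = 1 mm^2 -> 1.0 MPa axial stress
  expect_lt(abs(mean(res$stress[, 3]) - 1.0), 0.01)
  expect_lt(abs(mean(von_mises(res$stress)) - 1.0), 0.01)
  # global equilibrium: reactions balance the applied load to < 1e-8 N
  total_applied <- colSums(matrix(res$applied, ncol = 3, byrow = TRUE))
  expect_lt(max(abs(colSums(res$reactions) + total_applied)), 1e-8)
  # zero load -> zero displacement
  spec0 <- load_boundary_spec(force_magnitude = 0,
                              fixed_nodes = mesh$node_sets$zmin)
  res0 <- solve_fem(sys, spec0)
  expect_equal(max(abs(res0$u)), 0)
})

test_that("tet10 cantilever matches Euler-Bernoulli tip deflection", {
  E <- 1000; nu <- 0.3; L <- 10
  mesh <- mesh_to_order2(tet_mesh_box(c(1, 1, L), c(2, 2, 20)))
  nd <- mesh$nodes
  tip <- which(abs(nd[, 3] - L) < 1e-9)
  fix <- which(abs(nd[, 3]) < 1e-9)
  sys <- assemble(mesh, material_table("tooth", E, nu))
  spec <- load_boundary_spec(force_magnitude = 1, bracket_nodes = tip,
                             force_direction = c(1, 0, 0),
                             fixed_nodes = fix)
  res <- solve_fem(sys, spec)
  delta <- 1 * L^3 / (3 * E * (1 / 12))
  expect_lt(abs(mean(res$u[tip, 1]) - delta) / delta, 0.05)
})

test_that("solution is linear in the applied force", {
  sol <- default_solution()
  spec2 <- sol$spec
  spec2$force_magnitude <- 2
  res2 <- solve_fem(sol$sys, spec2)
  expect_equal(res2$u, 2 * sol$result$u, tolerance = 1e-9)
  expect_equal(res2$stress, 2 * sol$result$stress, tolerance = 1e-9)
})

test_that("singular systems are reported with a helpful message", {
  mesh <- tet_mesh_box(c(1, 1, 1), c(1, 1, 1))
  sys <- assemble(mesh, material_table("tooth", 10, 0.3))
  expect_error(load_boundary_spec(force_magnitude = 1,
                                  bracket_nodes = 1L,
                                  force_direction = c(1, 0, 0),
                                  fixed_nodes = integer()),
               "non-empty")
})

test_that("von Mises invariant behaves on canonical states", {
  # uniform uniaxial stress -> von Mises equals it; hydrostatic -> 0
  expect_equal(von_mises(c(1, 0, 0, 0, 0, 0)), 1)
  expect_equal(von_mises(c(0.4, 0.4, 0.4, 0, 0, 0)), 0)
  expect_equal(max_principal(c(-1, -2, -3, 0, 0, 0)), -1)
  # shear state: vm = sqrt(3) tau
  expect_equal(von_mises(c(0, 0, 0, 0.5, 0, 0)), sqrt(3) * 0.5)
})

test_that("landmark stress sampling is positive and cervical > middle", {
  sol <- default_solution()
  s <- von_mises_at(sol$result, sol$model$landmarks)
  expect_true(all(s$stress > 0))
  byid <- setNames(s$stress, s$landmark)
  # cervical-third landmarks carry more stress than the middle-third C2D
  # under the tipping-dominated point load
  expect_gt(byid["C1D"], byid["C2D"])
  expect_gt(byid["C1M"], byid["C2D"])
  # empty sample set triggers a sampling error
  expect_error(von_mises_at(sol$result, sol$model$landmarks, radius = 0.01),
               "sampling error")
  expect_error(von_mises_at(sol$result, sol$model$landmarks,
                            region = "nonexistent"),
               "no elements")
})

test_that("von Mises samples are invariant under a common rotation", {
  sol <- default_solution()
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  mesh_r <- sol$mesh
  mesh_r$nodes <- mesh_r$nodes %*% t(R)
  sys_r <- assemble(mesh_r)
  spec_r <- sol$spec
  spec_r$force_direction <- as.numeric(R %*% sol$spec$force_direction)
  res_r <- solve_fem(sys_r, spec_r)
  lm_r <- sol$model$landmarks %*% t(R)
  rownames(lm_r) <- rownames(sol$model$landmarks)
  s0 <- von_mises_at(sol$result, sol$model$landmarks, radius = 1.0)
  s1 <- von_mises_at(res_r, lm_r, radius = 1.0)
  expect_equal(s1$stress, s0$stress, tolerance = 1e-8)
})

test_that("sliding archwire constraint keeps bracket motion on the wire
           axis", {
  mesh <- tet_mesh_box(c(1, 1, 5), c(2, 2, 10))
  sys <- assemble(mesh, material_table("tooth", 1000, 0.3))
  wire <- c(0, 0, 1)
  spec <- load_boundary_spec(force_magnitude = 1,
                             bracket_nodes = mesh$node_sets$zmax,
                             force_direction = c(1, 0, 1) / sqrt(2),
                             fixed_nodes = mesh$node_sets$zmin,
                             wire_axis = wire)
  res <- solve_fem(sys, spec)
  ub <- res$u[mesh$node_sets$zmax, , drop = FALSE]
  # displacement perpendicular to the wire is suppressed at bracket nodes
  perp <- ub - outer(as.numeric(ub %*% wire), wire)
  expect_lt(max(abs(perp)), 1e-12)
})
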