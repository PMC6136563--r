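# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

default_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- build_model(anatomy_config())
  .fixtures$model
}

default_mesh <- function() {
  if (is.null(.fixtures$mesh))
    .fixtures$mesh <- tetrahedralize(default_model())
  .fixtures$mesh
}

# full default FE solve of the retraction load case (the expensive fixture)
default_solution <- function() {
  if (is.null(.fixtures$solution)) {
    model <- default_model()
    mesh <- default_mesh()
    sys <- assemble(mesh)
    spec <- load_boundary_spec(
      force_magnitude = 1,
      bracket_nodes = mesh$node_sets$bracket_nodes,
      force_direction = (model$tad_point - model$bracket_point) /
        sqrt(sum((model$tad_point - model$bracket_point)^2)),
      fixed_nodes = mesh$node_sets$fixed_base)
    .fixtures$solution <- list(model = model, mesh = mesh, sys = sys,
                               spec = spec, result = solve_fem(sys, spec))
  }
  .fixtures$solution
}

# independent dense normal-equations quadratic fit (oracle for lm-based fit)
quad_fit_oracle <- function(x, y) {
  V <- cbind(1, x, x^2)
  as.numeric(solve(t(V) %*% V, t(V) %*% y))  # (c, b, a)
}

# independent brute-force Dahlberg computation
dahlberg_oracle <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + (a[i] - b[i])^2
  sqrt(s / (2 * length(a)))
}

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
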