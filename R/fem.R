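#' Material table for the retraction model
#'
#' Linear-elastic constants per tissue region (units: N/mm^2 = MPa for E).
#' Defaults are the standard constants used for this model: cortical bone
#' 13,800 / 0.26; cancellous bone 345 / 0.31; tooth 20,000 / 0.15;
#' periodontal ligament 0.68 / 0.49; stainless steel (bracket/archwire)
#' 210,000 / 0.30.
#'
#' @param regions character vector of region names.
#' @param E Young's moduli (N/mm^2), parallel to `regions`.
#' @param nu Poisson's ratios, parallel to `regions`.
#' @return a `data.frame` with columns `region`, `E`, `nu`.
#' @export
material_table <- function(regions = c("cortical", "cancellous", "tooth",
                                       "pdl", "bracket"),
                           E = c(13800, 345, 20000, 0.68, 210000),
                           nu = c(0.26, 0.31, 0.15, 0.49, 0.30)) {
  stopifnot(length(regions) == length(E), length(E) == length(nu))
  if (any(E <= 0)) stop("Young's modulus must be > 0")
  if (any(nu < 0 | nu >= 0.5)) stop("Poisson's ratio must be in [0, 0.5)")
  data.frame(region = regions, E = E, nu = nu, stringsAsFactors = FALSE)
}

# isotropic elasticity matrix, Voigt order (xx, yy, zz, xy, yz, zx) with
# engineering shear strains
elasticity_matrix <- function(E, nu) {
  f <- E / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- f * nu
  diag(D)[1:3] <- f * (1 - nu)
  diag(D)[4:6] <- f * (1 - 2 * nu) / 2
  D
}

# B matrix (6 x 3n) from shape-function gradients (n x 3)
strain_matrix <- function(grads) {
  n <- nrow(grads)
  B <- matrix(0, 6, 3 * n)
  ix <- 3 * (seq_len(n) - 1L)
  B[1, ix + 1] <- grads[, 1]
  B[2, ix + 2] <- grads[, 2]
  B[3, ix + 3] <- grads[, 3]
  B[4, ix + 1] <- grads[, 2]; B[4, ix + 2] <- grads[, 1]
  B[5, ix + 2] <- grads[, 3]; B[5, ix + 3] <- grads[, 2]
  B[6, ix + 1] <- grads[, 3]; B[6, ix + 3] <- grads[, 1]
  B
}

# gradients of the 4 linear shape functions for a tet with corners X (4x3)
tet4_grads <- function(X) {
  J <- rbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
  G <- solve(J)                 # columns of G are grad(xi_k)
  g234 <- t(G)                  # rows: grad N2, grad N3, grad N4
  rbind(-colSums(g234), g234)
}

# tet10 shape function derivatives wrt (xi, eta, zeta) at a natural point
tet10_dN <- function(xi) {
  l2 <- xi[1]; l3 <- xi[2]; l4 <- xi[3]
  l1 <- 1 - l2 - l3 - l4
  # derivative wrt barycentric lambdas
  dL <- matrix(0, 10, 4)
  dL[1, 1] <- 4 * l1 - 1
  dL[2, 2] <- 4 * l2 - 1
  dL[3, 3] <- 4 * l3 - 1
  dL[4, 4] <- 4 * l4 - 1
  dL[5, 1] <- 4 * l2; dL[5, 2] <- 4 * l1       # edge 1-2
  dL[6, 2] <- 4 * l3; dL[6, 3] <- 4 * l2       # edge 2-3
  dL[7, 3] <- 4 * l1; dL[7, 1] <- 4 * l3       # edge 3-1
  dL[8, 1] <- 4 * l4; dL[8, 4] <- 4 * l1       # edge 1-4
  dL[9, 2] <- 4 * l4; dL[9, 4] <- 4 * l2       # edge 2-4
  dL[10, 3] <- 4 * l4; dL[10, 4] <- 4 * l3     # edge 3-4
  # lambda1 = 1 - xi - eta - zeta
  dL[, 2:4] - dL[, 1]
}

#' Assemble the global stiffness operator
#'
#' Small-strain isotropic linear elasticity on a region-tagged tetrahedral
#' mesh.  Tet4 elements use the exact constant-strain formulation; tet10
#' elements use 4-point Gauss quadrature.  The assembled operator is
#' symmetric and (before constraints) maps rigid-body displacements to zero
#' force.
#'
#' @param mesh a `volume_mesh`.
#' @param materials a [material_table()] covering every region tag present.
#' @return a `fem_system` holding the sparse stiffness matrix `K`, the mesh,
#'   the materials and per-element stress-recovery operators.
#' @export
assemble <- function(mesh, materials = material_table()) {
  regs <- unique(mesh$region)
  missing <- setdiff(regs, materials$region)
  if (length(missing))
    stop("configuration error: no material for region tag(s): ",
         paste(missing, collapse = ", "))
  Dm <- lapply(seq_len(nrow(materials)), function(i)
    elasticity_matrix(materials$E[i], materials$nu[i]))
  names(Dm) <- materials$region

  conn <- mesh$elems
  npe <- ncol(conn)
  M <- nrow(conn)
  ndof_e <- 3L * npe
  nent <- ndof_e^2
  ii <- integer(M * nent); jj <- integer(M * nent); xx <- numeric(M * nent)
  DB <- array(0, c(6, ndof_e, M))       # volume-averaged D*B per element
  vols <- numeric(M)

  if (npe == 10L) {
    a <- (5 + 3 * sqrt(5)) / 20; b <- (5 - sqrt(5)) / 20
    gp <- rbind(c(a, b, b), c(b, a, b), c(b, b, a), c(b, b, b))
    dNs <- lapply(seq_len(4), function(g) tet10_dN(gp[g, ]))
  }

  for (e in seq_len(M)) {
    idx <- conn[e, ]
    X <- mesh$nodes[idx, , drop = FALSE]
    D <- Dm[[mesh$region[e]]]
    if (npe == 4L) {
      J <- rbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
      V <- det(J) / 6
      B <- strain_matrix(tet4_grads(X))
      DBe <- D %*% B
      Ke <- V * crossprod(B, DBe)
      DB[, , e] <- DBe
    } else {
      Ke <- matrix(0, ndof_e, ndof_e)
      DBe <- matrix(0, 6, ndof_e)
      V <- 0
      for (g in seq_along(dNs)) {
        dN <- dNs[[g]]
        J <- t(X) %*% dN              # 3x3
        dJ <- det(J)
        grads <- dN %*% solve(J)
        B <- strain_matrix(grads)
        w <- dJ / 24                  # 4-point rule on the unit tet
        Ke <- Ke + w * crossprod(B, D %*% B)
        DBe <- DBe + w * (D %*% B)
        V <- V + w
      }
      DBe <- DBe / V
      DB[, , e] <- DBe
    }
    vols[e] <- V
    dofs <- as.integer(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
    span <- (e - 1L) * nent + seq_len(nent)
    ii[span] <- rep(dofs, times = ndof_e)
    jj[span] <- rep(dofs, each = ndof_e)
    xx[span] <- Ke
  }
  ndof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  structure(list(K = K, mesh = mesh, materials = materials, DB = DB,
                 volumes = vols),
            class = "fem_system")
}

#' @export
print.fem_system <- function(x, ...) {
  cat(sprintf("fem_system: %d dofs, %d elements\n", nrow(x$K),
              nrow(x$mesh$elems)))
  invisible(x)
}

#' Load and boundary specification
#'
#' @param force_magnitude applied retraction force (N); the clinical 100 gf
#'   is modelled as exactly 1.0 N.
#' @param bracket_nodes node indices receiving the load (split equally).
#' @param force_direction unit 3-vector; if NULL it is computed at solve
#'   time from the model's bracket point toward the TAD.
#' @param fixed_nodes node indices with all displacement components fixed
#'   to zero (bone-block cut faces).
#' @param wire_axis optional unit 3-vector: when given, bracket nodes may
#'   displace only along this axis (sliding-archwire multi-point
#'   constraint).
#' @param prescribed_nodes,prescribed_u optional nonzero Dirichlet data:
#'   node indices and a matching n x 3 displacement matrix.
#' @return a `load_boundary_spec`.
#' @export
load_boundary_spec <- function(force_magnitude = 1.0,
                               bracket_nodes = integer(),
                               force_direction = NULL,
                               fixed_nodes = integer(),
                               wire_axis = NULL,
                               prescribed_nodes = NULL,
                               prescribed_u = NULL) {
  if (force_magnitude < 0) stop("force_magnitude must be >= 0")
  if (!is.null(force_direction)) force_direction <- unit_vector(force_direction)
  if (!is.null(wire_axis)) wire_axis <- unit_vector(wire_axis)
  if (length(fixed_nodes) == 0 && is.null(prescribed_nodes))
    stop("fixed node set must be non-empty")
  structure(list(force_magnitude = force_magnitude,
                 bracket_nodes = as.integer(bracket_nodes),
                 force_direction = force_direction,
                 fixed_nodes = as.integer(fixed_nodes),
                 wire_axis = wire_axis,
                 prescribed_nodes = prescribed_nodes,
                 prescribed_u = prescribed_u),
            class = "load_boundary_spec")
}

#' Solve the constrained elasticity system
#'
#' Applies the load, eliminates Dirichlet constraints (zero at fixed nodes,
#' arbitrary prescribed values if given) and, when a `wire_axis` is present,
#' reduces bracket-node displacements to the sliding direction via a
#' transformation-matrix multi-point constraint.  The reduced SPD system is
#' solved by sparse Cholesky factorization; the relative residual is checked
#' against 1e-8.
#'
#' @param system a `fem_system` from [assemble()].
#' @param spec a [load_boundary_spec()].
#' @return a `solve_result` with nodal displacements `u` (N x 3, mm),
#'   per-element Voigt stresses `stress` (M x 6, N/mm^2), reaction forces at
#'   constrained nodes, the applied force vector and the solve residual.
#' @export
solve_fem <- function(system, spec) {
  mesh <- system$mesh
  K <- system$K
  N <- nrow(mesh$nodes)
  ndof <- 3L * N

  f <- numeric(ndof)
  if (length(spec$bracket_nodes) > 0 && spec$force_magnitude > 0) {
    if (is.null(spec$force_direction))
      stop("force_direction is required when a load is applied")
    per <- spec$force_magnitude / length(spec$bracket_nodes)
    for (n in spec$bracket_nodes) {
      f[3 * n - 2:0] <- f[3 * n - 2:0] + per * spec$force_direction
    }
  }

  u0 <- numeric(ndof)
  diri_nodes <- spec$fixed_nodes
  if (!is.null(spec$prescribed_nodes)) {
    pu <- spec$prescribed_u
    for (k in seq_along(spec$prescribed_nodes)) {
      n <- spec$prescribed_nodes[k]
      u0[3 * n - 2:0] <- pu[k, ]
    }
    diri_nodes <- union(diri_nodes, spec$prescribed_nodes)
  }
  diri_dofs <- as.integer(rbind(3L * diri_nodes - 2L,
                                3L * diri_nodes - 1L, 3L * diri_nodes))

  sliding <- if (!is.null(spec$wire_axis))
    setdiff(spec$bracket_nodes, diri_nodes) else integer()
  free_nodes <- setdiff(seq_len(N), union(diri_nodes, sliding))
  free_dofs <- as.integer(rbind(3L * free_nodes - 2L,
                                3L * free_nodes - 1L, 3L * free_nodes))
  nq <- length(free_dofs) + length(sliding)
  Ti <- c(free_dofs, as.integer(rbind(3L * sliding - 2L,
                                      3L * sliding - 1L, 3L * sliding)))
  Tj <- c(seq_along(free_dofs),
          rep(length(free_dofs) + seq_along(sliding), each = 3L))
  Tx <- c(rep(1, length(free_dofs)), rep(spec$wire_axis, length(sliding)))
  T <- Matrix::sparseMatrix(i = Ti, j = Tj, x = Tx, dims = c(ndof, nq))

  A <- Matrix::forceSymmetric(Matrix::crossprod(T, K %*% T))
  rhs <- Matrix::crossprod(T, f - K %*% u0)
  q <- tryCatch(
    as.numeric(Matrix::solve(Matrix::Cholesky(A, LDL = FALSE), rhs)),
    error = function(e) {
      mode <- if (length(diri_nodes) == 0) "all six rigid-body modes"
      else "a rigid-body rotation or translation left unconstrained"
      stop("singular system: ", mode,
           " (check the fixed node set); Cholesky said: ",
           conditionMessage(e))
    })
  res <- sqrt(sum((as.numeric(A %*% q) - as.numeric(rhs))^2))
  den <- sqrt(sum(as.numeric(rhs)^2))
  rel_res <- if (den > 0) res / den else res
  if (rel_res > 1e-8)
    warning(sprintf("solver residual %.3g exceeds 1e-8", rel_res))

  u <- as.numeric(T %*% q) + u0
  r_full <- as.numeric(K %*% u) - f
  reactions <- cbind(r_full[3 * diri_nodes - 2],
                     r_full[3 * diri_nodes - 1],
                     r_full[3 * diri_nodes])

  # element stresses from the stored (averaged) D*B operators
  conn <- mesh$elems
  npe <- ncol(conn)
  M <- nrow(conn)
  UE <- matrix(0, 3L * npe, M)
  for (a in seq_len(npe)) {
    UE[3 * a - 2, ] <- u[3 * conn[, a] - 2]
    UE[3 * a - 1, ] <- u[3 * conn[, a] - 1]
    UE[3 * a, ]     <- u[3 * conn[, a]]
  }
  stress <- matrix(0, M, 6)
  for (k in 1:6)
    stress[, k] <- colSums(matrix(system$DB[k, , ], ncol = M) * UE)

  structure(list(u = matrix(u, ncol = 3, byrow = TRUE),
                 stress = stress,
                 reaction_nodes = diri_nodes,
                 reactions = reactions,
                 applied = f,
                 residual = rel_res,
                 mesh = mesh,
                 volumes = system$volumes),
            class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("solve_result: max |u| = %.4g mm, residual = %.3g\n",
              max(abs(x$u)), x$residual))
  invisible(x)
}

#' Sample a stress invariant at root landmarks
#'
#' For each landmark, the Voigt stress tensors of the elements of the
#' requested tissue region whose centroids lie within `radius` of the
#' landmark are volume-averaged, and the scalar invariant of the averaged
#' tensor is returned.  The default radius is twice the local edge length
#' of the sampled region.
#'
#' @param result a `solve_result`.
#' @param landmarks matrix with 3 columns and row names (landmark ids).
#' @param region tissue region to sample (default `"pdl"`).
#' @param radius sampling radius (mm); NULL for the default.
#' @param measure `"von_mises"` (default) or `"max_principal"`.
#' @param period optional period label attached to the samples.
#' @return a `data.frame` with columns `landmark`, `period`, `stress`
#'   (N/mm^2) and attribute `measure`.
#' @export
von_mises_at <- function(result, landmarks, region = "pdl", radius = NULL,
                         measure = c("von_mises", "max_principal"),
                         period = NA_character_) {
  measure <- match.arg(measure)
  mesh <- result$mesh
  sel <- which(mesh$region == region)
  if (!length(sel)) stop("sampling error: no elements tagged '", region, "'")
  cent <- element_centroids(mesh)[sel, , drop = FALSE]
  vol <- abs(result$volumes[sel])
  if (is.null(radius)) {
    edge <- mean((6 * sqrt(2) * vol)^(1 / 3))
    radius <- 2 * edge
  }
  vals <- vapply(seq_len(nrow(landmarks)), function(i) {
    p <- landmarks[i, ]
    d2 <- (cent[, 1] - p[1])^2 + (cent[, 2] - p[2])^2 + (cent[, 3] - p[3])^2
    inside <- d2 <= radius^2
    if (!any(inside))
      stop("sampling error: no '", region, "' elements within r = ",
           signif(radius, 3), " mm of landmark ", rownames(landmarks)[i],
           "; increase radius")
    w <- vol[inside] / sum(vol[inside])
    sbar <- colSums(result$stress[sel[inside], , drop = FALSE] * w)
    if (measure == "von_mises") von_mises(sbar) else max_principal(sbar)
  }, numeric(1))
  out <- data.frame(landmark = rownames(landmarks),
                    period = period, stress = vals,
                    stringsAsFactors = FALSE)
  attr(out, "measure") <- measure
  attr(out, "radius") <- radius
  out
}
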