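#' Configuration for the parametric canine/PDL/bone anatomy
#'
#' Describes a single maxillary canine segment used throughout the retraction
#' simulation: a tapered elliptical root and capped frustum crown, a thin
#' periodontal-ligament (PDL) shell around the root, and a rectangular
#' alveolar bone block with a cortical outer shell.  All lengths are in mm.
#'
#' The coordinate convention is: x mesial(-)/distal(+), y buccal(+)/
#' palatal(-), z apical(-)/coronal(+), with the origin at the cervical centre
#' of the canine.  Positive tooth movement is distal (+x).
#'
#' @param root_length root length from cervix to apex (mm).
#' @param crown_height crown height above the cervix (mm).
#' @param cervical_radius mesio-distal semi-axis of the root at the cervix
#'   (mm); the bucco-palatal semi-axis is `ellipse_ratio` times this.
#' @param root_apical_radius mesio-distal semi-axis at the apex (mm).
#' @param ellipse_ratio bucco-palatal/mesio-distal semi-axis ratio.
#' @param pdl_thickness PDL shell thickness (mm).
#' @param bone_block named lengths `c(x=, y=, z=)` of the alveolar block:
#'   full widths in x and y, depth below the cervical plane in z (mm).
#' @param cortical_shell_thickness thickness of the cortical layer on the
#'   outer block faces (mm).
#' @param bracket_offset stand-off of the bracket point from the buccal crown
#'   surface (mm).
#' @param tad_position 3-vector (mm): temporary skeletal anchorage device
#'   (mini-screw) head; must lie distal (+x) to the canine.
#' @param random_seed integer seed for the (tiny) surface-vertex jitter that
#'   emulates scan roughness; volume meshing is unaffected.
#' @param surface_resolution number of circumferential points used when
#'   triangulating the region surfaces.
#' @return an object of class `anatomy_config`.
#' @export
anatomy_config <- function(root_length = 15,
                           crown_height = 8,
                           cervical_radius = 2.8,
                           root_apical_radius = 0.8,
                           ellipse_ratio = 0.85,
                           pdl_thickness = 0.25,
                           bone_block = c(x = 18, y = 12, z = 18),
                           cortical_shell_thickness = 1.5,
                           bracket_offset = 1.0,
                           tad_position = c(9, 0, -5),
                           random_seed = 1L,
                           surface_resolution = 48L) {
  cfg <- list(root_length = root_length, crown_height = crown_height,
              cervical_radius = cervical_radius,
              root_apical_radius = root_apical_radius,
              ellipse_ratio = ellipse_ratio,
              pdl_thickness = pdl_thickness,
              bone_block = bone_block,
              cortical_shell_thickness = cortical_shell_thickness,
              bracket_offset = bracket_offset,
              tad_position = as.numeric(tad_position),
              random_seed = as.integer(random_seed),
              surface_resolution = as.integer(surface_resolution))
  lengths <- c(root_length, crown_height, cervical_radius,
               root_apical_radius, pdl_thickness, bone_block,
               cortical_shell_thickness, bracket_offset)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("anatomy configuration error: all lengths must be finite and > 0")
  if (pdl_thickness >= cervical_radius)
    stop("anatomy configuration error: pdl_thickness must be much smaller ",
         "than cervical_radius")
  if (root_apical_radius >= cervical_radius)
    stop("anatomy configuration error: root must taper ",
         "(root_apical_radius < cervical_radius)")
  if (cfg$tad_position[1] <= cervical_radius)
    stop("anatomy configuration error: tad_position must be distal (+x) ",
         "to the canine")
  if (root_length + pdl_thickness >= bone_block[["z"]])
    stop("anatomy configuration error: bone_block z depth must exceed ",
         "root_length + pdl_thickness")
  if (2 * (cervical_radius + pdl_thickness) >= min(bone_block[["x"]],
                                                   bone_block[["y"]]))
    stop("anatomy configuration error: bone block too narrow for the socket")
  if (surface_resolution < 12L)
    stop("anatomy configuration error: surface_resolution must be >= 12")
  class(cfg) <- "anatomy_config"
  cfg
}

# Semi-axes (rx, ry) of the tooth cross-section at height z.
# Root: linear taper cervix -> apex.  Crown: linear flare to 1.15x.
# Below the apex a "virtual" continuation (floored) is used by the mesher.
root_semiaxes <- function(cfg, z) {
  L <- cfg$root_length
  taper <- (cfg$cervical_radius - cfg$root_apical_radius) / L
  rx <- ifelse(z >= 0,
               cfg$cervical_radius * (1 + 0.15 * pmin(z, cfg$crown_height) /
                                        cfg$crown_height),
               cfg$cervical_radius + taper * z)
  rx <- pmax(rx, 0.3)
  cbind(rx = rx, ry = cfg$ellipse_ratio * rx)
}

# Polar radius of the (optionally offset) tooth cross-section at angle theta.
radius_at <- function(cfg, theta, z, offset = 0) {
  ax <- root_semiaxes(cfg, z)
  1 / sqrt((cos(theta) / (ax[, "rx"] + offset))^2 +
           (sin(theta) / (ax[, "ry"] + offset))^2)
}

# Analytic landmark coordinates: C1D/C2D on the distal (+x) root surface at
# 1/3 and 2/3 of root length from the cervix, C1M mesial (-x) at 1/3.
landmark_positions <- function(cfg) {
  L <- cfg$root_length
  z1 <- -L / 3
  z2 <- -2 * L / 3
  r1 <- radius_at(cfg, 0, z1)
  r2 <- radius_at(cfg, 0, z2)
  m <- rbind(C1D = c(r1, 0, z1),
             C2D = c(r2, 0, z2),
             C1M = c(-r1, 0, z1))
  colnames(m) <- c("x", "y", "z")
  m
}

# ---- triangulated closed surfaces ------------------------------------------

new_tri_surface <- function(vertices, faces) {
  structure(list(vertices = vertices, faces = faces), class = "tri_surface")
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf("tri_surface: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Closed surface of revolution-like topology: pole, stack of rings (each a
# n_theta x 3 matrix, in sweep order), pole.  Faces are wound consistently so
# orientation is globally coherent; orient_outward() fixes the global sense.
lathe_closed <- function(rings, bottom_center, top_center) {
  nt <- nrow(rings[[1]])
  nr <- length(rings)
  verts <- rbind(matrix(bottom_center, 1, 3),
                 do.call(rbind, rings),
                 matrix(top_center, 1, 3))
  ring_id <- function(j, i) 1L + (j - 1L) * nt + ((i - 1L) %% nt) + 1L
  faces <- vector("list", nr + 1L)
  i <- seq_len(nt)
  faces[[1]] <- cbind(1L, ring_id(1L, i + 1L), ring_id(1L, i))
  for (j in seq_len(nr - 1L)) {
    a <- ring_id(j, i); a2 <- ring_id(j, i + 1L)
    b <- ring_id(j + 1L, i); b2 <- ring_id(j + 1L, i + 1L)
    faces[[j + 1L]] <- rbind(cbind(a, a2, b2), cbind(a, b2, b))
  }
  top <- nrow(verts)
  faces[[nr + 1L]] <- cbind(top, ring_id(nr, i), ring_id(nr, i + 1L))
  new_tri_surface(verts, do.call(rbind, faces))
}

# Signed volume enclosed by a closed triangulated surface (divergence
# theorem); positive when faces are wound outward.
surface_volume <- function(surf) {
  v <- surf$vertices; f <- surf$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

orient_outward <- function(surf) {
  if (surface_volume(surf) < 0) surf$faces <- surf$faces[, c(1L, 3L, 2L)]
  surf
}

#' Check that a triangulated surface is watertight
#'
#' A surface is watertight when every edge is shared by exactly two faces
#' with opposite orientation (each directed edge appears exactly once).
#'
#' @param surf a `tri_surface`.
#' @return logical scalar.
#' @export
surface_is_watertight <- function(surf) {
  f <- surf$faces
  he <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key)) return(FALSE)
  rkey <- paste(he[, 2], he[, 1])
  all(rkey %in% key)
}

# Euler characteristic V - E + F of a triangulated surface (2 for a sphere).
surface_euler <- function(surf) {
  f <- surf$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  nrow(surf$vertices) - nrow(e) + nrow(f)
}

# ---- model construction -----------------------------------------------------

ring_at <- function(cfg, theta, z, offset = 0) {
  r <- radius_at(cfg, theta, z, offset)
  cbind(r * cos(theta), r * sin(theta), z)
}

# theta grid shared by all surfaces/rings
theta_grid <- function(n) seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]

# Point on the bone-block rectangle boundary in direction theta.
rect_boundary_point <- function(cfg, theta, z) {
  hx <- cfg$bone_block[["x"]] / 2
  hy <- cfg$bone_block[["y"]] / 2
  s <- pmax(abs(cos(theta)) / hx, abs(sin(theta)) / hy)
  cbind(cos(theta) / s, sin(theta) / s, z)
}

#' Build the parametric anatomy model
#'
#' Generates watertight closed triangulated surfaces for the tooth (root +
#' crown), the PDL shell and the alveolar bone block (with the tooth socket
#' carved out), places the three canine-root landmarks C1D, C2D and C1M, the
#' bracket attachment point and the TAD anchor, and records the palatal
#' reference patch used for superimposition.  Deterministic for a given
#' configuration and `random_seed`.
#'
#' @param config an [anatomy_config()].
#' @return an object of class `anatomy_model` with elements `surfaces`
#'   (named list of `tri_surface`), `landmarks` (3x3 matrix, rows C1D, C2D,
#'   C1M), `bracket_point`, `tad_point`, `palatal_patch`, `config`, and the
#'   cumulative rigid `transform` of the tooth (identity for a fresh model).
#' @export
build_model <- function(config) {
  if (!inherits(config, "anatomy_config"))
    stop("config must be an anatomy_config")
  cfg <- config
  L <- cfg$root_length; H <- cfg$crown_height; t <- cfg$pdl_thickness
  nt <- cfg$surface_resolution
  th <- theta_grid(nt)
  spacing <- 2 * pi * cfg$cervical_radius / nt
  nz_root <- max(8L, ceiling(L / spacing))
  nz_crown <- max(4L, ceiling(H / spacing))

  z_root <- seq(-L, 0, length.out = nz_root + 1L)
  z_crown <- seq(0, H, length.out = nz_crown + 1L)

  # tooth: single lathe from apex pole to crown-top pole
  tooth_rings <- lapply(c(z_root, z_crown[-1L]),
                        function(z) ring_at(cfg, th, z))
  tooth <- lathe_closed(tooth_rings, c(0, 0, -L), c(0, 0, H))

  # PDL shell: up the inner (root) wall, across the cervical annulus, down
  # the outer (socket) wall -- one closed lathe path
  inner <- lapply(z_root, function(z) ring_at(cfg, th, z))
  outer <- lapply(rev(z_root), function(z) ring_at(cfg, th, z, offset = t))
  pdl <- lathe_closed(c(inner, outer), c(0, 0, -L), c(0, 0, -L - t))

  # bone block with socket: socket wall up from its apex, across the crest
  # annulus to the rectangle rim, down the block sides, bottom cap
  zb <- -cfg$bone_block[["z"]]
  sock <- lapply(z_root, function(z) ring_at(cfg, th, z, offset = t))
  z_side <- seq(0, zb, length.out = max(3L, ceiling(-zb / (4 * spacing)) + 1L))
  rim <- lapply(z_side, function(z) rect_boundary_point(cfg, th, z))
  bone <- lathe_closed(c(sock, rim), c(0, 0, -L - t), c(0, 0, zb))

  surfaces <- lapply(list(tooth = tooth, pdl = pdl, bone = bone),
                     orient_outward)

  # scan-roughness jitter on surface vertices only (shared vertices move
  # together, so watertightness is preserved)
  set.seed(cfg$random_seed)
  jitter_mm <- 1e-4
  surfaces <- lapply(surfaces, function(s) {
    s$vertices <- s$vertices +
      matrix(stats::runif(length(s$vertices), -jitter_mm, jitter_mm),
             ncol = 3)
    s
  })

  crown_mid <- H / 2
  ry_crown <- root_semiaxes(cfg, crown_mid)[, "ry"]
  bracket <- c(0, ry_crown + cfg$bracket_offset, crown_mid)

  crown_verts <- tooth$vertices[tooth$vertices[, 3] > 0.2 * H, , drop = FALSE]
  palatal <- crown_verts[crown_verts[, 2] <
                           -0.5 * root_semiaxes(cfg, crown_mid)[, "ry"], ,
                         drop = FALSE]

  model <- structure(list(
    surfaces = surfaces,
    landmarks = landmark_positions(cfg),
    bracket_point = bracket,
    tad_point = cfg$tad_position,
    palatal_patch = palatal,
    config = cfg,
    transform = rigid_transform(diag(3), c(0, 0, 0)),
    facet_counts = vapply(surfaces, function(s) nrow(s$faces), integer(1))
  ), class = "anatomy_model")
  model
}

#' @export
print.anatomy_model <- function(x, ...) {
  cat("anatomy_model (canine retraction segment)\n")
  cat(sprintf("  regions: %s\n", paste(names(x$surfaces), collapse = ", ")))
  cat(sprintf("  facets: %s\n",
              paste(sprintf("%s=%d", names(x$facet_counts), x$facet_counts),
                    collapse = ", ")))
  cat(sprintf("  landmarks: %s\n", paste(rownames(x$landmarks),
                                         collapse = ", ")))
  invisible(x)
}
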