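#' @title Region-tagged tetrahedral volume meshes
#' @description Internal constructor for `volume_mesh` objects.
#' @param nodes N x 3 coordinates (mm).
#' @param elems M x 4 (tet4) or M x 10 (tet10) connectivity.
#' @param region length-M character region tags.
#' @param node_sets named list of node index vectors.
#' @param order 1 or 2.
#' @param target_edge nominal edge length (mm), if applicable.
#' @return a `volume_mesh`.
#' @keywords internal
new_volume_mesh <- function(nodes, elems, region, node_sets = list(),
                            order = 1L, target_edge = NA_real_) {
  stopifnot(ncol(nodes) == 3, nrow(elems) == length(region))
  structure(list(nodes = nodes, elems = elems, region = region,
                 node_sets = node_sets, order = as.integer(order),
                 target_edge = target_edge),
            class = "volume_mesh")
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("volume_mesh: %d nodes, %d tet%d elements\n",
              nrow(x$nodes), nrow(x$elems), if (x$order == 1) 4L else 10L))
  print(table(x$region))
  invisible(x)
}

#' Signed volumes of the tetrahedral elements
#'
#' @param mesh a `volume_mesh` (corner nodes are used for tet10).
#' @return numeric vector of signed element volumes (mm^3).
#' @export
tet_volumes <- function(mesh) {
  signed_tet_volumes(mesh$nodes, mesh$elems[, 1:4, drop = FALSE])
}

signed_tet_volumes <- function(nodes, conn) {
  a <- nodes[conn[, 1], , drop = FALSE]
  b <- nodes[conn[, 2], , drop = FALSE] - a
  c_ <- nodes[conn[, 3], , drop = FALSE] - a
  d <- nodes[conn[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}

# flip tets with negative volume (swap last two corners)
fix_tet_orientation <- function(nodes, conn) {
  v <- signed_tet_volumes(nodes, conn)
  neg <- v < 0
  if (any(neg)) conn[neg, 3:4] <- conn[neg, 4:3]
  conn
}

element_centroids <- function(mesh) {
  conn <- mesh$elems[, 1:4, drop = FALSE]
  (mesh$nodes[conn[, 1], , drop = FALSE] +
   mesh$nodes[conn[, 2], , drop = FALSE] +
   mesh$nodes[conn[, 3], , drop = FALSE] +
   mesh$nodes[conn[, 4], , drop = FALSE]) / 4
}

# ---- prism splitting (minimum-global-index rule) ---------------------------
#
# Each triangular prism (bottom a,b,c; top d,e,f; vertical edges a-d, b-e,
# c-f) is cut into 3 tets.  Every quad face is split along the diagonal
# through its minimum global node index, which is consistent between
# neighbouring prisms and provably never produces the non-decomposable
# (Schoenhardt) diagonal cycle: the prism's minimum vertex lies on two of
# the three quads, so at most one diagonal can avoid it.
split_prisms <- function(P) {
  perms <- list(c(1, 2, 3, 4, 5, 6),
                c(2, 3, 1, 5, 6, 4),
                c(3, 1, 2, 6, 4, 5),
                c(4, 6, 5, 1, 3, 2),
                c(5, 4, 6, 2, 1, 3),
                c(6, 5, 4, 3, 2, 1))
  mpos <- max.col(-P, ties.method = "first")
  N <- P
  for (k in 2:6) {
    idx <- mpos == k
    if (any(idx)) N[idx, ] <- P[idx, perms[[k]], drop = FALSE]
  }
  a <- N[, 1]; b <- N[, 2]; c_ <- N[, 3]
  d <- N[, 4]; e <- N[, 5]; f <- N[, 6]
  t1 <- cbind(a, d, e, f)
  # quad (b, c, f, e): diagonal through its minimum vertex
  use_bf <- pmin(b, f) < pmin(c_, e)
  t2 <- cbind(a, b, c_, ifelse(use_bf, f, e))
  t3 <- cbind(a,
              ifelse(use_bf, b, c_),
              f,
              e)
  rbind(t1, t2, t3)
}

# ---- structured box mesh ----------------------------------------------------

#' Structured tetrahedral mesh of a rectangular box
#'
#' Divides the box into a regular hexahedral grid and splits each cell into
#' 6 tetrahedra (Kuhn/Freudenthal subdivision, conforming) or 5 tetrahedra
#' (alternating corner scheme with checkerboard parity).
#'
#' @param lengths box edge lengths `c(lx, ly, lz)` (mm).
#' @param n cell counts `c(nx, ny, nz)`.
#' @param origin minimum corner.
#' @param region region tag applied to all elements.
#' @param split 6 (default) or 5 tetrahedra per cell.
#' @return a `volume_mesh` with face node sets `xmin`, `xmax`, ..., `zmax`.
#' @export
tet_mesh_box <- function(lengths = c(1, 1, 1), n = c(2, 2, 2),
                         origin = c(0, 0, 0), region = "tooth", split = 6L) {
  n <- as.integer(n)
  xs <- seq(origin[1], origin[1] + lengths[1], length.out = n[1] + 1L)
  ys <- seq(origin[2], origin[2] + lengths[2], length.out = n[2] + 1L)
  zs <- seq(origin[3], origin[3] + lengths[3], length.out = n[3] + 1L)
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nid <- function(i, j, k)
    i + (n[1] + 1L) * (j - 1L) + (n[1] + 1L) * (n[2] + 1L) * (k - 1L)
  cells <- expand.grid(i = seq_len(n[1]), j = seq_len(n[2]),
                       k = seq_len(n[3]))
  corner <- function(di, dj, dk)
    nid(cells$i + di, cells$j + dj, cells$k + dk)
  v <- list(corner(0, 0, 0), corner(1, 0, 0), corner(0, 1, 0),
            corner(1, 1, 0), corner(0, 0, 1), corner(1, 0, 1),
            corner(0, 1, 1), corner(1, 1, 1))
  if (split == 6L) {
    # Kuhn: six tets around the main diagonal v1 -> v8
    paths <- list(c(1, 2, 4, 8), c(1, 4, 3, 8), c(1, 3, 7, 8),
                  c(1, 7, 5, 8), c(1, 5, 6, 8), c(1, 6, 2, 8))
    conn <- do.call(rbind, lapply(paths, function(p)
      cbind(v[[p[1]]], v[[p[2]]], v[[p[3]]], v[[p[4]]])))
  } else if (split == 5L) {
    par <- (cells$i + cells$j + cells$k) %% 2L == 0L
    five <- function(q) {
      # central tet (q1,q4,q6,q7 corners pattern) + 4 corner tets
      rbind(cbind(q[[1]], q[[4]], q[[6]], q[[7]]),
            cbind(q[[1]], q[[2]], q[[4]], q[[6]]),
            cbind(q[[1]], q[[3]], q[[7]], q[[4]]),
            cbind(q[[1]], q[[5]], q[[6]], q[[7]]),
            cbind(q[[4]], q[[6]], q[[7]], q[[8]]))
    }
    mirror <- list(v[[2]], v[[1]], v[[4]], v[[3]],
                   v[[6]], v[[5]], v[[8]], v[[7]])
    ce <- five(v); cm <- five(mirror)
    sel <- rep(par, 5L)
    conn <- ce
    conn[!sel, ] <- cm[!sel, ]
  } else stop("split must be 5 or 6")
  conn <- fix_tet_orientation(nodes, conn)
  tol <- 1e-9 * max(lengths)
  sets <- list(
    xmin = which(abs(nodes[, 1] - xs[1]) < tol),
    xmax = which(abs(nodes[, 1] - xs[n[1] + 1L]) < tol),
    ymin = which(abs(nodes[, 2] - ys[1]) < tol),
    ymax = which(abs(nodes[, 2] - ys[n[2] + 1L]) < tol),
    zmin = which(abs(nodes[, 3] - zs[1]) < tol),
    zmax = which(abs(nodes[, 3] - zs[n[3] + 1L]) < tol))
  new_volume_mesh(nodes, conn, rep(region, nrow(conn)), sets,
                  target_edge = max(lengths / n))
}

# ---- anatomy mesher ---------------------------------------------------------

# Analytic region classification of a point in the canonical (untransformed)
# frame.  Order matters: tooth, then PDL, then cortical/cancellous bone.
classify_points <- function(cfg, p) {
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  L <- cfg$root_length; t <- cfg$pdl_thickness
  hx <- cfg$bone_block[["x"]] / 2; hy <- cfg$bone_block[["y"]] / 2
  zb <- -cfg$bone_block[["z"]]
  ax <- root_semiaxes(cfg, z)
  in_tooth <- z >= -L & (x / ax[, "rx"])^2 + (y / ax[, "ry"])^2 <= 1
  in_tooth <- in_tooth | z > 0
  in_sock <- (x / (ax[, "rx"] + t))^2 + (y / (ax[, "ry"] + t))^2 <= 1
  axL <- root_semiaxes(cfg, -L)
  under_apex <- z < -L & z >= -L - t &
    (x / (axL[, "rx"] + t))^2 + (y / (axL[, "ry"] + t))^2 <= 1
  in_pdl <- (!in_tooth) & ((z >= -L & in_sock) | under_apex)
  dist_boundary <- pmin(hx - abs(x), hy - abs(y), z - zb, -z)
  out <- ifelse(in_tooth, "tooth",
         ifelse(in_pdl, "pdl",
         ifelse(dist_boundary <= cfg$cortical_shell_thickness,
                "cortical", "cancellous")))
  out
}

# z-levels of the main (bone) stack: snapped at block bottom, PDL apex cap,
# root apex and the cervical plane
main_z_levels <- function(cfg, h) {
  L <- cfg$root_length; t <- cfg$pdl_thickness
  zb <- -cfg$bone_block[["z"]]
  seg <- function(a, b, n) seq(a, b, length.out = max(1L, n) + 1L)
  z1 <- seg(zb, -L - t, ceiling((-L - t - zb) / (1.5 * h)))
  z2 <- seg(-L - t, -L, 1L)
  z3 <- seg(-L, 0, ceiling(L / h))
  unique(c(z1, z2[-1L], z3[-1L]))
}

#' Tetrahedralize an anatomy model
#'
#' Builds a boundary-fitted, region-tagged tetrahedral mesh of the full
#' segment (tooth + PDL + bone block).  A tooth-axis-centred ring template
#' is extruded through the block depth and the crown height; the resulting
#' triangular prisms are split into tetrahedra with the minimum-global-index
#' rule, which guarantees a conforming mesh.  The template is fitted to the
#' root surface and the socket wall, so tooth/PDL and PDL/bone interfaces
#' coincide with element faces along the root; elements are tagged by
#' analytic classification of their centroids.  Any accumulated rigid tooth
#' displacement in `model$transform` is applied to the tooth/PDL/socket
#' nodes with a smooth blend that leaves the block boundary fixed.
#'
#' @param model an `anatomy_model` (all surfaces must be watertight).
#' @param target_edge nominal element edge length near the root (mm).
#' @param order 1 for 4-node tets, 2 for 10-node tets (edge midpoints).
#' @param n_pdl_layers radial element layers through the PDL thickness.
#' @return a `volume_mesh` with node sets `fixed_base`, `bracket_nodes`,
#'   `palatal_patch`.
#' @export
tetrahedralize <- function(model, target_edge = 0.7, order = 1L,
                           n_pdl_layers = 2L) {
  if (!inherits(model, "anatomy_model")) stop("model must be an anatomy_model")
  for (nm in names(model$surfaces))
    if (!surface_is_watertight(model$surfaces[[nm]]))
      stop("meshing error: surface '", nm, "' is not watertight")
  if (target_edge <= 0) stop("target_edge must be > 0")
  cfg <- model$config
  h <- target_edge
  L <- cfg$root_length; H <- cfg$crown_height; t <- cfg$pdl_thickness
  hx <- cfg$bone_block[["x"]] / 2; hy <- cfg$bone_block[["y"]] / 2
  zb <- -cfg$bone_block[["z"]]

  nt <- 4L * max(4L, ceiling(pi * cfg$cervical_radius / (2 * h)))
  th <- theta_grid(nt)
  # include the block-corner directions so the rectangle rim is exact
  corners <- atan2(c(hy, hy, -hy, -hy), c(hx, -hx, -hx, hx)) %% (2 * pi)
  th <- sort(c(th, corners))
  th <- th[c(TRUE, diff(th) > 1e-9)]
  nt <- length(th)
  gap <- (hx + hy) / 2 - (cfg$cervical_radius + t)
  nb <- max(2L, ceiling(gap / (1.8 * h)))

  # radial station fractions: 0 = socket wall, 1 = block boundary
  f_bone <- (seq_len(nb) / nb)^1.3
  pdl_fr <- seq_len(n_pdl_layers) / n_pdl_layers

  zs_main <- main_z_levels(cfg, h)
  zs_crown <- seq(0, H, length.out = max(2L, ceiling(H / h)) + 1L)[-1L]
  n_ring <- 2L + n_pdl_layers + nb        # tooth-mid, root, pdl..., bone...
  tpl_n_main <- 1L + n_ring * nt
  tpl_n_crown <- 1L + 2L * nt

  # template coordinates at height z (main stack)
  level_coords <- function(z) {
    rr <- radius_at(cfg, th, z)                     # root surface
    rs <- radius_at(cfg, th, z, offset = t)         # socket wall
    rb <- rect_boundary_point(cfg, th, 0)[, 1:2]
    rrect <- sqrt(rowSums(rb^2))
    rings <- c(list(0.55 * rr, rr),
               lapply(pdl_fr, function(f) rr + f * (rs - rr)),
               lapply(f_bone, function(f) (1 - f) * rs + f * rrect))
    xy <- do.call(rbind, lapply(rings, function(r)
      cbind(r * cos(th), r * sin(th))))
    rbind(c(0, 0), xy)
  }
  # station fraction (for the rigid-motion blend): 0 inside socket,
  # rising to 1 at the block boundary
  station_frac <- c(0, rep(c(rep(0, 2L + n_pdl_layers), f_bone), each = nt))

  nlev_m <- length(zs_main)
  nlev_c <- length(zs_crown)
  n_nodes <- nlev_m * tpl_n_main + nlev_c * tpl_n_crown
  nodes <- matrix(0, n_nodes, 3L)
  frac <- numeric(n_nodes)
  for (j in seq_len(nlev_m)) {
    rows <- (j - 1L) * tpl_n_main + seq_len(tpl_n_main)
    nodes[rows, 1:2] <- level_coords(zs_main[j])
    nodes[rows, 3] <- zs_main[j]
    frac[rows] <- station_frac
  }
  off_c <- nlev_m * tpl_n_main
  for (j in seq_len(nlev_c)) {
    z <- zs_crown[j]
    rr <- radius_at(cfg, th, z)
    xy <- rbind(c(0, 0), cbind(0.55 * rr * cos(th), 0.55 * rr * sin(th)),
                cbind(rr * cos(th), rr * sin(th)))
    rows <- off_c + (j - 1L) * tpl_n_crown + seq_len(tpl_n_crown)
    nodes[rows, 1:2] <- xy
    nodes[rows, 3] <- z
    frac[rows] <- 0
  }

  # 2D template triangles (indices into a level's template)
  tri_template <- function(n_ring_used) {
    i <- seq_len(nt)
    nxt <- c(seq_len(nt - 1L) + 1L, 1L)
    fan <- cbind(1L, 1L + i, 1L + nxt)
    bands <- lapply(seq_len(n_ring_used - 1L), function(k) {
      a <- 1L + (k - 1L) * nt + i; a2 <- 1L + (k - 1L) * nt + nxt
      b <- 1L + k * nt + i;       b2 <- 1L + k * nt + nxt
      rbind(cbind(a, a2, b2), cbind(a, b2, b))
    })
    rbind(fan, do.call(rbind, bands))
  }
  tri_m <- tri_template(n_ring)
  tri_c <- tri_template(2L)

  # prisms: main stack
  prisms <- vector("list", nlev_m - 1L + nlev_c)
  for (j in seq_len(nlev_m - 1L)) {
    lo <- (j - 1L) * tpl_n_main; up <- j * tpl_n_main
    prisms[[j]] <- cbind(lo + tri_m, up + tri_m)
  }
  # crown stack: first layer connects the z=0 main level (template prefix is
  # identical to the crown template) to crown level 1
  top_main <- (nlev_m - 1L) * tpl_n_main
  for (j in seq_len(nlev_c)) {
    lo <- if (j == 1L) top_main else off_c + (j - 2L) * tpl_n_crown
    up <- off_c + (j - 1L) * tpl_n_crown
    prisms[[nlev_m - 1L + j]] <- cbind(lo + tri_c, up + tri_c)
  }
  conn <- split_prisms(do.call(rbind, prisms))
  conn <- fix_tet_orientation(nodes, conn)

  cent <- (nodes[conn[, 1], ] + nodes[conn[, 2], ] +
           nodes[conn[, 3], ] + nodes[conn[, 4], ]) / 4
  region <- classify_points(cfg, cent)

  # apply accumulated rigid tooth motion with a boundary-preserving blend
  tr <- model$transform
  if (!is_identity_transform(tr)) {
    lam_r <- (1 - frac)^2
    lam_z <- pmin(1, pmax(0, (nodes[, 3] - zb) / ((-L - t) - zb)))
    lam <- lam_r * pmax(lam_z, as.numeric(nodes[, 3] >= -L - t))
    moved <- transform_points(tr, nodes)
    nodes <- nodes + lam * (moved - nodes)
    conn <- fix_tet_orientation(nodes, conn)
  }

  tol <- 1e-6
  fixed <- which(abs(abs(nodes[, 1]) - hx) < tol | abs(nodes[, 3] - zb) < tol)
  # crown tooth-surface nodes: outer ring (ring 2) of each crown level
  crown_surface <- unlist(lapply(seq_len(nlev_c), function(j)
    off_c + (j - 1L) * tpl_n_crown + 1L + nt + seq_len(nt)))
  d2 <- rowSums((nodes[crown_surface, , drop = FALSE] -
                 matrix(model$bracket_point, length(crown_surface), 3,
                        byrow = TRUE))^2)
  bracket_nodes <- crown_surface[which.min(d2)]
  palatal <- crown_surface[nodes[crown_surface, 2] < -0.3 * cfg$cervical_radius]

  out <- new_volume_mesh(nodes, conn, region,
                         node_sets = list(fixed_base = fixed,
                                          bracket_nodes = bracket_nodes,
                                          palatal_patch = palatal),
                         order = 1L, target_edge = h)
  if (order == 2L) out <- mesh_to_order2(out)
  out
}

#' Convert a tet4 mesh to tet10 by edge-midpoint insertion
#'
#' @param mesh a `volume_mesh` of order 1.
#' @return a `volume_mesh` of order 2 (VTK/Abaqus tet10 node ordering).
#' @export
mesh_to_order2 <- function(mesh) {
  if (mesh$order != 1L) stop("mesh is already order 2")
  conn <- mesh$elems
  ed <- rbind(conn[, c(1, 2)], conn[, c(2, 3)], conn[, c(3, 1)],
              conn[, c(1, 4)], conn[, c(2, 4)], conn[, c(3, 4)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  uk <- unique(key)
  eid <- match(key, uk)
  first <- !duplicated(eid)
  mids <- (mesh$nodes[ed[first, 1], , drop = FALSE] +
           mesh$nodes[ed[first, 2], , drop = FALSE]) / 2
  n0 <- nrow(mesh$nodes)
  m <- nrow(conn)
  midcols <- matrix(n0 + eid, nrow = m)  # columns: edges in order above
  mesh$nodes <- rbind(mesh$nodes, mids)
  mesh$elems <- cbind(conn, midcols)
  mesh$order <- 2L
  # midside nodes join a node set when both edge endpoints belong to it
  ep <- cbind(ed[first, 1], ed[first, 2])
  mesh$node_sets <- lapply(mesh$node_sets, function(s) {
    inset <- ep[, 1] %in% s & ep[, 2] %in% s
    c(s, n0 + which(inset))
  })
  mesh
}

#' Mesh quality report
#'
#' Computes per-element volume, normalized aspect ratio
#' (circumradius / (3 inradius); 1 for the regular tetrahedron) and minimum
#' dihedral angle, and flags elements whose aspect ratio exceeds a
#' threshold.
#'
#' @param mesh a `volume_mesh`.
#' @param aspect_threshold flag elements above this normalized aspect ratio.
#' @return a list with `n_elements`, `region_counts`, `min_volume`,
#'   `aspect` (min/mean/max), `min_dihedral_deg`, and `flagged` element
#'   indices.
#' @export
mesh_quality <- function(mesh, aspect_threshold = 12) {
  conn <- mesh$elems[, 1:4, drop = FALSE]
  v <- signed_tet_volumes(mesh$nodes, conn)
  m <- nrow(conn)
  aspect <- numeric(m)
  mindih <- numeric(m)
  for (i in seq_len(m)) {
    p <- mesh$nodes[conn[i, ], , drop = FALSE]
    q <- sweep(p[2:4, , drop = FALSE], 2, p[1, ])
    rhs <- 0.5 * rowSums(q^2)
    cc <- tryCatch(solve(q, rhs), error = function(e) rep(Inf, 3))
    R <- sqrt(sum(cc^2))
    areas <- vapply(list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4)),
                    function(ix) {
                      e1 <- p[ix[2], ] - p[ix[1], ]
                      e2 <- p[ix[3], ] - p[ix[1], ]
                      cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
                              e1[3] * e2[1] - e1[1] * e2[3],
                              e1[1] * e2[2] - e1[2] * e2[1])
                      0.5 * sqrt(sum(cr^2))
                    }, numeric(1))
    r <- 3 * abs(v[i]) / sum(areas)
    aspect[i] <- if (r > 0) R / (3 * r) else Inf
    # dihedral angles: face normals oriented away from the opposite vertex
    faces <- list(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
    fn <- t(vapply(seq_along(faces), function(fi) {
      ix <- faces[[fi]]
      opp <- setdiff(1:4, ix)
      n <- face_normal(p[ix[1], ], p[ix[2], ], p[ix[3], ])
      if (sum(n * (p[opp, ] - p[ix[1], ])) > 0) n <- -n
      n
    }, numeric(3)))
    pairs <- utils::combn(4, 2)
    ang <- apply(pairs, 2, function(ix) {
      ca <- sum(fn[ix[1], ] * fn[ix[2], ])
      pi - acos(pmin(1, pmax(-1, ca)))
    })
    mindih[i] <- min(ang) * 180 / pi
  }
  list(n_elements = m,
       region_counts = table(mesh$region),
       min_volume = min(v),
       aspect = c(min = min(aspect), mean = mean(aspect),
                  max = max(aspect)),
       min_dihedral_deg = min(mindih),
       dihedral_deg = mindih,
       aspect_ratio = aspect,
       flagged = which(aspect > aspect_threshold | v <= 0))
}

face_normal <- function(a, b, c) {
  e1 <- b - a; e2 <- c - a
  n <- c(e1[2] * e2[3] - e1[3] * e2[2],
         e1[3] * e2[1] - e1[1] * e2[3],
         e1[1] * e2[2] - e1[2] * e2[1])
  len <- sqrt(sum(n^2))
  if (len < .Machine$double.eps) return(c(0, 0, 1))  # degenerate face
  n / len
}
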