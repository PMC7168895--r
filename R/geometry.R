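#' Shape parameters of a synthetic saccular aneurysm
#'
#' Parameterizes the spherical-cap dome family: a sphere of radius
#' `dome_radius` clipped by the neck (ostium) plane at signed distance
#' `neck_offset` from the sphere center (negative offsets put the neck plane
#' below the center, i.e. a supra-hemispherical dome taller than its radius).
#' `parent_diameter` and `neck_position` locate the dome on the parent
#' vessel for the 2D simulation domain.
#'
#' @param dome_radius Sphere radius, mm (> 0).
#' @param neck_offset Signed distance of the neck plane from the dome center,
#'   mm; |neck_offset| < dome_radius. 0 gives a hemisphere.
#' @param parent_diameter Parent vessel diameter, mm (> 0).
#' @param neck_position Dome center position along the parent vessel, as a
#'   fraction of channel length (0, 1); default mid-channel.
#' @return An object of class `shape_params`.
#' @export
shape_params <- function(dome_radius, neck_offset = 0, parent_diameter = 4,
                         neck_position = 0.5) {
  if (dome_radius <= 0) stop_domain("`dome_radius` must be positive (mm).")
  if (abs(neck_offset) >= dome_radius)
    stop_domain("|neck_offset| must be smaller than `dome_radius`.")
  if (parent_diameter <= 0) stop_domain("`parent_diameter` must be positive (mm).")
  if (neck_position <= 0 || neck_position >= 1)
    stop_domain("`neck_position` must lie strictly inside (0, 1).")
  structure(list(dome_radius = dome_radius, neck_offset = neck_offset,
                 parent_diameter = parent_diameter,
                 neck_position = neck_position),
            class = "shape_params")
}

#' Dome height, neck radius and width of a spherical cap
#'
#' Closed forms for the cap family: height \eqn{H = R - s}, neck (ostium)
#' radius \eqn{\sqrt{R^2 - s^2}}, and width \eqn{W = 2R} when the cap
#' contains the equator (\eqn{s \le 0}) else the neck diameter.
#'
#' @param shape A [shape_params()].
#' @return Named list with `height`, `neck_radius`, `width` (mm).
#' @keywords internal
cap_closed_form <- function(shape) {
  R <- shape$dome_radius; s <- shape$neck_offset
  nr <- sqrt(R^2 - s^2)
  list(height = R - s, neck_radius = nr,
       width = if (s <= 0) 2 * R else 2 * nr)
}

#' Triangulated surface mesh
#'
#' Vertices in mm, 0-based-free: `triangles` holds 1-based vertex indices.
#' @param vertices n x 3 numeric matrix, mm.
#' @param triangles m x 3 integer matrix of vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3 || ncol(triangles) != 3)
    stop_domain("vertices and triangles must have 3 columns.")
  if (max(triangles) > nrow(vertices) || min(triangles) < 1L)
    stop_domain("triangle indices out of range.")
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles (mm units)\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

#' Neck (ostium) plane
#'
#' @param point A point on the plane, mm.
#' @param normal Plane normal pointing into the dome; normalized on input.
#' @return An object of class `neck_plane`.
#' @export
neck_plane <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  if (length(point) != 3 || length(normal) != 3)
    stop_domain("`point` and `normal` must be length-3.")
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop_domain("`normal` must be non-zero.")
  structure(list(point = point, normal = normal / nn), class = "neck_plane")
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# Edges used by exactly one triangle, as a 2-column index matrix.
boundary_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

#' Build a triangulated spherical-cap dome mesh
#'
#' Constructs the dome as rings of latitude from the apex down to the neck
#' plane, triangulated with an apex fan and quad-split bands. The neck plane
#' is returned with its normal pointing into the dome. The mesh is watertight
#' up to the neck boundary loop, whose vertices lie exactly on the plane.
#'
#' @param shape A [shape_params()].
#' @param resolution Target edge length, mm.
#' @return List with elements `mesh` ([surface_mesh()]) and `neck`
#'   ([neck_plane()]). The dome apex points along +z; the neck plane is
#'   z = 0 with normal (0, 0, 1); coordinates in mm, neck centered at origin.
#' @examples
#' dm <- make_dome_mesh(shape_params(2), resolution = 0.3)
#' measure_morphometrics(dm$mesh, dm$neck)
#' @export
make_dome_mesh <- function(shape, resolution = 0.2) {
  stopifnot(inherits(shape, "shape_params"))
  if (resolution <= 0) stop_domain("`resolution` must be positive (mm).")
  R <- shape$dome_radius; s <- shape$neck_offset
  cf <- cap_closed_form(shape)
  # polar angle from apex (+z through sphere center) down to the neck ring
  theta_max <- acos(s / R)
  n_rings <- max(2L, ceiling(theta_max * R / resolution))
  n_boundary <- ceiling(2 * pi * cf$neck_radius / resolution)
  if (n_boundary < 8L)
    stop_domain("`resolution` too coarse to resolve the neck (need >= 8 boundary vertices).")
  # sphere center sits at z = -s so the neck plane is z = 0
  thetas <- seq(0, theta_max, length.out = n_rings + 1L)
  verts <- matrix(c(0, 0, R - s), ncol = 3)  # apex
  ring_start <- integer(n_rings); ring_len <- integer(n_rings)
  for (i in seq_len(n_rings)) {
    th <- thetas[i + 1L]
    r_ring <- R * sin(th)
    m <- max(8L, ceiling(2 * pi * r_ring / resolution))
    if (i == n_rings) m <- max(m, 8L)
    phi <- 2 * pi * (seq_len(m) - 1L) / m
    ring <- cbind(r_ring * cos(phi), r_ring * sin(phi), R * cos(th) - s)
    ring_start[i] <- nrow(verts) + 1L
    ring_len[i] <- m
    verts <- rbind(verts, ring)
  }
  # snap the neck ring exactly onto the plane
  last <- seq.int(ring_start[n_rings], length.out = ring_len[n_rings])
  verts[last, 3] <- 0
  tris <- matrix(integer(), 0, 3)
  # apex fan
  m1 <- ring_len[1]
  fan <- cbind(1L, ring_start[1] + (seq_len(m1) - 1L),
               ring_start[1] + (seq_len(m1) %% m1))
  tris <- rbind(tris, fan)
  # bands between consecutive rings (possibly different counts): stitch by
  # angular proximity
  if (n_rings > 1L) for (i in seq_len(n_rings - 1L)) {
    a0 <- ring_start[i]; na <- ring_len[i]
    b0 <- ring_start[i + 1L]; nb <- ring_len[i + 1L]
    ia <- 0L; ib <- 0L
    repeat {
      if (ia == na && ib == nb) break
      # advance whichever ring's next vertex trails in angle
      ang_a <- (ia + 1) / na; ang_b <- (ib + 1) / nb
      if (ib == nb || (ia < na && ang_a <= ang_b)) {
        tris <- rbind(tris, c(a0 + ia %% na, b0 + ib %% nb, a0 + (ia + 1L) %% na))
        ia <- ia + 1L
      } else {
        tris <- rbind(tris, c(a0 + ia %% na, b0 + ib %% nb, b0 + (ib + 1L) %% nb))
        ib <- ib + 1L
      }
    }
  }
  list(mesh = surface_mesh(verts, tris),
       neck = neck_plane(c(0, 0, 0), c(0, 0, 1)))
}

#' Classify aneurysm size
#'
#' Small if the dome height (the aneurysm size) is at or below the cutoff,
#' large above it. The conventional cutoff is 5 mm, boundary inclusive on
#' the small side.
#'
#' @param height Dome height, mm (> 0). Vectorized.
#' @param cutoff Size cutoff, mm (default 5).
#' @return Character vector, `"small"` or `"large"`.
#' @examples
#' classify_size(c(3.4, 5, 6.2))
#' @export
classify_size <- function(height, cutoff = 5) {
  if (any(!is.finite(height)) || any(height <= 0))
    stop_domain("`height` must be positive.")
  ifelse(height <= cutoff, "small", "large")
}

#' Measure aneurysm morphometrics on a surface mesh
#'
#' The five morphological variables of a saccular aneurysm, measured on a
#' triangulated dome with an annotated neck plane:
#' \itemize{
#'   \item height `H`: maximum distance from the neck plane to the dome tip,
#'     measured along the neck normal;
#'   \item width `W`: longest diameter orthogonal to the height, i.e. the
#'     maximum pairwise distance among dome vertices projected onto the neck
#'     plane;
#'   \item ostium diameter `O`: maximum pairwise distance among neck
#'     boundary-loop vertices;
#'   \item ostium cross-sectional area: area of the neck-plane polygon
#'     (boundary loop ordered angularly about its centroid, shoelace);
#'   \item dome surface area: sum of dome triangle areas.
#' }
#'
#' @param mesh A [surface_mesh()] of the dome.
#' @param neck A [neck_plane()] with normal pointing into the dome.
#' @param cutoff Size cutoff in mm for [classify_size()].
#' @param plane_tol Vertices within this distance of the plane (mm) count as
#'   on-plane for the boundary loop.
#' @return A one-row tibble: `height_mm`, `width_mm`, `ostium_diameter_mm`,
#'   `ostium_area_mm2`, `surface_area_mm2`, `size_class`.
#' @export
measure_morphometrics <- function(mesh, neck, cutoff = 5, plane_tol = 1e-6) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(neck, "neck_plane"))
  v <- mesh$vertices
  d <- as.numeric((v - matrix(neck$point, nrow(v), 3, byrow = TRUE)) %*% neck$normal)
  if (!any(d > plane_tol)) stop_domain("no vertices on the dome side of the neck plane.")
  H <- max(d)
  # in-plane orthonormal basis
  n <- neck$normal
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2], n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  dome_idx <- which(d > -plane_tol)
  proj <- cbind((v %*% e1)[dome_idx], (v %*% e2)[dome_idx])
  W <- max_pairwise_diameter(proj)
  be <- boundary_edges(mesh)
  if (nrow(be) == 0L) stop_domain("mesh has no boundary loop (closed surface?).")
  loop_idx <- unique(as.vector(be))
  if (any(abs(d[loop_idx]) > max(plane_tol, 1e-3 * H)))
    warn("neck boundary loop does not lie on the neck plane; ostium metrics are approximate.")
  lp <- cbind((v %*% e1)[loop_idx], (v %*% e2)[loop_idx])
  O <- max_pairwise_diameter(lp)
  ctr <- colMeans(lp)
  ord <- order(atan2(lp[, 2] - ctr[2], lp[, 1] - ctr[1]))
  poly <- lp[ord, , drop = FALSE]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  ostium_area <- abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2])) / 2
  tibble(height_mm = H, width_mm = W, ostium_diameter_mm = O,
         ostium_area_mm2 = ostium_area,
         surface_area_mm2 = sum(triangle_areas(mesh)),
         size_class = classify_size(H, cutoff))
}

# max pairwise distance of 2D points; convex hull first to keep it O(h^2)
max_pairwise_diameter <- function(p) {
  if (nrow(p) < 2L) return(0)
  h <- grDevices::chull(p)
  q <- p[h, , drop = FALSE]
  d2 <- outer(q[, 1], q[, 1], "-")^2 + outer(q[, 2], q[, 2], "-")^2
  sqrt(max(d2))
}

#' Solve cap shape parameters from target morphometrics
#'
#' Finds the spherical-cap `(dome_radius, neck_offset)` best matching target
#' height, width and ostium diameter in least squares. Exact when the
#' targets are mutually consistent with a cap (e.g. `W = 2 dome_radius` for
#' supra-hemispherical caps); otherwise the closest cap.
#'
#' @param height,width,ostium Target measurements, mm.
#' @param parent_diameter,neck_position Passed through to [shape_params()].
#' @param height_weight Relative weight of the height residual in the least
#'   squares (default 1; the cohort generator uses a larger weight so the
#'   fitted cap's height stays on its group's side of the size cutoff).
#' @return A [shape_params()].
#' @export
cap_from_morphometrics <- function(height, width, ostium, parent_diameter = 4,
                                   neck_position = 0.5, height_weight = 1) {
  if (height <= 0 || width <= 0 || ostium <= 0)
    stop_domain("targets must be positive.")
  obj <- function(par) {
    R <- exp(par[1]); frac <- tanh(par[2])  # s = frac * R keeps |s| < R
    s <- frac * R
    nr <- sqrt(max(R^2 - s^2, 1e-12))
    w <- if (s <= 0) 2 * R else 2 * nr
    height_weight * (R - s - height)^2 + (w - width)^2 + (2 * nr - ostium)^2
  }
  # exact-cap initial guess from (H, O)
  R0 <- (height^2 + (ostium / 2)^2) / (2 * height)
  s0 <- max(min((R0 - height) / R0, 0.99), -0.99)
  fit <- optim(c(log(R0), atanh(s0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  R <- exp(fit$par[1]); s <- tanh(fit$par[2]) * R
  shape_params(dome_radius = R, neck_offset = s,
               parent_diameter = parent_diameter, neck_position = neck_position)
}
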