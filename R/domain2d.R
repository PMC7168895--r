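# 2D simulation domain: uniform staggered (MAC) grid over a straight channel
# (the parent vessel mid-plane) with a circular-segment dome opening through
# a neck gap on the upper wall. Cells are tagged parent/dome/solid; boundary
# faces are tagged inlet / outlet / wall / ostium. All coordinates are SI (m);
# shape parameters come in mm.

CELL_SOLID <- 0L
CELL_PARENT <- 1L
CELL_DOME <- 2L

#' Build the 2D channel-and-dome simulation domain
#'
#' Desk-scale analog of the 3D vascular domain: a straight channel of width
#' `parent_diameter` and length `length_factor` diameters, with the aneurysm
#' dome represented as a circular segment (the mid-plane cut of the
#' spherical-cap dome) communicating with the channel through a neck gap on
#' the upper wall. The dome circle is placed so its chord on the wall equals
#' the ostium diameter and its apex height equals the cap height.
#'
#' The domain is discretized on a uniform Cartesian grid of spacing
#' `mesh_size` (snapped so the channel width is an integer number of cells),
#' with cells tagged `parent`, `dome` or solid, and boundary faces tagged
#' inlet (left edge), outlet (right edge), wall, and the ostium segment (the
#' grid line where dome cells sit above parent cells).
#'
#' @param shape A [shape_params()], or `NULL` for a plain channel.
#' @param mesh_size Target grid spacing, mm.
#' @param length_factor Channel length in parent diameters (default 10).
#' @param parent_diameter Channel width in mm when `shape` is `NULL`.
#' @return An object of class `sim_domain` (grid geometry, cell tags, face
#'   tables, and precomputed solver structures).
#' @export
build_2d_domain <- function(shape, mesh_size = 0.25, length_factor = 10,
                            parent_diameter = 4) {
  if (!is.null(shape)) {
    stopifnot(inherits(shape, "shape_params"))
    parent_diameter <- shape$parent_diameter
  }
  if (mesh_size <= 0) stop_domain("`mesh_size` must be positive (mm).")
  d <- parent_diameter * 1e-3                     # channel width, m
  ny_chan <- max(4L, round(parent_diameter / mesh_size))
  h <- d / ny_chan                                # snapped spacing
  L <- length_factor * d
  nx <- max(8L, round(L / h)); L <- nx * h
  if (is.null(shape)) {
    ny <- ny_chan
    circ <- NULL
  } else {
    R <- shape$dome_radius * 1e-3
    s <- shape$neck_offset * 1e-3
    dome_height <- R - s
    x0 <- shape$neck_position * L
    y0 <- d - s                                   # circle center
    half_chord <- sqrt(R^2 - s^2)
    if (2 * half_chord > 0.8 * L)
      stop_domain("neck gap wider than the channel length margin.")
    ny <- ny_chan + ceiling(dome_height / h) + 1L
    circ <- list(x0 = x0, y0 = y0, R = R, tip = c(x0, d + dome_height))
  }
  xc <- (seq_len(nx) - 0.5) * h
  yc <- (seq_len(ny) - 0.5) * h
  cell <- matrix(CELL_SOLID, nx, ny)
  cell[, seq_len(ny_chan)] <- CELL_PARENT
  if (!is.null(circ)) {
    for (j in seq.int(ny_chan + 1L, ny)) {
      inside <- (xc - circ$x0)^2 + (yc[j] - circ$y0)^2 < circ$R^2
      cell[inside, j] <- CELL_DOME
    }
    if (!any(cell == CELL_DOME))
      stop_domain("`mesh_size` too coarse: dome region empty.")
  }
  dom <- list(h = h, nx = nx, ny = ny, ny_chan = ny_chan, L = L,
              width = d, cell = cell, circ = circ, shape = shape,
              xc = xc, yc = yc)
  dom$fluid <- cell != CELL_SOLID
  # ostium segment: faces on the channel-top grid line with a dome cell above
  if (!is.null(circ)) {
    io <- which(cell[, ny_chan + 1L] == CELL_DOME & cell[, ny_chan] == CELL_PARENT)
    if (length(io) < 2L)
      stop_domain("`mesh_size` too coarse: ostium not resolved.")
    dom$ostium <- list(i = io, j = ny_chan + 1L)  # v-face (i, ny_chan+1)
  } else {
    dom$ostium <- list(i = integer(), j = ny_chan + 1L)
  }
  dom$walls <- wall_face_table(dom)
  dom <- precompute_solver(dom)
  class(dom) <- "sim_domain"
  dom
}

#' @export
print.sim_domain <- function(x, ...) {
  cat(sprintf(
    "sim_domain: %d x %d grid (h = %.3g mm), %d fluid cells (%d dome), channel %g x %g mm\n",
    x$nx, x$ny, x$h * 1e3, sum(x$fluid), sum(x$cell == CELL_DOME),
    x$L * 1e3, x$width * 1e3))
  invisible(x)
}

#' Areas of the tagged regions
#'
#' @param dom A `sim_domain`.
#' @return Tibble with region (`parent`, `dome`) and area in m^2.
#' @export
domain_region_areas <- function(dom) {
  tibble(region = c("parent", "dome"),
         area_m2 = c(sum(dom$cell == CELL_PARENT), sum(dom$cell == CELL_DOME)) * dom$h^2)
}

# Wall faces: fluid cell with a solid (or out-of-box, excluding inlet/outlet)
# neighbor. One row per face: fluid cell (i, j), outward normal direction
# (N/S/E/W as dy/dx), wall midpoint, region flag of the fluid cell.
wall_face_table <- function(dom) {
  nx <- dom$nx; ny <- dom$ny; h <- dom$h
  cell <- dom$cell
  rows <- list()
  solid_at <- function(i, j) {
    if (j < 1L || j > ny) return(TRUE)             # bottom/top box edge: wall
    if (i < 1L || i > nx) return(FALSE)            # left/right: inlet/outlet
    cell[i, j] == CELL_SOLID
  }
  k <- 0L
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (cell[i, j] == CELL_SOLID) next
    for (dirn in list(c(0L, -1L), c(0L, 1L), c(-1L, 0L), c(1L, 0L))) {
      if (solid_at(i + dirn[1], j + dirn[2])) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          i = i, j = j, dx = dirn[1], dy = dirn[2],
          x = (i - 0.5 + 0.5 * dirn[1]) * h,
          y = (j - 0.5 + 0.5 * dirn[2]) * h,
          dome = cell[i, j] == CELL_DOME)
      }
    }
  }
  do.call(rbind, rows)
}

# --- precomputed solver structures -----------------------------------------
# Unknown numbering and neighbor classification for the momentum solves, and
# the (factorized) pressure-Poisson matrix. Codes: 0 zero-value neighbor,
# k>0 unknown index, -1 ghost (value = -self), -2 inlet Dirichlet,
# -3 outlet copy (value = self).
NB_ZERO <- 0L; NB_GHOST <- -1L; NB_INLET <- -2L; NB_OUTLET <- -3L

precompute_solver <- function(dom) {
  nx <- dom$nx; ny <- dom$ny
  fl <- dom$fluid
  # --- u faces: (nx+1) x ny, face i between cells i-1 and i
  u_act <- matrix(FALSE, nx + 1L, ny)
  for (i in 2:nx) u_act[i, ] <- fl[i - 1L, ] & fl[i, ]
  u_idx <- matrix(0L, nx + 1L, ny)
  u_idx[u_act] <- seq_len(sum(u_act))
  uw <- which(u_act, arr.ind = TRUE)
  ord <- order(u_idx[u_act])
  uw <- uw[ord, , drop = FALSE]
  ui <- uw[, 1]; uj <- uw[, 2]
  nu <- length(ui)
  u_nb <- function(i2, j2, lateral) {
    # classification of neighbor u face (i2, j2) seen from an active face
    out <- integer(length(i2))
    for (k in seq_along(i2)) {
      i <- i2[k]; j <- j2[k]
      if (lateral) {                              # east/west neighbor
        if (i == 1L) { out[k] <- NB_INLET; next }
        if (i == nx + 1L) { out[k] <- NB_OUTLET; next }
        out[k] <- if (u_idx[i, j] > 0L) u_idx[i, j] else NB_ZERO
      } else {                                    # north/south neighbor
        if (j < 1L || j > ny) { out[k] <- NB_GHOST; next }
        if (u_idx[i, j] > 0L) { out[k] <- u_idx[i, j]; next }
        cA <- if (i - 1L >= 1L) dom$cell[i - 1L, j] else CELL_SOLID
        cB <- if (i <= nx) dom$cell[i, j] else CELL_SOLID
        out[k] <- if (cA == CELL_SOLID && cB == CELL_SOLID) NB_GHOST else NB_ZERO
      }
    }
    out
  }
  u_str <- list(i = ui, j = uj, n = nu, idx = u_idx, act = u_act,
                E = u_nb(ui + 1L, uj, TRUE), W = u_nb(ui - 1L, uj, TRUE),
                N = u_nb(ui, uj + 1L, FALSE), S = u_nb(ui, uj - 1L, FALSE))
  # --- v faces: nx x (ny+1), face j between cells j-1 and j
  v_act <- matrix(FALSE, nx, ny + 1L)
  for (j in 2:ny) v_act[, j] <- fl[, j - 1L] & fl[, j]
  v_idx <- matrix(0L, nx, ny + 1L)
  v_idx[v_act] <- seq_len(sum(v_act))
  vw <- which(v_act, arr.ind = TRUE)
  ord <- order(v_idx[v_act])
  vw <- vw[ord, , drop = FALSE]
  vi <- vw[, 1]; vj <- vw[, 2]
  nv <- length(vi)
  v_nb <- function(i2, j2, lateral) {
    out <- integer(length(i2))
    for (k in seq_along(i2)) {
      i <- i2[k]; j <- j2[k]
      if (lateral) {                              # east/west neighbor
        if (i < 1L) { out[k] <- NB_GHOST; next }  # x = 0 boundary line
        if (i > nx) { out[k] <- NB_OUTLET; next }
        if (v_idx[i, j] > 0L) { out[k] <- v_idx[i, j]; next }
        cA <- if (j - 1L >= 1L) dom$cell[i, j - 1L] else CELL_SOLID
        cB <- if (j <= ny) dom$cell[i, j] else CELL_SOLID
        out[k] <- if (cA == CELL_SOLID && cB == CELL_SOLID) NB_GHOST else NB_ZERO
      } else {                                    # north/south: wall sits on
        if (j < 1L || j > ny + 1L) { out[k] <- NB_ZERO; next }  # the face itself
        out[k] <- if (v_idx[i, j] > 0L) v_idx[i, j] else NB_ZERO
      }
    }
    out
  }
  v_str <- list(i = vi, j = vj, n = nv, idx = v_idx, act = v_act,
                E = v_nb(vi + 1L, vj, TRUE), W = v_nb(vi - 1L, vj, TRUE),
                N = v_nb(vi, vj + 1L, FALSE), S = v_nb(vi, vj - 1L, FALSE))
  # --- pressure Poisson (constant): -Laplacian with Neumann walls/inlet and
  # Dirichlet phi = 0 on the outlet face, assembled over fluid cells
  p_idx <- matrix(0L, nx, ny)
  p_idx[fl] <- seq_len(sum(fl))
  pw <- which(fl, arr.ind = TRUE)
  ord <- order(p_idx[fl])
  pw <- pw[ord, , drop = FALSE]
  np <- nrow(pw)
  ent <- vector("list", np)
  for (k in seq_len(np)) {
    i <- pw[k, 1]; j <- pw[k, 2]
    diag <- 0
    nb_j <- integer(0)
    for (dirn in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      i2 <- i + dirn[1]; j2 <- j + dirn[2]
      if (i2 == nx + 1L) { diag <- diag + 2 }     # outlet Dirichlet face
      else if (i2 >= 1L && i2 <= nx && j2 >= 1L && j2 <= ny && fl[i2, j2]) {
        diag <- diag + 1
        nb_j <- c(nb_j, p_idx[i2, j2])
      }                                           # else Neumann: no term
    }
    ent[[k]] <- cbind(i = rep.int(k, length(nb_j) + 1L),
                      j = c(nb_j, k),
                      x = c(rep.int(-1, length(nb_j)), diag))
  }
  ent <- do.call(rbind, ent)
  A_p <- Matrix::sparseMatrix(i = ent[, 1], j = ent[, 2],
                              x = ent[, 3] / dom$h^2, dims = c(np, np))
  dom$u_str <- u_str
  dom$v_str <- v_str
  dom$p_str <- list(i = pw[, 1], j = pw[, 2], n = np, idx = p_idx)
  dom$p_chol <- Matrix::Cholesky(methods::as(A_p, "symmetricMatrix"), LDL = FALSE)
  dom
}
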