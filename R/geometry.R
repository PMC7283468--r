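#' Build the triangulated cell cortex
#'
#' Constructs an icosphere (subdivided icosahedron) of the requested radius:
#' a closed, outward-oriented triangle mesh whose vertices are the cortex
#' nodes. Edge rest lengths, reference triangle areas, total area, volume and
#' reference dihedral angles are recorded from the built state, so the sphere
#' is the stress-free configuration of the cortex.
#'
#' @param radius cell radius in m (> 0).
#' @param subdivision icosahedron subdivision level (>= 1); level `s` gives
#'   `10 * 4^s + 2` nodes and `20 * 4^s` triangles. Level 2 (162 nodes) is the
#'   test fixture size; level 3 (642 nodes) the production default.
#' @param center numeric length-3, initial center position in m.
#' @return an object of class `cell_mesh`; see Details.
#' @details A `cell_mesh` is a list with node positions `pos` (N x 3, m) and
#'   velocities `vel` (m/s), triangle index matrix `tris` (T x 3, 1-based,
#'   outward orientation), `edges` (E x 2), per-edge rest length `edge_rest`,
#'   hinge table `hinges` (E x 4: the two edge nodes then the two opposite
#'   vertices of the adjacent triangles), reference dihedral cosines/sines,
#'   per-triangle reference areas, reference total area and volume, and the
#'   triangle adjacency `tri_adj` (T x 3) used by the surface diffusion
#'   operator.
#' @export
#' @examples
#' m <- build_cell_mesh(8e-6, 2)
#' nrow(m$pos)    # 162
#' nrow(m$tris)   # 320
build_cell_mesh <- function(radius = 8e-6, subdivision = 3L,
                            center = c(0, 0, radius)) {
  stopifnot(radius > 0, subdivision >= 1)
  if (subdivision < 2)
    warning("subdivision < 2 cannot resolve the lamellipodium band")
  ico <- icosphere(subdivision)
  pos <- ico$verts * radius
  pos <- sweep(pos, 2, center, `+`)
  mesh_from_triangulation(pos, ico$tris)
}

#' Build a closed mesh object from positions and triangles
#'
#' Derives edges, hinge connectivity, triangle adjacency and the reference
#' (rest) state from an arbitrary closed, outward-oriented triangulation.
#'
#' @param pos N x 3 matrix of vertex positions, m.
#' @param tris T x 3 integer matrix, counter-clockwise seen from outside.
#' @return a `cell_mesh` object.
#' @export
mesh_from_triangulation <- function(pos, tris) {
  pos <- as.matrix(pos); storage.mode(pos) <- "double"
  tris <- as.matrix(tris); storage.mode(tris) <- "integer"
  conn <- build_connectivity(tris)
  v <- enclosed_volume_raw(pos, tris)
  if (v <= 0)
    stop("mesh orientation error: enclosed volume must be positive", call. = FALSE)
  m <- list(
    pos = pos,
    vel = matrix(0, nrow(pos), 3),
    tris = tris,
    edges = conn$edges,
    edge_rest = sqrt(rowSums((pos[conn$edges[, 1], ] - pos[conn$edges[, 2], ])^2)),
    hinges = conn$hinges,
    tri_adj = conn$tri_adj,
    tri_ref_area = triangle_areas(pos, tris),
    ref_volume = v
  )
  m$ref_total_area <- sum(m$tri_ref_area)
  m$theta_ref <- dihedral_angles(pos, m$hinges)
  ## vertex of each edge-neighbor triangle not shared with the triangle
  nt <- nrow(tris)
  tri_opp <- matrix(0L, nt, 3L)
  for (t in seq_len(nt)) {
    for (s in 1:3) {
      u <- m$tri_adj[t, s]
      if (u > 0) {
        opp <- setdiff(tris[u, ], tris[t, ])
        tri_opp[t, s] <- if (length(opp) == 1L) opp else 0L
      }
    }
  }
  m$tri_opp <- tri_opp
  ## node -> incident triangle CSR (0-based, consumed by the C++ loop)
  inc <- split(rep(seq_len(nt) - 1L, 3L), as.vector(tris))
  nn <- nrow(pos)
  ptr <- integer(nn + 1L)
  idx <- integer(3L * nt)
  at <- 0L
  for (i in seq_len(nn)) {
    ptr[i] <- at
    ids <- inc[[as.character(i)]]
    if (!is.null(ids)) {
      idx[at + seq_along(ids)] <- ids
      at <- at + length(ids)
    }
  }
  ptr[nn + 1L] <- at
  m$node_tri_ptr <- ptr
  m$node_tri_idx <- idx[seq_len(at)]
  class(m) <- "cell_mesh"
  m
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("<cell_mesh> %d nodes, %d edges, %d triangles\n",
              nrow(x$pos), nrow(x$edges), nrow(x$tris)))
  cat(sprintf("  area %.1f um^2, volume %.1f um^3\n",
              sum(triangle_areas(x$pos, x$tris)) * 1e12,
              enclosed_volume(x) * 1e18))
  invisible(x)
}

## icosahedron + loop-style midpoint subdivision, unit radius
icosphere <- function(subdivision) {
  t <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  t, 0), c(1,  t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1,  t), c(0, 1,  t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1)
  )
  verts <- verts / sqrt(rowSums(verts^2))
  tris <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivision)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(verts)
    new_verts <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      p <- verts[a, ] + verts[b, ]
      p <- p / sqrt(sum(p^2))
      new_verts[[length(new_verts) + 1L]] <<- p
      id <- nv + length(new_verts)
      mid_cache[[key]] <- id
      id
    }
    new_tris <- matrix(0L, nrow(tris) * 4L, 3L)
    for (k in seq_len(nrow(tris))) {
      a <- tris[k, 1]; b <- tris[k, 2]; c <- tris[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      new_tris[4 * k - 3, ] <- c(a, ab, ca)
      new_tris[4 * k - 2, ] <- c(b, bc, ab)
      new_tris[4 * k - 1, ] <- c(c, ca, bc)
      new_tris[4 * k, ]     <- c(ab, bc, ca)
    }
    verts <- rbind(verts, do.call(rbind, new_verts))
    tris <- new_tris
  }
  list(verts = verts, tris = tris)
}

## edges, hinges (two opposite vertices per shared edge) and triangle adjacency
build_connectivity <- function(tris) {
  nt <- nrow(tris)
  ek <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  tri_of <- rep(seq_len(nt), 3L)
  opp <- c(tris[, 3], tris[, 1], tris[, 2])
  key <- paste(pmin(ek[, 1], ek[, 2]), pmax(ek[, 1], ek[, 2]))
  sp <- split(seq_along(key), key)
  bad <- vapply(sp, length, integer(1)) != 2L
  if (any(bad))
    stop("mesh is not closed: every edge must be shared by exactly 2 triangles",
         call. = FALSE)
  ne <- length(sp)
  edges <- matrix(0L, ne, 2L)
  hinges <- matrix(0L, ne, 4L)
  htri <- matrix(0L, ne, 2L)
  for (i in seq_len(ne)) {
    idx <- sp[[i]]
    e <- ek[idx[1], ]
    edges[i, ] <- sort(e)
    hinges[i, ] <- c(e[1], e[2], opp[idx[1]], opp[idx[2]])
    htri[i, ] <- tri_of[idx]
  }
  tri_adj <- matrix(0L, nt, 3L)
  slot <- rep(1L, nt)
  for (i in seq_len(ne)) {
    a <- htri[i, 1]; b <- htri[i, 2]
    tri_adj[a, slot[a]] <- b; slot[a] <- slot[a] + 1L
    tri_adj[b, slot[b]] <- a; slot[b] <- slot[b] + 1L
  }
  list(edges = edges, hinges = hinges, hinge_tris = htri, tri_adj = tri_adj)
}

#' Per-triangle areas
#' @param pos N x 3 vertex positions.
#' @param tris T x 3 triangle indices.
#' @return numeric vector of areas, m^2.
#' @export
triangle_areas <- function(pos, tris) {
  e1 <- pos[tris[, 2], , drop = FALSE] - pos[tris[, 1], , drop = FALSE]
  e2 <- pos[tris[, 3], , drop = FALSE] - pos[tris[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

triangle_normals <- function(pos, tris, normalize = TRUE) {
  e1 <- pos[tris[, 2], , drop = FALSE] - pos[tris[, 1], , drop = FALSE]
  e2 <- pos[tris[, 3], , drop = FALSE] - pos[tris[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  if (normalize) n / sqrt(rowSums(n^2)) else n
}

triangle_centroids <- function(pos, tris) {
  (pos[tris[, 1], , drop = FALSE] + pos[tris[, 2], , drop = FALSE] +
     pos[tris[, 3], , drop = FALSE]) / 3
}

dihedral_angles <- function(pos, hinges) {
  x0 <- pos[hinges[, 1], , drop = FALSE]; x1 <- pos[hinges[, 2], , drop = FALSE]
  x2 <- pos[hinges[, 3], , drop = FALSE]; x3 <- pos[hinges[, 4], , drop = FALSE]
  e <- x1 - x0
  n1 <- .rowcross(x1 - x0, x2 - x0)
  n2 <- .rowcross(x3 - x0, x1 - x0)
  n1n <- sqrt(rowSums(n1^2)); n2n <- sqrt(rowSums(n2^2))
  cosb <- rowSums(n1 * n2) / (n1n * n2n)
  sinb <- rowSums(.rowcross(n1, n2) * e) / (n1n * n2n * sqrt(rowSums(e^2)))
  atan2(sinb, cosb)
}

.rowcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

enclosed_volume_raw <- function(pos, tris) {
  p1 <- pos[tris[, 1], , drop = FALSE]
  p2 <- pos[tris[, 2], , drop = FALSE]
  p3 <- pos[tris[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the divergence theorem; positive for outward orientation.
#'
#' @param mesh a `cell_mesh`, or an N x 3 position matrix (then `tris` is
#'   required).
#' @param tris triangle index matrix when `mesh` is a raw position matrix.
#' @return volume in m^3.
#' @export
enclosed_volume <- function(mesh, tris = NULL) {
  if (inherits(mesh, "cell_mesh")) {
    pos <- mesh$pos; tris <- mesh$tris
  } else {
    pos <- as.matrix(mesh)
    if (is.null(tris)) stop("tris required for raw positions", call. = FALSE)
  }
  ek <- rbind(tris[, c(1, 2)], tris[, c(2, 3)], tris[, c(3, 1)])
  key <- paste(pmin(ek[, 1], ek[, 2]), pmax(ek[, 1], ek[, 2]))
  if (any(table(key) != 2L))
    stop("mesh is not closed", call. = FALSE)
  v <- enclosed_volume_raw(pos, tris)
  if (v <= 0)
    stop("mesh orientation error: negative enclosed volume", call. = FALSE)
  v
}

#' Fit a sphere to the neighborhood of a mesh triangle
#'
#' Least-squares algebraic sphere fit through the triangle's vertices and
#' their one-ring neighbors; used by the adhesive contact model, which
#' replaces each contacting triangle by its locally fitted sphere. Flat
#' neighborhoods (such as the rigid substrate plane) have infinite radius.
#'
#' @param mesh a `cell_mesh`.
#' @param triangle triangle index.
#' @param r_max radii above this bound (default 1 mm, far beyond cell scale)
#'   are reported as `Inf`.
#' @return fitted curvature radius in m, possibly `Inf`.
#' @export
fit_local_sphere <- function(mesh, triangle, r_max = 1e-3) {
  stopifnot(inherits(mesh, "cell_mesh"))
  vids <- mesh$tris[triangle, ]
  ring <- unique(c(mesh$edges[mesh$edges[, 1] %in% vids |
                                mesh$edges[, 2] %in% vids, ]))
  pts <- mesh$pos[unique(c(vids, ring)), , drop = FALSE]
  sphere_fit_radius(pts, r_max = r_max)
}

#' Least-squares sphere radius through a point set
#'
#' Solves the algebraic fit `|x|^2 = 2 c . x + k` for center `c`; near-planar
#' point sets return `Inf`, collinear sets are an error.
#'
#' @param pts n x 3 matrix of points (n >= 4 for a finite radius).
#' @param r_max radius cap beyond which `Inf` is returned.
#' @return radius in m, possibly `Inf`.
#' @export
sphere_fit_radius <- function(pts, r_max = 1e-3) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(pts)
  q <- sweep(pts, 2, ctr)
  sv <- svd(q)$d
  scale <- sqrt(sum(q^2) / nrow(q))
  if (scale == 0 || sv[2] / sv[1] < 1e-8)
    stop("degenerate (collinear) point set", call. = FALSE)
  if (sv[3] / sv[1] < 1e-8) return(Inf)  # coplanar: flat neighborhood
  A <- cbind(2 * q, 1)
  b <- rowSums(q^2)
  sol <- qr.solve(A, b)
  r <- sqrt(sum(sol[1:3]^2) + sol[4])
  if (!is.finite(r) || r > r_max) Inf else r
}

#' Build the substrate grid
#'
#' A rigid plane at `z = 0` tiled by squares, each split into two right
#' isosceles triangles of area `A_tri` (default 2.102 um^2, leg
#' `sqrt(2 A_tri)` = 2.050 um). The requested extent is snapped to a whole
#' number of squares so the triangles tile the rectangle exactly; the grid is
#' centered on the origin in y and starts at `x0` in x.
#'
#' @param length,width extent along x and y, m (defaults 80 um x 40 um,
#'   enough to contain a full 24-h trajectory).
#' @param A_tri triangle area, m^2.
#' @param x0 x-coordinate of the left edge, m.
#' @return an object of class `substrate_grid` with fields `l` (leg length),
#'   `nx`, `ny`, `x0`, `y0`, `A_tri`, and `n_tri = 2 nx ny`.
#' @export
build_substrate_grid <- function(length = 80e-6, width = 40e-6,
                                 A_tri = 2.102e-12, x0 = -length / 2) {
  stopifnot(length > 0, width > 0, A_tri > 0)
  l <- sqrt(2 * A_tri)
  nx <- max(1L, as.integer(round(length / l)))
  ny <- max(1L, as.integer(round(width / l)))
  structure(list(l = l, nx = nx, ny = ny, x0 = x0, y0 = -ny * l / 2,
                 A_tri = A_tri, n_tri = 2L * nx * ny),
            class = "substrate_grid")
}

#' @export
print.substrate_grid <- function(x, ...) {
  cat(sprintf("<substrate_grid> %d x %d squares (%d triangles of %.3f um^2), %0.1f x %0.1f um\n",
              x$nx, x$ny, x$n_tri, x$A_tri * 1e12,
              x$nx * x$l * 1e6, x$ny * x$l * 1e6))
  invisible(x)
}

#' Per-triangle areas of a substrate grid
#' @param grid a `substrate_grid`.
#' @return numeric vector of length `grid$n_tri` (all equal to `A_tri`).
#' @export
substrate_areas <- function(grid) rep(grid$A_tri, grid$n_tri)

#' Locate the substrate triangle containing a point
#'
#' Each grid square holds a lower-left triangle (odd id) and an upper-right
#' triangle (even id); points on the shared diagonal belong to the lower one.
#'
#' @param grid a `substrate_grid`.
#' @param x,y point coordinates, m (vectorized).
#' @return integer triangle ids; an error if any point lies off the grid.
#' @export
locate_substrate_triangle <- function(grid, x, y) {
  i <- floor((x - grid$x0) / grid$l)
  j <- floor((y - grid$y0) / grid$l)
  if (any(i < 0 | i >= grid$nx | j < 0 | j >= grid$ny))
    stop("anchor outside the substrate grid: enlarge the grid extent",
         call. = FALSE)
  u <- (x - grid$x0) - i * grid$l
  v <- (y - grid$y0) - j * grid$l
  as.integer(2 * (j * grid$nx + i) + (u + v > grid$l) + 1)
}
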