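# Structured triangulation of the disk with electrodes on the boundary ring.

#' Build a quasi-uniform triangular disk mesh
#'
#' Concentric-ring construction: ring `j` of `n` carries `k*j` nodes
#' (`k` = number of electrodes, so sector boundaries align with electrode
#' angles), and each annulus is triangulated by an angular sweep.  The
#' element count is `k * n_rings^2`; `n_rings` is chosen to approach
#' `target_elements`.  Boundary nodes land exactly on the tank circle and
#' every electrode angle coincides with a boundary node.
#'
#' @param radius_m Tank radius in meters.
#' @param target_elements Requested number of triangles (>= 64); achieved
#'   count is within 30 percent.
#' @param layout An [electrode_layout()]; electrode angles must be
#'   equispaced multiples of `2*pi/n_electrodes` for exact node placement.
#' @return An object of class `disk_mesh`: list with `nodes` (N x 2 matrix,
#'   meters), `triangles` (M x 3 integer matrix, positively oriented),
#'   `boundary` (node indices of the outer ring, counterclockwise),
#'   `electrode_nodes` (one node index per electrode), `radius_m`,
#'   `areas` and `centroids` per element.
#' @examples
#' m <- build_disk_mesh(0.07, 200)
#' nrow(m$triangles)  # 200
#' @export
build_disk_mesh <- function(radius_m, target_elements = 1024L,
                            layout = electrode_layout(8L)) {
  stopifnot(radius_m > 0)
  k <- layout$n_electrodes
  if (target_elements < 64L) stop("target_elements must be at least 64")
  n_rings <- max(2L, as.integer(round(sqrt(target_elements / k))))
  # nodes: center is 1; ring j (1..n_rings) has k*j nodes
  ring_start <- cumsum(c(2L, k * seq_len(n_rings - 1L)))
  nodes <- matrix(0, nrow = 1L + k * n_rings * (n_rings + 1L) / 2L, ncol = 2L)
  ring_idx <- vector("list", n_rings)
  ring_ang <- vector("list", n_rings)
  for (j in seq_len(n_rings)) {
    m <- k * j
    ang <- 2 * pi * (0:(m - 1L)) / m
    idx <- ring_start[j] + 0:(m - 1L)
    r <- radius_m * j / n_rings
    nodes[idx, ] <- cbind(r * cos(ang), r * sin(ang))
    ring_idx[[j]] <- idx
    ring_ang[[j]] <- ang
  }
  tris <- vector("list", n_rings)
  # innermost fan around the center node
  i1 <- ring_idx[[1]]
  tris[[1]] <- cbind(1L, i1, c(i1[-1L], i1[1L]))
  if (n_rings >= 2L) for (j in 2:n_rings) {
    inner <- ring_idx[[j - 1L]]; ia <- ring_ang[[j - 1L]]
    outer <- ring_idx[[j]]; oa <- ring_ang[[j]]
    strips <- vector("list", k)
    for (s in seq_len(k)) {
      # sector s spans (j-1) inner and j outer intervals; close with the
      # next sector's first node (wrapping on the last sector)
      ii <- (s - 1L) * (j - 1L) + seq_len(j - 1L)
      oi <- (s - 1L) * j + seq_len(j)
      iidx <- c(inner[ii], inner[if (s < k) ii[length(ii)] + 1L else 1L])
      oidx <- c(outer[oi], outer[if (s < k) oi[length(oi)] + 1L else 1L])
      iang <- c(ia[ii], 2 * pi * s / k)
      oang <- c(oa[oi], 2 * pi * s / k)
      strips[[s]] <- .strip_triangulate(iidx, iang, oidx, oang)
    }
    tris[[j]] <- do.call(rbind, strips)
  }
  tri <- do.call(rbind, tris)
  # enforce positive (counterclockwise) orientation
  a2 <- .signed_area2(nodes, tri)
  flip <- a2 < 0
  tri[flip, 2:3] <- tri[flip, 3:2]
  a2 <- abs(a2)
  if (any(a2 <= 0)) stop("degenerate triangle in mesh construction")
  achieved <- nrow(tri)
  if (abs(achieved - target_elements) > 0.3 * target_elements)
    stop(sprintf("cannot approach %d elements with %d sectors (achieved %d)",
                 target_elements, k, achieved))
  boundary <- ring_idx[[n_rings]]
  # electrode nodes: nearest boundary node to each layout angle
  bang <- ring_ang[[n_rings]]
  enodes <- vapply(layout$angles, function(a) {
    d <- abs(((bang - a + pi) %% (2 * pi)) - pi)
    boundary[which.min(d)]
  }, integer(1))
  centroids <- (nodes[tri[, 1L], ] + nodes[tri[, 2L], ] + nodes[tri[, 3L], ]) / 3
  structure(list(nodes = nodes, triangles = tri, boundary = boundary,
                 electrode_nodes = enodes, radius_m = radius_m,
                 layout = layout, n_rings = n_rings,
                 areas = a2 / 2, centroids = centroids),
            class = "disk_mesh")
}

# Triangulate the strip between two node chains sorted by angle (both
# including the sector-boundary nodes at each end).  Advances along
# whichever chain has the smaller next angle, emitting one triangle per step.
.strip_triangulate <- function(inner_idx, inner_ang, outer_idx, outer_ang) {
  i <- 1L; o <- 1L
  out <- matrix(0L, nrow = (length(inner_idx) - 1L) + (length(outer_idx) - 1L),
                ncol = 3L)
  t <- 0L
  while (i < length(inner_idx) || o < length(outer_idx)) {
    adv_outer <- if (i >= length(inner_idx)) TRUE
      else if (o >= length(outer_idx)) FALSE
      else outer_ang[o + 1L] <= inner_ang[i + 1L]
    t <- t + 1L
    if (adv_outer) {
      out[t, ] <- c(outer_idx[o], outer_idx[o + 1L], inner_idx[i])
      o <- o + 1L
    } else {
      out[t, ] <- c(inner_idx[i], outer_idx[o], inner_idx[i + 1L])
      i <- i + 1L
    }
  }
  out[seq_len(t), , drop = FALSE]
}

# Twice the signed area of each triangle.
.signed_area2 <- function(nodes, tri) {
  x1 <- nodes[tri[, 1L], 1L]; y1 <- nodes[tri[, 1L], 2L]
  x2 <- nodes[tri[, 2L], 1L]; y2 <- nodes[tri[, 2L], 2L]
  x3 <- nodes[tri[, 3L], 1L]; y3 <- nodes[tri[, 3L], 2L]
  (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
}

#' @export
print.disk_mesh <- function(x, ...) {
  cat(sprintf("<disk_mesh> r = %g m, %d nodes, %d elements, %d electrodes\n",
              x$radius_m, nrow(x$nodes), nrow(x$triangles),
              length(x$electrode_nodes)))
  invisible(x)
}

#' Locate points in mesh elements
#'
#' Barycentric point-in-triangle search; points outside the mesh polygon get
#' `NA`.
#'
#' @param mesh A [disk_mesh()].
#' @param points Numeric n x 2 matrix of coordinates (meters).
#' @return Integer vector of element indices (or `NA`).
#' @export
locate_points <- function(mesh, points) {
  points <- matrix(as.numeric(points), ncol = 2L)
  np <- nrow(points)
  found <- rep(NA_integer_, np)
  open <- seq_len(np)
  tri <- mesh$triangles
  nd <- mesh$nodes
  tol <- 1e-12
  for (e in seq_len(nrow(tri))) {
    if (length(open) == 0L) break
    p1 <- nd[tri[e, 1L], ]; p2 <- nd[tri[e, 2L], ]; p3 <- nd[tri[e, 3L], ]
    det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
    dx <- points[open, 1L] - p1[1]
    dy <- points[open, 2L] - p1[2]
    l2 <- ((p3[2] - p1[2]) * dx - (p3[1] - p1[1]) * dy) / det
    l3 <- (-(p2[2] - p1[2]) * dx + (p2[1] - p1[1]) * dy) / det
    inside <- l2 >= -tol & l3 >= -tol & (l2 + l3) <= 1 + tol
    if (any(inside)) {
      found[open[inside]] <- e
      open <- open[!inside]
    }
  }
  found
}

#' Write a mesh to a plain-text node/element file pair
#'
#' `<stem>.node` holds `x y` per line; `<stem>.ele` holds the three 1-based
#' node indices per triangle.
#'
#' @param mesh A [disk_mesh()].
#' @param stem File path stem.
#' @return Invisibly, the two file paths.
#' @export
write_mesh <- function(mesh, stem) {
  npath <- paste0(stem, ".node")
  epath <- paste0(stem, ".ele")
  utils::write.table(mesh$nodes, npath, row.names = FALSE, col.names = FALSE)
  utils::write.table(mesh$triangles, epath, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(npath, epath))
}
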