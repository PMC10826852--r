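#' @importFrom Matrix sparseMatrix Diagonal t crossprod solve colSums rowSums
#' @importFrom methods as is
#' @importFrom stats optimize optim rnorm runif setNames cor
#' @importFrom rlang .data
NULL

#' Simplex mesh with electrode and tissue labels
#'
#' Constructs the mesh container used throughout the package: a 2D triangular
#' or 3D tetrahedral mesh with boundary facets, an electrode label per
#' boundary facet (0 = bare boundary) and a tissue label per element.
#' Elements are reordered to positive orientation; geometric quantities
#' (volumes, shape-function gradients, mass matrix) are computed lazily and
#' cached.
#'
#' @param nodes numeric matrix, node coordinates (rows) in metres.
#' @param elements integer matrix, one simplex per row (3 or 4 columns).
#' @param boundary integer matrix of boundary facets (2 or 3 columns).
#' @param electrode integer vector, electrode id per boundary facet
#'   (0 for none); every id `1..n_electrodes` must own at least one facet.
#' @param n_electrodes number of electrodes L.
#' @param tissue character vector, tissue label per element.
#' @param hemorrhage_d numeric vector per element: the smallest hemorrhage
#'   sphere diameter (m) containing the element centroid, `NA` outside all
#'   spheres.
#' @param spec the [head_phantom_spec()] the mesh was built from (optional).
#' @return an object of class `eit_mesh`.
#' @export
eit_mesh <- function(nodes, elements, boundary, electrode,
                     n_electrodes = max(electrode),
                     tissue = NULL, hemorrhage_d = NULL, spec = NULL) {
  nodes <- as.matrix(nodes)
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  boundary <- as.matrix(boundary)
  storage.mode(boundary) <- "integer"
  dim <- ncol(nodes)
  stopifnot(dim %in% c(2L, 3L), ncol(elements) == dim + 1L,
            ncol(boundary) == dim)
  electrode <- as.integer(electrode)
  if (length(electrode) != nrow(boundary))
    stop("electrode labels must match boundary facets")
  L <- as.integer(n_electrodes)
  owned <- tabulate(electrode[electrode > 0L], nbins = L)
  if (L < 1L || any(owned == 0L))
    stop("every electrode 1..L must own at least one boundary facet")
  m <- structure(list(
    dim = dim, nodes = nodes, elements = elements,
    boundary = boundary, electrode = electrode, n_electrodes = L,
    tissue = tissue, hemorrhage_d = hemorrhage_d, spec = spec,
    geom = new.env(parent = emptyenv())
  ), class = "eit_mesh")
  m <- orient_elements(m)
  v <- mesh_geometry(m)$vol
  if (any(v <= 0)) stop("mesh contains degenerate elements")
  m
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("<eit_mesh> %dD: %d nodes, %d elements, %d boundary facets, %d electrodes\n",
              x$dim, nrow(x$nodes), nrow(x$elements), nrow(x$boundary),
              x$n_electrodes))
  if (!is.null(x$tissue))
    cat("  tissues:", paste(names(table(x$tissue)), collapse = ", "), "\n")
  invisible(x)
}

orient_elements <- function(mesh) {
  el <- mesh$elements
  nd <- mesh$nodes
  d <- mesh$dim
  if (d == 2L) {
    det <- (nd[el[, 2], 1] - nd[el[, 1], 1]) * (nd[el[, 3], 2] - nd[el[, 1], 2]) -
           (nd[el[, 3], 1] - nd[el[, 1], 1]) * (nd[el[, 2], 2] - nd[el[, 1], 2])
  } else {
    a <- nd[el[, 2], ] - nd[el[, 1], ]
    b <- nd[el[, 3], ] - nd[el[, 1], ]
    c3 <- nd[el[, 4], ] - nd[el[, 1], ]
    det <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
           a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
           a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  }
  flip <- det < 0
  if (any(flip)) {
    tmp <- el[flip, 2]
    el[flip, 2] <- el[flip, 3]
    el[flip, 3] <- tmp
    mesh$elements <- el
  }
  mesh
}

#' Geometric quantities of a mesh (cached)
#'
#' Element volumes, centroids, P1 shape-function gradient operators (one
#' sparse matrix per coordinate, mapping nodal values to element-wise
#' gradient components), stiffness-matrix assembly triplets, the consistent
#' mass matrix and boundary facet measures.
#'
#' @param mesh an [eit_mesh()].
#' @return a list; see source for fields. Cached in the mesh.
#' @export
mesh_geometry <- function(mesh) {
  g <- mesh$geom
  if (!is.null(g$vol)) return(as.list(g))
  nd <- mesh$nodes
  el <- mesh$elements
  d <- mesh$dim
  ne <- nrow(el)
  nn <- nrow(nd)
  if (d == 2L) {
    x1 <- nd[el[, 1], 1]; y1 <- nd[el[, 1], 2]
    x2 <- nd[el[, 2], 1]; y2 <- nd[el[, 2], 2]
    x3 <- nd[el[, 3], 1]; y3 <- nd[el[, 3], 2]
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    vol <- det / 2
    # gradient of basis a on each element: rows stacked per node slot
    gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det
    gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
    grads <- list(gx, gy)
    centroid <- cbind(x1 + x2 + x3, y1 + y2 + y3) / 3
  } else {
    p1 <- nd[el[, 1], ]; p2 <- nd[el[, 2], ]
    p3 <- nd[el[, 3], ]; p4 <- nd[el[, 4], ]
    a <- p2 - p1; b <- p3 - p1; c3 <- p4 - p1
    cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                               u[, 3] * v[, 1] - u[, 1] * v[, 3],
                               u[, 1] * v[, 2] - u[, 2] * v[, 1])
    bc <- cr(b, c3); ca <- cr(c3, a); ab <- cr(a, b)
    det <- rowSums(a * bc)
    vol <- det / 6
    g2 <- bc / det; g3 <- ca / det; g4 <- ab / det
    g1 <- -(g2 + g3 + g4)
    grads <- lapply(1:3, function(k) cbind(g1[, k], g2[, k], g3[, k], g4[, k]))
    centroid <- (p1 + p2 + p3 + p4) / 4
  }
  eidx <- rep(seq_len(ne), d + 1L)
  # sparse gradient operators D[[k]] : nodal -> per-element gradient comp k
  D <- lapply(grads, function(gk)
    sparseMatrix(i = eidx, j = as.vector(el), x = as.vector(gk),
                 dims = c(ne, nn)))
  # stiffness triplets: for element e, K_ab = vol * g_a . g_b
  nl <- d + 1L
  ia <- rep(seq_len(nl), each = nl)
  ib <- rep(seq_len(nl), times = nl)
  kv <- matrix(0, ne, nl * nl)
  for (q in seq_len(nl * nl)) {
    s <- numeric(ne)
    for (k in seq_len(d)) s <- s + grads[[k]][, ia[q]] * grads[[k]][, ib[q]]
    kv[, q] <- vol * s
  }
  ki <- el[, ia]; kj <- el[, ib]
  # consistent mass matrix
  mv <- matrix(vol / ((d + 1) * (d + 2)), ne, nl * nl)
  mv[, ia == ib] <- 2 * mv[, ia == ib]
  mass <- sparseMatrix(i = as.vector(ki), j = as.vector(kj),
                       x = as.vector(mv), dims = c(nn, nn))
  lumped <- as.vector(sparseMatrix(i = rep(1L, ne * nl), j = as.vector(el),
                                   x = rep(vol / (d + 1), nl),
                                   dims = c(1L, nn)))
  # boundary facet measures
  bf <- mesh$boundary
  if (d == 2L) {
    bmeas <- sqrt(rowSums((nd[bf[, 2], , drop = FALSE] -
                           nd[bf[, 1], , drop = FALSE])^2))
    bcent <- (nd[bf[, 1], , drop = FALSE] + nd[bf[, 2], , drop = FALSE]) / 2
  } else {
    u <- nd[bf[, 2], ] - nd[bf[, 1], ]
    v <- nd[bf[, 3], ] - nd[bf[, 1], ]
    crn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                 u[, 3] * v[, 1] - u[, 1] * v[, 3],
                 u[, 1] * v[, 2] - u[, 2] * v[, 1])
    bmeas <- sqrt(rowSums(crn^2)) / 2
    bcent <- (nd[bf[, 1], ] + nd[bf[, 2], ] + nd[bf[, 3], ]) / 3
  }
  g$vol <- vol; g$centroid <- centroid; g$D <- D
  g$ki <- as.vector(ki); g$kj <- as.vector(kj); g$kv <- kv
  g$mass <- mass; g$lumped <- lumped
  g$bmeas <- bmeas; g$bcent <- bcent
  as.list(g)
}

#' Total mesh volume (or area in 2D)
#' @param mesh an [eit_mesh()].
#' @export
mesh_volume <- function(mesh) sum(mesh_geometry(mesh)$vol)

#' Integral of a piecewise linear nodal field over the mesh
#'
#' Exact integral of the P1 interpolant: the lumped-mass weighted sum of
#' nodal values (each element contributes volume times the mean of its
#' vertex values).
#'
#' @param values numeric vector of nodal values, or an `eit_field`.
#' @param mesh an [eit_mesh()]; taken from the field if omitted.
#' @return scalar integral (units of value times m^dim).
#' @export
integral_field <- function(values, mesh = NULL) {
  if (inherits(values, "eit_field")) {
    if (is.null(mesh)) mesh <- values$mesh
    values <- values$values
  }
  stopifnot(!is.null(mesh), length(values) == nrow(mesh$nodes))
  sum(mesh_geometry(mesh)$lumped * values)
}

#' P1 interpolation matrix between meshes
#'
#' Builds the sparse matrix `P` with `P %*% v` evaluating the piecewise
#' linear field `v` (nodal on `from`) at the given points. Points slightly
#' outside `from` (e.g. boundary nodes of a finer polygonal approximation of
#' the same curved domain) are extrapolated linearly from the
#' least-violating element.
#'
#' @param from an [eit_mesh()] carrying the field.
#' @param points matrix of evaluation points, or an [eit_mesh()] whose nodes
#'   are used.
#' @return sparse matrix (n points x n nodes of `from`).
#' @export
interp_matrix <- function(from, points) {
  if (inherits(points, "eit_mesh")) points <- points$nodes
  points <- as.matrix(points)
  d <- from$dim
  stopifnot(ncol(points) == d)
  np <- nrow(points)
  el <- from$elements
  nd <- from$nodes
  ne <- nrow(el)
  best_min <- rep(-Inf, np)
  best_el <- integer(np)
  best_bc <- matrix(0, np, d + 1L)
  # loop over elements, vectorized over points within a bounding box
  for (e in seq_len(ne)) {
    vid <- el[e, ]
    vx <- nd[vid, , drop = FALSE]
    lo <- apply(vx, 2, min) - 1e-9; hi <- apply(vx, 2, max) + 1e-9
    cand <- which(best_min[] < 1 - 1e-12)
    # bounding-box prefilter (skip for points already matched)
    inside <- best_min < 0.999999
    sel <- which(inside)
    if (length(sel) == 0L) next
    pp <- points[sel, , drop = FALSE]
    keep <- rep(TRUE, length(sel))
    for (k in seq_len(d)) keep <- keep & pp[, k] >= lo[k] - 0.05 * (hi[k] - lo[k] + 1e-12) &
                                   pp[, k] <= hi[k] + 0.05 * (hi[k] - lo[k] + 1e-12)
    sel <- sel[keep]
    if (length(sel) == 0L) next
    pp <- points[sel, , drop = FALSE]
    A <- t(vx[-1, , drop = FALSE]) - vx[1, ]
    rel <- sweep(pp, 2, vx[1, ])
    lam <- t(solve(A, t(rel)))           # barycentric for vertices 2..d+1
    bc <- cbind(1 - rowSums(lam), lam)
    mn <- apply(bc, 1, min)
    upd <- mn > best_min[sel]
    if (any(upd)) {
      su <- sel[upd]
      best_min[su] <- mn[upd]
      best_el[su] <- e
      best_bc[su, ] <- bc[upd, , drop = FALSE]
    }
  }
  miss <- best_el == 0L
  if (any(miss)) {
    # fall back: brute force without bounding box for unmatched points
    for (p in which(miss)) {
      for (e in seq_len(ne)) {
        vid <- el[e, ]
        vx <- nd[vid, , drop = FALSE]
        A <- t(vx[-1, , drop = FALSE]) - vx[1, ]
        lam <- solve(A, points[p, ] - vx[1, ])
        bc <- c(1 - sum(lam), lam)
        if (min(bc) > best_min[p]) {
          best_min[p] <- min(bc); best_el[p] <- e; best_bc[p, ] <- bc
        }
      }
    }
  }
  sparseMatrix(i = rep(seq_len(np), d + 1L),
               j = as.vector(el[best_el, ]),
               x = as.vector(best_bc),
               dims = c(np, nrow(nd)))
}
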