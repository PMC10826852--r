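# Structured mesh generators for circular / spherical layered phantoms.
# Both are fully deterministic: no external mesher is involved.

# Radial breakpoints: include every layer interface, subdivide each layer
# to steps <= h.
radial_breaks <- function(interfaces, h) {
  rs <- sort(unique(interfaces))
  out <- 0
  prev <- 0
  for (r in rs) {
    n <- max(1L, ceiling((r - prev) / h - 1e-9))
    out <- c(out, prev + (r - prev) * seq_len(n) / n)
    prev <- r
  }
  out[-1]
}

# Graded polar disk mesh. Ring node counts halve toward the centre
# (always by factor 2 between consecutive rings) so element aspect ratios
# stay bounded. n_out must be L * 2^p.
disk_mesh_raw <- function(breaks, n_out, n_min = 8L) {
  K <- length(breaks)
  R <- breaks[K]
  # desired halving level per ring, forced to change by <= 1 between rings
  m <- floor(log2(pmax(1, R / breaks)))
  mmax <- max(0L, floor(log2(n_out / n_min)))
  m <- pmin(m, mmax)
  for (k in (K - 1):1) if (K > 1) m[k] <- min(m[k], m[k + 1] + 1L)
  nring <- as.integer(n_out / 2^m)
  nodes <- matrix(0, 1, 2)  # centre
  ring_start <- integer(K)
  for (k in seq_len(K)) {
    ring_start[k] <- nrow(nodes) + 1L
    th <- 2 * pi * (seq_len(nring[k]) - 1L) / nring[k]
    nodes <- rbind(nodes, cbind(breaks[k] * cos(th), breaks[k] * sin(th)))
  }
  tris <- list()
  # centre fan
  n1 <- nring[1]
  i1 <- ring_start[1] + (seq_len(n1) - 1L)
  tris[[1]] <- cbind(1L, i1, ring_start[1] + (seq_len(n1) %% n1))
  for (k in seq_len(K - 1)) {
    na <- nring[k]; nb <- nring[k + 1]
    a <- ring_start[k] + (seq_len(na) - 1L)
    b <- ring_start[k + 1] + (seq_len(nb) - 1L)
    an <- ring_start[k] + (seq_len(na) %% na)        # a_{i+1}
    if (nb == na) {
      bn <- ring_start[k + 1] + (seq_len(nb) %% nb)
      tris[[length(tris) + 1L]] <- cbind(a, b, bn)
      tris[[length(tris) + 1L]] <- cbind(a, bn, an)
    } else if (nb == 2L * na) {
      f1 <- ring_start[k + 1] + (2L * (seq_len(na) - 1L))
      f2 <- ring_start[k + 1] + (2L * (seq_len(na) - 1L) + 1L)
      f3 <- ring_start[k + 1] + ((2L * seq_len(na)) %% nb)
      tris[[length(tris) + 1L]] <- cbind(a, f1, f2)
      tris[[length(tris) + 1L]] <- cbind(a, f2, an)
      tris[[length(tris) + 1L]] <- cbind(an, f2, f3)
    } else stop("ring counts must be equal or double")
  }
  elements <- do.call(rbind, tris)
  nb <- nring[K]
  bi <- ring_start[K] + (seq_len(nb) - 1L)
  boundary <- cbind(bi, ring_start[K] + (seq_len(nb) %% nb))
  list(nodes = nodes, elements = elements, boundary = boundary,
       n_out = nring[K])
}

# Kuhn (Freudenthal) triangulation of a structured grid over [-R,R]^3,
# mapped to the ball of radius R by p -> p * |p|_inf / |p|_2. Grid planes
# at +/- each radial break, so every concentric-sphere interface is a mesh
# surface.
ball_mesh_raw <- function(breaks, extra = numeric()) {
  R <- max(breaks)
  extra <- extra[extra > 0 & extra < max(breaks)]
  g <- sort(unique(round(c(-breaks, 0, breaks, extra, -extra), 10)))
  n <- length(g)
  idx <- function(i, j, k) i + n * (j - 1L) + n * n * (k - 1L)
  gr <- expand.grid(x = g, y = g, z = g)
  pts <- as.matrix(gr)
  # map cube -> ball
  rinf <- pmax(abs(pts[, 1]), abs(pts[, 2]), abs(pts[, 3]))
  r2 <- sqrt(rowSums(pts^2))
  sc <- ifelse(r2 > 0, rinf / r2, 0)
  nodes <- pts * sc
  # cells
  ci <- expand.grid(i = seq_len(n - 1L), j = seq_len(n - 1L), k = seq_len(n - 1L))
  c000 <- idx(ci$i, ci$j, ci$k)
  dx <- 1L; dy <- n; dz <- n * n
  corner <- function(bx, by, bz) c000 + bx * dx + by * dy + bz * dz
  v <- list(`000` = corner(0, 0, 0), `100` = corner(1, 0, 0),
            `010` = corner(0, 1, 0), `110` = corner(1, 1, 0),
            `001` = corner(0, 0, 1), `101` = corner(1, 0, 1),
            `011` = corner(0, 1, 1), `111` = corner(1, 1, 1))
  paths <- list(c("100", "110"), c("100", "101"), c("010", "110"),
                c("010", "011"), c("001", "101"), c("001", "011"))
  tets <- lapply(paths, function(p)
    cbind(v[["000"]], v[[p[1]]], v[[p[2]]], v[["111"]]))
  elements <- do.call(rbind, tets)
  # boundary facets: faces of the cube surface, split consistently with Kuhn
  # (extract all element faces appearing once)
  fc <- rbind(elements[, c(1, 2, 3)], elements[, c(1, 2, 4)],
              elements[, c(1, 3, 4)], elements[, c(2, 3, 4)])
  lo <- pmin(fc[, 1], fc[, 2], fc[, 3])
  hi <- pmax(fc[, 1], fc[, 2], fc[, 3])
  mid <- fc[, 1] + fc[, 2] + fc[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  boundary <- cbind(lo, mid, hi)[once, , drop = FALSE]
  list(nodes = nodes, elements = elements, boundary = boundary)
}
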