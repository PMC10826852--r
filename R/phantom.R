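#' Tissue electrical properties at 1 kHz
#'
#' Conductivities (S/m) and relative permittivities of head tissues at
#' 1 kHz, as used for the simulated measurements. Permittivity is recorded
#' for completeness only: the forward and inverse models in this package are
#' real-valued (quasi-static conductivity imaging).
#'
#' @return a tibble with columns `tissue`, `conductivity` (S/m),
#'   `permittivity` (relative).
#' @export
tissue_table <- function() {
  tibble::tibble(
    tissue = c("scalp", "skull", "csf", "white", "gray", "cerebellum", "blood"),
    conductivity = c(0.32, 0.02, 2.00, 0.06, 0.10, 0.12, 0.70),
    permittivity = c(434932, 2702, 109, 69810, 164062, 164358, 5259)
  )
}

tissue_sigma <- function(table, name) {
  v <- table$conductivity[match(name, table$tissue)]
  if (any(is.na(v))) stop("unknown tissue: ", paste(name[is.na(v)], collapse = ", "))
  if (any(v <= 0)) stop("tissue conductivities must be positive")
  v
}

#' Parametric layered head phantom specification
#'
#' Describes a concentric-layer head phantom (disk in 2D, ball in 3D) with
#' scalp, skull, CSF and brain layers, surface electrodes, and a nest of
#' concentric hemorrhage spheres at a chosen location whose growth is
#' simulated by switching sphere contents to blood.
#'
#' @param dimension 2 or 3.
#' @param radii named or ordered numeric: outer radii (m) of scalp, skull,
#'   CSF and brain layers, strictly decreasing.
#' @param n_electrodes number of electrodes L.
#' @param electrode_width electrode width (2D arc, m) or diameter (3D, m).
#' @param hemorrhage_center coordinates (m) of the hemorrhage centre; default
#'   depends on `location` (near the brain surface for "cortical", near the
#'   centre for "deep").
#' @param hemorrhage_diameters ascending sphere diameters (m).
#' @param location `"cortical"` or `"deep"`; selects the default centre and
#'   which brain tissue the hemorrhage displaces (white matter for cortical,
#'   gray matter for deep).
#' @param collapse_brain collapse white/gray/cerebellum to one brain
#'   compartment (default TRUE). The collapsed compartment takes the
#'   conductivity of the displaced tissue.
#' @return object of class `head_phantom_spec`.
#' @export
head_phantom_spec <- function(dimension = 2,
                              radii = c(scalp = 0.090, skull = 0.085,
                                        csf = 0.078, brain = 0.076),
                              n_electrodes = if (dimension == 2) 16L else 32L,
                              electrode_width = 0.010,
                              hemorrhage_center = NULL,
                              hemorrhage_diameters = seq(0.010, 0.030, by = 0.005),
                              location = c("cortical", "deep"),
                              collapse_brain = TRUE) {
  location <- match.arg(location)
  dimension <- as.integer(dimension)
  stopifnot(dimension %in% c(2L, 3L), length(radii) == 4)
  radii <- unname(radii)
  if (any(diff(radii) >= 0)) stop("layer radii must be strictly decreasing")
  if (is.null(hemorrhage_center)) {
    hemorrhage_center <- if (location == "cortical") {
      c(0, 0.055, 0)[seq_len(dimension)]
    } else {
      c(0, 0.020, 0)[seq_len(dimension)]
    }
  }
  stopifnot(length(hemorrhage_center) == dimension)
  hemorrhage_diameters <- sort(hemorrhage_diameters)
  if (any(hemorrhage_diameters <= 0)) stop("diameters must be positive")
  r_brain <- radii[4]
  reach <- sqrt(sum(hemorrhage_center^2)) + max(hemorrhage_diameters) / 2
  if (sqrt(sum(hemorrhage_center^2)) >= r_brain)
    stop("hemorrhage center must lie inside the brain layer")
  if (reach >= r_brain)
    stop("hemorrhage spheres must lie fully inside the brain layer ",
         sprintf("(reach %.3f m >= brain radius %.3f m)", reach, r_brain))
  L <- as.integer(n_electrodes)
  spacing <- 2 * pi * radii[1] / L
  if (electrode_width <= 0 || (dimension == 2 && electrode_width >= spacing))
    stop("electrode width must be positive and below inter-electrode spacing")
  structure(list(
    dimension = dimension, radii = radii, n_electrodes = L,
    electrode_width = electrode_width,
    hemorrhage_center = hemorrhage_center,
    hemorrhage_diameters = hemorrhage_diameters,
    location = location, collapse_brain = collapse_brain
  ), class = "head_phantom_spec")
}

# electrode direction set for the 3D layout: vertex + three latitude rings
electrode_directions_3d <- function(L) {
  if (L < 4L) stop("need at least 4 electrodes in 3D")
  nrest <- L - 1L
  n2 <- max(1L, round(nrest * 6 / 31))
  n3 <- max(1L, round(nrest * 12 / 31))
  n4 <- nrest - n2 - n3
  colat <- c(30, 60, 90) * pi / 180
  dirs <- rbind(c(0, 0, 1))
  for (r in 1:3) {
    nr <- c(n2, n3, n4)[r]
    ph <- 2 * pi * (seq_len(nr) - 1L) / nr + (r - 1) * pi / 7
    dirs <- rbind(dirs, cbind(sin(colat[r]) * cos(ph),
                              sin(colat[r]) * sin(ph),
                              cos(colat[r])))
  }
  dirs
}

assign_electrodes <- function(nodes, boundary, bcent, spec) {
  L <- spec$n_electrodes
  R <- spec$radii[1]
  electrode <- integer(nrow(boundary))
  if (spec$dimension == 2L) {
    th <- atan2(bcent[, 2], bcent[, 1])
    cth <- 2 * pi * (seq_len(L) - 1L) / L
    half <- (spec$electrode_width / 2) / R
    for (m in seq_len(L)) {
      dd <- abs(((th - cth[m] + pi) %% (2 * pi)) - pi)
      electrode[dd <= half + 1e-12] <- m
    }
    for (m in seq_len(L)) {
      if (!any(electrode == m)) {
        # electrode narrower than one facet: take the symmetric pair of
        # facets flanking the centre node so the patch stays mirror
        # symmetric about the electrode centre
        dd <- abs(((th - cth[m] + pi) %% (2 * pi)) - pi)
        free <- which(electrode == 0L)
        if (length(free) < 2L) stop("cannot place electrode ", m)
        cand <- free[order(dd[free])[1:2]]
        electrode[cand] <- m
      }
    }
  } else {
    dirs <- electrode_directions_3d(L)
    cd <- bcent / sqrt(rowSums(bcent^2))
    cosang <- cd %*% t(dirs)
    cosang[cosang > 1] <- 1
    cosang[cosang < -1] <- -1
    ang <- acos(cosang)                              # nb x L
    half <- asin(pmin(1, (spec$electrode_width / 2) / R))
    nearest <- max.col(-ang)
    mins <- ang[cbind(seq_len(nrow(ang)), nearest)]
    electrode[mins <= half] <- nearest[mins <= half]
    for (m in seq_len(L)) {
      if (!any(electrode == m)) {
        free <- electrode == 0L
        if (!any(free)) stop("cannot place electrode ", m)
        cand <- which(free)[which.min(ang[free, m])]
        electrode[cand] <- m
      }
    }
  }
  electrode
}

#' Build a simplex mesh of a layered head phantom
#'
#' Meshes the concentric-layer phantom with a deterministic structured
#' generator (graded polar rings in 2D; a Kuhn-triangulated cube mapped to
#' the ball in 3D). Layer interfaces coincide with mesh surfaces; hemorrhage
#' spheres are labelled by element centroid. Electrodes are placed
#' equi-angularly on the outer boundary in 2D and on an upper-hemisphere
#' ring layout (vertex + three latitude rings) in 3D.
#'
#' @param spec a [head_phantom_spec()].
#' @param density `"coarse"`, `"medium"`, `"fine"`, or a numeric target
#'   element edge length (m).
#' @return an [eit_mesh()] with `tissue` and `hemorrhage_d` element labels.
#' @export
build_phantom <- function(spec, density = "medium") {
  stopifnot(inherits(spec, "head_phantom_spec"))
  R <- spec$radii[1]
  if (is.character(density)) {
    density <- match.arg(density, c("coarse", "medium", "fine"))
    h <- switch(density,
                coarse = if (spec$dimension == 2) 2 * pi * R / (4 * spec$n_electrodes) else R / 5,
                medium = if (spec$dimension == 2) 2 * pi * R / (8 * spec$n_electrodes) else R / 7.5,
                fine   = if (spec$dimension == 2) 2 * pi * R / (16 * spec$n_electrodes) else R / 11)
  } else h <- as.numeric(density)
  breaks <- radial_breaks(spec$radii, h)
  if (spec$dimension == 2L) {
    n_out <- spec$n_electrodes
    while (2 * pi * R / n_out > h) n_out <- 2L * n_out
    raw <- disk_mesh_raw(breaks, n_out)
  } else {
    # refine the axis grid over the hemorrhage bounding box so that the
    # sphere nest is resolved (centroid labelling converges with the grid)
    hw <- max(spec$hemorrhage_diameters) / 2
    extra <- unlist(lapply(seq_len(3), function(k) {
      lo <- spec$hemorrhage_center[k] - hw
      hi <- spec$hemorrhage_center[k] + hw
      abs(seq(lo, hi, length.out = max(2L, ceiling((hi - lo) / (0.4 * h)) + 1L)))
    }))
    raw <- ball_mesh_raw(breaks, extra = extra)
  }
  # tissue labels by centroid radius
  el <- raw$elements
  nd <- raw$nodes
  cent <- matrix(0, nrow(el), spec$dimension)
  for (k in seq_len(spec$dimension))
    cent[, k] <- rowMeans(matrix(nd[el, k], nrow(el)))
  r <- sqrt(rowSums(cent^2))
  tissue <- rep("brain", nrow(el))
  tissue[r > spec$radii[4]] <- "csf"
  tissue[r > spec$radii[3]] <- "skull"
  tissue[r > spec$radii[2]] <- "scalp"
  dist <- sqrt(rowSums(sweep(cent, 2, spec$hemorrhage_center)^2))
  hem <- rep(NA_real_, nrow(el))
  for (D in rev(spec$hemorrhage_diameters)) hem[dist <= D / 2] <- D
  if (any(!is.na(hem) & tissue != "brain"))
    stop("hemorrhage intersects a non-brain layer; adjust the phantom spec")
  # boundary centroids for electrode placement
  bf <- raw$boundary
  bcent <- matrix(0, nrow(bf), spec$dimension)
  for (k in seq_len(spec$dimension))
    bcent[, k] <- rowMeans(matrix(nd[bf, k], nrow(bf)))
  electrode <- assign_electrodes(nd, bf, bcent, spec)
  eit_mesh(nd, el, bf, electrode, n_electrodes = spec$n_electrodes,
           tissue = tissue, hemorrhage_d = hem, spec = spec)
}

#' Nodal conductivity field for a phantom state
#'
#' Maps tissue labels to conductivities and sets all hemorrhage shells with
#' diameter up to `state` to blood. Element values are converted to the
#' nodal piecewise linear basis by volume-weighted averaging over incident
#' elements (tissue interfaces are smeared over one element layer).
#'
#' @param mesh phantom mesh from [build_phantom()].
#' @param table tissue table, see [tissue_table()].
#' @param state `"healthy"` or a hemorrhage diameter (m) present in the
#'   spec's diameter set.
#' @return an `eit_field`: list with nodal `values` (S/m), per-element
#'   `element_values`, the `mesh` and the `state` label.
#' @export
assign_conductivity <- function(mesh, table = tissue_table(), state = "healthy") {
  spec <- mesh$spec
  if (is.null(spec)) stop("mesh carries no phantom spec")
  base_brain <- if (spec$location == "cortical") "white" else "gray"
  lab <- mesh$tissue
  ev <- numeric(length(lab))
  ev[lab == "scalp"] <- tissue_sigma(table, "scalp")
  ev[lab == "skull"] <- tissue_sigma(table, "skull")
  ev[lab == "csf"] <- tissue_sigma(table, "csf")
  ev[lab == "brain"] <- tissue_sigma(table, base_brain)
  if (!identical(state, "healthy")) {
    state <- as.numeric(state)
    ok <- any(abs(spec$hemorrhage_diameters - state) < 1e-12)
    if (is.na(state) || !ok)
      stop("state must be \"healthy\" or one of the spec's hemorrhage diameters")
    sel <- !is.na(mesh$hemorrhage_d) & mesh$hemorrhage_d <= state + 1e-12
    ev[sel] <- tissue_sigma(table, "blood")
  }
  eit_field(element_to_node(mesh, ev), mesh, element_values = ev,
            state = if (identical(state, "healthy")) "healthy" else state)
}

element_to_node <- function(mesh, evals) {
  g <- mesh_geometry(mesh)
  el <- mesh$elements
  nl <- ncol(el)
  w <- rep(g$vol, nl)
  num <- as.vector(sparseMatrix(i = as.vector(el), j = rep(1L, length(el)),
                                x = w * rep(evals, nl),
                                dims = c(nrow(mesh$nodes), 1L)))
  den <- as.vector(sparseMatrix(i = as.vector(el), j = rep(1L, length(el)),
                                x = w, dims = c(nrow(mesh$nodes), 1L)))
  num / den
}

#' Nodal field container
#' @param values nodal values.
#' @param mesh the mesh the values live on.
#' @param ... extra fields stored alongside.
#' @export
eit_field <- function(values, mesh, ...) {
  stopifnot(length(values) == nrow(mesh$nodes))
  structure(list(values = as.numeric(values), mesh = mesh, ...),
            class = "eit_field")
}

#' @export
print.eit_field <- function(x, ...) {
  cat(sprintf("<eit_field> %d nodes, range [%.4g, %.4g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Structural reference image, edge indicator and region of interest
#'
#' Builds the piecewise-constant reference image kappa distinguishing the
#' scalp, skull and brain compartments (CSF is grouped with brain, as in a
#' CT-derived skull map), its per-element unit gradient directions, the
#' thresholded edge indicator gamma, and the ROI (the brain compartment).
#' Only the level-set geometry of kappa matters, so its values 0/1/2 are
#' arbitrary.
#'
#' @param mesh phantom mesh.
#' @param threshold_frac gradient-magnitude threshold as a fraction of the
#'   maximum; elements at or above it are edges.
#' @param gamma1 edge value of the indicator (0 < gamma1 << 1); elsewhere
#'   gamma = 1.
#' @return an `eit_reference`: kappa (nodal), per-element `gamma`, unit
#'   gradient `nu` (zero where the gradient vanishes), compartment labels,
#'   ROI element/node index sets.
#' @export
make_reference <- function(mesh, threshold_frac = 0.5, gamma1 = 0.01) {
  stopifnot(gamma1 > 0, gamma1 < 1, threshold_frac > 0, threshold_frac < 1)
  comp <- mesh$tissue
  comp[comp == "csf"] <- "brain"
  kval <- c(scalp = 0, skull = 1, brain = 2)[comp]
  kappa <- element_to_node(mesh, unname(kval))
  g <- mesh_geometry(mesh)
  d <- mesh$dim
  grad <- sapply(seq_len(d), function(k) as.vector(g$D[[k]] %*% kappa))
  gn <- sqrt(rowSums(grad^2))
  gamma <- rep(1, length(gn))
  nu <- matrix(0, length(gn), d)
  if (max(gn) <= 1e-12) {
    warning("reference image is constant: gamma is 1 everywhere")
  } else {
    edge <- gn >= threshold_frac * max(gn)
    gamma[edge] <- gamma1
    pos <- gn > 1e-12
    nu[pos, ] <- grad[pos, , drop = FALSE] / gn[pos]
  }
  roi_el <- which(mesh$tissue == "brain")
  roi_nodes <- sort(unique(as.vector(mesh$elements[roi_el, ])))
  structure(list(mesh = mesh, kappa = kappa, gamma = gamma, nu = nu,
                 grad_norm = gn, compartments = comp,
                 roi_elements = roi_el, roi_nodes = roi_nodes,
                 gamma1 = gamma1, threshold_frac = threshold_frac),
            class = "eit_reference")
}

#' Hemorrhage sphere volume
#'
#' Volume of a spherical hemorrhage of diameter `d`: pi d^3 / 6.
#'
#' @param d diameter(s) in metres.
#' @param units `"ml"` (default) or `"m3"`.
#' @export
hemorrhage_volume <- function(d, units = c("ml", "m3")) {
  units <- match.arg(units)
  v <- pi * d^3 / 6
  if (units == "ml") v * 1e6 else v
}

#' Volume increase between two hemorrhage states
#'
#' @param d1,d2 sphere diameters (m); `0` or `"healthy"` for no hemorrhage.
#' @param units `"ml"` or `"m3"`.
#' @export
volume_increase <- function(d1, d2, units = c("ml", "m3")) {
  units <- match.arg(units)
  num <- function(d) ifelse(d %in% "healthy", 0, suppressWarnings(as.numeric(d)))
  hemorrhage_volume(num(d2), units) - hemorrhage_volume(num(d1), units)
}
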