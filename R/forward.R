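#' Pairwise skip-s current injection patterns
#'
#' One pattern per electrode: current `amplitude` injected at electrode k
#' and withdrawn at electrode k+s (cyclic). The default skip
#' `floor(L/2) - 4` reproduces the 1-13, 2-14, ..., 32-12 layout for L = 32
#' and scales it to smaller electrode counts. Every row sums to zero.
#'
#' @param L number of electrodes.
#' @param skip electrode offset s between source and sink.
#' @param amplitude injected current (A); 1 mA default.
#' @return a P x L matrix of class `eit_patterns` (P = L).
#' @export
current_patterns <- function(L, skip = max(1L, floor(L / 2) - 4L),
                             amplitude = 1e-3) {
  L <- as.integer(L)
  skip <- as.integer(skip)
  if (skip %% L == 0L) stop("skip must not be a multiple of L")
  I <- matrix(0, L, L)
  for (k in seq_len(L)) {
    I[k, k] <- amplitude
    I[k, 1L + (k - 1L + skip) %% L] <- -amplitude
  }
  validate_patterns(I)
  structure(I, class = c("eit_patterns", "matrix"),
            descriptor = sprintf("pairwise skip-%d", skip))
}

validate_patterns <- function(I) {
  if (any(abs(rowSums(I)) > 1e-12 * max(abs(I))))
    stop("every current pattern must sum to zero")
  if (anyDuplicated(round(I / max(abs(I)), 12)))
    stop("duplicate current patterns")
  invisible(I)
}

#' Adjacent differential observation operator
#'
#' Sparse matrix mapping per-electrode potentials U in R^L to the observed
#' channels: differential voltages between adjacent electrodes
#' 1-2, 2-3, ..., L-1. Applying it to a constant vector gives zero. With
#' `drop_injecting = TRUE` a per-pattern channel mask removes channels that
#' touch a current-carrying electrode.
#'
#' @param L number of electrodes.
#' @param patterns pattern matrix; needed only for `drop_injecting`.
#' @param drop_injecting drop channels touching injecting electrodes.
#' @return list with sparse `O` (L x L), and `keep`, a logical vector over
#'   the stacked pattern-major channel index.
#' @export
observation_operator <- function(L, patterns = NULL, drop_injecting = FALSE) {
  L <- as.integer(L)
  O <- sparseMatrix(i = c(seq_len(L), seq_len(L)),
                    j = c(seq_len(L), c(seq_len(L - 1L) + 1L, 1L)),
                    x = c(rep(1, L), rep(-1, L)), dims = c(L, L))
  if (drop_injecting) {
    stopifnot(!is.null(patterns))
    P <- nrow(patterns)
    keep <- matrix(TRUE, L, P)
    for (k in seq_len(P)) {
      act <- which(abs(patterns[k, ]) > 0)
      touches <- vapply(seq_len(L), function(m)
        any(c(m, m %% L + 1L) %in% act), logical(1))
      keep[touches, k] <- FALSE
    }
    keep <- as.vector(keep)
  } else keep <- NULL
  list(O = O, keep = keep)
}

#' Forward model of the complete electrode model
#'
#' Bundles everything needed to map a conductivity field to electrode
#' voltages: the potential mesh, an optional coarser conductivity mesh (the
#' two-mesh inverse protocol), contact impedances, current patterns and the
#' observation operator. Electrode boundary integrals are precomputed.
#'
#' @param mesh potential mesh (an [eit_mesh()]).
#' @param z contact impedances (Ohm m^2), scalar or length-L vector.
#' @param patterns current patterns, default [current_patterns()].
#' @param observation from [observation_operator()]; default adjacent pairs.
#' @param conductivity_mesh optional coarser [eit_mesh()] carrying the
#'   unknown conductivity; nodal values are interpolated onto the potential
#'   mesh. Default: the potential mesh itself.
#' @return object of class `eit_forward_model`.
#' @export
forward_model <- function(mesh, z = 1e-3, patterns = NULL,
                          observation = NULL, conductivity_mesh = NULL) {
  L <- mesh$n_electrodes
  if (is.null(patterns)) patterns <- current_patterns(L)
  if (is.null(observation)) observation <- observation_operator(L)
  validate_patterns(patterns)
  if (ncol(patterns) != L) stop("patterns do not match electrode count")
  z <- rep_len(as.numeric(z), L)
  if (any(z <= 0)) stop("contact impedances must be positive")
  nn <- nrow(mesh$nodes)
  g <- mesh_geometry(mesh)
  # per-electrode facet mass matrices and load vectors
  elec <- vector("list", L)
  bf <- mesh$boundary
  d <- mesh$dim
  for (l in seq_len(L)) {
    fs <- which(mesh$electrode == l)
    meas <- g$bmeas[fs]
    if (d == 2L) {
      loc <- matrix(c(2, 1, 1, 2) / 6, 2, 2)
      nl <- 2L
    } else {
      loc <- (matrix(1, 3, 3) + diag(3)) / 12
      nl <- 3L
    }
    ia <- rep(seq_len(nl), each = nl); ib <- rep(seq_len(nl), nl)
    fv <- bf[fs, , drop = FALSE]
    Mi <- as.vector(fv[, ia]); Mj <- as.vector(fv[, ib])
    Mx <- as.vector(outer(meas, as.vector(loc)))
    Mb <- sparseMatrix(i = Mi, j = Mj, x = Mx, dims = c(nn, nn))
    b <- as.vector(sparseMatrix(i = as.vector(fv), j = rep(1L, length(fv)),
                                x = rep(meas / nl, nl), dims = c(nn, 1L)))
    elec[[l]] <- list(M = Mb, b = b, area = sum(meas))
  }
  # zero-mean voltage basis: columns e_1 - e_{j+1}
  Nb <- matrix(0, L, L - 1L)
  Nb[1, ] <- 1
  Nb[cbind(2:L, seq_len(L - 1L))] <- -1
  cmesh <- if (is.null(conductivity_mesh)) mesh else conductivity_mesh
  Pint <- if (is.null(conductivity_mesh)) Diagonal(nn) else
    interp_matrix(conductivity_mesh, mesh)
  structure(list(mesh = mesh, cmesh = cmesh, interp = Pint,
                 patterns = patterns, obs = observation$O,
                 keep = observation$keep, z = z, elec = elec, Nb = Nb),
            class = "eit_forward_model")
}

field_values <- function(sigma, fm) {
  v <- if (inherits(sigma, "eit_field")) sigma$values else as.numeric(sigma)
  if (length(v) == 1L) v <- rep(v, nrow(fm$cmesh$nodes))
  if (length(v) != nrow(fm$cmesh$nodes))
    stop("conductivity length does not match the conductivity mesh")
  v
}

#' Assemble and factorize the CEM system
#'
#' Builds the symmetric positive definite FEM system of the complete
#' electrode model in the (interior potential, zero-mean electrode voltage)
#' unknowns and computes a reusable sparse Cholesky factorization.
#'
#' @param fm an [forward_model()].
#' @param sigma conductivity: `eit_field`, nodal vector on the conductivity
#'   mesh, or a scalar.
#' @return list with the factor `Ch`, system size bookkeeping and the
#'   element-mean conductivities used.
#' @export
assemble_cem <- function(fm, sigma) {
  v <- field_values(sigma, fm)
  if (any(v <= 0)) stop("conductivity must be strictly positive")
  g <- mesh_geometry(fm$mesh)
  spot <- as.vector(fm$interp %*% v)
  el <- fm$mesh$elements
  sigbar <- rowMeans(matrix(spot[el], nrow(el)))
  nn <- nrow(fm$mesh$nodes)
  L <- fm$mesh$n_electrodes
  A <- sparseMatrix(i = g$ki, j = g$kj, x = as.vector(g$kv * sigbar),
                    dims = c(nn, nn))
  for (l in seq_len(L)) A <- A + fm$elec[[l]]$M / fm$z[l]
  Bfull <- do.call(cbind, lapply(seq_len(L), function(l)
    -fm$elec[[l]]$b / fm$z[l]))
  Cfull <- Diagonal(x = vapply(seq_len(L), function(l)
    fm$elec[[l]]$area / fm$z[l], numeric(1)))
  Auv <- Matrix::Matrix(Bfull %*% fm$Nb, sparse = TRUE)
  Avv <- t(fm$Nb) %*% Cfull %*% fm$Nb
  K <- rbind(cbind(A, Auv), cbind(t(Auv), Matrix::Matrix(Avv, sparse = TRUE)))
  K <- methods::as(Matrix::forceSymmetric(K), "CsparseMatrix")
  Ch <- Matrix::Cholesky(K, LDL = FALSE)
  list(Ch = Ch, nn = nn, L = L, sigbar = sigbar, spot = spot)
}

cem_rhs <- function(fm, currents) {
  # currents: P x L matrix -> (nn + L - 1) x P right-hand sides
  nn <- nrow(fm$mesh$nodes)
  rhs <- rbind(matrix(0, nn, nrow(currents)),
               t(fm$Nb) %*% t(currents))
  as.matrix(rhs)
}

#' Solve the CEM forward problem
#'
#' Electrode voltages and interior potentials for all current patterns, and
#' the observed (differential) voltage vector stacked pattern-major.
#'
#' @param fm an [forward_model()].
#' @param sigma conductivity (see [assemble_cem()]).
#' @param sys optional pre-assembled system from [assemble_cem()].
#' @return class `eit_forward`: `U` (L x P electrode voltages), `u`
#'   (nodal potentials), `V` (observed channels, mask applied).
#' @export
forward_solve <- function(fm, sigma, sys = NULL) {
  if (is.null(sys)) sys <- assemble_cem(fm, sigma)
  rhs <- cem_rhs(fm, fm$patterns)
  X <- as.matrix(Matrix::solve(sys$Ch, rhs, system = "A"))
  nn <- sys$nn
  u <- X[seq_len(nn), , drop = FALSE]
  U <- fm$Nb %*% X[-seq_len(nn), , drop = FALSE]
  V <- as.vector(as.matrix(fm$obs %*% U))
  if (!is.null(fm$keep)) V <- V[fm$keep]
  structure(list(U = as.matrix(U), u = u, V = V, sys = sys),
            class = "eit_forward")
}

#' Electrode currents recovered from a forward solution
#'
#' Post-processed currents I_l = (|e_l| U_l - int_{e_l} u) / z_l; should
#' match the injected patterns to solver accuracy and sum to zero.
#'
#' @param fm forward model; @param fw an `eit_forward`.
#' @export
recovered_currents <- function(fm, fw) {
  L <- fm$mesh$n_electrodes
  P <- ncol(fw$U)
  I <- matrix(0, P, L)
  for (l in seq_len(L)) {
    bl <- fm$elec[[l]]$b
    I[, l] <- (fm$elec[[l]]$area * fw$U[l, ] -
                 as.vector(crossprod(bl, fw$u))) / fm$z[l]
  }
  I
}

#' Jacobian of the observed voltages with respect to nodal conductivity
#'
#' Sensitivity matrix J with one row per observed channel (pattern-major)
#' and one column per conductivity-mesh node, computed with the standard
#' adjoint formulation: dV/dsigma_j = -u^T (dA/dsigma_j) w, sharing one
#' factorization between the forward and adjoint solves.
#'
#' @param fm forward model.
#' @param sigma conductivity at which to linearize.
#' @param sys optional pre-assembled system.
#' @return dense matrix (channels x N).
#' @export
cem_jacobian <- function(fm, sigma, sys = NULL) {
  if (is.null(sys)) sys <- assemble_cem(fm, sigma)
  g <- mesh_geometry(fm$mesh)
  nn <- sys$nn
  P <- nrow(fm$patterns)
  n_obs <- nrow(fm$obs)
  rhsf <- cem_rhs(fm, fm$patterns)
  Xf <- as.matrix(Matrix::solve(sys$Ch, rhsf, system = "A"))
  u <- Xf[seq_len(nn), , drop = FALSE]
  rhso <- rbind(matrix(0, nn, n_obs), as.matrix(t(fm$Nb) %*% t(fm$obs)))
  Xo <- as.matrix(Matrix::solve(sys$Ch, rhso, system = "A"))
  w <- Xo[seq_len(nn), , drop = FALSE]
  d <- fm$mesh$dim
  Gu <- lapply(seq_len(d), function(k) as.matrix(g$D[[k]] %*% u))
  Gw <- lapply(seq_len(d), function(k) as.matrix(g$D[[k]] %*% w))
  el <- fm$mesh$elements
  nl <- ncol(el)
  ne <- nrow(el)
  Tmat <- sparseMatrix(i = rep(seq_len(ne), nl), j = as.vector(el),
                       x = rep(1 / nl, length(el)), dims = c(ne, nn))
  J <- matrix(0, P * n_obs, nn)
  vol <- g$vol
  for (m in seq_len(n_obs)) {
    S <- Gu[[1]] * Gw[[1]][, m]
    for (k in seq_len(d - 1L) + 1L) S <- S + Gu[[k]] * Gw[[k]][, m]
    Jm <- -as.matrix(Matrix::crossprod(Tmat, S * vol))   # nn x P
    J[(seq_len(P) - 1L) * n_obs + m, ] <- t(Jm)
  }
  J <- J %*% fm$interp
  J <- as.matrix(J)
  if (!is.null(fm$keep)) J <- J[fm$keep, , drop = FALSE]
  J
}

#' Simulate a noisy measurement frame
#'
#' Solves the forward problem for the true conductivity and adds i.i.d.
#' zero-mean Gaussian noise. The noise standard deviation is given either
#' absolutely (V) or relative to the maximum amplitude of the noise-free
#' data (the measurement-device convention, e.g. 0.067%).
#'
#' @param fm forward model built on the *simulation* mesh (kept distinct
#'   from the reconstruction meshes to avoid the inverse crime).
#' @param sigma_true true conductivity field.
#' @param noise_std absolute noise std (V); ignored if `relative_noise` set.
#' @param relative_noise std as a fraction of `max(abs(V))` (e.g. 0.00067).
#' @param seed RNG seed for reproducibility.
#' @param label frame label, e.g. "t1".
#' @return class `eit_frame`: `V`, `noise_std`, `label`, `seed`.
#' @export
simulate_frame <- function(fm, sigma_true, noise_std = 0,
                           relative_noise = NULL, seed = NULL,
                           label = "t1") {
  fw <- forward_solve(fm, sigma_true)
  V0 <- fw$V
  if (!is.null(relative_noise)) noise_std <- relative_noise * max(abs(V0))
  if (noise_std < 0) stop("noise std must be nonnegative")
  if (noise_std > 0) {
    if (!is.null(seed)) {
      e <- withr::with_seed(seed, rnorm(length(V0), sd = noise_std))
    } else e <- rnorm(length(V0), sd = noise_std)
    V <- V0 + e
  } else V <- V0
  structure(list(V = V, noise_std = noise_std, label = label,
                 seed = seed, n = length(V)),
            class = "eit_frame")
}

#' @export
print.eit_frame <- function(x, ...) {
  cat(sprintf("<eit_frame> %s: %d channels, noise std %.3g V\n",
              x$label, x$n, x$noise_std))
  invisible(x)
}

frame_V <- function(frame) {
  if (inherits(frame, "eit_frame")) frame$V else as.numeric(frame)
}

#' Best fitting constant conductivity
#'
#' One-dimensional nonlinear least squares fit of a homogeneous
#' conductivity to a measurement frame, solved by bounded minimization on a
#' log scale; used as the absolute-imaging starting point and as the
#' linearization point of linear difference imaging.
#'
#' @param frame an `eit_frame`.
#' @param fm forward model (reconstruction meshes).
#' @param interval search interval for sigma (S/m).
#' @return homogeneous `eit_field` on the conductivity mesh, with the
#'   fitted scalar in `$sigma0`.
#' @export
fit_constant_sigma <- function(frame, fm, interval = c(1e-3, 10)) {
  V <- frame_V(frame)
  if (length(V) == 0L) stop("empty frame")
  cost <- function(lc) {
    fw <- forward_solve(fm, exp(lc))
    sum((V - fw$V)^2)
  }
  op <- tryCatch(optimize(cost, interval = log(interval), tol = 1e-8),
                 error = function(e) NULL)
  if (is.null(op)) {
    warning("1D optimization failed; falling back to grid search")
    gr <- seq(log(interval[1]), log(interval[2]), length.out = 60)
    cv <- vapply(gr, cost, numeric(1))
    op <- list(minimum = gr[which.min(cv)])
  }
  s0 <- exp(op$minimum)
  f <- eit_field(rep(s0, nrow(fm$cmesh$nodes)), fm$cmesh)
  f$sigma0 <- s0
  f
}

#' Anatomically guided three-compartment conductivity fit
#'
#' Nonlinear least squares fit of one conductivity value per scalp, skull
#' and brain compartment (from the reference image partition), used as the
#' initial estimate of the monitoring algorithm.
#'
#' @param frame an `eit_frame`.
#' @param fm forward model.
#' @param ref an `eit_reference` built on the conductivity mesh.
#' @param control passed to [stats::optim()] (Nelder-Mead on log values).
#' @return piecewise-constant `eit_field` with fitted values in `$theta`.
#' @export
fit_three_compartment <- function(frame, fm, ref,
                                  control = list(maxit = 200, reltol = 1e-8)) {
  stopifnot(inherits(ref, "eit_reference"))
  V <- frame_V(frame)
  comps <- c("scalp", "skull", "brain")
  idx <- match(ref$compartments, comps)
  if (anyNA(idx)) stop("reference compartments must be scalp/skull/brain")
  if (length(unique(idx)) == 1L) return(fit_constant_sigma(frame, fm))
  to_field <- function(theta) element_to_node(fm$cmesh, theta[idx])
  cost <- function(lt) {
    fw <- forward_solve(fm, to_field(exp(lt)))
    sum((V - fw$V)^2)
  }
  s0 <- fit_constant_sigma(frame, fm)$sigma0
  # start from literature-typical head-tissue values; the constant fit is a
  # fallback start if that basin fails
  tt <- tissue_table()
  start <- log(c(tissue_sigma(tt, "scalp"), tissue_sigma(tt, "skull"),
                 tissue_sigma(tt, "gray")))
  op <- optim(start, cost, method = "Nelder-Mead", control = control)
  op2 <- optim(log(rep(s0, 3)), cost, method = "Nelder-Mead",
               control = list(maxit = 50, reltol = 1e-6))
  if (op2$value < op$value) op <- op2
  if (op$convergence != 0 && op$value > cost(log(rep(s0, 3))))
    warning("three-compartment fit did not converge; using constant fit")
  theta <- exp(op$par)
  f <- eit_field(to_field(theta), fm$cmesh)
  f$theta <- setNames(theta, comps)
  f
}
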