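#' Smoothed total variation functional
#'
#' TV(v) = alpha * int (||grad v||^2 + beta^2)^(1/2) dx on piecewise linear
#' fields; beta > 0 makes it differentiable. For any field the value is at
#' least alpha * beta * |Omega|, with equality exactly for constants.
#'
#' @param alpha regularization weight (> 0).
#' @param beta smoothing parameter (> 0).
#' @export
tv_functional <- function(alpha, beta) {
  stopifnot(alpha > 0)
  if (beta <= 0) stop("beta must be positive (smoothed TV)")
  structure(list(alpha = alpha, beta = beta, type = "tv"),
            class = "eit_prior_tv")
}

#' Parallel-level-sets weighted total variation
#'
#' Anisotropic TV with per-element weighting tensor
#' B = I - (1 - gamma) nu nu^T built from a structural reference image:
#' gradients aligned with the reference's level-set normals on edge
#' elements are penalized by the factor gamma1 only, so reconstructed edges
#' are cheap where the reference image has edges. Reduces to plain TV when
#' gamma = 1 everywhere.
#'
#' @param alpha,beta as in [tv_functional()].
#' @param ref an `eit_reference` from [make_reference()].
#' @export
weighted_tv_functional <- function(alpha, beta, ref) {
  stopifnot(inherits(ref, "eit_reference"), alpha > 0)
  if (beta <= 0) stop("beta must be positive (smoothed TV)")
  structure(list(alpha = alpha, beta = beta, type = "wtv",
                 gamma = ref$gamma, nu = ref$nu),
            class = c("eit_prior_wtv", "eit_prior_tv"))
}

#' Value, gradient and lagged Gauss-Newton Hessian of (weighted) TV
#'
#' Element-wise one-point quadrature (exact for the element-constant
#' gradients of P1 fields). The Hessian is the lagged linearization: the
#' weights 1/sqrt(||grad v||_B^2 + beta^2) are frozen at the supplied
#' field, giving a symmetric positive semidefinite sparse operator.
#'
#' @param values nodal values (or `eit_field`).
#' @param mesh the mesh (taken from the field if omitted).
#' @param tv a [tv_functional()] or [weighted_tv_functional()].
#' @return list with `value`, `gradient` (vector), `hessian` (sparse).
#' @export
tv_eval_grad_hess <- function(values, mesh = NULL, tv) {
  if (inherits(values, "eit_field")) {
    if (is.null(mesh)) mesh <- values$mesh
    values <- values$values
  }
  g <- mesh_geometry(mesh)
  d <- mesh$dim
  ne <- length(g$vol)
  gk <- lapply(seq_len(d), function(k) as.vector(g$D[[k]] %*% values))
  gn2 <- Reduce(`+`, lapply(gk, function(x) x^2))
  if (tv$type == "wtv") {
    gamma <- tv$gamma
    nu <- tv$nu
    if (length(gamma) != ne) stop("weighting tensor does not match mesh")
    nug <- Reduce(`+`, lapply(seq_len(d), function(k) nu[, k] * gk[[k]]))
    q <- gn2 - (1 - gamma) * nug^2
  } else {
    gamma <- NULL
    q <- gn2
  }
  w <- sqrt(q + tv$beta^2)
  value <- tv$alpha * sum(g$vol * w)
  s <- tv$alpha * g$vol / w
  grad <- Reduce(`+`, lapply(seq_len(d), function(k) {
    bg <- gk[[k]]
    if (!is.null(gamma)) bg <- bg - (1 - gamma) * nug * nu[, k]
    as.vector(Matrix::crossprod(g$D[[k]], s * bg))
  }))
  H <- Reduce(`+`, lapply(seq_len(d), function(k)
    Matrix::crossprod(g$D[[k]], s * g$D[[k]])))
  if (!is.null(gamma)) {
    Dn <- Reduce(`+`, lapply(seq_len(d), function(k) nu[, k] * g$D[[k]]))
    H <- H - Matrix::crossprod(Dn, (s * (1 - gamma)) * Dn)
  }
  list(value = value, gradient = grad,
       hessian = Matrix::forceSymmetric(H), weights = w)
}

#' Distance-based Gaussian smoothness prior
#'
#' Covariance Gamma_p(i, j) = std^2 exp(-||x_i - x_j||^2 / (2 a^2)) with
#' the correlation length a solved from a target correlation level at a
#' chosen distance: corr_level = exp(-d^2 / (2 a^2)). The returned factor
#' L satisfies L^T L = Gamma_p^{-1}.
#'
#' @param mesh conductivity mesh.
#' @param std_sigma marginal standard deviation (S/m).
#' @param corr_distance distance d (m) at which the correlation equals
#'   `corr_level`.
#' @param corr_level correlation at distance d (0 < level < 1).
#' @return class `eit_prior_smooth`: `L` (dense), `a`, `std`, `Gamma`.
#' @export
smoothness_prior <- function(mesh, std_sigma, corr_distance,
                             corr_level = 0.01) {
  stopifnot(std_sigma > 0, corr_distance > 0,
            corr_level > 0, corr_level < 1)
  a <- corr_distance / sqrt(-2 * log(corr_level))
  x <- mesh$nodes
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  Gamma <- std_sigma^2 * exp(-d2 / (2 * a^2))
  # the Gaussian kernel is numerically rank deficient for smooth
  # correlation lengths; a small diagonal jitter bounds the condition number
  R <- NULL
  for (t in 1:6) {
    jit <- 10^(t - 11) * std_sigma^2
    R <- tryCatch(chol(Gamma + jit * diag(n)), error = function(e) NULL)
    if (!is.null(R)) break
  }
  if (is.null(R)) stop("smoothness covariance is numerically indefinite")
  L <- t(backsolve(R, diag(n)))
  structure(list(L = L, a = a, std = std_sigma, Gamma = Gamma,
                 jitter = jit, mesh = mesh),
            class = "eit_prior_smooth")
}
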