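#' LSQR for least squares problems, matrix-free
#'
#' Paige-Saunders Golub-Kahan bidiagonalization for min ||A w - b||. The
#' operator is supplied as a pair of functions (products with A and A^T),
#' so augmented or transformed systems never need to be formed.
#'
#' @param Afun function(w) returning A w.
#' @param Atfun function(r) returning A^T r.
#' @param b right-hand side.
#' @param n number of unknowns.
#' @param tol relative residual-gradient tolerance.
#' @param maxit maximum iterations.
#' @return list(x, iterations, converged, relres).
#' @export
lsqr <- function(Afun, Atfun, b, n, tol = 1e-6, maxit = 200L) {
  x <- numeric(n)
  beta <- sqrt(sum(b^2))
  if (beta == 0) return(list(x = x, iterations = 0L, converged = TRUE,
                             relres = 0))
  u <- b / beta
  v <- Atfun(u)
  alpha <- sqrt(sum(v^2))
  if (alpha == 0) return(list(x = x, iterations = 0L, converged = TRUE,
                              relres = 0))
  v <- v / alpha
  wvec <- v
  phibar <- beta
  rhobar <- alpha
  norm_ar0 <- alpha * beta
  converged <- FALSE
  it <- 0L
  relres <- 1
  while (it < maxit) {
    it <- it + 1L
    u <- Afun(v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) {
      u <- u / beta
      v <- Atfun(u) - beta * v
      alpha <- sqrt(sum(v^2))
      if (alpha > 0) v <- v / alpha
    }
    rho <- sqrt(rhobar^2 + beta^2)
    c1 <- rhobar / rho
    s1 <- beta / rho
    theta <- s1 * alpha
    rhobar <- -c1 * alpha
    phi <- c1 * phibar
    phibar <- s1 * phibar
    x <- x + (phi / rho) * wvec
    wvec <- v - (theta / rho) * wvec
    # ||A^T r|| estimate
    norm_ar <- phibar * alpha * abs(c1)
    relres <- norm_ar / norm_ar0
    if (relres <= tol) { converged <- TRUE; break }
  }
  list(x = x, iterations = it, converged = converged, relres = relres)
}

#' Settings for the prior-conditioned LSQR search-direction solver
#' @param tol relative tolerance. @param maxit maximum inner iterations.
#' @export
mlsqr_settings <- function(tol = 1e-6, maxit = 200L) {
  stopifnot(tol > 0, maxit >= 1)
  list(tol = tol, maxit = as.integer(maxit))
}

#' Prior-conditioned LSQR solve of the Gauss-Newton direction
#'
#' Solves (2 A^T A + H) d = 2 A^T b - g, the lagged Gauss-Newton normal
#' equations with noise-weighted Jacobian A, prior Hessian H and prior
#' gradient g, without forming the normal matrix: with an upper-triangular
#' factor F (H = F^T F) the substitution d = F^{-1} w turns the system into
#' the damped least squares problem min ||[sqrt(2) A F^{-1}; I] w - rhs||,
#' solved by LSQR using only products with A, A^T, F^{-1}, F^{-T}.
#'
#' @param A weighted Jacobian: a matrix, or list(mv =, tmv =) of functions.
#' @param b weighted residual vector.
#' @param F upper-triangular prior factor with `H = t(F) %*% F`.
#' @param g_prior gradient of the regularization functional at the current
#'   iterate (zero vector for a pure least squares step).
#' @param settings an [mlsqr_settings()].
#' @return list(direction, iterations, converged, relres).
#' @export
mlsqr_solve <- function(A, b, F, g_prior = NULL, settings = mlsqr_settings()) {
  if (is.matrix(A) || is(A, "Matrix")) {
    Amv <- function(x) as.vector(A %*% x)
    Atmv <- function(y) as.vector(Matrix::crossprod(A, y))
    n <- ncol(A)
  } else {
    Amv <- A$mv; Atmv <- A$tmv; n <- A$n
  }
  if (is.null(g_prior)) g_prior <- numeric(n)
  Fi <- function(w) backsolve(F, w)
  Fit <- function(v) backsolve(F, v, transpose = TRUE)
  m <- length(b)
  Op <- function(w) c(sqrt(2) * Amv(Fi(w)), w)
  Opt <- function(r) Fit(sqrt(2) * Atmv(r[seq_len(m)])) + r[-seq_len(m)]
  rhs <- c(sqrt(2) * b, -Fit(g_prior))
  sol <- lsqr(Op, Opt, rhs, n, tol = settings$tol, maxit = settings$maxit)
  if (!sol$converged)
    warning(sprintf("MLSQR reached %d iterations (relres %.2e); using best iterate",
                    sol$iterations, sol$relres))
  list(direction = Fi(sol$x), iterations = sol$iterations,
       converged = sol$converged, relres = sol$relres)
}
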