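#' Gauss-Newton settings
#'
#' @param max_iter maximum outer iterations.
#' @param tol relative cost-decrease stopping tolerance.
#' @param ls_factor backtracking shrink factor in (0, 1).
#' @param ls_max maximum backtracking trials.
#' @param sigma_min positivity floor (S/m) enforced by projection.
#' @export
gn_settings <- function(max_iter = 25L, tol = 1e-4, ls_factor = 0.5,
                        ls_max = 20L, sigma_min = 1e-5) {
  stopifnot(tol > 0, sigma_min > 0, ls_factor > 0, ls_factor < 1)
  list(max_iter = as.integer(max_iter), tol = tol, ls_factor = ls_factor,
       ls_max = as.integer(ls_max), sigma_min = sigma_min)
}

noise_weight <- function(std) if (is.null(std) || all(std <= 0)) 1 else 1 / std

new_recon <- function(algorithm, fm, sigma1 = NULL, sigma2 = NULL,
                      dsigma = NULL, cost_trace = numeric(),
                      termination = "max_iter", extra = list()) {
  structure(c(list(algorithm = algorithm,
                   sigma1 = sigma1, sigma2 = sigma2, dsigma = dsigma,
                   cost_trace = cost_trace, termination = termination,
                   iterations = max(0L, length(cost_trace) - 1L),
                   mesh = fm$cmesh), extra),
            class = "eit_recon")
}

#' @export
print.eit_recon <- function(x, ...) {
  cat(sprintf("<eit_recon> %s: %d iterations, termination: %s\n",
              x$algorithm, x$iterations, x$termination))
  if (length(x$cost_trace))
    cat(sprintf("  cost %.6g -> %.6g\n", x$cost_trace[1],
                x$cost_trace[length(x$cost_trace)]))
  invisible(x)
}

#' TV-regularized absolute imaging
#'
#' Reconstructs the conductivity from a single measurement frame by
#' minimizing the noise-weighted data misfit plus smoothed total variation,
#' with a lagged Gauss-Newton iteration, projected backtracking line search
#' enforcing sigma >= sigma_min, and the best-fitting constant conductivity
#' as the starting point.
#'
#' @param frame an `eit_frame`.
#' @param fm forward model (reconstruction meshes).
#' @param tv a [tv_functional()]; defaults alpha 0.01, beta 0.001.
#' @param settings a [gn_settings()].
#' @param init optional starting `eit_field` (default: constant fit).
#' @return an `eit_recon` with the estimate in `$sigma1`.
#' @export
reconstruct_absolute <- function(frame, fm, tv = tv_functional(0.01, 0.001),
                                 settings = gn_settings(), init = NULL) {
  V <- frame_V(frame)
  w <- noise_weight(frame$noise_std)
  sig <- if (is.null(init)) fit_constant_sigma(frame, fm)$values else
    field_values(init, fm)
  cost_of <- function(s) {
    fw <- forward_solve(fm, s)
    sum((w * (V - fw$V))^2) + tv_eval_grad_hess(s, fm$cmesh, tv)$value
  }
  cost <- cost_of(sig)
  trace <- cost
  term <- "max_iter"
  for (it in seq_len(settings$max_iter)) {
    sys <- assemble_cem(fm, sig)
    fw <- forward_solve(fm, sig, sys = sys)
    r <- w * (V - fw$V)
    J <- w * cem_jacobian(fm, sig, sys = sys)
    p <- tv_eval_grad_hess(sig, fm$cmesh, tv)
    H <- 2 * crossprod(J) + as.matrix(p$hessian)
    rhs <- 2 * as.vector(crossprod(J, r)) - p$gradient
    d <- solve(H, rhs)
    # projected backtracking line search
    s <- 1
    ok <- FALSE
    for (ls in seq_len(settings$ls_max)) {
      cand <- pmax(sig + s * d, settings$sigma_min)
      cnew <- cost_of(cand)
      if (cnew < cost) { ok <- TRUE; break }
      s <- s * settings$ls_factor
    }
    if (!ok) { term <- "line_search_failure"; break }
    rel <- (cost - cnew) / cost
    sig <- cand
    cost <- cnew
    trace <- c(trace, cost)
    if (rel < settings$tol) { term <- "converged"; break }
  }
  new_recon("tv_absolute", fm,
            sigma1 = eit_field(sig, fm$cmesh),
            cost_trace = trace, termination = term,
            extra = list(settings = settings))
}

#' Conductivity change by subtraction of two absolute reconstructions
#'
#' @param r1,r2 `eit_recon` results on the same mesh (times t1, t2).
#' @return `eit_field` with delta sigma = sigma2_hat - sigma1_hat.
#' @export
difference_by_subtraction <- function(r1, r2) {
  f1 <- r1$sigma1; f2 <- r2$sigma1
  if (!isTRUE(all.equal(dim(f1$mesh$nodes), dim(f2$mesh$nodes))) ||
      length(f1$values) != length(f2$values))
    stop("reconstructions live on different meshes")
  eit_field(f2$values - f1$values, f1$mesh)
}
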