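#' Nonlinear ROI difference imaging with parallel level sets (monitoring)
#'
#' Jointly estimates the baseline conductivity sigma_1 on the whole domain
#' and the change delta_sigma supported on the region of interest (the
#' brain compartment) from both frames' full nonlinear models. sigma_1 is
#' regularized by reference-image weighted TV (parallel level sets), the
#' change by smoothed TV. The stacked problem is minimized by a lagged
#' Gauss-Newton iteration whose search direction is solved matrix-free by
#' prior-conditioned LSQR; a projected backtracking line search enforces
#' sigma_1 > 0 and sigma_1 + K delta_sigma > 0. The initial estimate is the
#' anatomically guided three-compartment fit to the first frame, with zero
#' initial change.
#'
#' @param frame1,frame2 measurement frames at t1 and t2.
#' @param fm forward model (reconstruction meshes).
#' @param ref `eit_reference` on the conductivity mesh (provides the
#'   weighting tensor and the ROI).
#' @param tv_dsigma TV functional for the change; defaults alpha 0.005,
#'   beta 0.001.
#' @param wtv_sigma1 weighted TV for sigma_1; defaults alpha 1e-7 scaled by
#'   `alpha1_scale`, beta 0.001.
#' @param gn outer [gn_settings()].
#' @param mlsqr inner [mlsqr_settings()].
#' @param init optional initial sigma_1 field (skips the compartment fit).
#' @param alpha1_scale multiplier applied to the default sigma_1 weight
#'   (the weight is geometry and scale dependent).
#' @return an `eit_recon` with `$sigma1` and `$dsigma` (extended by zero
#'   outside the ROI).
#' @export
reconstruct_monitoring <- function(frame1, frame2, fm, ref,
                                   tv_dsigma = NULL, wtv_sigma1 = NULL,
                                   gn = gn_settings(), mlsqr = mlsqr_settings(),
                                   init = NULL, alpha1_scale = 1) {
  if (is.null(tv_dsigma)) tv_dsigma <- tv_functional(0.005, 0.001)
  if (is.null(wtv_sigma1))
    wtv_sigma1 <- weighted_tv_functional(1e-7 * alpha1_scale, 0.001, ref)
  V1 <- frame_V(frame1); V2 <- frame_V(frame2)
  if (length(V1) != length(V2)) stop("frames are not congruent")
  w1 <- noise_weight(frame1$noise_std)
  w2 <- noise_weight(frame2$noise_std)
  cmesh <- fm$cmesh
  N <- nrow(cmesh$nodes)
  roi <- ref$roi_nodes
  if (length(roi) == 0L) stop("ROI is empty")
  nroi <- length(roi)
  K <- sparseMatrix(i = roi, j = seq_len(nroi), x = 1, dims = c(N, nroi))
  g <- mesh_geometry(cmesh)
  Mroi <- crossprod(K, g$mass %*% K)
  sig1 <- if (is.null(init)) fit_three_compartment(frame1, fm, ref)$values
          else field_values(init, fm)
  dlt <- numeric(nroi)
  cost_of <- function(s1v, dv) {
    f1 <- forward_solve(fm, s1v)
    f2 <- forward_solve(fm, s1v + as.vector(K %*% dv))
    sum((w1 * (V1 - f1$V))^2) + sum((w2 * (V2 - f2$V))^2) +
      tv_eval_grad_hess(s1v, cmesh, wtv_sigma1)$value +
      tv_eval_grad_hess(as.vector(K %*% dv), cmesh, tv_dsigma)$value
  }
  cost <- cost_of(sig1, dlt)
  trace <- cost
  term <- "max_iter"
  inner_its <- integer(0)
  for (it in seq_len(gn$max_iter)) {
    s2v <- sig1 + as.vector(K %*% dlt)
    sys1 <- assemble_cem(fm, sig1)
    sys2 <- assemble_cem(fm, s2v)
    f1 <- forward_solve(fm, sig1, sys = sys1)
    f2 <- forward_solve(fm, s2v, sys = sys2)
    r <- c(w1 * (V1 - f1$V), w2 * (V2 - f2$V))
    J1 <- cem_jacobian(fm, sig1, sys = sys1)
    J2 <- cem_jacobian(fm, s2v, sys = sys2)
    J2K <- as.matrix(J2 %*% K)
    A <- rbind(cbind(w1 * J1, matrix(0, nrow(J1), nroi)),
               cbind(w2 * J2, w2 * J2K))
    p1 <- tv_eval_grad_hess(sig1, cmesh, wtv_sigma1)
    pdfull <- tv_eval_grad_hess(as.vector(K %*% dlt), cmesh, tv_dsigma)
    gd <- as.vector(crossprod(K, pdfull$gradient))
    Hd <- as.matrix(crossprod(K, pdfull$hessian %*% K))
    H1 <- as.matrix(p1$hessian)
    # mass-matrix jitter so the block prior factorizes
    e1 <- 1e-12 * sum(diag(H1)) / sum(Matrix::diag(g$mass))
    ed <- 1e-12 * max(sum(diag(Hd)), sum(diag(H1))) / sum(Matrix::diag(Mroi))
    Hp <- matrix(0, N + nroi, N + nroi)
    Hp[seq_len(N), seq_len(N)] <- H1 + e1 * as.matrix(g$mass)
    Hp[N + seq_len(nroi), N + seq_len(nroi)] <- Hd + ed * as.matrix(Mroi)
    F <- chol(Hp)
    gprior <- c(p1$gradient, gd)
    sol <- mlsqr_solve(A, r, F, gprior, mlsqr)
    inner_its <- c(inner_its, sol$iterations)
    d <- sol$direction
    d1 <- d[seq_len(N)]
    dd <- d[N + seq_len(nroi)]
    s <- 1
    ok <- FALSE
    for (ls in seq_len(gn$ls_max)) {
      c1 <- pmax(sig1 + s * d1, gn$sigma_min)
      cd <- dd * s + dlt
      cd <- pmax(cd, gn$sigma_min - c1[roi])   # sigma1 + K delta >= floor
      cnew <- cost_of(c1, cd)
      if (cnew < cost) { ok <- TRUE; break }
      s <- s * gn$ls_factor
    }
    if (!ok) { term <- "line_search_failure"; break }
    rel <- (cost - cnew) / cost
    sig1 <- c1
    dlt <- cd
    cost <- cnew
    trace <- c(trace, cost)
    if (rel < gn$tol) { term <- "converged"; break }
  }
  ds_full <- as.vector(K %*% dlt)
  new_recon("monitoring", fm,
            sigma1 = eit_field(sig1, cmesh),
            sigma2 = eit_field(sig1 + ds_full, cmesh),
            dsigma = eit_field(ds_full, cmesh),
            cost_trace = trace, termination = term,
            extra = list(settings = gn, mlsqr = mlsqr,
                         roi_nodes = roi, inner_iterations = inner_its))
}
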