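test_that("monitoring estimate vanishes identically outside the ROI", {
  s <- study_setup()
  f1 <- study_frame(0.020, 921)
  f2 <- study_frame(0.025, 922)
  suppressWarnings(
    mo <- reconstruct_monitoring(f1, f2, s$fm, s$ref,
                                 tv_dsigma = tv_functional(300, 0.001),
                                 wtv_sigma1 = weighted_tv_functional(30, 0.001, s$ref),
                                 gn = gn_settings(max_iter = 6)))
  out <- setdiff(seq_len(nrow(s$fm$cmesh$nodes)), s$ref$roi_nodes)
  expect_true(all(mo$dsigma$values[out] == 0))
  expect_true(all(diff(mo$cost_trace) <= 0))
  expect_true(all(mo$sigma1$values >= 1e-5))
  .fixtures$mo_growth <- mo
})

test_that("no-growth frames give a much smaller change than real growth", {
  s <- study_setup()
  f1 <- study_frame(0.020, 921)
  f2b <- study_frame(0.020, 923)
  suppressWarnings(
    mo0 <- reconstruct_monitoring(f1, f2b, s$fm, s$ref,
                                  tv_dsigma = tv_functional(300, 0.001),
                                  wtv_sigma1 = weighted_tv_functional(30, 0.001, s$ref),
                                  gn = gn_settings(max_iter = 6),
                                  init = .fixtures$mo_growth$sigma1))
  mo <- .fixtures$mo_growth
  expect_gt(sqrt(sum(mo$dsigma$values^2)) / sqrt(sum(mo0$dsigma$values^2)), 5)
  # growth blob centred near the true inclusion
  com <- positive_center_of_mass(mo$dsigma)
  expect_lt(sqrt(sum((com - s$spec$hemorrhage_center)^2)), 0.02)
})

test_that("with full ROI and gamma = 1 the solver matches a dense GN oracle", {
  m <- tiny_mesh()
  fm <- tiny_fm()
  ref <- make_reference(m)
  ref$gamma <- rep(1, length(ref$gamma))      # no parallel-level-sets bias
  ref$roi_elements <- seq_len(nrow(m$elements))
  ref$roi_nodes <- seq_len(nrow(m$nodes))     # Omega_ROI = Omega
  ctr <- c(0, 0.055)
  d <- sqrt((m$nodes[, 1] - ctr[1])^2 + (m$nodes[, 2] - ctr[2])^2)
  f1 <- simulate_frame(fm, 0.2, noise_std = 2e-6, seed = 41)
  f2 <- simulate_frame(fm, eit_field(0.2 + 0.3 * (d < 0.015), m),
                       noise_std = 2e-6, seed = 42)
  tvd <- tv_functional(5, 0.001)
  wtv <- weighted_tv_functional(5, 0.001, ref)
  init <- eit_field(rep(0.2, nrow(m$nodes)), m)
  suppressWarnings(
    mo <- reconstruct_monitoring(f1, f2, fm, ref, tv_dsigma = tvd,
                                 wtv_sigma1 = wtv,
                                 gn = gn_settings(max_iter = 6, tol = 1e-9),
                                 mlsqr = mlsqr_settings(tol = 1e-13, maxit = 20000),
                                 init = init))
  # independent dense Gauss-Newton with direct normal-equation solves
  N <- nrow(m$nodes)
  w <- 1 / 2e-6
  g <- mesh_geometry(m)
  sig1 <- rep(0.2, N); dlt <- numeric(N)
  cost_of <- function(s1v, dv) {
    sum((w * (f1$V - forward_solve(fm, s1v)$V))^2) +
      sum((w * (f2$V - forward_solve(fm, s1v + dv)$V))^2) +
      tv_eval_grad_hess(s1v, m, wtv)$value +
      tv_eval_grad_hess(dv, m, tvd)$value
  }
  cost <- cost_of(sig1, dlt)
  for (it in 1:6) {
    s2v <- sig1 + dlt
    J1 <- cem_jacobian(fm, sig1)
    J2 <- cem_jacobian(fm, s2v)
    r <- c(w * (f1$V - forward_solve(fm, sig1)$V),
           w * (f2$V - forward_solve(fm, s2v)$V))
    A <- rbind(cbind(w * J1, matrix(0, nrow(J1), N)),
               cbind(w * J2, w * J2))
    p1 <- tv_eval_grad_hess(sig1, m, wtv)
    pd <- tv_eval_grad_hess(dlt, m, tvd)
    e1 <- 1e-12 * sum(Matrix::diag(p1$hessian)) / sum(Matrix::diag(g$mass))
    ed <- 1e-12 * max(sum(Matrix::diag(pd$hessian)), sum(Matrix::diag(p1$hessian))) /
      sum(Matrix::diag(g$mass))
    Hp <- matrix(0, 2 * N, 2 * N)
    Hp[1:N, 1:N] <- as.matrix(p1$hessian + e1 * g$mass)
    Hp[N + 1:N, N + 1:N] <- as.matrix(pd$hessian + ed * g$mass)
    dir <- solve(2 * crossprod(A) + Hp,
                 2 * crossprod(A, r) - c(p1$gradient, pd$gradient))
    step <- 1
    repeat {
      c1 <- pmax(sig1 + step * dir[1:N], 1e-5)
      cd <- dlt + step * dir[N + 1:N]
      cd <- pmax(cd, 1e-5 - c1)
      cnew <- cost_of(c1, cd)
      if (cnew < cost || step < 1e-6) break
      step <- step / 2
    }
    sig1 <- c1; dlt <- cd; cost <- cnew
  }
  scale <- max(abs(dlt))
  expect_lt(max(abs(mo$sigma1$values - sig1)) / max(abs(sig1)), 1e-5)
  expect_lt(max(abs(mo$dsigma$values - dlt)) / scale, 1e-5)
})
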