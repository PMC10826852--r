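#' Scenario grid of hemorrhage states
#'
#' Enumerates all ordered diameter pairs (D_i, D_j) with D_j >= D_i
#' (including the no-growth diagonal) crossed with hemorrhage locations
#' and algorithms: S states give S (S + 1) / 2 pairs per location and
#' algorithm.
#'
#' @param states numeric hemorrhage diameters (m); use 0 for the healthy
#'   (no hemorrhage) state.
#' @param locations subset of c("cortical", "deep").
#' @param algorithms subset of c("tv", "ld", "mo").
#' @return tibble with columns `algorithm`, `location`, `d1`, `d2`.
#' @export
build_grid <- function(states, locations = "cortical", algorithms = "mo") {
  states <- sort(unique(as.numeric(states)))
  if (length(states) < 1L) stop("need at least one state")
  pairs <- expand.grid(d1 = states, d2 = states)
  pairs <- pairs[pairs$d2 >= pairs$d1, ]
  grid <- tidyr::expand_grid(
    algorithm = algorithms, location = locations,
    tibble::as_tibble(pairs))
  dplyr::arrange(grid, .data$algorithm, .data$location, .data$d1, .data$d2)
}

#' Adjusted normalized integrals Q
#'
#' For each algorithm and location separately, the integrals of the
#' reconstructed conductivity changes are normalized by their maximum
#' absolute value over all pairs, and the maximum absolute normalized
#' integral of the no-growth (diagonal) pairs -- a proxy for the deviation
#' caused by measurement noise alone -- is subtracted:
#' Q = I_norm - max |I_norm(diagonal)|. Pairs with Q <= 0 are considered
#' indistinguishable from noise.
#'
#' @param results tibble with columns `algorithm`, `location`, `d1`, `d2`,
#'   `integral`.
#' @return the tibble with `normalized` and `Q` columns added.
#' @export
adjusted_Q <- function(results) {
  stopifnot(all(c("algorithm", "location", "d1", "d2", "integral")
                %in% names(results)))
  grp <- dplyr::group_by(results, .data$algorithm, .data$location)
  out <- dplyr::mutate(grp, normalized = {
    mx <- max(abs(.data$integral), na.rm = TRUE)
    if (!is.finite(mx) || mx == 0) {
      warning("all integrals are zero for an algorithm/location group")
      mx <- 1
    }
    .data$integral / mx
  })
  out <- dplyr::mutate(out, Q = {
    diagn <- abs(.data$normalized[.data$d1 == .data$d2])
    if (length(diagn) == 0L)
      stop("no-growth diagonal pairs are required to compute Q")
    .data$normalized - max(diagn, na.rm = TRUE)
  })
  dplyr::ungroup(out)
}

#' Center of mass of the positive part of a change field
#'
#' Lumped-mass weighted centroid of max(delta sigma, 0); used to check that
#' a detected change localizes near the true growth region.
#'
#' @param field an `eit_field` (or nodal values with `mesh`).
#' @param mesh mesh if `field` is a plain vector.
#' @return coordinate vector, or NA if the field has no positive part.
#' @export
positive_center_of_mass <- function(field, mesh = NULL) {
  if (inherits(field, "eit_field")) {
    mesh <- field$mesh
    v <- field$values
  } else v <- as.numeric(field)
  wts <- mesh_geometry(mesh)$lumped * pmax(v, 0)
  if (sum(wts) <= 0) return(rep(NA_real_, mesh$dim))
  as.vector(crossprod(mesh$nodes, wts) / sum(wts))
}

state_label <- function(d) ifelse(d == 0, "healthy", sprintf("%gmm", d * 1000))

derive_seed <- function(master, loc_idx, state_idx, role) {
  (as.integer(master) %% 1000000L) * 2000L + loc_idx * 500L +
    state_idx * 10L + role
}

#' Run the hemorrhage-growth detectability experiment
#'
#' Full scenario-grid driver: builds the phantom meshes (a fine simulation
#' mesh and separate potential/conductivity reconstruction meshes, avoiding
#' the inverse crime), simulates two noisy frames per state (the state as
#' first and as second measurement, with deterministic per-state seeds),
#' runs the requested algorithms on every pair (D_i, D_j), integrates each
#' reconstructed change over the domain and computes the adjusted
#' normalized integrals Q.
#'
#' @param states hemorrhage diameters (m), 0 = healthy.
#' @param locations subset of c("cortical", "deep").
#' @param algorithms subset of c("tv", "ld", "mo").
#' @param seed master seed; all per-frame seeds derive from it.
#' @param dimension phantom dimension (2 recommended at desk scale).
#' @param n_electrodes electrode count L.
#' @param noise_rel noise std as a fraction of the maximum healthy-state
#'   amplitude (device convention; default 0.067%).
#' @param densities list of mesh densities: `sim`, `potential`,
#'   `conductivity` (see [build_phantom()]).
#' @param gn,mlsqr solver settings for the iterative algorithms.
#' @param tv_alpha,tv_beta absolute-imaging TV parameters.
#' @param mo_alpha_dsigma,mo_alpha_sigma1,mo_beta monitoring-algorithm
#'   regularization parameters.
#' @param store_fields keep all reconstructed change fields in the result.
#' @param spec_args extra arguments passed to [head_phantom_spec()].
#' @return class `eit_detectability`: tibble `results` (one row per grid
#'   cell with raw/normalized integrals, Q, data-change norms and volume
#'   changes), plus meshes and frames metadata.
#' @export
run_experiment <- function(states = c(0, seq(0.010, 0.030, 0.005)),
                           locations = "cortical",
                           algorithms = c("tv", "ld", "mo"),
                           seed = 1L,
                           dimension = 2,
                           n_electrodes = 16L,
                           noise_rel = 6.7e-4,
                           densities = list(sim = "fine",
                                            potential = "medium",
                                            conductivity = "coarse"),
                           gn = gn_settings(max_iter = 12, tol = 1e-4),
                           mlsqr = mlsqr_settings(),
                           tv_alpha = 300, tv_beta = 0.001,
                           mo_alpha_dsigma = 300, mo_alpha_sigma1 = 30,
                           mo_beta = 0.001, mo_alpha1_scale = 1,
                           store_fields = FALSE,
                           spec_args = list()) {
  states <- sort(unique(as.numeric(states)))
  grid <- build_grid(states, locations, algorithms)
  rows <- list()
  fields <- list()
  info <- list()
  diam <- states[states > 0]
  for (li in seq_along(locations)) {
    loc <- locations[li]
    spec <- do.call(head_phantom_spec, c(list(
      dimension = dimension, n_electrodes = n_electrodes,
      hemorrhage_diameters = diam, location = loc), spec_args))
    sim_mesh <- build_phantom(spec, densities$sim)
    pot_mesh <- build_phantom(spec, densities$potential)
    cond_mesh <- build_phantom(spec, densities$conductivity)
    fm_sim <- forward_model(sim_mesh)
    fm <- forward_model(pot_mesh, conductivity_mesh = cond_mesh)
    ref <- make_reference(cond_mesh)
    # noise level calibrated on noise-free healthy data
    healthy <- assign_conductivity(sim_mesh, state = "healthy")
    V_healthy <- forward_solve(fm_sim, healthy)$V
    std_abs <- noise_rel * max(abs(V_healthy))
    state_of <- function(d) if (d == 0) "healthy" else d
    V0 <- list(); fr1 <- list(); fr2 <- list()
    for (si in seq_along(states)) {
      st <- state_of(states[si])
      sig <- assign_conductivity(sim_mesh, state = st)
      fw <- forward_solve(fm_sim, sig)
      key <- as.character(si)
      V0[[key]] <- fw$V
      fr1[[key]] <- simulate_frame(fm_sim, sig, noise_std = std_abs,
                                   seed = derive_seed(seed, li, si, 1L),
                                   label = paste0(state_label(states[si]), "_t1"))
      fr2[[key]] <- simulate_frame(fm_sim, sig, noise_std = std_abs,
                                   seed = derive_seed(seed, li, si, 2L),
                                   label = paste0(state_label(states[si]), "_t2"))
    }
    # per-state caches
    abs1 <- list(); abs2 <- list(); lin <- list(); init3 <- list()
    tvf <- tv_functional(tv_alpha, tv_beta)
    tvd <- tv_functional(mo_alpha_dsigma, mo_beta)
    wtv <- weighted_tv_functional(mo_alpha_sigma1 * mo_alpha1_scale,
                                  mo_beta, ref)
    gloc <- grid[grid$location == loc, ]
    for (gi in seq_len(nrow(gloc))) {
      alg <- gloc$algorithm[gi]
      k1 <- as.character(match(gloc$d1[gi], states))
      k2 <- as.character(match(gloc$d2[gi], states))
      res <- tryCatch({
        ds <- switch(alg,
          tv = {
            if (is.null(abs1[[k1]]))
              abs1[[k1]] <- reconstruct_absolute(fr1[[k1]], fm, tv = tvf,
                                                  settings = gn)
            if (is.null(abs2[[k2]]))
              abs2[[k2]] <- reconstruct_absolute(fr2[[k2]], fm, tv = tvf,
                                                  settings = gn)
            difference_by_subtraction(abs1[[k1]], abs2[[k2]])
          },
          ld = {
            if (is.null(lin[[k1]])) lin[[k1]] <- linearize(fr1[[k1]], fm)
            reconstruct_linear(fr1[[k1]], fr2[[k2]], fm,
                               model = lin[[k1]])$dsigma
          },
          mo = {
            if (is.null(init3[[k1]]))
              init3[[k1]] <- fit_three_compartment(fr1[[k1]], fm, ref)
            reconstruct_monitoring(fr1[[k1]], fr2[[k2]], fm, ref,
                                   tv_dsigma = tvd, wtv_sigma1 = wtv,
                                   gn = gn, mlsqr = mlsqr,
                                   init = init3[[k1]])$dsigma
          },
          stop("unknown algorithm: ", alg))
        ds
      }, error = function(e) e)
      if (inherits(res, "error")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          algorithm = alg, location = loc,
          d1 = gloc$d1[gi], d2 = gloc$d2[gi],
          integral = NA_real_, dV_norm = NA_real_, dV0_norm = NA_real_,
          com_x = NA_real_, com_y = NA_real_,
          error = conditionMessage(res))
        next
      }
      com <- positive_center_of_mass(res)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        algorithm = alg, location = loc,
        d1 = gloc$d1[gi], d2 = gloc$d2[gi],
        integral = integral_field(res),
        dV_norm = sqrt(sum((fr2[[k2]]$V - fr1[[k1]]$V)^2)),
        dV0_norm = sqrt(sum((V0[[k2]] - V0[[k1]])^2)),
        com_x = com[1], com_y = com[2],
        error = NA_character_)
      if (store_fields)
        fields[[paste(alg, loc, gloc$d1[gi], gloc$d2[gi], sep = "_")]] <- res
    }
    info[[loc]] <- list(spec = spec, noise_std = std_abs,
                        sim_mesh = sim_mesh, fm = fm, ref = ref,
                        frames_t1 = fr1, frames_t2 = fr2, V0 = V0)
  }
  results <- dplyr::bind_rows(rows)
  results$volume_change_ml <- volume_increase(results$d1, results$d2)
  results <- adjusted_Q(results)
  structure(list(results = results, states = states, seed = seed,
                 fields = fields, info = info),
            class = "eit_detectability")
}

#' @export
print.eit_detectability <- function(x, ...) {
  cat(sprintf("<eit_detectability> %d cells (%d states)\n",
              nrow(x$results), length(x$states)))
  print(x$results, n = 10)
  invisible(x)
}

#' Smallest detected volume increase
#'
#' The smallest true hemorrhage volume increase among growth pairs with
#' Q > 0 for the given algorithm and location.
#'
#' @param x an `eit_detectability` (or its results tibble).
#' @param algorithm,location cell selectors.
#' @return volume increase in ml (Inf if nothing is detected).
#' @export
smallest_detected_increase <- function(x, algorithm = "mo",
                                       location = "cortical") {
  res <- if (inherits(x, "eit_detectability")) x$results else x
  sel <- res$algorithm == algorithm & res$location == location &
    res$d2 > res$d1 & !is.na(res$Q) & res$Q > 0
  if (!any(sel)) return(Inf)
  min(res$volume_change_ml[sel])
}
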