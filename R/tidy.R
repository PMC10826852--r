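#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a reconstruction result into a node-level tibble
#'
#' @param x an `eit_recon`.
#' @param ... unused.
#' @return tibble with node coordinates and the estimated fields.
#' @method tidy eit_recon
#' @export
tidy.eit_recon <- function(x, ...) {
  nd <- x$mesh$nodes
  out <- tibble::tibble(node = seq_len(nrow(nd)), x = nd[, 1], y = nd[, 2])
  if (ncol(nd) == 3) out$z <- nd[, 3]
  if (!is.null(x$sigma1)) out$sigma1 <- x$sigma1$values
  if (!is.null(x$sigma2)) out$sigma2 <- x$sigma2$values
  if (!is.null(x$dsigma)) out$dsigma <- x$dsigma$values
  out
}

#' One-row summary of a reconstruction
#' @param x an `eit_recon`. @param ... unused.
#' @method glance eit_recon
#' @export
glance.eit_recon <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    iterations = x$iterations,
    termination = x$termination,
    initial_cost = if (length(x$cost_trace)) x$cost_trace[1] else NA_real_,
    final_cost = if (length(x$cost_trace))
      x$cost_trace[length(x$cost_trace)] else NA_real_)
}

#' Tidy detectability results
#' @param x an `eit_detectability`. @param ... unused.
#' @method tidy eit_detectability
#' @export
tidy.eit_detectability <- function(x, ...) x$results

#' Per algorithm/location detectability summary
#' @param x an `eit_detectability`. @param ... unused.
#' @method glance eit_detectability
#' @export
glance.eit_detectability <- function(x, ...) {
  res <- x$results
  grp <- dplyr::group_by(res, .data$algorithm, .data$location)
  dplyr::summarise(grp,
    n_pairs = dplyr::n(),
    n_detected = sum(.data$Q > 0 & .data$d2 > .data$d1, na.rm = TRUE),
    smallest_detected_ml = {
      s <- .data$volume_change_ml[.data$Q > 0 & .data$d2 > .data$d1 &
                                    !is.na(.data$Q)]
      if (length(s)) min(s) else Inf
    },
    .groups = "drop")
}

#' Heat maps of the adjusted normalized integrals
#'
#' One tile per (D1, D2) scenario pair, faceted by algorithm and location.
#' Pairs with Q <= 0 (indistinguishable from measurement noise) are drawn
#' white.
#'
#' @param object an `eit_detectability`.
#' @param ... unused.
#' @method autoplot eit_detectability
#' @export
autoplot.eit_detectability <- function(object, ...) {
  res <- object$results
  res$D1 <- factor(state_label(res$d1), levels = state_label(sort(unique(res$d1))))
  res$D2 <- factor(state_label(res$d2), levels = state_label(sort(unique(res$d2))))
  res$Qpos <- ifelse(res$Q > 0, res$Q, NA_real_)
  ggplot2::ggplot(res, ggplot2::aes(x = .data$D2, y = .data$D1,
                                    fill = .data$Qpos)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::scale_fill_viridis_c(na.value = "white", limits = c(0, 1),
                                  name = "Q") +
    ggplot2::facet_grid(location ~ algorithm) +
    ggplot2::labs(x = "diameter at second measurement",
                  y = "diameter at first measurement") +
    ggplot2::theme_minimal()
}

#' Plot a nodal field on a 2D mesh
#'
#' Element-filled polygon rendering of a piecewise linear field (element
#' colour = mean of vertex values).
#'
#' @param object an `eit_field` on a 2D mesh.
#' @param ... unused.
#' @method autoplot eit_field
#' @export
autoplot.eit_field <- function(object, ...) {
  mesh <- object$mesh
  if (mesh$dim != 2L) stop("plotting is implemented for 2D meshes")
  el <- mesh$elements
  ne <- nrow(el)
  df <- tibble::tibble(
    id = rep(seq_len(ne), each = 3L),
    x = mesh$nodes[as.vector(t(el)), 1],
    y = mesh$nodes[as.vector(t(el)), 2],
    value = rep(rowMeans(matrix(object$values[el], ne)), each = 3L))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$id,
                                   fill = .data$value)) +
    ggplot2::geom_polygon() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = expression(sigma)) +
    ggplot2::theme_void()
}

#' Plot mesh tissue layout
#' @param object an `eit_mesh` (2D). @param ... unused.
#' @method autoplot eit_mesh
#' @export
autoplot.eit_mesh <- function(object, ...) {
  if (object$dim != 2L) stop("plotting is implemented for 2D meshes")
  el <- object$elements
  ne <- nrow(el)
  lab <- object$tissue
  lab[!is.na(object$hemorrhage_d)] <- "hemorrhage"
  df <- tibble::tibble(
    id = rep(seq_len(ne), each = 3L),
    x = object$nodes[as.vector(t(el)), 1],
    y = object$nodes[as.vector(t(el)), 2],
    tissue = rep(lab, each = 3L))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, group = .data$id,
                                   fill = .data$tissue)) +
    ggplot2::geom_polygon(color = NA) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
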