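#' Write a mesh (with optional fields) as legacy VTK ASCII
#'
#' Unstructured-grid export readable by ParaView: tissue and electrode
#' labels as cell data, nodal fields as point data.
#'
#' @param mesh an [eit_mesh()].
#' @param file output path (.vtk).
#' @param point_data named list of nodal vectors.
#' @param cell_data named list of per-element vectors.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  nd <- mesh$nodes
  if (ncol(nd) == 2) nd <- cbind(nd, 0)
  el <- mesh$elements
  nl <- ncol(el)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("eitmon mesh")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", nrow(nd))
  writeLines(apply(nd, 1, function(p) paste(format(p, digits = 12),
                                            collapse = " ")), con)
  w("CELLS %d %d", nrow(el), nrow(el) * (nl + 1))
  writeLines(apply(el, 1, function(e)
    paste(c(nl, e - 1L), collapse = " ")), con)
  w("CELL_TYPES %d", nrow(el))
  writeLines(rep(if (nl == 3) "5" else "10", nrow(el)), con)
  if (!is.null(mesh$tissue))
    cell_data$tissue_id <- as.integer(factor(mesh$tissue))
  if (length(cell_data)) {
    w("CELL_DATA %d", nrow(el))
    for (nm in names(cell_data)) {
      w("SCALARS %s double 1", nm)
      w("LOOKUP_TABLE default")
      writeLines(format(as.numeric(cell_data[[nm]]), digits = 12), con)
    }
  }
  if (length(point_data)) {
    w("POINT_DATA %d", nrow(nd))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (inherits(v, "eit_field")) v <- v$values
      w("SCALARS %s double 1", nm)
      w("LOOKUP_TABLE default")
      writeLines(format(as.numeric(v), digits = 12), con)
    }
  }
  invisible(file)
}

#' Write a mesh in Gmsh MSH 4.1 ASCII format
#'
#' Single-block export with tissue labels as element tags readable back by
#' [read_msh()].
#'
#' @param mesh an [eit_mesh()].
#' @param file output path (.msh).
#' @export
write_msh <- function(mesh, file) {
  nd <- mesh$nodes
  if (ncol(nd) == 2) nd <- cbind(nd, 0)
  el <- mesh$elements
  nl <- ncol(el)
  dim <- mesh$dim
  type <- if (dim == 2) 2L else 4L
  btype <- if (dim == 2) 1L else 2L
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("4.1 0 8"); w("$EndMeshFormat")
  w("$Nodes")
  w("1 %d 1 %d", nrow(nd), nrow(nd))
  w("%d 1 0 %d", dim, nrow(nd))
  writeLines(format(seq_len(nrow(nd))), con)
  writeLines(apply(nd, 1, function(p) paste(format(p, digits = 12),
                                            collapse = " ")), con)
  w("$EndNodes")
  nb <- nrow(mesh$boundary)
  w("$Elements")
  w("2 %d 1 %d", nrow(el) + nb, nrow(el) + nb)
  w("%d 1 %d %d", dim - 1L, btype, nb)
  writeLines(apply(cbind(seq_len(nb), mesh$boundary), 1, paste,
                   collapse = " "), con)
  w("%d 1 %d %d", dim, type, nrow(el))
  writeLines(apply(cbind(nb + seq_len(nrow(el)), el), 1, paste,
                   collapse = " "), con)
  w("$EndElements")
  # labels in auxiliary sections (plain, tool-specific)
  w("$ElementData"); w("1"); w("\"electrode\""); w("1"); w("0")
  w("3"); w("0"); w("1"); w("%d", nb)
  writeLines(paste(seq_len(nb), mesh$electrode), con)
  w("$EndElementData")
  invisible(file)
}

#' Read a Gmsh MSH 4.1 ASCII mesh
#'
#' Parses nodes and elements; the highest-dimensional simplices become the
#' mesh, codimension-one simplices the boundary. Electrode labels are read
#' from an `$ElementData` field named "electrode" when present, otherwise
#' all boundary facets are unlabelled (supply labels before using the mesh
#' in a forward model).
#'
#' @param file path to a .msh file.
#' @param n_electrodes electrode count if labels are present.
#' @return an [eit_mesh()] (or list of parts if no electrode labels).
#' @export
read_msh <- function(file, n_electrodes = NULL) {
  ln <- readLines(file)
  sec <- function(name) {
    a <- which(ln == paste0("$", name)) + 1L
    b <- which(ln == paste0("$End", name)) - 1L
    if (!length(a)) return(NULL)
    ln[a:b]
  }
  nds <- sec("Nodes")
  hdr <- scan(text = nds[1], quiet = TRUE)
  nblocks <- hdr[1]; ntot <- hdr[2]
  pos <- 2L
  ids <- integer(0); xyz <- NULL
  for (b in seq_len(nblocks)) {
    bh <- scan(text = nds[pos], quiet = TRUE)
    nb <- bh[4]
    bids <- as.integer(nds[pos + seq_len(nb)])
    coords <- do.call(rbind, lapply(nds[pos + nb + seq_len(nb)], function(s)
      scan(text = s, quiet = TRUE)))
    ids <- c(ids, bids)
    xyz <- rbind(xyz, coords)
    pos <- pos + 2L * nb + 1L
  }
  ord <- order(ids)
  xyz <- xyz[ord, , drop = FALSE]
  remap <- integer(max(ids)); remap[ids[ord]] <- seq_along(ids)
  els <- sec("Elements")
  hdr <- scan(text = els[1], quiet = TRUE)
  nblocks <- hdr[1]
  pos <- 2L
  tris <- NULL; tets <- NULL; lines2 <- NULL
  for (b in seq_len(nblocks)) {
    bh <- scan(text = els[pos], quiet = TRUE)
    type <- bh[3]; nb <- bh[4]
    rows <- do.call(rbind, lapply(els[pos + seq_len(nb)], function(s)
      scan(text = s, quiet = TRUE)))
    conn <- matrix(remap[as.integer(rows[, -1, drop = FALSE])], nrow = nb)
    if (type == 1) lines2 <- rbind(lines2, conn)
    if (type == 2) tris <- rbind(tris, conn)
    if (type == 4) tets <- rbind(tets, conn)
    pos <- pos + nb + 1L
  }
  if (!is.null(tets)) {
    dim <- 3L; elements <- tets; boundary <- tris
  } else {
    dim <- 2L; elements <- tris; boundary <- lines2
  }
  nodes <- xyz[, seq_len(dim), drop = FALSE]
  electrode <- rep(0L, if (is.null(boundary)) 0L else nrow(boundary))
  ed <- sec("ElementData")
  if (!is.null(ed) && any(grepl("electrode", ed[2]))) {
    nv <- as.integer(ed[8])
    for (k in seq_len(nv)) {
      pr <- scan(text = ed[8 + k], quiet = TRUE)
      electrode[pr[1]] <- pr[2]
    }
  }
  if (any(electrode > 0)) {
    eit_mesh(nodes, elements, boundary, electrode,
             n_electrodes = if (is.null(n_electrodes)) max(electrode)
                            else n_electrodes)
  } else {
    list(nodes = nodes, elements = elements, boundary = boundary)
  }
}

#' Export / import measurement frames as CSV
#'
#' One row per current injection, one column per differential channel,
#' with the noise level and label in a comment header.
#'
#' @param frame an `eit_frame`. @param file path.
#' @param n_patterns number of injections (rows).
#' @export
write_frame_csv <- function(frame, file, n_patterns) {
  V <- matrix(frame$V, ncol = n_patterns)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# label=%s noise_std=%.12g seed=%s", frame$label,
                     frame$noise_std,
                     if (is.null(frame$seed)) "NA" else frame$seed), con)
  utils::write.table(t(V), con, sep = ",", row.names = FALSE,
                     col.names = paste0("ch", seq_len(nrow(V))))
  invisible(file)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(file) {
  hdr <- readLines(file, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(meta, "=")
  vals <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  M <- utils::read.csv(file, comment.char = "#")
  structure(list(V = as.vector(t(as.matrix(M))),
                 noise_std = as.numeric(vals["noise_std"]),
                 label = unname(vals["label"]),
                 seed = suppressWarnings(as.integer(vals["seed"])),
                 n = length(as.matrix(M))),
            class = "eit_frame")
}

#' Read a YAML run configuration
#'
#' Keys mirror the arguments of [run_experiment()] (states in mm are
#' converted to metres if a `states_mm` key is used).
#'
#' @param file path to a YAML file.
#' @return named list of arguments for [run_experiment()].
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (!is.null(cfg$states_mm)) {
    cfg$states <- as.numeric(cfg$states_mm) / 1000
    cfg$states_mm <- NULL
  }
  cfg
}
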