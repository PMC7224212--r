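#' Write a displacement field to NIfTI volumes
#'
#' One NIfTI file per displacement component (suffix `_x`, `_y`, `_z`) plus a
#' `_mask` volume and, when weights are not all 1, a `_weights` volume. The
#' voxel spacing and origin are carried in the NIfTI affine. A JSON sidecar
#' `<prefix>.json` records the axis order and units; [write_field_sidecar()]
#' can extend it with encoding and noise metadata.
#'
#' @param field a [displacement_field()].
#' @param prefix path prefix; files are `<prefix>_x.nii.gz`, etc.
#' @return invisibly, the vector of files written.
#' @export
write_field_nifti <- function(field, prefix) {
  nd <- length(field$components)
  ax <- c("x", "y", "z")[seq_len(nd)]
  files <- character(0)
  as_img <- function(arr) {  # voxel spacing carried in the NIfTI header
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- field$spacing
    img
  }
  for (a in seq_len(nd)) {
    f <- paste0(prefix, "_", ax[a], ".nii.gz")
    RNifti::writeNifti(as_img(field$components[[a]]), f)
    files <- c(files, f)
  }
  fm <- paste0(prefix, "_mask.nii.gz")
  RNifti::writeNifti(as_img(array(as.integer(field$mask),
                                  dim = grid_dim(field$mask))), fm)
  files <- c(files, fm)
  if (any(field$weights != 1)) {
    fw <- paste0(prefix, "_weights.nii.gz")
    RNifti::writeNifti(as_img(field$weights), fw)
    files <- c(files, fw)
  }
  meta <- list(axes = ax, units = "mm", spacing = field$spacing,
               origin = field$origin)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(files, paste0(prefix, ".json")))
}

#' Read a displacement field from NIfTI volumes
#'
#' Counterpart of [write_field_nifti()]; expects the same `<prefix>_<axis>`
#' naming and the JSON sidecar for grid geometry.
#'
#' @param prefix path prefix used at write time.
#' @return a [displacement_field()].
#' @export
read_field_nifti <- function(prefix) {
  sidecar <- paste0(prefix, ".json")
  imgs <- list()
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    ax <- meta$axes
  } else {
    # no sidecar: take geometry from the NIfTI headers
    ax <- c("x", "y", "z")
    ax <- ax[file.exists(paste0(prefix, "_", ax, ".nii.gz"))]
    img1 <- RNifti::readNifti(paste0(prefix, "_", ax[1], ".nii.gz"))
    meta <- list(spacing = RNifti::pixdim(img1)[seq_along(dim(img1))],
                 origin = rep(0, length(dim(img1))))
  }
  comps <- lapply(ax, function(a) {
    img <- RNifti::readNifti(paste0(prefix, "_", a, ".nii.gz"))
    array(as.numeric(img), dim = dim(img))
  })
  maskf <- paste0(prefix, "_mask.nii.gz")
  mask <- if (file.exists(maskf)) {
    img <- RNifti::readNifti(maskf)
    array(as.numeric(img) > 0.5, dim = dim(img))
  } else NULL
  wf <- paste0(prefix, "_weights.nii.gz")
  weights <- if (file.exists(wf)) {
    img <- RNifti::readNifti(wf)
    array(as.numeric(img), dim = dim(img))
  } else NULL
  if (!is.null(mask)) for (a in seq_along(comps)) comps[[a]][!mask] <- 0
  displacement_field(comps, spacing = as.numeric(meta$spacing),
                     origin = as.numeric(meta$origin), mask = mask,
                     weights = weights)
}

#' Write a displacement field as delimited text
#'
#' One whitespace-delimited file per component (`<prefix>_x.txt`, ...) in
#' row-major order (first grid axis varies across columns of a row), plus
#' `<prefix>_mask.txt` and the JSON geometry sidecar. Only 2D grids are
#' supported in text form; use NIfTI for 3D.
#'
#' @param field a 2D [displacement_field()].
#' @param prefix path prefix.
#' @return invisibly, the files written.
#' @export
write_field_text <- function(field, prefix) {
  shp <- grid_dim(field$mask)
  if (length(shp) != 2L) stop("text export supports 2D fields only")
  ax <- c("x", "y")
  files <- character(0)
  for (a in seq_len(2L)) {
    f <- paste0(prefix, "_", ax[a], ".txt")
    utils::write.table(t(field$components[[a]]), f, row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, f)
  }
  fm <- paste0(prefix, "_mask.txt")
  utils::write.table(t(field$mask * 1L), fm, row.names = FALSE,
                     col.names = FALSE)
  meta <- list(axes = ax, units = "mm", spacing = field$spacing,
               origin = field$origin, layout = "row-major (x across columns)")
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(files, fm, paste0(prefix, ".json")))
}

#' Read a displacement field from delimited text
#'
#' @param prefix path prefix used by [write_field_text()].
#' @return a [displacement_field()].
#' @export
read_field_text <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  comps <- lapply(meta$axes, function(a) {
    m <- as.matrix(utils::read.table(paste0(prefix, "_", a, ".txt")))
    t(unname(m))
  })
  maskf <- paste0(prefix, "_mask.txt")
  mask <- if (file.exists(maskf))
    t(unname(as.matrix(utils::read.table(maskf)))) > 0.5 else NULL
  if (!is.null(mask)) for (a in seq_along(comps)) comps[[a]][!mask] <- 0
  displacement_field(comps, spacing = as.numeric(meta$spacing),
                     origin = as.numeric(meta$origin), mask = mask)
}

#' Write encoding/noise metadata sidecar
#'
#' Serializes a [phase_encoding_spec()] and/or [noise_spec()] to a JSON file
#' so that raw-phase inputs are self-describing.
#'
#' @param path output JSON path.
#' @param encoding optional [phase_encoding_spec()].
#' @param noise optional [noise_spec()].
#' @return invisibly, `path`.
#' @export
write_field_sidecar <- function(path, encoding = NULL, noise = NULL) {
  obj <- list()
  if (!is.null(encoding)) obj$encoding <- unclass(encoding)
  if (!is.null(noise)) obj$noise <- unclass(noise)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read encoding/noise metadata sidecar
#'
#' @param path JSON path written by [write_field_sidecar()].
#' @return list with elements `encoding` ([phase_encoding_spec()] or `NULL`)
#'   and `noise` ([noise_spec()] or `NULL`).
#' @export
read_field_sidecar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc <- if (!is.null(obj$encoding))
    phase_encoding_spec(gyromagnetic_ratio = obj$encoding$gyromagnetic_ratio,
                        encoding_duration = obj$encoding$encoding_duration,
                        encoding_gradient = obj$encoding$encoding_gradient,
                        reference_gradient = obj$encoding$reference_gradient)
  ns <- if (!is.null(obj$noise))
    noise_spec(sigma = obj$noise$sigma, seed = obj$noise$seed,
               apply_to_boundary = obj$noise$apply_to_boundary)
  list(encoding = enc, noise = ns)
}

# VTK cell-type ids for the supported element families
vtk_cell_type <- function(family) {
  switch(family,
         tri3 = 5L, quad4 = 9L, quad8 = 23L, tet4 = 10L, hex8 = 12L,
         stop("unknown element family: ", family))
}

#' Write a mesh (with optional data) as legacy ASCII VTK
#'
#' Writes an unstructured-grid `.vtk` file readable by ParaView and
#' [read_mesh_vtk()]. Element-wise arrays (for example a reconstructed
#' relative-stiffness map) go into `CELL_DATA`, node-wise arrays (for example
#' displacement solutions) into `POINT_DATA`; 2D vectors are padded with a
#' zero z-component.
#'
#' @param mesh an [fe_mesh()].
#' @param path output file path.
#' @param cell_data named list of numeric vectors (length = number of
#'   elements).
#' @param point_data named list of numeric vectors (length = number of
#'   nodes) or matrices (nodes x dimension) written as vectors.
#' @return invisibly, `path`.
#' @export
write_mesh_vtk <- function(mesh, path, cell_data = list(), point_data = list()) {
  stopifnot(inherits(mesh, "fe_mesh"))
  nn <- nrow(mesh$nodes)
  ne <- nrow(mesh$elements)
  npe <- ncol(mesh$elements)
  pts <- cbind(mesh$nodes, matrix(0, nn, 3 - ncol(mesh$nodes)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "fdelast unstructured grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(format(pts, scientific = TRUE, digits = 12), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, ne * (npe + 1L)), con)
  utils::write.table(cbind(npe, mesh$elements - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(vtk_cell_type(mesh$family), ne)), con)
  if (length(cell_data) > 0) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(format(as.numeric(cell_data[[nm]]), digits = 12), con)
    }
  }
  if (length(point_data) > 0) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nm in names(point_data)) {
      val <- point_data[[nm]]
      if (is.matrix(val)) {
        v3 <- cbind(val, matrix(0, nn, 3 - ncol(val)))
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(format(v3, scientific = TRUE, digits = 12), con,
                           row.names = FALSE, col.names = FALSE, quote = FALSE)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(as.numeric(val), digits = 12), con)
      }
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid
#'
#' Reads files produced by [write_mesh_vtk()] (a single homogeneous cell
#' type; scalar cell data and scalar/vector point data).
#'
#' @param path `.vtk` file path.
#' @return list with `mesh` (an [fe_mesh()]), `cell_data` and `point_data`
#'   named lists.
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  toks <- function(s) strsplit(trimws(s), "\\s+")[[1]]
  i <- grep("^POINTS", lines)[1]
  nn <- as.integer(toks(lines[i])[2])
  ptvals <- scan(text = lines[(i + 1):length(lines)], n = nn * 3, quiet = TRUE)
  pts <- matrix(ptvals, ncol = 3, byrow = TRUE)
  i <- grep("^CELLS", lines)[1]
  ne <- as.integer(toks(lines[i])[2])
  cellvals <- scan(text = lines[(i + 1):length(lines)],
                   n = as.integer(toks(lines[i])[3]), quiet = TRUE)
  npe <- cellvals[1]
  cells <- matrix(cellvals, ncol = npe + 1L, byrow = TRUE)[, -1, drop = FALSE] + 1L
  i <- grep("^CELL_TYPES", lines)[1]
  ctype <- as.integer(toks(lines[i + 1])[1])
  family <- unname(c(`5` = "tri3", `9` = "quad4", `23` = "quad8",
                     `10` = "tet4", `12` = "hex8")[as.character(ctype)])
  dim3 <- family %in% c("tet4", "hex8")
  nodes <- pts[, seq_len(if (dim3) 3 else 2), drop = FALSE]
  mesh <- fe_mesh(nodes = nodes, elements = cells, family = family)
  read_arrays <- function(start, stopat, n) {
    out <- list()
    j <- start
    while (j <= length(lines) && !grepl(stopat, lines[j])) {
      if (grepl("^SCALARS", lines[j])) {
        nm <- toks(lines[j])[2]
        vals <- scan(text = lines[(j + 2):length(lines)], n = n, quiet = TRUE)
        out[[nm]] <- vals
        j <- j + 2
      } else if (grepl("^VECTORS", lines[j])) {
        nm <- toks(lines[j])[2]
        vals <- scan(text = lines[(j + 1):length(lines)], n = n * 3,
                     quiet = TRUE)
        out[[nm]] <- matrix(vals, ncol = 3, byrow = TRUE)[,
          seq_len(if (dim3) 3 else 2), drop = FALSE]
      }
      j <- j + 1
    }
    out
  }
  cd <- integer(0)
  cell_data <- list(); point_data <- list()
  icd <- grep("^CELL_DATA", lines)
  ipd <- grep("^POINT_DATA", lines)
  if (length(icd) > 0) cell_data <- read_arrays(icd[1] + 1, "^POINT_DATA", ne)
  if (length(ipd) > 0) point_data <- read_arrays(ipd[1] + 1, "^CELL_DATA", nn)
  list(mesh = mesh, cell_data = cell_data, point_data = point_data)
}

#' Export/import Dirichlet boundary data as JSON
#'
#' @param bc a [dirichlet_bc()].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_bc_json <- function(bc, path) {
  stopifnot(inherits(bc, "dirichlet_bc"))
  obj <- list(nodes = bc$nodes, values = unname(split(bc$values, row(bc$values))))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_bc_json
#' @export
read_bc_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- do.call(rbind, if (is.list(obj$values)) obj$values else
    list(obj$values))
  if (is.matrix(obj$values)) vals <- obj$values
  dirichlet_bc(nodes = as.integer(obj$nodes), values = vals)
}
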