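# The connectivity-matrix container and its on-disk formats.

#' Construct a connectivity matrix
#'
#' The central container of the workflow: one row per ROI voxel (the voxel's
#' connectivity fingerprint), one column per target feature (target voxel,
#' or principal component after reduction). `voxel_index` keeps the 0-based
#' grid coordinate of every row so labels can be mapped back onto the ROI.
#'
#' @param values numeric matrix, ROI voxels x target features.
#' @param voxel_index n x 3 integer matrix of 0-based voxel coordinates, one
#'   row per matrix row.
#' @param transform_log character vector of transform names applied so far.
#' @return A `connectivity_matrix` object.
#' @export
connectivity_matrix <- function(values, voxel_index,
                                transform_log = character()) {
  values <- as.matrix(values)
  voxel_index <- matrix(as.integer(voxel_index), ncol = 3L)
  if (nrow(values) != nrow(voxel_index))
    stop("row count (", nrow(values), ") does not match voxel_index length (",
         nrow(voxel_index), ")")
  if (anyDuplicated(voxel_index))
    stop("voxel_index contains duplicate coordinates")
  if (any(voxel_index < 0L))
    stop("voxel coordinates must be 0-based non-negative indices")
  structure(list(values = values, voxel_index = voxel_index,
                 transform_log = as.character(transform_log)),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d ROI voxels x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (length(x$transform_log))
                paste0(" [", paste(x$transform_log, collapse = " -> "), "]")
              else ""))
  invisible(x)
}

.append_log <- function(cm, name) {
  cm$transform_log <- c(cm$transform_log, name)
  cm
}

#' Read a sparse coordinate-list connectivity file and densify it
#'
#' Probabilistic-tractography tools emit the ROI-by-target streamline-count
#' matrix as sparse coordinate-list text: one `row col value` triple per
#' line with 1-based indices. Unlisted cells are zero.
#'
#' @param path path to the whitespace-separated triple file.
#' @param n_rows,n_cols declared dense dimensions.
#' @param voxel_index optional n_rows x 3 matrix of 0-based ROI voxel
#'   coordinates; defaults to a placeholder index `(0..n_rows-1, 0, 0)`.
#' @return A [connectivity_matrix()] with `"densified"` in its log.
#' @export
read_sparse_connectivity <- function(path, n_rows, n_cols,
                                     voxel_index = NULL) {
  if (!file.exists(path)) stop("sparse connectivity file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- matrix(0, nrow = n_rows, ncol = n_cols)
  if (length(lines) > 0L) {
    fields <- strsplit(trimws(lines), "[[:space:]]+")
    nf <- lengths(fields)
    if (any(nf != 3L))
      stop("malformed line in sparse file (expected 'row col value'): line ",
           which(nf != 3L)[1])
    trip <- matrix(as.numeric(unlist(fields)), ncol = 3L, byrow = TRUE)
    if (anyNA(trip)) stop("non-numeric entry in sparse file: ", path)
    r <- trip[, 1]; cc <- trip[, 2]
    if (any(r < 1 | r > n_rows | cc < 1 | cc > n_cols))
      stop("sparse index out of declared bounds (", n_rows, "x", n_cols, ")")
    m[cbind(as.integer(r), as.integer(cc))] <- trip[, 3]
  }
  if (is.null(voxel_index))
    voxel_index <- cbind(seq_len(n_rows) - 1L, 0L, 0L)
  connectivity_matrix(m, voxel_index, transform_log = "densified")
}

#' Write a matrix as sparse coordinate-list text
#' @param values numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sparse_connectivity <- function(values, path) {
  values <- as.matrix(values)
  nz <- which(values != 0, arr.ind = TRUE)
  df <- data.frame(row = nz[, 1], col = nz[, 2], value = values[nz])
  df <- df[order(df$row, df$col), , drop = FALSE]
  writeLines(sprintf("%d %d %.17g", df$row, df$col, df$value), path)
  invisible(path)
}

# Interim dense matrices are stored as a raw little-endian float64 stream
# (column-major) next to a JSON sidecar carrying dimensions, voxel index and
# transform log; endianness is fixed so files move across hosts.

#' Write a connectivity matrix to the dense binary container
#' @param cm a [connectivity_matrix()].
#' @param path output path for the binary payload; a `<path>.json` sidecar
#'   header is written alongside.
#' @return `path`, invisibly.
#' @export
write_dense_connectivity <- function(cm, path) {
  header <- list(format = "rcbp-dense-1", dtype = "float64",
                 endian = "little", order = "column-major",
                 shape = dim(cm$values),
                 voxel_index = unname(apply(cm$voxel_index, 1, as.integer,
                                            simplify = FALSE)),
                 transform_log = cm$transform_log)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(cm$values), con, size = 8L, endian = "little")
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a connectivity matrix from the dense binary container
#' @param path path written by [write_dense_connectivity()].
#' @return A [connectivity_matrix()].
#' @export
read_dense_connectivity <- function(path) {
  hpath <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(hpath))
    stop("dense container or its .json header missing: ", path)
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (!identical(header$format, "rcbp-dense-1"))
    stop("unrecognized dense container format: ", header$format)
  shape <- as.integer(header$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(shape), size = 8L,
                  endian = "little")
  vi <- header$voxel_index
  if (is.list(vi)) vi <- do.call(rbind, vi)
  connectivity_matrix(matrix(vals, nrow = shape[1], ncol = shape[2]),
                      voxel_index = vi,
                      transform_log = as.character(header$transform_log))
}
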