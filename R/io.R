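.toolVersion <- function() {
  as.character(utils::packageVersion("nufftTomo"))
}

#' Write a volume to disk
#'
#' \code{"tiff"}: one image per slice, 32-bit samples. TIFF samples are
#' stored normalized to [0, 1] (fixed-point, ~2^-32 precision); the affine
#' restore parameters, tool version and resolved metadata go to a JSON
#' sidecar \code{<path>.json}, so \code{\link{readVolumeTiff}} round-trips
#' values to better than 32-bit float rounding of the data range.
#' \code{"h5"}: a float64 HDF5 dataset \code{/volume} (via the system
#' Python's h5py).
#'
#' @param path output file path.
#' @param volume a \linkS4class{Volume}.
#' @param format \code{"tiff"} or \code{"h5"}.
#' @param metadata optional named list stored alongside the data.
#' @return invisibly, \code{path}.
#' @export
writeVolume <- function(path, volume, format = c("tiff", "h5"),
                        metadata = list()) {
  if (!format[1L] %in% c("tiff", "h5"))
    stop(sprintf("invalid format '%s' (supported: tiff, h5)", format[1L]))
  format <- format[1L]
  v <- volume@data
  meta <- c(metadata, list(version = .toolVersion(),
                           voxelSize = volume@voxelSize,
                           dim = dim(v)))
  if (format == "tiff") {
    lo <- min(v); hi <- max(v)
    scale <- if (hi > lo) hi - lo else 1
    imgs <- lapply(seq_len(dim(v)[1L]),
                   function(s) (matrix(v[s, , ], dim(v)[2L], dim(v)[3L]) - lo) / scale)
    tiff::writeTIFF(imgs, path, bits.per.sample = 32L, compression = "none")
    meta$offset <- lo
    meta$scale <- scale
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    .h5WriteDatasets(path, list(volume = v), meta)
  }
  invisible(path)
}

#' Read a TIFF volume written by \code{\link{writeVolume}}
#'
#' @param path TIFF path (its \code{.json} sidecar, when present, restores
#'   the original intensity scale).
#' @return a \linkS4class{Volume}.
#' @export
readVolumeTiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  off <- 0; sc <- 1; vox <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    off <- meta$offset %||% 0; sc <- meta$scale %||% 1
    vox <- meta$voxelSize %||% 1
  }
  n1 <- nrow(imgs[[1L]]); n2 <- ncol(imgs[[1L]])
  out <- array(0, c(length(imgs), n1, n2))
  for (s in seq_along(imgs)) out[s, , ] <- imgs[[s]] * sc + off
  tomoVolume(out, vox)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- HDF5 bridge (data-exchange dialect) via the system Python's h5py ----

.pythonBin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no python interpreter found for HDF5 I/O")
  p
}

.runPython <- function(code) {
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  on.exit(unlink(script))
  out <- suppressWarnings(system2(.pythonBin(), script,
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop("HDF5 bridge failed: ", paste(out, collapse = "\n"))
  out
}

# write named float64 datasets (R arrays, index order preserved) plus
# root attributes to an HDF5 file
.h5WriteDatasets <- function(path, datasets, attrs = list()) {
  tmp <- tempfile()
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  desc <- list()
  for (nm in names(datasets)) {
    d <- datasets[[nm]]
    bin <- file.path(tmp, paste0(gsub("/", "_", nm), ".bin"))
    writeBin(as.numeric(d), bin, size = 8, endian = "little")
    desc[[nm]] <- list(file = bin, dim = if (is.null(dim(d))) length(d) else dim(d))
  }
  meta <- file.path(tmp, "meta.json")
  jsonlite::write_json(list(path = path, datasets = desc, attrs = attrs),
                       meta, auto_unbox = TRUE, digits = NA)
  .runPython(c(
    "import json, sys",
    "import numpy as np",
    "import h5py",
    sprintf("meta = json.load(open(%s))", deparse(meta)),
    "with h5py.File(meta['path'], 'w') as f:",
    "    for name, d in meta['datasets'].items():",
    "        dim = d['dim'] if isinstance(d['dim'], list) else [d['dim']]",
    "        a = np.fromfile(d['file'], dtype='<f8')",
    "        # R arrays are column-major; store with R's index order",
    "        a = a.reshape(list(reversed(dim))).transpose()",
    "        f.create_dataset(name, data=a)",
    "    for k, v in (meta.get('attrs') or {}).items():",
    "        f.attrs[k] = json.dumps(v)"))
  invisible(path)
}

# read named datasets back as R arrays; returns list(datasets=, names=)
.h5ReadDatasets <- function(path, wanted) {
  tmp <- tempfile()
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  meta <- file.path(tmp, "meta.json")
  .runPython(c(
    "import json",
    "import numpy as np",
    "import h5py",
    sprintf("path = %s", deparse(path)),
    sprintf("wanted = %s",
            paste0("[", paste(sprintf("'%s'", wanted), collapse = ","), "]")),
    sprintf("tmp = %s", deparse(tmp)),
    "out = {'available': [], 'found': {}}",
    "with h5py.File(path, 'r') as f:",
    "    f.visit(lambda n: out['available'].append(n))",
    "    for i, name in enumerate(wanted):",
    "        if name in f and isinstance(f[name], h5py.Dataset):",
    "            a = np.asarray(f[name], dtype='<f8')",
    "            fn = tmp + '/d%d.bin' % i",
    "            a.transpose().tofile(fn)  # column-major for R",
    "            out['found'][name] = {'file': fn, 'dim': list(a.shape)}",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(meta))))
  info <- jsonlite::read_json(meta, simplifyVector = TRUE)
  datasets <- list()
  for (nm in names(info$found)) {
    d <- info$found[[nm]]
    x <- readBin(d$file, "numeric", n = prod(d$dim), size = 8,
                 endian = "little")
    datasets[[nm]] <- if (length(d$dim) > 1L) array(x, unlist(d$dim)) else x
  }
  list(datasets = datasets, available = info$available)
}

#' Write projection data in the data-exchange HDF5 dialect
#'
#' Datasets \code{exchange/data} (raw intensity or attenuation,
#' [angle, slice, column]), optional \code{exchange/data_white}
#' (flat field) and \code{exchange/theta} (degrees, the convention of
#' Tomobank-style files). The tool version and resolved parameters are
#' stored as root attributes.
#'
#' @param path output HDF5 path.
#' @param data 3-D array [angle, slice, column].
#' @param anglesRad projection angles in radians.
#' @param flat optional flat-field array (or scalar, expanded).
#' @param metadata optional named list stored as attributes.
#' @return invisibly, \code{path}.
#' @export
writeProjectionH5 <- function(path, data, anglesRad, flat = NULL,
                              metadata = list()) {
  ds <- list("exchange/data" = data,
             "exchange/theta" = anglesRad * 180 / pi)
  if (!is.null(flat)) {
    if (length(flat) == 1L) flat <- array(flat, dim(data))
    ds[["exchange/data_white"]] <- flat
  }
  .h5WriteDatasets(path, ds,
                   c(metadata, list(version = .toolVersion())))
  invisible(path)
}

#' Read projection data from a data-exchange HDF5 file
#'
#' Reads \code{exchange/data}, \code{exchange/data_white} (when present)
#' and \code{exchange/theta}. Angles stored in degrees are auto-converted
#' to radians (values exceeding \eqn{2\pi} imply degrees; override with
#' \code{layoutHint$thetaUnits}). When a flat field is present the raw
#' intensities are returned for Beer-Lambert conversion; otherwise the
#' data are treated as an attenuation sinogram.
#'
#' @param path HDF5 file path.
#' @param layoutHint optional list: alternative dataset paths
#'   (\code{data}, \code{flat}, \code{theta}) and/or \code{thetaUnits}
#'   ("degrees"/"radians").
#' @return list with \code{intensity} (or NULL), \code{flat} (or NULL),
#'   \code{sinogram} (attenuation array or NULL), \code{angles} (radians),
#'   \code{metadata}.
#' @export
readProjectionH5 <- function(path, layoutHint = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  dataPath <- layoutHint$data %||% "exchange/data"
  flatPath <- layoutHint$flat %||% "exchange/data_white"
  thetaPath <- layoutHint$theta %||% "exchange/theta"
  got <- .h5ReadDatasets(path, c(dataPath, flatPath, thetaPath))
  ds <- got$datasets
  if (is.null(ds[[dataPath]]))
    stop(sprintf("dataset '%s' missing; available: %s", dataPath,
                 paste(got$available, collapse = ", ")))
  if (is.null(ds[[thetaPath]]))
    stop(sprintf("dataset '%s' missing; available: %s", thetaPath,
                 paste(got$available, collapse = ", ")))
  theta <- as.numeric(ds[[thetaPath]])
  units <- layoutHint$thetaUnits %||%
    (if (max(abs(theta)) > 2 * pi) "degrees" else "radians")
  if (units == "degrees") theta <- theta * pi / 180
  flat <- ds[[flatPath]]
  if (is.null(flat))
    list(intensity = NULL, flat = NULL, sinogram = ds[[dataPath]],
         angles = theta, metadata = got$available)
  else
    list(intensity = ds[[dataPath]], flat = flat, sinogram = NULL,
         angles = theta, metadata = got$available)
}

#' Reorder a projection stack into per-slice sinogram views
#'
#' Index algebra: element \code{[a, s, c]} of the source equals element
#' \code{[a, c]} of view \code{s}. (R has copy-on-modify value semantics,
#' so views are extracted copies; use \code{\link{sinogramSlice<-}} to
#' write a slice back.)
#'
#' @param stack 3-D array [angle, slice, column].
#' @return list of [angle, column] matrices, one per slice.
#' @export
reorderToSinogram <- function(stack) {
  stopifnot(length(dim(stack)) == 3L)
  lapply(seq_len(dim(stack)[2L]),
         function(s) matrix(stack[, s, ], dim(stack)[1L], dim(stack)[3L]))
}

#' Extract or replace one sinogram slice
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param slice 1-based slice index.
#' @return [angle, column] matrix.
#' @export
sinogramSlice <- function(sino, slice) {
  d <- sino@data
  matrix(d[, slice, ], dim(d)[1L], dim(d)[3L])
}

#' @rdname sinogramSlice
#' @param value [angle, column] matrix.
#' @export
`sinogramSlice<-` <- function(sino, slice, value) {
  sino@data[, slice, ] <- value
  sino
}

#' Restrict a sinogram to a subset of slices
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param slices 1-based slice indices to keep.
#' @return a \linkS4class{Sinogram} over the selected slices.
#' @export
subsetSlices <- function(sino, slices) {
  g <- sino@geometry
  geomOut <- scanGeometry(g@angles, g@numColumns, length(slices),
                          g@centerOffset, g@pixelSize)
  sinogram(sino@data[, slices, , drop = FALSE], geomOut)
}
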