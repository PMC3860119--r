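# sidecar path: data file plus ".json"
sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

read_sidecar <- function(path, required) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop(sprintf("missing JSON sidecar '%s'", sp))
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in required)
    if (is.null(meta[[f]]))
      stop(sprintf("sidecar '%s' is missing required field '%s'", sp, f))
  meta
}

#' Read and write volumes
#'
#' Two on-disk representations, chosen by file extension:
#' * `.raw` / `.bin` — little-endian float32 in x-fastest order with a JSON
#'   sidecar (`dims`, `spacing`, `extent`). Lossless at float32 precision:
#'   a write/read/write cycle is bit-identical.
#' * `.tif` / `.tiff` — 32-bit multi-page TIFF, one page per z-slice.
#'   The TIFF codec stores normalized `[0, 1]` samples, so data are
#'   affinely rescaled with the offset and scale recorded in the JSON
#'   sidecar and undone on read (values recovered to about 1e-9 of the
#'   data range). The pages are readable as a plain image stack by any
#'   TIFF tool; use the raw format where exactness matters.
#'
#' @param vol a [volume3d()].
#' @param path output path; extension selects the format.
#' @return `write_volume` returns `path` invisibly; `read_volume` a
#'   [volume3d()].
#' @export
write_volume <- function(vol, path) {
  ext <- tolower(tools::file_ext(path))
  d <- dim(vol$values)
  meta <- list(dims = d, spacing = vol$spacing, extent = vol$extent,
               dtype = "float32", order = "x-fastest")
  if (ext %in% c("raw", "bin")) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(vol$values), con, size = 4, endian = "little")
  } else if (ext %in% c("tif", "tiff")) {
    lo <- min(vol$values); hi <- max(vol$values)
    scale <- if (hi > lo) hi - lo else 1
    meta$tiff_offset <- lo
    meta$tiff_scale <- scale
    pages <- lapply(seq_len(d[3]),
                    function(k) (vol$values[, , k] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  } else stop(sprintf("unsupported volume format '.%s'", ext))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file '%s'", path))
  ext <- tolower(tools::file_ext(path))
  meta <- read_sidecar(path, c("dims", "spacing", "extent"))
  d <- as.integer(meta$dims)
  if (ext %in% c("raw", "bin")) {
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = prod(d), size = 4, endian = "little")
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != d[3])
      stop(sprintf("TIFF page count %d does not match sidecar nz = %d",
                   length(pages), d[3]))
    vals <- unlist(pages)
    dim(vals) <- c(d[1], d[2], d[3])
    vals <- vals * meta$tiff_scale + meta$tiff_offset
  } else stop(sprintf("unsupported volume format '.%s'", ext))
  volume3d(array(vals, d), extent = meta$extent)
}

#' Read and write projection stacks
#'
#' Same formats as [write_volume()]; the JSON sidecar additionally records
#' the ordered angle list, which round-trips exactly.
#'
#' @param stack a [projection_stack()].
#' @param path output path; extension selects the format.
#' @return `write_projections` returns `path` invisibly;
#'   `read_projections` a [projection_stack()].
#' @export
write_projections <- function(stack, path) {
  ext <- tolower(tools::file_ext(path))
  d <- dim(stack$data)
  meta <- list(dims = d, spacing = stack$spacing, angles = stack$angles,
               dtype = "float32", order = "u-fastest")
  if (ext %in% c("raw", "bin")) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(stack$data), con, size = 4, endian = "little")
  } else if (ext %in% c("tif", "tiff")) {
    lo <- min(stack$data); hi <- max(stack$data)
    scale <- if (hi > lo) hi - lo else 1
    meta$tiff_offset <- lo
    meta$tiff_scale <- scale
    pages <- lapply(seq_len(d[3]),
                    function(k) (stack$data[, , k] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  } else stop(sprintf("unsupported projection format '.%s'", ext))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file '%s'", path))
  ext <- tolower(tools::file_ext(path))
  meta <- read_sidecar(path, c("dims", "spacing", "angles"))
  d <- as.integer(meta$dims)
  if (d[3] < 1L || length(meta$angles) == 0L)
    stop("empty projection stack")
  if (length(meta$angles) != d[3])
    stop(sprintf("angle count %d does not match image count %d",
                 length(meta$angles), d[3]))
  if (ext %in% c("raw", "bin")) {
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, numeric(), n = prod(d), size = 4, endian = "little")
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != d[3])
      stop(sprintf("TIFF page count %d does not match angle count %d",
                   length(pages), d[3]))
    vals <- unlist(pages) * meta$tiff_scale + meta$tiff_offset
  } else stop(sprintf("unsupported projection format '.%s'", ext))
  projection_stack(array(vals, d), meta$angles, meta$spacing)
}

#' Read a run configuration file
#'
#' YAML file mirroring the command-line flags: fields `n`, `extent`,
#' `angles`, `wavelet`, `sigma`, `scale`, `variance`, `seed`, `quantile`,
#' `outdir`. All numeric fields are validated.
#'
#' @param path YAML config path.
#' @return named list with validated defaults filled in.
#' @export
read_runconfig <- function(path) {
  # literal-key handlers: plain YAML would resolve the key `n` (grid size)
  # as the 1.1 boolean `no`
  cfg <- yaml::read_yaml(path,
                         handlers = list("bool#yes" = function(x) x,
                                         "bool#no" = function(x) x))
  defaults <- list(n = 64L, extent = 1, angles = 90L, wavelet = "dgauss-x",
                   sigma = 1, scale = 1, variance = 0, seed = 0L,
                   quantile = 0.9, outdir = ".")
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  validate_runconfig(cfg)
  cfg
}

validate_runconfig <- function(cfg) {
  if (cfg$n < 8) stop("grid size `n` must be at least 8")
  if (cfg$scale <= 0) stop("scale `a` must be positive")
  if (cfg$sigma <= 0) stop("`sigma` must be positive")
  if (cfg$variance < 0) stop("`variance` must be non-negative")
  if (cfg$quantile <= 0 || cfg$quantile >= 1)
    stop("`quantile` must lie strictly between 0 and 1")
  if (cfg$angles < 1) stop("`angles` must be at least 1")
  invisible(cfg)
}
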