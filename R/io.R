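#' Write / read a volume (NIfTI)
#'
#' Volumes are stored as double-precision NIfTI with the voxel spacing in
#' `pixdim` and the grid origin in the sform translation, so a round trip
#' preserves voxels bitwise and geometry exactly. [read_volume] also accepts
#' uncompressed MetaImage (`.mha`) files with embedded (`LOCAL`) data.
#'
#' @param vol a [volume3d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [volume3d].
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$data, datatype = "double")
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return(read_mha(path))
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  origin <- aff[1:3, 4]
  ## our frame is stored directly in the sform; undo any axis sign flips
  sgn <- sign(diag(aff[1:3, 1:3]))
  dat <- array(as.numeric(img), dim(img))
  if (any(sgn < 0)) {
    idx <- lapply(1:3, function(a) if (sgn[a] < 0) rev(seq_len(dim(dat)[a]))
                  else seq_len(dim(dat)[a]))
    dat <- dat[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    for (a in 1:3) if (sgn[a] < 0)
      origin[a] <- origin[a] - (dim(dat)[a] - 1) * spacing[a]
  }
  volume3d(dat, spacing, origin)
}

## minimal uncompressed MetaImage reader (MET_FLOAT / MET_DOUBLE, LOCAL data)
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0) stop("malformed MHA header: no ElementDataFile")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only MHA files with embedded (LOCAL) data are supported")
  if (isTRUE(toupper(hdr[["CompressedData"]]) == "TRUE"))
    stop("compressed MHA is not supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- if (!is.null(hdr[["ElementSpacing"]]))
    as.numeric(strsplit(hdr[["ElementSpacing"]], "\\s+")[[1]]) else rep(1, 3)
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], "\\s+")[[1]]) else NULL
  et <- hdr[["ElementType"]]
  size <- switch(et, MET_FLOAT = 4L, MET_DOUBLE = 8L,
                 stop(sprintf("unsupported MHA ElementType '%s'", et)))
  n <- prod(dims)
  raw <- readBin(con, "numeric", n = n, size = size, endian = "little")
  volume3d(array(raw, dims), spacing, origin)
}

#' Write / read a projection set (raw float32 stack + JSON sidecar)
#'
#' The stack is stored as little-endian float32 in `<path>.raw`; the sidecar
#' `<path>.json` carries the geometry and the per-projection angle/time/bin
#' metadata. Reading restores the float32-rounded stack bitwise.
#'
#' @param p a [projection_set].
#' @param path base path (without extension).
#' @return `write_projections` returns `path` invisibly; `read_projections`
#'   a [projection_set].
#' @export
write_projections <- function(p, path) {
  stopifnot(inherits(p, "projection_set"))
  con <- file(paste0(path, ".raw"), "wb")
  writeBin(as.numeric(p$stack), con, size = 4, endian = "little")
  close(con)
  side <- list(dims = dim(p$stack), dtype = "float32", order = "u_v_k",
               geometry = unclass(p$geometry),
               angle_deg = p$meta$angle_deg, t_s = p$meta$t_s,
               bin = p$meta$bin)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  for (f in c("dims", "geometry", "angle_deg"))
    if (is.null(side[[f]]))
      stop(sprintf("projection sidecar missing required field '%s'", f))
  g <- side$geometry
  for (f in c("sad", "sdd", "det_rows", "det_cols", "det_pitch", "arc_deg"))
    if (is.null(g[[f]]))
      stop(sprintf("projection sidecar missing geometry field '%s'", f))
  geom <- scan_geometry(g$sad, g$sdd, g$det_rows, g$det_cols, g$det_pitch,
                        g$arc_deg)
  con <- file(paste0(path, ".raw"), "rb")
  raw <- readBin(con, "numeric", n = prod(side$dims), size = 4,
                 endian = "little")
  close(con)
  projection_set(array(raw, side$dims), side$angle_deg, geom,
                 times_s = if (is.null(side$t_s)) NA_real_ else
                   as.numeric(side$t_s),
                 bins = if (is.null(side$bin)) NA_integer_ else
                   as.integer(side$bin))
}

#' Write / read a breathing trace (CSV)
#'
#' Columns `time_s`, `amplitude_mm`, `phase_bin`.
#'
#' @param trace a [breathing_trace].
#' @param path CSV path.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   `breathing_trace` (without generator metadata).
#' @export
write_trace <- function(trace, path) {
  write.csv(data.frame(time_s = trace$times, amplitude_mm = trace$amplitude,
                       phase_bin = trace$true_phase),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  for (f in c("time_s", "amplitude_mm", "phase_bin"))
    if (is.null(df[[f]])) stop(sprintf("trace CSV missing column '%s'", f))
  structure(list(times = df$time_s, amplitude = df$amplitude_mm,
                 true_phase = as.integer(df$phase_bin),
                 breath_starts = NULL, breath_periods = NULL, params = NULL),
            class = "breathing_trace")
}

#' Write / read an acquisition schedule (CSV)
#'
#' Columns `k`, `t_s`, `angle_deg`, `bin`, `acquired`.
#'
#' @param schedule an `acquisition_schedule`.
#' @param path CSV path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule` an
#'   `acquisition_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(as.data.frame(schedule)[c("k", "t_s", "angle_deg", "bin",
                                      "acquired")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- read.csv(path)
  for (f in c("k", "t_s", "angle_deg", "bin", "acquired"))
    if (is.null(df[[f]])) stop(sprintf("schedule CSV missing column '%s'", f))
  new_schedule(df$k, df$t_s, df$angle_deg, df$bin, df$acquired,
               provenance = "file")
}
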