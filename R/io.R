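# Readers/writers for DSCE series and TOI definitions.
#
# File conventions:
#   * 4D NIfTI-1 stores axes (row, col, slice, time); internally everything is
#     (time, slice, row, col).
#   * Acquisition metadata travels in a BIDS-style JSON sidecar next to the
#     NIfTI (`EchoTime` / `RepetitionTime` in seconds); explicit arguments
#     override the sidecar.
#   * TOI sets are either a JSON file of named closed polygons (0-based voxel
#     coordinates) or an integer label raster (NIfTI) plus a JSON sidecar
#     mapping each label value to a tissue class.

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE) else list()
}

#' Load a DSCE-MRI time series
#'
#' Reads a 4D acquisition from disk and normalises it to the internal
#' `(time, slice, row, col)` axis order. Two formats are supported: a 4D
#' NIfTI-1 file (time last) and a DICOM series directory. Echo time and
#' repetition time must come from the metadata (JSON sidecar for NIfTI,
#' standard tags for DICOM) or be given explicitly; loading fails otherwise.
#'
#' DICOM directories are sorted by `(AcquisitionTime, InstanceNumber)` with a
#' fallback to `InstanceNumber` alone; a non-uniform slice count across time
#' points is a hard error. DICOM decoding is delegated to a bundled Python
#' helper (pydicom).
#'
#' @param path File (NIfTI) or directory (DICOM) to read.
#' @param format `"nifti4d"` or `"dicom_dir"`; the default guesses from
#'   `path`.
#' @param te_ms,tr_ms Optional metadata overrides in milliseconds.
#' @return A [dsce_series].
#' @export
load_dsce_series <- function(path, format = c("auto", "nifti4d", "dicom_dir"),
                             te_ms = NULL, tr_ms = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_dir" else "nifti4d"
  if (format == "dicom_dir") {
    conv <- dicom_dir_to_nifti(path)
    on.exit(unlink(c(conv$nifti, sidecar_path(conv$nifti))), add = TRUE)
    path <- conv$nifti
  }
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 3L) a <- array(a, dim = c(dim(a), 1L))
  if (length(dim(a)) != 4L)
    stop("expected a 4D NIfTI image (row, col, slice, time)")
  meta <- read_sidecar(path)
  te_ms <- te_ms %||% (if (!is.null(meta$EchoTime)) meta$EchoTime * 1000 else NULL)
  if (is.null(te_ms))
    stop("echo time required: no EchoTime in metadata and no `te_ms` override")
  tr_sidecar <- if (!is.null(meta$RepetitionTime)) meta$RepetitionTime * 1000 else NULL
  tr_pixdim <- {
    pd <- attr(img, "pixdim")
    if (length(pd) >= 4L && is.finite(pd[4]) && pd[4] > 0) pd[4] * 1000 else NULL
  }
  tr_ms <- tr_ms %||% tr_sidecar %||% tr_pixdim
  if (is.null(tr_ms))
    stop("repetition time required: no RepetitionTime in metadata and no `tr_ms` override")
  pd <- attr(img, "pixdim")
  vox <- if (length(pd) >= 3L) pd[1:3] else c(1, 1, 1)
  dsce_series(aperm(a, c(4L, 3L, 1L, 2L)),
              te_ms = te_ms, tr_ms = tr_ms,
              voxel_size_mm = vox,
              field_strength_T = meta$FieldStrength %||% NA_real_,
              provenance = meta$Provenance %||% path)
}

#' Write a DSCE-MRI time series as 4D NIfTI plus JSON sidecar
#'
#' Inverse of [load_dsce_series()] for the NIfTI format: round-tripping
#' preserves the signal voxelwise and the acquisition metadata.
#'
#' @param series A [dsce_series].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_dsce_series <- function(series, path) {
  stopifnot(inherits(series, "dsce_series"))
  a <- aperm(series$signal, c(3L, 4L, 2L, 1L))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(series$voxel_size_mm, series$tr_ms / 1000)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(EchoTime = series$te_ms / 1000,
         RepetitionTime = series$tr_ms / 1000,
         FieldStrength = series$field_strength_T,
         Provenance = series$provenance),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Convert a DICOM directory to a temporary 4D NIfTI + sidecar via the bundled
# pydicom helper; returns list(nifti = path).
dicom_dir_to_nifti <- function(dir) {
  py <- Sys.which("python")
  if (py == "") stop("DICOM input needs a `python` interpreter with pydicom on the PATH")
  helper <- system.file("python", "dicom_to_nifti.py", package = "dtpa")
  if (helper == "") stop("bundled DICOM helper not found")
  out <- tempfile(fileext = ".nii")
  res <- suppressWarnings(
    system2(py, c(helper, shQuote(dir), shQuote(out)), stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L)
    stop("DICOM conversion failed: ", paste(res, collapse = "\n"))
  list(nifti = out)
}

#' Load a TOI set
#'
#' Reads tissue-of-interest definitions from either a JSON polygon file or an
#' integer label raster (NIfTI) with a JSON sidecar mapping labels to tissue
#' classes.
#'
#' The polygon format is a JSON object with fields `grid = [nrow, ncol]`
#' (slice size), optional `n_slices`, and `tois`, a list of objects with
#' `label`, `tissue_class`, `slice_index` (1-based), optional
#' `definition_interval`, and `vertices`, an n x 2 array of `(row, col)`
#' 0-based voxel coordinates. Polygons are rasterised on voxel centers with
#' the even-odd rule (boundary inclusive, see [point_in_polygon()]).
#'
#' The raster sidecar maps stringified label values to either a tissue-class
#' string or an object `{label, tissue_class}`; a raster value missing from
#' the sidecar is an error (0 is background).
#'
#' @param path `.json` polygon file or `.nii`/`.nii.gz` label raster.
#' @return A list of [toi] objects.
#' @export
load_toi_set <- function(path) {
  if (grepl("\\.json$", path)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(spec$grid) || is.null(spec$tois))
      stop("polygon TOI file needs `grid` and `tois` fields")
    tois <- spec$tois
    if (is.data.frame(tois)) tois <- split(tois, seq_len(nrow(tois)))
    lapply(tois, function(p) {
      p <- as.list(p)
      verts <- p$vertices
      if (is.list(verts) && !is.matrix(verts)) verts <- verts[[1]]
      verts <- matrix(as.numeric(as.matrix(verts)), ncol = 2L)
      toi_from_polygon(p$label, p$tissue_class, verts,
                       nrow = spec$grid[1], ncol = spec$grid[2],
                       slice_index = p$slice_index %||% 1L,
                       definition_interval = p$definition_interval %||% NULL)
    }) |> unname()
  } else {
    img <- as.array(RNifti::readNifti(path))
    if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
    lab <- aperm(img, c(3L, 1L, 2L))  # -> (slice, row, col)
    side <- read_sidecar(path)
    if (length(side) == 0L)
      stop("label raster needs a JSON sidecar mapping labels to tissue classes")
    vals <- sort(setdiff(unique(as.vector(lab)), 0))
    lapply(vals, function(v) {
      entry <- side[[as.character(v)]]
      if (is.null(entry))
        stop(sprintf("label %s present in raster but absent from sidecar", v))
      if (is.character(entry)) entry <- list(tissue_class = entry)
      toi(entry$label %||% sprintf("label_%s", v), entry$tissue_class,
          lab == v,
          definition_interval = entry$definition_interval %||% NULL)
    })
  }
}

#' Write a TOI set as a label raster plus sidecar
#'
#' @param tois List of [toi] objects with 3D masks on a common grid.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_toi_labels <- function(tois, path) {
  stopifnot(length(tois) >= 1L)
  d <- dim(tois[[1]]$mask)
  lab <- array(0L, dim = d)
  side <- list()
  for (i in seq_along(tois)) {
    if (any(lab[tois[[i]]$mask] != 0L))
      warning("overlapping TOI masks: later labels overwrite earlier ones")
    lab[tois[[i]]$mask] <- i
    side[[as.character(i)]] <- list(label = tois[[i]]$label,
                                    tissue_class = tois[[i]]$tissue_class)
  }
  RNifti::writeNifti(RNifti::asNifti(aperm(lab, c(2L, 3L, 1L))), path)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}
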