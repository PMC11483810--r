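#' Read a 3D volume from NIfTI or multi-page TIFF
#'
#' NIfTI (.nii/.nii.gz) is the canonical format: spacing comes from the
#' header pixdim (mm, converted to um) and the origin from the stored xform
#' translation. Multi-page TIFF stacks are supported read-only and require a
#' JSON sidecar `<path>.json` with fields `spacing_um` (and optionally
#' `origin_um`), since TIFF carries no calibrated 3D spacing.
#'
#' @param path file path.
#' @return A [volume3d].
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    vals <- array(as.numeric(img), dim(img))
    pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
    units <- tryCatch(RNifti::pixunits(img), error = function(e) "mm")
    scale <- if ("um" %in% units) 1 else 1000  # default/mm -> um
    xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
    origin <- if (!is.null(xf)) xf[1:3, 4] * scale else c(0, 0, 0)
    volume3d(vals, grid3d(dim(img), pd[1:3] * scale, as.numeric(origin)))
  } else if (grepl("\\.tiff?$", path)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("read_volume: the 'tiff' package is required for TIFF input")
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("read_volume: TIFF input requires a JSON sidecar '", sidecar,
           "' with field 'spacing_um'")
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$spacing_um))
      stop("read_volume: sidecar is missing the required field 'spacing_um'")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    nz <- length(pages)
    d <- dim(pages[[1]])
    vals <- array(0, c(d[2], d[1], nz))  # TIFF pages are (row=y, col=x)
    for (k in seq_len(nz)) vals[, , k] <- t(pages[[k]])
    volume3d(vals, grid3d(dim(vals), meta$spacing_um,
                          meta$origin_um %||% c(0, 0, 0)))
  } else stop("read_volume: unknown extension (expect .nii, .nii.gz, .tif, .tiff)")
}

#' Write a volume to NIfTI
#'
#' Values are stored as float64 so a write/read round trip is bit-identical.
#' Spacing and origin are written in micrometres (header unit "um"): NIfTI-1
#' headers hold pixdim as 32-bit floats, and mesoscopy spacings are exactly
#' representable in um but not in mm.
#'
#' @param v a [volume3d] (a [binary_mask] is accepted and written as 0/1).
#' @param path output path ending in .nii or .nii.gz.
#' @export
write_volume <- function(v, path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("write_volume: only NIfTI output is supported (.nii/.nii.gz)")
  m <- diag(4)
  diag(m)[1:3] <- v$grid$spacing
  m[1:3, 4] <- v$grid$origin
  img <- RNifti::asNifti(structure(v$values, pixdim = v$grid$spacing,
                                   pixunits = c("um", "s")),
                         datatype = "double")
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write landmark tables
#'
#' CSV schema: columns `label`, `x_um`, `y_um`, `z_um`. Labels must be
#' unique; fewer than 3 rows triggers a warning since rigid landmark
#' initialisation needs at least 3 points.
#'
#' @param path CSV file path.
#' @return n x 3 matrix with rownames = labels (um).
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_um", "y_um", "z_um")
  if (!all(need %in% names(df)))
    stop("read_landmarks: CSV must have columns label, x_um, y_um, z_um")
  if (anyDuplicated(df$label)) stop("read_landmarks: duplicate labels")
  if (nrow(df) < 3) warning("read_landmarks: fewer than 3 landmarks")
  m <- as.matrix(df[, c("x_um", "y_um", "z_um")])
  dimnames(m) <- list(df$label, c("x", "y", "z"))
  m
}

#' @rdname read_landmarks
#' @param lm labelled landmark matrix (rownames = labels).
#' @export
write_landmarks <- function(lm, path) {
  df <- data.frame(label = rownames(lm), x_um = lm[, 1], y_um = lm[, 2],
                   z_um = lm[, 3], row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a transform as JSON
#'
#' Serialises the 4x4 homogeneous matrix (row-major, physical um
#' coordinates, fixed -> moving pull-back convention).
#' @param t an `affine3d`.
#' @param path output path.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(list(convention = "fixed_to_moving_um",
                            matrix_row_major = as.numeric(t(t$matrix))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine3d(matrix(j$matrix_row_major, 4, 4, byrow = TRUE))
}
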