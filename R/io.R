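#' Read and write acquisition schemes as JSON
#'
#' Schemes are stored as JSON objects with keys `b0_directions` (list of
#' unit 3-vectors), `echo_times_ms`, `reference_time_ms` and `echo_mask`.
#' Reading validates and renormalises the field directions (tolerance
#' `1e-6`) and rejects non-increasing echo times.
#'
#' @param path File path.
#' @return `read_scheme()` returns an [acquisition_scheme()];
#'   `write_scheme()` returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("b0_directions", "echo_times_ms", "reference_time_ms", "echo_mask")
  missing_keys <- setdiff(req, names(obj))
  if (length(missing_keys)) {
    stop("scheme JSON is missing keys: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  }
  b0 <- obj$b0_directions
  if (is.list(b0)) b0 <- do.call(rbind, b0)
  acquisition_scheme(as.matrix(b0), obj$echo_times_ms,
                     obj$reference_time_ms, obj$echo_mask)
}

#' @rdname read_scheme
#' @param scheme An [acquisition_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  obj <- list(
    b0_directions = apply(scheme$b0_directions, 1L, identity, simplify = FALSE),
    echo_times_ms = scheme$echo_times_ms,
    reference_time_ms = scheme$reference_time_ms,
    echo_mask = scheme$echo_mask
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

SH_BASIS_DESCRIPTION <- paste(
  "real orthonormal spherical harmonics, even orders ascending,",
  "degrees -l..l within each order; m<0 -> sin, m>0 -> cos terms,",
  "Condon-Shortley phase in the associated Legendre functions")

#' Write and read spherical-harmonic coefficient volumes
#'
#' ODF fields are stored as 4D NIfTI volumes whose fourth axis holds the SH
#' coefficients in the package's basis ordering (45 volumes for order 8),
#' accompanied by a JSON sidecar recording the basis convention and maximum
#' order.  Reading validates the volume count against the sidecar's order
#' and checks each voxel's unit mass.
#'
#' @param odfs List of [odf] objects (flattened voxel order).
#' @param grid_shape 3D voxel grid dimensions (`prod(grid_shape)` must equal
#'   `length(odfs)`).
#' @param path Output `.nii` / `.nii.gz` path; the sidecar replaces the
#'   extension with `.json`.
#' @return `write_sh_volume()` returns `path` invisibly; `read_sh_volume()`
#'   returns a list with `odfs` (per-voxel list) and `grid_shape`.
#' @export
write_sh_volume <- function(odfs, grid_shape, path) {
  stopifnot(prod(grid_shape) == length(odfs))
  max_order <- odfs[[1L]]$max_order
  nc <- sh_n_coef(max_order)
  arr <- array(0, dim = c(grid_shape, nc))
  mat <- t(vapply(odfs, function(o) o$sh, numeric(nc)))
  arr[] <- as.vector(mat)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  jsonlite::write_json(
    list(basis = SH_BASIS_DESCRIPTION, max_order = max_order,
         n_coefficients = nc),
    sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sh_volume
#' @param mass_tol Tolerance on the per-voxel order-0 (unit mass)
#'   coefficient.
#' @export
read_sh_volume <- function(path, mass_tol = 1e-5) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("missing JSON sidecar declaring the SH basis convention: ", sc,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  max_order <- as.integer(meta$max_order)
  nc <- sh_n_coef(max_order)
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4L || dim(arr)[4L] != nc) {
    stop(sprintf("expected a 4D volume with %d coefficient maps for order %d, got dims %s",
                 nc, max_order, paste(dim(arr), collapse = "x")), call. = FALSE)
  }
  grid_shape <- dim(arr)[1:3]
  mat <- matrix(arr, prod(grid_shape), nc)
  if (any(abs(mat[, 1L] - 1 / (2 * sqrt(pi))) > mass_tol)) {
    stop("some voxels do not have unit total mass", call. = FALSE)
  }
  mat[, 1L] <- 1 / (2 * sqrt(pi))     # absorb storage rounding
  odfs <- lapply(seq_len(nrow(mat)), function(i) odf(mat[i, ], max_order))
  list(odfs = odfs, grid_shape = grid_shape)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Write fitted microscopic shift maps
#'
#' Writes per-echo maps of the estimated microscopic frequency shift in Hz
#' (`omega / (2 pi)`, the displayed convention), the fit residual, and the
#' estimated global offsets as CSV.
#'
#' @param fits List of `micro_shift_fit` objects (flattened voxel order).
#' @param grid_shape 3D voxel grid dimensions.
#' @param path_prefix Output prefix; files `<prefix>_omega_hz.nii.gz`,
#'   `<prefix>_residual.nii.gz` and (when `offsets` is given)
#'   `<prefix>_offsets.csv` are produced.
#' @param offsets Optional `n_positions x n_echoes` offset matrix (rad/s).
#' @param scheme Scheme used to label the offsets CSV.
#' @return Invisible character vector of the files written.
#' @export
write_maps <- function(fits, grid_shape, path_prefix, offsets = NULL,
                       scheme = NULL) {
  K <- length(fits[[1L]]$omega)
  omega <- t(vapply(fits, function(f) f$omega, numeric(K)))
  resid <- t(vapply(fits, function(f) f$residual, numeric(K)))
  files <- character(0)
  arr <- array(omega / (2 * pi), dim = c(grid_shape, K))
  f1 <- paste0(path_prefix, "_omega_hz.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), f1)
  files <- c(files, f1)
  arr <- array(resid, dim = c(grid_shape, K))
  f2 <- paste0(path_prefix, "_residual.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), f2)
  files <- c(files, f2)
  if (!is.null(offsets)) {
    f3 <- paste0(path_prefix, "_offsets.csv")
    echo_ms <- if (!is.null(scheme)) scheme_fit_times_ms(scheme) else seq_len(ncol(offsets))
    tab <- data.frame(
      position = rep(seq_len(nrow(offsets)), times = ncol(offsets)),
      echo_ms = rep(echo_ms, each = nrow(offsets)),
      offset_rad_per_s = as.vector(offsets)
    )
    utils::write.csv(tab, f3, row.names = FALSE)
    files <- c(files, f3)
  }
  invisible(files)
}
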