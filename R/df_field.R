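#' Synthetic dominant-frequency field
#'
#' A `df_field` describes the "true" spatial distribution of local activation
#' rate (dominant frequency, DF) over the atrial surface used by the
#' simulator: a base rate, a linear spatial gradient, and a set of focal
#' high-DF patches modelled as Gaussian bumps. Field values are clipped to
#' the physiological DF band (4-10 Hz by default).
#'
#' @param base_df base dominant frequency in Hz.
#' @param gradient length-3 numeric, Hz per mm along x, y, z. The linear term
#'   is evaluated on absolute cube coordinates in mm.
#' @param patches list of [focal_patch()] objects. Patch centers must lie
#'   inside the bounding cube and patch peaks must exceed `base_df`.
#' @param cube_mm side length of the axis-aligned bounding cube (mm). The
#'   cube spans `[0, cube_mm]` on every axis.
#' @param df_range length-2 numeric, clipping range in Hz.
#' @return an object of class `df_field`.
#' @seealso [sample_df_field()], [simulate_dataset()]
#' @export
#' @examples
#' f <- df_field(base_df = 6, gradient = c(0.02, 0, 0), patches = list())
#' sample_df_field(f, c(50, 0, 0)) - sample_df_field(f, c(0, 0, 0)) # 1 Hz
df_field <- function(base_df = 6,
                     gradient = c(0.01, 0, 0),
                     patches = list(focal_patch()),
                     cube_mm = 100,
                     df_range = c(4, 10)) {
  stopifnot(is.numeric(base_df), length(base_df) == 1L,
            is.numeric(gradient), length(gradient) == 3L,
            is.list(patches),
            cube_mm > 0, length(df_range) == 2L, df_range[1] < df_range[2])
  for (p in patches) {
    if (!inherits(p, "focal_patch")) stop("patches must be focal_patch objects")
    if (any(p$center < 0) || any(p$center > cube_mm))
      stop("patch center lies outside the bounding cube")
    if (p$peak_df <= base_df)
      stop("focal patch peak_df must exceed base_df")
  }
  structure(list(base_df = base_df, gradient = as.numeric(gradient),
                 patches = patches, cube_mm = cube_mm,
                 df_range = as.numeric(df_range)),
            class = "df_field")
}

#' Focal high-DF patch
#'
#' Gaussian bump added on top of the base field. At distance `d` from the
#' center the bump contributes `(peak_df - base_df) * exp(-d^2 / (2 radius^2))`,
#' so `radius_mm` plays the role of the Gaussian scale.
#'
#' @param center length-3 numeric, mm.
#' @param radius_mm Gaussian scale in mm.
#' @param peak_df field value at the patch center (before clipping), Hz.
#' @return an object of class `focal_patch`.
#' @export
focal_patch <- function(center = shell_point(0.8, 1.2),
                        radius_mm = 8, peak_df = 8.5) {
  stopifnot(length(center) == 3L, radius_mm > 0, peak_df > 0)
  structure(list(center = as.numeric(center), radius_mm = radius_mm,
                 peak_df = peak_df),
            class = "focal_patch")
}

#' Ellipsoidal shell geometry
#'
#' The simulator constrains the catheter to an axis-aligned ellipsoidal shell
#' inscribed in the bounding cube, a stand-in for the closed atrial surface.
#'
#' @param center length-3 numeric, mm.
#' @param semi_axes length-3 numeric, ellipsoid semi-axes in mm.
#' @return an object of class `shell_spec`.
#' @export
shell_spec <- function(center = c(50, 50, 50), semi_axes = c(30, 27, 24)) {
  stopifnot(length(center) == 3L, length(semi_axes) == 3L, all(semi_axes > 0))
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes)),
            class = "shell_spec")
}

#' Point on the ellipsoidal shell
#'
#' Convenience for placing focal patches on the surface the trajectory
#' actually visits.
#'
#' @param theta azimuthal angle (radians).
#' @param phi polar angle (radians, 0 = +z pole).
#' @param shell a [shell_spec()].
#' @return length-3 numeric position in mm.
#' @export
shell_point <- function(theta, phi, shell = shell_spec()) {
  shell$center + shell$semi_axes *
    c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Evaluate the true DF field
#'
#' Returns `base + gradient . position + sum of Gaussian focal bumps`,
#' clipped to the field's DF range. Deterministic.
#'
#' @param field a [df_field()].
#' @param position length-3 numeric or an n x 3 matrix of positions in mm.
#'   All positions must lie inside the bounding cube.
#' @return numeric vector of DF values in Hz.
#' @export
sample_df_field <- function(field, position) {
  stopifnot(inherits(field, "df_field"))
  p <- if (is.matrix(position)) position else matrix(position, ncol = 3L)
  if (ncol(p) != 3L) stop("position must have 3 columns")
  if (any(p < 0) || any(p > field$cube_mm))
    stop("position outside the bounding cube [0, ", field$cube_mm, "] mm")
  v <- field$base_df + as.numeric(p %*% field$gradient)
  for (pt in field$patches) {
    d2 <- (p[, 1] - pt$center[1])^2 + (p[, 2] - pt$center[2])^2 +
      (p[, 3] - pt$center[3])^2
    v <- v + (pt$peak_df - field$base_df) * exp(-d2 / (2 * pt$radius_mm^2))
  }
  pmin(pmax(v, field$df_range[1]), field$df_range[2])
}
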