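# Deterministic ophthalmic-optics transforms: cylinder transposition,
# spectacle-to-corneal vertex correction, and polar <-> double-angle
# conversion. All functions are vectorized over rows.

#' Construct a sphero-cylinder refraction
#'
#' A refraction is a sphere/cylinder/axis/vertex quadruple. Cylinder may be
#' signed (negative-cylinder clinical notation or positive-cylinder
#' computational notation); the axis is in degrees and normalized into
#' \code{[0, 180)} (an entered axis of 180 becomes 0). A vertex of 0 means the
#' powers are already at the corneal plane.
#'
#' @param sphere Sphere power, dioptres.
#' @param cylinder Cylinder power, dioptres (signed).
#' @param axis Cylinder axis, degrees in \code{[0, 180]}.
#' @param vertex Vertex distance, millimetres (>= 0); 0 for corneal-plane data.
#' @return A data frame with columns \code{sphere}, \code{cylinder},
#'   \code{axis}, \code{vertex}; one row per eye.
#' @examples
#' refraction(-1.50, -0.75, 30, 12)
#' @export
refraction <- function(sphere, cylinder, axis = 0, vertex = 0) {
  n <- max(length(sphere), length(cylinder), length(axis), length(vertex))
  r <- data.frame(
    sphere = rep_len(as.numeric(sphere), n),
    cylinder = rep_len(as.numeric(cylinder), n),
    axis = normalize_axis(rep_len(as.numeric(axis), n)),
    vertex = rep_len(as.numeric(vertex), n)
  )
  ok <- stats::complete.cases(r)
  if (any(r$vertex[ok] < 0)) stop("vertex distance must be >= 0 mm")
  r
}

# Fold an axis in degrees into [0, 180); 180 maps to 0.
normalize_axis <- function(axis) {
  a <- axis %% 180
  a[abs(a - 180) < 1e-12] <- 0
  a
}

#' Transpose a refraction to positive-cylinder form
#'
#' Rows with a negative cylinder are rewritten in the equivalent
#' positive-cylinder notation: sphere' = sphere + cylinder,
#' cylinder' = -cylinder, axis' = (axis + 90) mod 180. The optical power along
#' every meridian is unchanged. Rows with cylinder >= 0 pass through.
#'
#' @param r A refraction data frame (see [refraction()]).
#' @return The refraction in positive-cylinder form.
#' @examples
#' transpose_to_positive_cyl(refraction(-1.50, -0.75, 30))
#' @export
transpose_to_positive_cyl <- function(r) {
  neg <- !is.na(r$cylinder) & r$cylinder < 0
  r$sphere[neg] <- r$sphere[neg] + r$cylinder[neg]
  r$axis[neg] <- normalize_axis(r$axis[neg] + 90)
  r$cylinder[neg] <- -r$cylinder[neg]
  r$axis[!is.na(r$cylinder) & r$cylinder == 0] <- 0
  r
}

#' Propagate a refraction from the spectacle plane to the corneal plane
#'
#' Each principal power F in \{sphere, sphere + cylinder\} is vertex-corrected
#' with the standard effectivity formula F' = F / (1 - (vertex/1000) * F).
#' The corneal sphere is the corrected flat power, the corneal cylinder the
#' corrected power difference; the axis is unchanged. A vertex of 0 is the
#' identity, so corneal-plane data flow through untouched.
#'
#' @param r A refraction in positive-cylinder form.
#' @return The refraction at the corneal plane (vertex 0).
#' @examples
#' to_corneal_plane(refraction(4, 0, 0, 12))  # 4 / 0.952 = 4.2017 D
#' @export
to_corneal_plane <- function(r) {
  d <- r$vertex / 1000
  f1 <- r$sphere
  f2 <- r$sphere + r$cylinder
  if (any(abs(1 - d * f1) < 1e-9 | abs(1 - d * f2) < 1e-9, na.rm = TRUE)) {
    stop("vertex correction undefined: power focuses at the corneal plane")
  }
  f1c <- f1 / (1 - d * f1)
  f2c <- f2 / (1 - d * f2)
  out <- r
  out$sphere <- f1c
  out$cylinder <- f2c - f1c
  out$vertex <- 0
  out
}

#' Propagate a corneal-plane refraction out to a spectacle plane
#'
#' Inverse of [to_corneal_plane()]: F = F' / (1 + (vertex/1000) * F') per
#' principal meridian. Used by the cohort simulator to express corneal-plane
#' outcomes as spectacle refractions.
#'
#' @param r A corneal-plane refraction in positive-cylinder form (vertex 0).
#' @param vertex Target vertex distance, millimetres.
#' @return The refraction at the requested spectacle plane.
#' @export
from_corneal_plane <- function(r, vertex) {
  d <- rep_len(vertex, nrow(r)) / 1000
  f1c <- r$sphere
  f2c <- r$sphere + r$cylinder
  f1 <- f1c / (1 + d * f1c)
  f2 <- f2c / (1 + d * f2c)
  out <- r
  out$sphere <- f1
  out$cylinder <- f2 - f1
  out$vertex <- rep_len(vertex, nrow(r))
  out
}

#' Extract the astigmatism component of a corneal-plane refraction
#'
#' @param r A corneal-plane refraction in positive-cylinder form.
#' @return A data frame with columns \code{magnitude} (D, >= 0) and
#'   \code{axis} (degrees in \code{[0, 180)}); magnitude 0 forces axis 0.
#' @export
astigmatism_of <- function(r) {
  astigmatism(r$cylinder, r$axis)
}

#' Construct a polar astigmatism
#'
#' @param magnitude Astigmatism magnitude, dioptres (>= 0).
#' @param axis Axis, degrees; normalized into \code{[0, 180)}.
#' @return Data frame with columns \code{magnitude}, \code{axis}.
#' @export
astigmatism <- function(magnitude, axis = 0) {
  n <- max(length(magnitude), length(axis))
  m <- rep_len(as.numeric(magnitude), n)
  a <- normalize_axis(rep_len(as.numeric(axis), n))
  if (any(m < 0, na.rm = TRUE)) stop("astigmatism magnitude must be >= 0")
  a[!is.na(m) & m == 0] <- 0
  data.frame(magnitude = m, axis = a)
}

#' Convert polar astigmatism to a double-angle Cartesian vector
#'
#' In double-angle space an astigmatism (M, theta) becomes
#' (M cos 2theta, M sin 2theta), which makes astigmatism addition and
#' subtraction ordinary vector arithmetic.
#'
#' @param a An astigmatism data frame (see [astigmatism()]).
#' @return Data frame with columns \code{x}, \code{y} (dioptres).
#' @export
to_double_angle <- function(a) {
  t2 <- 2 * a$axis * pi / 180
  data.frame(x = a$magnitude * cos(t2), y = a$magnitude * sin(t2))
}

#' Convert a double-angle vector back to polar astigmatism
#'
#' @param v Data frame with columns \code{x}, \code{y}.
#' @param zero_tol Magnitudes below this are snapped to exactly 0 (with
#'   axis 0), absorbing floating-point residue from vector cancellation.
#' @return An astigmatism data frame.
#' @export
from_double_angle <- function(v, zero_tol = 0) {
  m <- sqrt(v$x^2 + v$y^2)
  ax <- (atan2(v$y, v$x) / 2 * 180 / pi) %% 180
  zero <- !is.na(m) & m <= zero_tol
  m[zero] <- 0
  ax[zero] <- 0
  astigmatism(m, ax)
}
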