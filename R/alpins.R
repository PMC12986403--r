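# Alpins vector metrics. All astigmatism arithmetic happens in double-angle
# space, where subtraction of polar astigmatisms is plain vector subtraction.

# Double-angle difference a - b, returned as polar astigmatism.
da_difference <- function(a, b, zero_tol = 0) {
  va <- to_double_angle(a)
  vb <- to_double_angle(b)
  from_double_angle(data.frame(x = va$x - vb$x, y = va$y - vb$y), zero_tol)
}

# Double-angle sum a + b.
da_sum <- function(a, b, zero_tol = 0) {
  va <- to_double_angle(a)
  vb <- to_double_angle(b)
  from_double_angle(data.frame(x = va$x + vb$x, y = va$y + vb$y), zero_tol)
}

#' Target-induced astigmatism (TIA)
#'
#' The astigmatic change the surgery intends to achieve: the double-angle
#' vector difference between the target and preoperative astigmatisms.
#'
#' @param pre,target Corneal-plane astigmatisms (see [astigmatism()]).
#' @return An astigmatism data frame (magnitude, axis).
#' @examples
#' compute_tia(astigmatism(1, 90), astigmatism(0, 0))  # (1.00 D, 0 deg)
#' @export
compute_tia <- function(pre, target) da_difference(target, pre)

#' Surgically induced astigmatism (SIA)
#'
#' The astigmatic change the surgery actually achieved: the double-angle
#' vector difference between the postoperative and preoperative astigmatisms.
#'
#' @param pre,post Corneal-plane astigmatisms.
#' @return An astigmatism data frame.
#' @export
compute_sia <- function(pre, post) da_difference(post, pre)

#' Difference vector (DV)
#'
#' The residual astigmatic error: the vector change still needed to move the
#' achieved result onto the target. Algebraically equals TIA - SIA in
#' double-angle space.
#'
#' @param target,post Corneal-plane astigmatisms.
#' @return An astigmatism data frame.
#' @export
compute_dv <- function(target, post) da_difference(target, post)

#' Scalar Alpins indices from the three vectors
#'
#' Computes, per eye:
#' \itemize{
#'   \item CI (correction index) = |SIA| / |TIA|; 1 is ideal, < 1
#'     undercorrection, > 1 overcorrection.
#'   \item ME (magnitude of error) = |SIA| - |TIA|, signed; negative means
#'     undercorrection.
#'   \item AE (angle of error) = signed angle between the achieved and
#'     intended vector axes, in single-angle degrees normalized to
#'     \code{(-90, 90]}; positive = counterclockwise misalignment. Reported
#'     as 0 when |SIA| = 0 (no achieved change has no axis).
#'   \item IOS (index of success) = |DV| / |TIA|; 0 is perfect.
#' }
#'
#' @param tia,sia,dv Astigmatism data frames from [compute_tia()],
#'   [compute_sia()], [compute_dv()].
#' @return Data frame with columns \code{ci}, \code{me}, \code{ae},
#'   \code{ios}.
#' @export
compute_scalar_indices <- function(tia, sia, dv) {
  if (any(tia$magnitude == 0, na.rm = TRUE)) {
    stop("CI/ME/AE/IOS undefined for TIA magnitude 0; ",
         "such eyes must be excluded upstream")
  }
  ci <- sia$magnitude / tia$magnitude
  me <- sia$magnitude - tia$magnitude
  ae <- signed_axis_difference(sia$axis, tia$axis)
  ae[!is.na(sia$magnitude) & sia$magnitude == 0] <- 0
  ios <- dv$magnitude / tia$magnitude
  data.frame(ci = ci, me = me, ae = ae, ios = ios)
}

# Signed single-angle difference a - b, normalized to (-90, 90]; a tie at
# +/-90 resolves to +90.
signed_axis_difference <- function(a, b) {
  d <- (a - b) %% 180
  d[d > 90] <- d[d > 90] - 180
  d
}

#' Per-eye Alpins metrics from the three refractions
#'
#' Composes the full chain for each row of a 12-column dataset: transpose the
#' preoperative, target and postoperative refractions to positive-cylinder
#' form, vertex-correct them to the corneal plane, extract their astigmatism
#' components, and compute TIA, SIA, DV, CI, ME, AE and IOS. Corneal-mode
#' rows (sphere and vertex entered as 0) pass through the optics untouched.
#'
#' @param data A data frame with the 12 mandatory columns (names as produced
#'   by [read_cohort()]: \code{pre_sphere} ... \code{post_vertex}), complete
#'   rows only. Typically \code{included_data(cohort)}.
#' @return A data frame with one row per eye: \code{row_index} (if present in
#'   \code{data}), \code{tia_mag}, \code{tia_axis}, \code{sia_mag},
#'   \code{sia_axis}, \code{dv_mag}, \code{dv_axis}, \code{ci}, \code{me},
#'   \code{ae}, \code{ios}.
#' @export
compute_eye_metrics <- function(data) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) stop("no eyes to analyze")
  pre <- corneal_astigmatism(data, "pre")
  target <- corneal_astigmatism(data, "target")
  post <- corneal_astigmatism(data, "post")
  tia <- compute_tia(pre, target)
  sia <- compute_sia(pre, post)
  dv <- compute_dv(target, post)
  idx <- compute_scalar_indices(tia, sia, dv)
  out <- data.frame(
    tia_mag = tia$magnitude, tia_axis = tia$axis,
    sia_mag = sia$magnitude, sia_axis = sia$axis,
    dv_mag = dv$magnitude, dv_axis = dv$axis
  )
  out <- cbind(out, idx)
  if (!is.null(data$row_index)) out <- cbind(row_index = data$row_index, out)
  out
}

# Refraction columns <prefix>_{sphere,cyl,axis,vertex} -> corneal-plane
# astigmatism, via transpose -> vertex-correct -> extract.
corneal_astigmatism <- function(data, prefix) {
  r <- refraction(
    data[[paste0(prefix, "_sphere")]],
    data[[paste0(prefix, "_cyl")]],
    data[[paste0(prefix, "_axis")]],
    data[[paste0(prefix, "_vertex")]]
  )
  astigmatism_of(to_corneal_plane(transpose_to_positive_cyl(r)))
}

# Corneal-plane TIA magnitude for complete rows; used by the exclusion rule.
corneal_tia_magnitude <- function(data) {
  pre <- corneal_astigmatism(data, "pre")
  target <- corneal_astigmatism(data, "target")
  compute_tia(pre, target)$magnitude
}
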