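# Synthetic-cohort simulator with known ground truth. Generates 12-column
# spectacle-plane, negative-cylinder datasets in which the true correction
# ratio (ci_true), axis-rotation noise (rot_sd) and magnitude noise
# (mag_noise_sd) are known by construction, so the whole pipeline can be
# validated by parameter recovery.

#' Simulation parameters for a synthetic cohort
#'
#' The generative model, per eye: draw a preoperative spectacle refraction
#' (normal sphere; truncated-normal cylinder magnitude with a floor so every
#' eye clears the low-TIA exclusion; uniform or clustered axis), compute the
#' corneal-plane TIA toward the target, then apply an achieved correction
#' SIA whose magnitude is \code{ci_true * |TIA| + N(0, mag_noise_sd)}
#' (floored at 0) and whose axis is the TIA axis plus
#' \code{N(0, rot_sd)} degrees. The postoperative corneal astigmatism is the
#' double-angle sum of the preoperative astigmatism and the SIA; the
#' postoperative sphere is the target corneal sphere plus
#' \code{N(0, residual_sphere_sd)}. Everything is then back-propagated to
#' the spectacle plane and written in negative-cylinder notation.
#'
#' @param n Number of eyes (>= 1).
#' @param sphere_mean,sphere_sd Preoperative spectacle sphere, dioptres
#'   (negative-cylinder notation, so hyperopes have positive means).
#' @param cyl_mean,cyl_sd Preoperative cylinder magnitude, dioptres,
#'   truncated at \code{cyl_floor}.
#' @param cyl_floor Minimum cylinder magnitude, dioptres (default 0.50,
#'   which keeps every generated eye above the 0.25 D TIA exclusion).
#' @param axis_mode \code{"uniform"} or \code{"clustered"}.
#' @param axis_center,axis_sd Center and spread (degrees) of the clustered
#'   axis mode (wrapped normal on the half-turn circle).
#' @param ci_true True correction ratio (> 0); 1 = perfect magnitude.
#' @param rot_sd SD of the axis-rotation noise, degrees.
#' @param mag_noise_sd SD of the SIA magnitude noise, dioptres.
#' @param residual_sphere_sd SD of the residual postoperative corneal
#'   sphere, dioptres.
#' @param target Either \code{"plano"} (target 0/0/0 at 12 mm) or a numeric
#'   vector \code{c(sphere, cylinder, axis)} in negative-cylinder notation.
#' @param vertex Vertex distance for the pre- and postoperative refractions,
#'   millimetres.
#' @param seed Integer RNG seed; a fixed seed makes the cohort reproducible.
#' @return A validated \code{sim_params} list.
#' @export
sim_params <- function(n = 100,
                       sphere_mean = -2.0, sphere_sd = 1.0,
                       cyl_mean = 1.5, cyl_sd = 0.5, cyl_floor = 0.50,
                       axis_mode = c("uniform", "clustered"),
                       axis_center = 90, axis_sd = 20,
                       ci_true = 1.0, rot_sd = 0, mag_noise_sd = 0,
                       residual_sphere_sd = 0,
                       target = "plano", vertex = 12, seed = 1L) {
  axis_mode <- match.arg(axis_mode)
  p <- list(n = as.integer(n), sphere_mean = sphere_mean,
            sphere_sd = sphere_sd, cyl_mean = cyl_mean, cyl_sd = cyl_sd,
            cyl_floor = cyl_floor, axis_mode = axis_mode,
            axis_center = axis_center, axis_sd = axis_sd,
            ci_true = ci_true, rot_sd = rot_sd,
            mag_noise_sd = mag_noise_sd,
            residual_sphere_sd = residual_sphere_sd,
            target = target, vertex = vertex, seed = as.integer(seed))
  if (p$n < 1) stop("n must be >= 1")
  if (p$ci_true <= 0) stop("ci_true must be > 0")
  sds <- c(p$sphere_sd, p$cyl_sd, p$axis_sd, p$rot_sd, p$mag_noise_sd,
           p$residual_sphere_sd)
  if (any(sds < 0)) stop("all SD parameters must be >= 0")
  if (p$vertex < 0) stop("vertex must be >= 0 mm")
  if (is.numeric(p$target) && length(p$target) != 3) {
    stop("a numeric target must be c(sphere, cylinder, axis)")
  }
  class(p) <- "sim_params"
  p
}

#' Generate a synthetic 12-column cohort
#'
#' @param params A [sim_params()] object.
#' @return Data frame with the 12 dataset columns (negative-cylinder,
#'   spectacle-plane values; vertex columns in millimetres), ready for
#'   [write_cohort_csv()] or direct analysis. Deterministic for a fixed
#'   seed.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n
  sphere <- stats::rnorm(n, params$sphere_mean, params$sphere_sd)
  cylmag <- truncated_normal(n, params$cyl_mean, params$cyl_sd,
                             params$cyl_floor)
  axis <- if (params$axis_mode == "uniform") {
    stats::runif(n, 0, 180)
  } else {
    normalize_axis(stats::rnorm(n, params$axis_center, params$axis_sd))
  }

  # preop spectacle refraction in negative-cylinder notation
  pre_neg <- refraction(sphere, -cylmag, axis, params$vertex)
  if (identical(params$target, "plano")) {
    tgt_neg <- refraction(rep(0, n), rep(0, n), rep(0, n), rep(12, n))
  } else {
    tgt_neg <- refraction(rep(params$target[1], n), rep(params$target[2], n),
                          rep(params$target[3], n), rep(params$vertex, n))
  }

  pre_c <- to_corneal_plane(transpose_to_positive_cyl(pre_neg))
  tgt_c <- to_corneal_plane(transpose_to_positive_cyl(tgt_neg))
  pre_a <- astigmatism_of(pre_c)
  tgt_a <- astigmatism_of(tgt_c)
  tia <- compute_tia(pre_a, tgt_a)

  sia_mag <- pmax(0, params$ci_true * tia$magnitude +
                    stats::rnorm(n, 0, params$mag_noise_sd))
  sia_axis <- tia$axis + stats::rnorm(n, 0, params$rot_sd)
  sia <- astigmatism(sia_mag, normalize_axis(sia_axis))

  # postop corneal astigmatism = preop (+) SIA in double-angle space;
  # snap exact cancellations (ci_true = 1, zero noise) to a clean zero
  post_a <- da_sum(pre_a, sia, zero_tol = 1e-9)
  post_sphere_c <- tgt_c$sphere + stats::rnorm(n, 0, params$residual_sphere_sd)
  post_c <- refraction(post_sphere_c, post_a$magnitude, post_a$axis, 0)
  post_s <- from_corneal_plane(post_c, params$vertex)

  # back to negative-cylinder notation for the spreadsheet
  post_neg <- positive_to_negative_cyl(post_s)

  out <- data.frame(
    pre_sphere = pre_neg$sphere, pre_cyl = pre_neg$cylinder,
    pre_axis = pre_neg$axis, pre_vertex = pre_neg$vertex,
    target_sphere = tgt_neg$sphere, target_cyl = tgt_neg$cylinder,
    target_axis = tgt_neg$axis, target_vertex = tgt_neg$vertex,
    post_sphere = post_neg$sphere, post_cyl = post_neg$cylinder,
    post_axis = post_neg$axis, post_vertex = post_neg$vertex
  )
  out
}

# Rejection-sampled normal truncated below at `floor`.
truncated_normal <- function(n, mean, sd, floor) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < floor)) {
    low <- x < floor
    x[low] <- stats::rnorm(sum(low), mean, sd)
  }
  x
}

# Positive-cylinder (S, C, axis) -> negative-cylinder (S + C, -C, axis + 90).
positive_to_negative_cyl <- function(r) {
  pos <- !is.na(r$cylinder) & r$cylinder > 0
  r$sphere[pos] <- r$sphere[pos] + r$cylinder[pos]
  r$axis[pos] <- normalize_axis(r$axis[pos] + 90)
  r$cylinder[pos] <- -r$cylinder[pos]
  r$axis[!is.na(r$cylinder) & r$cylinder == 0] <- 0
  r
}

#' Write the three demonstration trial fixtures
#'
#' Generates four CSV files emulating three common surgical scenarios:
#' \describe{
#'   \item{Trial 1 (paired)}{\code{trial1_group_a.csv} /
#'     \code{trial1_group_b.csv}: a contralateral-eye laser vision
#'     correction study in hyperopic astigmats comparing two treatment
#'     platforms (equal row counts; group B slightly undercorrects).}
#'   \item{Trial 2 (single group)}{\code{trial2.csv}: toric phakic IOL
#'     implantation in hyperopic eyes with moderate-to-high astigmatism
#'     (cylinder magnitudes >= 1.00 D).}
#'   \item{Trial 3 (unpaired)}{\code{trial3_group_a.csv} /
#'     \code{trial3_group_b.csv}: two cataract-surgery toric-IOL groups in
#'     myopic astigmats with different eye counts.}
#' }
#' Seeds are fixed constants, so the fixtures are identical on every call.
#'
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_trial_fixtures <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  specs <- trial_fixture_params()
  paths <- vapply(names(specs), function(nm) {
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write_cohort_csv(generate_cohort(specs[[nm]]), path)
    path
  }, character(1))
  invisible(paths)
}

# Committed scenario parameters for the demonstration trials.
trial_fixture_params <- function() {
  list(
    trial1_group_a = sim_params(
      n = 80, sphere_mean = 2.5, sphere_sd = 0.75,
      cyl_mean = 1.5, cyl_sd = 0.5, cyl_floor = 0.5,
      ci_true = 1.00, rot_sd = 4, mag_noise_sd = 0.12,
      residual_sphere_sd = 0.15, seed = 101L),
    trial1_group_b = sim_params(
      n = 80, sphere_mean = 2.5, sphere_sd = 0.75,
      cyl_mean = 1.5, cyl_sd = 0.5, cyl_floor = 0.5,
      ci_true = 0.90, rot_sd = 6, mag_noise_sd = 0.15,
      residual_sphere_sd = 0.18, seed = 102L),
    trial2 = sim_params(
      n = 60, sphere_mean = 4.0, sphere_sd = 1.0,
      cyl_mean = 2.5, cyl_sd = 0.75, cyl_floor = 1.0,
      ci_true = 0.95, rot_sd = 5, mag_noise_sd = 0.15,
      residual_sphere_sd = 0.20, seed = 201L),
    trial3_group_a = sim_params(
      n = 70, sphere_mean = -3.5, sphere_sd = 1.25,
      cyl_mean = 1.75, cyl_sd = 0.6, cyl_floor = 0.5,
      ci_true = 0.98, rot_sd = 5, mag_noise_sd = 0.12,
      residual_sphere_sd = 0.20, seed = 301L),
    trial3_group_b = sim_params(
      n = 65, sphere_mean = -3.5, sphere_sd = 1.25,
      cyl_mean = 1.75, cyl_sd = 0.6, cyl_floor = 0.5,
      ci_true = 0.90, rot_sd = 7, mag_noise_sd = 0.15,
      residual_sphere_sd = 0.20, seed = 302L)
  )
}
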