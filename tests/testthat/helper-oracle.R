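# Independent oracle: represent every sphero-cylinder as a 2x2 symmetric
# dioptric power matrix. Astigmatism subtraction is then matrix subtraction
# of the traceless parts, magnitudes and axes come from eigen decomposition,
# and vertex correction is the matrix effectivity map. No double-angle
# trigonometry is used anywhere in this path.

# Power matrix of cylinder C (signed) at axis theta degrees.
pm_cyl <- function(C, axis_deg) {
  th <- axis_deg * pi / 180
  matrix(c(C * sin(th)^2, -C * sin(th) * cos(th),
           -C * sin(th) * cos(th), C * cos(th)^2), 2, 2)
}

# Power matrix of a sphero-cylinder (any sign convention).
pm_refraction <- function(sphere, cylinder, axis_deg) {
  sphere * diag(2) + pm_cyl(cylinder, axis_deg)
}

# Vertex propagation of a power matrix by d metres: F' = F (I - d F)^-1.
pm_vertex <- function(F, d) {
  F %*% solve(diag(2) - d * F)
}

# Traceless (astigmatic) part of a power matrix.
pm_traceless <- function(F) {
  F - (sum(diag(F)) / 2) * diag(2)
}

# Polar astigmatism (magnitude, axis) from a traceless matrix, via eigen
# decomposition: magnitude = spread of the eigenvalues, axis = direction of
# the eigenvector with the smaller eigenvalue (the zero-power meridian of
# the equivalent cylinder).
pm_to_polar <- function(T, tol = 1e-12) {
  ev <- eigen(T, symmetric = TRUE)
  mag <- ev$values[1] - ev$values[2]
  if (mag < tol) return(c(magnitude = 0, axis = 0))
  v <- ev$vectors[, 2]
  axis <- (atan2(v[2], v[1]) * 180 / pi) %% 180
  if (abs(axis - 180) < 1e-9) axis <- 0
  c(magnitude = mag, axis = axis)
}

# Signed single-angle axis difference a - b in (-90, 90].
oracle_axis_diff <- function(a, b) {
  d <- (a - b) %% 180
  if (d > 90) d <- d - 180
  d
}

# All seven Alpins metrics for one eye via the power-matrix route, from the
# three refractions in negative-cylinder spectacle notation.
oracle_eye_metrics <- function(row) {
  corneal_traceless <- function(prefix) {
    F <- pm_refraction(row[[paste0(prefix, "_sphere")]],
                       row[[paste0(prefix, "_cyl")]],
                       row[[paste0(prefix, "_axis")]])
    Fc <- pm_vertex(F, row[[paste0(prefix, "_vertex")]] / 1000)
    pm_traceless(Fc)
  }
  Tp <- corneal_traceless("pre")
  Tt <- corneal_traceless("target")
  Ts <- corneal_traceless("post")
  tia <- pm_to_polar(Tt - Tp)
  sia <- pm_to_polar(Ts - Tp)
  dv <- pm_to_polar(Tt - Ts)
  ae <- if (sia[["magnitude"]] == 0) 0 else
    oracle_axis_diff(sia[["axis"]], tia[["axis"]])
  c(tia_mag = tia[["magnitude"]], tia_axis = tia[["axis"]],
    sia_mag = sia[["magnitude"]], sia_axis = sia[["axis"]],
    dv_mag = dv[["magnitude"]], dv_axis = dv[["axis"]],
    ci = sia[["magnitude"]] / tia[["magnitude"]],
    me = sia[["magnitude"]] - tia[["magnitude"]],
    ae = ae,
    ios = dv[["magnitude"]] / tia[["magnitude"]])
}

# Random negative-cylinder spectacle-plane eyes whose corneal TIA clears the
# exclusion threshold (resampling rejected eyes keeps the draw seeded).
random_eye_rows <- function(n, seed) {
  set.seed(seed)
  draw <- function(k) {
    data.frame(
      pre_sphere = round(stats::runif(k, -6, 6) * 4) / 4,
      pre_cyl = -round(stats::runif(k, 0.5, 4) * 4) / 4,
      pre_axis = sample(0:179, k, replace = TRUE),
      pre_vertex = sample(c(0, 10, 12, 13.5), k, replace = TRUE),
      target_sphere = round(stats::runif(k, -1, 1) * 4) / 4,
      target_cyl = -round(stats::runif(k, 0, 0.5) * 4) / 4,
      target_axis = sample(0:179, k, replace = TRUE),
      target_vertex = sample(c(0, 12), k, replace = TRUE),
      post_sphere = round(stats::runif(k, -1.5, 1.5) * 4) / 4,
      post_cyl = -round(stats::runif(k, 0, 1.5) * 4) / 4,
      post_axis = sample(0:179, k, replace = TRUE),
      post_vertex = sample(c(0, 12), k, replace = TRUE)
    )
  }
  rows <- draw(n)
  repeat {
    tia <- astigvec:::corneal_tia_magnitude(rows)
    low <- tia < 0.25
    if (!any(low)) break
    rows[low, ] <- draw(sum(low))
  }
  rows
}
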