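#' Channel geometry with layered lumen corrections
#'
#' Describes one microchannel of the parallel network: the bare (PDMS) side
#' length and the successive reductions of the available lumen caused by the
#' endothelial lining — the thickness of the peripheral cell body
#' (`h_peri`), the mean height of the apical-membrane topography (`h_mean`),
#' the effective no-slip boundary shift due to surface waviness (`delta`),
#' and the thickness of the endothelial surface layer (`h_esl`). All lengths
#' in micrometres.
#'
#' @param bare_side side length of the bare square channel (um).
#' @param n_parallel number of identical channels fed in parallel.
#' @param h_peri peripheral cell-body thickness (um).
#' @param h_mean mean apical-membrane height above its lowest points (um).
#' @param delta no-slip boundary shift from surface roughness (um).
#' @param h_esl endothelial-surface-layer thickness (um).
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(bare_side, n_parallel = 16L, h_peri = 0,
                             h_mean = 0, delta = 0, h_esl = 0) {
  stopifnot(bare_side > 0, n_parallel >= 1,
            h_peri >= 0, h_mean >= 0, delta >= 0, h_esl >= 0)
  if (bare_side <= 2 * (h_peri + h_mean + delta + h_esl))
    stop("lumen corrections close the channel: 2*(h_peri + h_mean + delta + h_esl) >= bare_side")
  structure(list(bare_side = bare_side, n_parallel = as.integer(n_parallel),
                 h_peri = h_peri, h_mean = h_mean, delta = delta, h_esl = h_esl),
            class = "channel_geometry")
}

#' Effective lumen side length
#'
#' The hydrodynamically relevant side of the square lumen: the bare side
#' reduced on both walls by the cell periphery, the mean membrane height and
#' the roughness boundary shift, and optionally further by the endothelial
#' surface layer.
#'
#' @param geom a [channel_geometry()].
#' @param include_esl logical; subtract the ESL thickness as well.
#' @return Effective side length in um.
#' @export
effective_side <- function(geom, include_esl = TRUE) {
  stopifnot(inherits(geom, "channel_geometry"))
  s <- geom$bare_side - 2 * (geom$h_mean + geom$h_peri + geom$delta)
  if (include_esl) s <- s - 2 * geom$h_esl
  if (s <= 0) stop("effective lumen is non-positive")
  s
}

#' Laminar rectangular-duct flow model
#'
#' Exact series solution of pressure-driven laminar flow in a rectangular
#' duct, scaled so that the cross-sectional integral of the velocity equals
#' the imposed per-channel flow rate.
#'
#' @param width duct width (um), coordinate y in `[-width/2, width/2]`.
#' @param height duct height (um), coordinate z in `[-height/2, height/2]`.
#' @param flow_rate per-channel volumetric flow rate, uL/min.
#' @param viscosity dynamic viscosity, Pa s. Default 0.75 mPa s (cell-culture
#'   medium at 37 C).
#' @param series_terms number of odd Fourier terms kept in the series.
#' @return An object of class `duct_flow_model`.
#' @export
duct_flow_model <- function(width, height, flow_rate,
                            viscosity = 7.5e-4, series_terms = 101L) {
  stopifnot(width > 0, height > 0, flow_rate > 0, viscosity > 0,
            series_terms >= 11)
  m <- structure(list(width = width, height = height, flow_rate = flow_rate,
                      viscosity = viscosity,
                      series_terms = as.integer(series_terms)),
                 class = "duct_flow_model")
  m$phi_integral <- duct_phi_integral(m)
  m
}

# Odd harmonics used by the series.
duct_ns <- function(model) seq(1L, by = 2L, length.out = model$series_terms)

# Unnormalized shape function phi(y, z); the physical velocity is
# u = phi * flow_rate / integral(phi). Vectorized over equal-length y, z.
duct_phi <- function(model, y, z) {
  w <- model$width; h <- model$height
  ns <- duct_ns(model)
  sgn <- (-1)^((ns - 1) / 2)
  out <- numeric(length(y))
  for (i in seq_along(ns)) {
    n <- ns[i]
    # cosh ratio written via exp to stay finite for large n*h/w
    a <- n * pi * z / w
    b <- n * pi * h / (2 * w)
    ratio <- exp(abs(a) - b) * (1 + exp(-2 * abs(a))) / (1 + exp(-2 * b))
    out <- out + sgn[i] / n^3 * (1 - ratio) * cos(n * pi * y / w)
  }
  out
}

# Analytic cross-sectional integral of phi.
duct_phi_integral <- function(model) {
  w <- model$width; h <- model$height
  ns <- duct_ns(model)
  sum(1 / ns^3 * (2 * w / (ns * pi)) *
        (h - (2 * w / (ns * pi)) * tanh(ns * pi * h / (2 * w))))
}

#' Duct velocity at a point
#'
#' @param model a [duct_flow_model()].
#' @param y,z coordinates in um measured from the duct axis; recycled to a
#'   common length.
#' @return Velocity in um/s (zero on the walls, maximal on the axis).
#' @export
duct_velocity <- function(model, y, z) {
  stopifnot(inherits(model, "duct_flow_model"))
  n <- max(length(y), length(z))
  y <- rep_len(y, n); z <- rep_len(z, n)
  if (any(abs(y) > model$width / 2 + 1e-9) || any(abs(z) > model$height / 2 + 1e-9))
    stop("point outside the duct cross-section")
  q <- ul_min_to_um3_s(model$flow_rate)
  pmax(0, duct_phi(model, y, z) * q / model$phi_integral)
}

#' Ratio of maximum to mean velocity in a rectangular duct
#'
#' For a square cross-section this ratio is about 2.096.
#'
#' @inheritParams duct_velocity
#' @return Dimensionless ratio `V_max / V_avg`.
#' @export
vmax_vavg_ratio <- function(model) {
  stopifnot(inherits(model, "duct_flow_model"))
  duct_phi(model, 0, 0) * model$width * model$height / model$phi_integral
}

#' Theoretical maximum velocity in the parallel-channel network
#'
#' The network splits the imposed flow rate equally over `n_parallel` square
#' channels; the mean velocity per channel is `Q_total / (n_parallel * side^2)`
#' and the centreline maximum follows from the square-duct max/mean ratio.
#'
#' @param q_total total imposed flow rate, uL/min.
#' @param n_parallel number of parallel channels.
#' @param side lumen side length, um.
#' @param series_terms series truncation used for the max/mean ratio.
#' @return Named list with `v_avg` and `v_max` in um/s.
#' @export
vmax_theory <- function(q_total, n_parallel = 16L, side, series_terms = 101L) {
  stopifnot(q_total > 0, side > 0, n_parallel >= 1)
  v_avg <- ul_min_to_um3_s(q_total) / (n_parallel * side^2)
  m <- duct_flow_model(side, side, q_total / n_parallel,
                       series_terms = series_terms)
  list(v_avg = v_avg, v_max = vmax_vavg_ratio(m) * v_avg)
}

#' Mean wall shear stress in the duct
#'
#' Recovered from the axial force balance: the pressure gradient (known
#' analytically from the flow rate) times the cross-section area equals the
#' mean wall shear stress times the wetted perimeter.
#'
#' @inheritParams duct_velocity
#' @return Mean wall shear stress in Pa.
#' @export
wall_shear_stress <- function(model) {
  stopifnot(inherits(model, "duct_flow_model"))
  q_si <- ul_min_to_um3_s(model$flow_rate) * 1e-18   # m^3/s
  w <- model$width * 1e-6; h <- model$height * 1e-6  # m
  phi_int <- model$phi_integral * 1e-12              # um^2 -> m^2
  # u_phys = (4 G w^2 / (mu pi^3)) phi, so Q = (4 G w^2 / (mu pi^3)) integral(phi)
  g <- q_si * model$viscosity * pi^3 / (4 * w^2 * phi_int)  # -dp/dx, Pa/m
  g * (w * h) / (2 * (w + h))
}
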