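#' Calibrated stair-ascent gait-cycle templates
#'
#' Smooth periodic curves for the four hip outputs (sagittal/frontal angle
#' and mass-normalized moment) over one gait cycle (0-100%), plus the
#' auxiliary shank and ankle angle curves needed for forward kinematics.
#' Templates are periodic cubic splines through hand-placed knots, then
#' calibrated so the key landmarks of healthy stair ascent are reproduced
#' exactly on a dense grid:
#'
#' * sagittal hip angle: 58.0 deg at heel strike (cycle maximum) with a
#'   range of motion of 55.6 deg;
#' * frontal hip angle: range of motion 17.4 deg (adduction positive);
#' * sagittal moment: peak flexion moment 1.0 Nm/kg near 50% gait, peak
#'   extension moment near 20% (flexion positive, extension negative);
#' * frontal moment: double abduction bump during stance, first peak
#'   1.6 Nm/kg in magnitude and larger than the second (abduction negative);
#' * stance fraction 0.67 (toe off at 67% gait).
#'
#' Angle curves are stationary at 0% so that heel strike is a well-defined
#' event of every virtual sensor: the heel-marker anteroposterior velocity
#' crosses zero downward exactly at 0%, and the shank mediolateral angular
#' velocity has the first of its two stance minima exactly at 0%. The knee
#' and ankle shapes are stair-ascent-plausible fixtures supporting the
#' kinematic chain, not calibrated claims.
#'
#' @param stance_fraction stance duration as a fraction of the cycle.
#' @param cycle_duration_s mean cycle duration in seconds; the default
#'   follows from ~4.53 cycles per 10 s trial.
#' @param subject_scale_sd SD of the per-subject multiplicative amplitude
#'   scale (mean 1) applied to each output curve.
#' @param angle_offset_sd_deg,moment_offset_sd SDs of per-subject additive
#'   offsets for angles (deg) and moments (Nm/kg).
#' @param cycle_duration_sd_s SD of the per-subject mean cycle duration (s).
#' @param stance_fraction_sd per-subject SD of the stance fraction (the
#'   cohort value is 67.0 +/- 3.4%).
#' @param cycle_jitter_sd fractional SD of per-cycle duration jitter.
#' @return A `gait_templates` object: list of curve functions (`sag_angle`,
#'   `front_angle`, `sag_moment`, `front_moment`, `shank_angle`,
#'   `knee_angle`, `ankle_angle`, each taking a gait-percent vector) plus
#'   the parameter fields above.
#' @examples
#' tpl <- default_templates()
#' p <- seq(0, 100, by = 0.1)
#' diff(range(tpl$sag_angle(p)))   # 55.6
#' @export
default_templates <- function(stance_fraction = 0.67,
                              cycle_duration_s = 10 / 4.53,
                              subject_scale_sd = 0.08,
                              angle_offset_sd_deg = 2,
                              moment_offset_sd = 0.05,
                              cycle_duration_sd_s = 0.15,
                              stance_fraction_sd = 0.034,
                              cycle_jitter_sd = 0.03) {
  dense <- seq(0, 100, by = 0.01)

  ## shank sagittal angle, built from an angular-velocity shape whose first
  ## stance minimum falls exactly at heel strike (0%)
  shank <- build_shank_angle()
  shank_angle <- shank$fun

  ## sagittal hip angle: affine-calibrated to peak 58.0 deg, range 55.6.
  ## A localized slope correction at 0% cancels the shank and foot
  ## contributions to the heel-marker anteroposterior velocity, so the
  ## velocity zero crossing (the optical heel-strike definition) lands
  ## exactly on the cycle boundary.
  sa0 <- periodic_spline(
    c(0, 3, 6, 10, 14, 20, 30, 40, 50, 58, 64, 70, 75, 80, 86, 92, 96, 100),
    c(58, 59.3, 58.8, 56.2, 52.5, 45, 25.2, 13, 6, 3.2, 2.6, 5, 12, 32.6,
      45, 50.5, 53.2, 58))
  # ankle fixture value at heel strike is 5 deg (first knot below)
  slope_target <- hip_slope_for_heel_zero(58, shank$fun(0), 5,
                                          shank$fun(0, deriv = 1))
  local_slope <- local_slope_at0
  a1 <- 55.6 / diff(range(sa0(dense)))  # provisional scale
  corr <- 0
  for (i in 1:3) {  # fixed-point: scale and slope correction interact
    corr <- slope_target / a1 - sa0(0, deriv = 1)
    v <- sa0(dense) + corr * local_slope(dense)
    a1 <- 55.6 / (max(v) - min(v))
  }
  sa <- function(p) sa0(p %% 100) + corr * local_slope(p)
  b1 <- 58.0 - a1 * sa(0)
  sag_angle <- function(p) a1 * sa(p %% 100) + b1

  ## frontal hip angle: range calibrated to 17.4 about the curve midpoint
  fa <- periodic_spline(
    c(0, 2, 8, 15, 20, 30, 40, 50, 60, 70, 78, 85, 92, 96, 98, 100),
    c(1.1, 1.35, 3.5, 6.5, 7.2, 2.8, -0.5, -2.0, -3.1, -6.5, -8.8, -6.0,
      -2.5, 0.2, 1.35, 1.1))
  v <- fa(dense)
  a2 <- 17.4 / (max(v) - min(v)); b2 <- (max(v) + min(v)) / 2
  front_angle <- function(p) (fa(p %% 100) - b2) * a2 + b2

  ## sagittal moment: scaled so the flexion (positive) peak is exactly 1.0
  sm <- periodic_spline(
    seq(0, 100, by = 5),
    c(-0.1, -0.45, -0.75, -0.88, -0.92, -0.85, -0.7, -0.45, -0.05, 0.6, 1.0,
      0.85, 0.6, 0.25, 0.02, -0.12, -0.2, -0.22, -0.18, -0.14, -0.1))
  s3 <- 1.0 / max(sm(dense))
  sag_moment <- function(p) s3 * sm(p %% 100)

  ## frontal moment: scaled so the first (larger) abduction peak is -1.6
  fm <- periodic_spline(
    c(0, 5, 10, 15, 20, 25, 30, 35, 42, 48, 55, 60, 66, 70, 80, 90, 100),
    c(-0.003, -0.9, -1.45, -1.6, -1.5, -1.38, -1.3, -1.32, -1.42, -1.45,
      -1.1, -0.7, -0.15, -0.02, -0.01, -0.005, -0.003))
  s4 <- 1.6 / abs(min(fm(dense)))
  front_moment <- function(p) s4 * fm(p %% 100)

  ## ankle angle fixture (dorsiflexion positive), stationary at 0%
  ankle_angle <- periodic_spline(
    c(0, 2, 10, 25, 40, 50, 60, 75, 90, 96, 98, 100),
    c(5, 4.6, 0, -8, -15, -18, -5, 8, 8, 4.8, 4.6, 5))

  knee_angle <- function(p) sag_angle(p) - shank_angle(p)

  structure(list(
    sag_angle = sag_angle, front_angle = front_angle,
    sag_moment = sag_moment, front_moment = front_moment,
    shank_angle = function(p) shank_angle(p %% 100),
    knee_angle = function(p) knee_angle(p %% 100),
    ankle_angle = function(p) ankle_angle(p %% 100),
    stance_fraction = stance_fraction,
    cycle_duration_s = cycle_duration_s,
    subject_scale_sd = subject_scale_sd,
    angle_offset_sd_deg = angle_offset_sd_deg,
    moment_offset_sd = moment_offset_sd,
    cycle_duration_sd_s = cycle_duration_sd_s,
    stance_fraction_sd = stance_fraction_sd,
    cycle_jitter_sd = cycle_jitter_sd),
    class = "gait_templates")
}

periodic_spline <- function(x, y) {
  if (abs(y[1] - y[length(y)]) > 0)
    stop("periodic template knots must satisfy y(0) == y(100)")
  stats::splinefun(x, y, method = "periodic")
}

# Shank sagittal angle from an angular-velocity shape (deg per gait percent)
# with a sharp local minimum at heel strike (0%, value d0) and a second,
# deeper minimum in mid-stance -- the classic two-minima stance signature of
# the shank mediolateral gyro. The shape is corrected to zero mean with a
# smooth bump confined to swing (so the heel-strike minimum is untouched)
# and integrated to a periodic angle curve starting at theta0 = 5 deg.
build_shank_angle <- function() {
  d_base <- periodic_spline(
    c(0, 5, 9, 14, 22, 30, 40, 48, 54, 62, 72, 80, 88, 91, 95, 100),
    c(-0.50, -0.05, 0.10, -0.15, -0.70, -0.75, -0.50, -0.15, 0.10, 0.55,
      0.95, 0.80, 0.45, 0.10, -0.05, -0.50))
  # The 2.3 Hz zero-phase filter used before event detection displaces the
  # minimum of this shape slightly backward in time because of the
  # asymmetric swing context; a localized warp moves the raw dip ~0.85%
  # later so the *filtered* minimum falls on the cycle boundary across the
  # physiological range of cycle durations.
  warp <- function(p) {
    ph <- ((p + 50) %% 100) - 50
    p - 0.85 * exp(-(ph / 6)^2)
  }
  d_warp <- function(p) d_base(warp(p) %% 100)
  bump <- function(p) ifelse(p > 55 & p < 87, sin(pi * (p - 55) / 32)^2, 0)
  grid <- seq(0, 100, by = 0.01)
  c0 <- trapz(grid, d_warp(grid)) / trapz(grid, bump(grid))
  d_fun <- function(p) d_warp(p) - c0 * bump(p)
  v <- d_fun(grid)
  theta <- 5 + c(0, cumsum((v[-1] + v[-length(v)]) / 2) * 0.01)
  # re-fit a periodic spline at 0.5% resolution (the integral is periodic
  # up to numerical residue, which is absorbed into the last knot)
  knots <- seq(1, length(grid), by = 50)
  xk <- grid[knots]; yk <- theta[knots]
  if (xk[length(xk)] < 100) { xk <- c(xk, 100); yk <- c(yk, yk[1]) }
  yk[length(yk)] <- yk[1]
  list(fun = stats::splinefun(xk, yk, method = "periodic"))
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2

# unit-slope correction shape localized at the cycle boundary; adding
# c * local_slope_at0(p) to an angle curve changes its 0% slope by c
# (deg per gait percent) while leaving the rest of the cycle untouched
local_slope_at0 <- function(p) {
  ph <- ((p + 50) %% 100) - 50
  ph * exp(-(ph / 3)^2)
}

# slope (deg/%) the hip curve must have at 0% so that the heel-marker
# anteroposterior velocity is exactly zero at the cycle boundary, given the
# hip/shank/foot angles and the shank angular velocity there; segment
# length ratios come from the anthropometric table (heights cancel)
hip_slope_for_heel_zero <- function(hip0_deg, shank0_deg, ankle0_deg,
                                    shank_slope) {
  lt <- 0.245; ls <- 0.246; lf <- 0.152
  d2r <- pi / 180
  -(ls * cos(shank0_deg * d2r) +
      0.3 * lf * sin((shank0_deg + ankle0_deg) * d2r)) *
    shank_slope / (lt * cos(hip0_deg * d2r))
}

#' Evaluate a named template curve
#'
#' @param templates a [default_templates()] object.
#' @param metric one of `"sag_angle"`, `"front_angle"`, `"sag_moment"`,
#'   `"front_moment"`, `"shank_angle"`, `"knee_angle"`, `"ankle_angle"`.
#' @param percent gait-percent vector (values outside 0-100 wrap).
#' @return Numeric vector of template values (deg or Nm/kg).
#' @export
template_curve <- function(templates, metric, percent) {
  stopifnot(inherits(templates, "gait_templates"))
  f <- templates[[metric]]
  if (!is.function(f)) stop("unknown template metric: ", metric)
  f(percent)
}

#' Synthetic vertical ground-reaction-force template
#'
#' Smooth double-bump vertical GRF over the stance window
#' `[0, stance_fraction * 100]` percent of the gait cycle and exactly zero
#' in swing. The loading and unloading edges are steep ramps with a brief
#' linear toe, so the force rises through the 20 N detection threshold once
#' per cycle within a few milliseconds of the true stance boundary (and the
#' crossing survives 10 Hz zero-phase filtering in place); the two force
#' peaks (~1.2 body weight) bracket a mid-stance valley (~0.9 body weight),
#' and peak force scales linearly with body mass.
#'
#' @param percent gait-percent vector (values outside 0-100 wrap).
#' @param mass_kg body mass in kilograms.
#' @param stance_fraction stance duration as a fraction of the cycle.
#' @return Vertical GRF in newtons.
#' @export
grf_template <- function(percent, mass_kg, stance_fraction = 0.67) {
  p <- percent %% 100
  u <- (p / 100) / stance_fraction
  y <- ifelse(u < 1, grf_shape(u), 0)
  y * mass_kg * 9.81
}

grf_shape <- function(u) {
  s <- function(x) { x <- pmin(pmax(x, 0), 1); x * x * (3 - 2 * x) }
  # loading/unloading edges: a steep linear "toe" carries the force through
  # the 20 N detection band (a locally linear segment keeps the threshold
  # crossing in place under zero-phase low-pass filtering), then a
  # smoothstep completes the rise
  toe_w <- 0.025; toe_h <- 0.5
  edge <- function(x) pmin(x / toe_w, 1) * toe_h +
    s((x - 0.6 * toe_w) / 0.012) * (1 - toe_h)
  bumps <- 0.85 + 0.25 * sin(pi * u) + 0.18 * cos(4 * pi * (u - 0.25))
  edge(u) * edge(1 - u) * bumps * (1.03 - 0.06 * u)
}
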