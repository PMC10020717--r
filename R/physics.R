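#' Reduced-order hemodynamics oracle parameters
#'
#' Constants and tuning knobs of the quasi-1D model that stands in for the
#' 3D CFD stage. Blood is treated as Newtonian with the infinite-shear
#' viscosity; pressures are reported in mmHg (internal physics in SI,
#' 1 mmHg = 133.322 Pa).
#'
#' @param rho blood density, kg/m^3.
#' @param mu dynamic viscosity, Pa s.
#' @param cc orifice contraction coefficient (vena-contracta area divided by
#'   anatomic orifice area), dimensionless, in (0, 1].
#' @param recovery_length pressure-recovery length downstream of the vena
#'   contracta, mm.
#' @param expansion_k Borda-Carnot expansion loss coefficient.
#' @param jet_wss_gain dimensionless gain converting jet dynamic pressure to
#'   a wall-shear contribution downstream of the vena contracta.
#' @param sample_noise_frac within-plane sample spread as a fraction of the
#'   local dynamic pressure.
#' @param outlet_pressure pressure pinned at the last centerline point
#'   during post-processing, mmHg.
#' @param friction logical; include Darcy friction losses in the pressure
#'   march (wall-shear stress itself is always computed).
#' @return list of class `oracle_params`.
#' @export
oracle_params <- function(rho = 1050, mu = 0.0035, cc = 0.85,
                          recovery_length = 40, expansion_k = 1.0,
                          jet_wss_gain = 0.02, sample_noise_frac = 0.05,
                          outlet_pressure = 130, friction = TRUE) {
  if (rho <= 0 || mu <= 0) abort("rho and mu must be positive")
  if (cc <= 0 || cc > 1) abort("contraction coefficient must be in (0, 1]")
  if (recovery_length <= 0) abort("recovery_length must be positive")
  structure(list(rho = rho, mu = mu, cc = cc,
                 recovery_length = recovery_length, expansion_k = expansion_k,
                 jet_wss_gain = jet_wss_gain,
                 sample_noise_frac = sample_noise_frac,
                 outlet_pressure = outlet_pressure,
                 friction = isTRUE(friction)),
            class = "oracle_params")
}

new_profile <- function(case, pressure, wss, flow_rate, source) {
  out <- tibble(
    index = seq_len(nrow(case$centerline)),
    s_mm = case$centerline$s,
    region = case$centerline$region,
    pressure_mmHg = pressure,
    wss_Pa = wss
  )
  attr(out, "flow_rate") <- flow_rate
  attr(out, "source") <- source
  class(out) <- c("hemodynamic_profile", class(out))
  out
}

# internal per-point effective velocities (m/s) and friction factors
oracle_kinematics <- function(case, flow_rate, params) {
  A <- case$centerline$area * 1e-6            # m^2
  if (any(!is.finite(A)) || any(A <= 0)) abort("physics error: non-positive cross-section area")
  Q <- flow_rate * 1e-6                       # m^3/s
  valve <- case$centerline$region == "valve"
  cc_i <- ifelse(valve, params$cc, 1)
  A_eff <- cc_i * A
  v <- Q / A_eff
  D <- 2 * sqrt(A_eff / pi)
  Re <- params$rho * v * D / params$mu
  f <- ifelse(Re < 2300, 64 / Re, 0.316 * Re^(-0.25))
  list(A_eff = A_eff, v = v, D = D, Re = Re, f = f, valve = valve,
       s = case$centerline$s * 1e-3)
}

#' Solve the quasi-1D pressure / WSS profile for a case
#'
#' Marches extended Bernoulli pressure from the inlet along the centerline:
#' reversible dynamic-pressure exchange `0.5 rho (v_in^2 - v_i^2)` minus
#' cumulative irreversible losses, namely Darcy friction (laminar `64/Re`
#' below Re = 2300, Blasius `0.316 Re^-0.25` above) and a Borda-Carnot jet
#' expansion loss `K 0.5 rho (V_vc - V_ds)^2` distributed linearly over the
#' recovery length downstream of the vena contracta. In the valve region the
#' effective jet area is `cc` times the orifice area, so the minimum
#' pressure occurs at the vena contracta. WSS combines the Darcy estimate
#' `(f/8) rho v^2` with an exponentially decaying jet-impingement term
#' downstream of the vena contracta. Pressures are finally shifted so the
#' outlet matches `params$outlet_pressure`.
#'
#' @param case a `case_geometry`.
#' @param flow_rate steady peak-systolic flow rate, ml/s.
#' @param params an [oracle_params()] list.
#' @return a `hemodynamic_profile` tibble: columns `index`, `s_mm`,
#'   `region`, `pressure_mmHg`, `wss_Pa`; attributes `flow_rate` (ml/s) and
#'   `source = "oracle"`.
#' @export
#' @examples
#' case <- build_case(sample_geometry_params(seed = 3))
#' prof <- solve_profile(case, flow_rate = 300)
#' compute_mpd(prof)
solve_profile <- function(case, flow_rate, params = oracle_params()) {
  if (flow_rate <= 0) abort("flow_rate must be positive")
  kin <- oracle_kinematics(case, flow_rate, params)
  v <- kin$v; s <- kin$s; f <- kin$f; D <- kin$D
  n <- length(v)
  rho <- params$rho

  # cumulative Darcy friction loss (trapezoidal in s)
  g <- f / D * 0.5 * rho * v^2                 # Pa per m
  ds <- diff(s)
  loss_f <- c(0, cumsum(0.5 * (g[-n] + g[-1]) * ds))
  if (!params$friction) loss_f <- numeric(n)

  # Borda-Carnot expansion loss after the vena contracta
  loss_bc <- numeric(n)
  jet <- numeric(n)
  if (any(kin$valve)) {
    iv <- which(kin$valve)
    i_vc <- iv[which.min(case$centerline$area[iv])]
    v_vc <- v[i_vc]
    s_vc <- s[i_vc]
    l_rec <- params$recovery_length * 1e-3
    i_rec <- which(s >= s_vc + l_rec & !kin$valve)
    v_ds <- if (length(i_rec)) v[i_rec[1]] else v[n]
    bc_total <- params$expansion_k * 0.5 * rho * (v_vc - v_ds)^2
    # loss accrual: at least as fast as the local jet expansion (so the
    # marched pressure can never overshoot the inlet during re-expansion),
    # with residual mixing losses completing linearly over recovery_length
    frac_lin <- pmin(pmax((s - s_vc) / l_rec, 0), 1)
    denom <- v_vc^2 - v_ds^2
    frac_exp <- if (denom > 0) pmin(pmax((v_vc^2 - v^2) / denom, 0), 1) else 1
    frac_exp[s <= s_vc] <- 0
    loss_bc <- bc_total * pmax(frac_lin, frac_exp)
    jet <- ifelse(s >= s_vc,
                  params$jet_wss_gain * 0.5 * rho * v_vc^2 *
                    exp(-(s - s_vc) / l_rec),
                  0)
  }

  p_pa <- 0.5 * rho * (v[1]^2 - v^2) - loss_f - loss_bc
  wss <- f / 8 * rho * v^2 + jet
  prof <- new_profile(case, pressure = pa_to_mmhg(p_pa), wss = wss,
                      flow_rate = flow_rate, source = "oracle")
  shift_pressure(prof, params$outlet_pressure)
}

#' Shift a pressure profile to a prescribed outlet pressure
#'
#' Adds a constant so the last centerline point matches `outlet_pressure`
#' (130 mmHg by default); pairwise pressure differences are unchanged.
#'
#' @param profile a `hemodynamic_profile`.
#' @param outlet_pressure target pressure at the last point, mmHg.
#' @return the shifted profile.
#' @export
shift_pressure <- function(profile, outlet_pressure = 130) {
  if (nrow(profile) == 0) abort("empty profile")
  profile$pressure_mmHg <- profile$pressure_mmHg +
    (outlet_pressure - profile$pressure_mmHg[nrow(profile)])
  profile
}

#' Maximum pressure drop of a profile
#'
#' Inlet pressure minus the lowest pressure found anywhere within the
#' vessel; used for data filtering (cases above 120 mmHg are considered
#' unphysiological) and stratification.
#'
#' @param profile a `hemodynamic_profile`, or a numeric pressure vector in
#'   mmHg.
#' @return MPD in mmHg (non-negative).
#' @export
compute_mpd <- function(profile) {
  p <- profile_pressure(profile)
  if (length(p) == 0) abort("empty profile")
  p[1] - min(p)
}

#' Transvalvular pressure gradient of a profile
#'
#' Inlet pressure minus the pressure at the point of highest pressure
#' recovery downstream of the minimum-pressure point. Always between 0 and
#' the maximum pressure drop. If the pressure minimum is the last point (no
#' downstream segment), returns inlet minus outlet with a warning.
#'
#' @inheritParams compute_mpd
#' @return TPG in mmHg.
#' @export
compute_tpg <- function(profile) {
  p <- profile_pressure(profile)
  n <- length(p)
  if (n == 0) abort("empty profile")
  i_min <- which.min(p)
  if (i_min == n) {
    warn("pressure minimum at the last point; TPG falls back to inlet - outlet")
    return(p[1] - p[n])
  }
  p[1] - max(p[(i_min + 1):n])
}

profile_pressure <- function(profile) {
  if (is.numeric(profile)) return(profile)
  profile$pressure_mmHg
}

profile_wss <- function(profile) {
  if (is.numeric(profile)) return(profile)
  profile$wss_Pa
}
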