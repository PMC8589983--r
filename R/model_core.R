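#' Firing-rate transfer function of the decision pools
#'
#' The current-to-rate function of the excitatory decision populations,
#' `phi(I) = (c_e*I - i_th) / (1 - exp(-g_e*(c_e*I - i_th)))`, evaluated
#' with a series expansion at the removable singularity `c_e*I = i_th`
#' where the continuous limit is `1/g_e`.
#'
#' @param i synaptic current, nA (vectorised)
#' @param params a [model_parameters()] object
#' @return Firing rate(s), Hz; always non-negative.
#' @examples
#' p <- model_parameters()
#' phi_decision(0.4, p)   # removable singularity: 1/g_e
#' phi_decision(0.5, p)
#' @export
phi_decision <- function(i, params = model_parameters()) {
  if (!length(i) || any(!is.finite(i)))
    stop("phi_decision: input current must be finite", call. = FALSE)
  u <- params$c_e * i - params$i_th
  z <- params$g_e * u
  out <- numeric(length(u))
  small <- abs(z) < 1e-8
  # z/(1 - exp(-z)) = 1 + z/2 + z^2/12 + O(z^4)
  out[small] <- (1 + z[small] / 2 + z[small]^2 / 12) / params$g_e
  if (any(!small)) {
    den <- 1 - exp(-z[!small])
    out[!small] <- u[!small] / den
  }
  pmax(out, 0)
}

#' Firing-rate transfer function of the confidence pool
#'
#' Threshold-linear transfer with a 0.5 Hz spontaneous floor:
#' `max(c_e*I - i_th_c, 0.5)`.
#'
#' @inheritParams phi_decision
#' @return Firing rate(s), Hz; at least 0.5.
#' @examples
#' phi_confidence(0.5, model_parameters())   # 270*0.5 - 108 = 27 Hz
#' @export
phi_confidence <- function(i, params = model_parameters()) {
  if (!length(i) || any(!is.finite(i)))
    stop("phi_confidence: input current must be finite", call. = FALSE)
  pmax(params$c_e * i - params$i_th_c, 0.5)
}

#' Initial network state
#'
#' The quiescent initial condition: all NMDA gating variables at zero,
#' depression resources full (`x = 1`), the adaptation variable at its
#' zero-rate fixed point `tau_a * a_0`, the confidence rate at the floor
#' of its transfer function given background input, and zero noise
#' currents. The pre-stimulus epoch of the protocol then settles the
#' network near its spontaneous equilibrium before stimulus onset.
#'
#' @param params a [model_parameters()] object
#' @param t0 initial time, s
#' @return An object of class `network_state` (a named list).
#' @examples
#' initial_state(model_parameters())
#' @export
initial_state <- function(params = model_parameters(), t0 = -0.2) {
  structure(list(
    s_a = 0, s_b = 0, s_c = 0,
    r_c = phi_confidence(params$i_0c, params),
    a = params$tau_a * params$a_0,
    x = 1,
    i_noise_a = 0, i_noise_b = 0, i_noise_c = 0,
    t = t0
  ), class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(
    "network_state @ t = %.4f s: S = (%.4f, %.4f, %.4f), r_C = %.2f Hz, a = %.4f, x = %.4f\n",
    x$t, x$s_a, x$s_b, x$s_c, x$r_c, x$a, x$x))
  invisible(x)
}

validate_state <- function(state) {
  need <- c("s_a", "s_b", "s_c", "r_c", "a", "x",
            "i_noise_a", "i_noise_b", "i_noise_c", "t")
  miss <- setdiff(need, names(state))
  if (length(miss))
    stop("network state is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (f in need)
    if (!is.numeric(state[[f]]) || length(state[[f]]) != 1L ||
        !is.finite(state[[f]]))
      stop("network state field '", f, "' must be a single finite number",
           call. = FALSE)
  invisible(state)
}

stimulus_active <- function(stimulus, t) {
  !is.null(stimulus) && t >= stimulus$onset_s && t < stimulus$offset_s
}

#' External stimulus currents to the decision pools
#'
#' The biased sensory drive: the preferred pool receives
#' `j_ext * mu_0 * (1 + c/100)` and the other pool
#' `j_ext * mu_0 * (1 - c/100)`. Their sum, `2 * j_ext * mu_0`, is
#' independent of coherence. Epoch gating (stimulus on/off) is the
#' caller's responsibility.
#'
#' @param stimulus a [stimulus_spec()] object
#' @param params a [model_parameters()] object
#' @return Named numeric vector `c(a = , b = )`, nA.
#' @examples
#' external_input(stimulus_spec(51.2, "A"), model_parameters())
#' @export
external_input <- function(stimulus, params = model_parameters()) {
  c <- stimulus$coherence_pct
  if (c > 100) stop("coherence above 100% is not defined", call. = FALSE)
  base <- params$j_ext * params$mu_0
  plus <- base * (1 + c / 100)
  minus <- base * (1 - c / 100)
  if (stimulus$preferred_pool == "A") c(a = plus, b = minus)
  else c(a = minus, b = plus)
}

#' Total synaptic currents of the decision pools
#'
#' `I_syn_i = j_ii*S_i - j_ij*S_j + i_0 + I_ext_i + j_fc*r_C + I_noise_i`
#' for pools `i` in (A, B). The stimulus term is present only while
#' `state$t` lies inside the stimulus epoch (or `stimulus` may be `NULL`
#' for no stimulus).
#'
#' @param state a `network_state`
#' @param stimulus a [stimulus_spec()] or `NULL`
#' @param params a [model_parameters()] object
#' @return Named numeric vector `c(a = , b = )`, nA.
#' @examples
#' decision_currents(initial_state(), NULL, model_parameters())
#' @export
decision_currents <- function(state, stimulus = NULL,
                              params = model_parameters()) {
  validate_state(state)
  i_ext <- if (stimulus_active(stimulus, state$t))
    external_input(stimulus, params) else c(a = 0, b = 0)
  fb <- params$j_fc * state$r_c
  c(a = params$j_ii * state$s_a - params$j_ij * state$s_b + params$i_0 +
      i_ext[["a"]] + fb + state$i_noise_a,
    b = params$j_ii * state$s_b - params$j_ij * state$s_a + params$i_0 +
      i_ext[["b"]] + fb + state$i_noise_b)
}

#' Total synaptic current of the confidence pool
#'
#' Depends on the confidence mechanism:
#' \describe{
#'   \item{adaptation}{`j_c*S_C + j_dc*(r_A + r_B) + i_0c -
#'     j_a*j_a_scale*a + I_noise_C`}
#'   \item{std, feedforward site}{`j_c*S_C + j_dc*(r_A + r_B)*x + i_0c +
#'     I_noise_C` (depression of the decision-to-confidence synapses)}
#'   \item{std, recurrent site}{`j_c*S_C*x + j_dc*(r_A + r_B) + i_0c +
#'     I_noise_C`}
#'   \item{none}{the adaptation formula with `a = 0`}
#' }
#' The decision rates entering `r_in = r_A + r_B` are recomputed from the
#' instantaneous decision currents.
#'
#' @inheritParams decision_currents
#' @return Confidence synaptic current, nA (scalar).
#' @examples
#' confidence_current(initial_state(), NULL, model_parameters())
#' @export
confidence_current <- function(state, stimulus = NULL,
                               params = model_parameters()) {
  i_dec <- decision_currents(state, stimulus, params)
  r_in <- sum(phi_decision(i_dec, params))
  base <- params$i_0c + state$i_noise_c
  switch(params$variant,
    adaptation = params$j_c * state$s_c + params$j_dc * r_in + base -
      params$j_a * params$j_a_scale * state$a,
    std = if (params$std_site == "feedforward")
      params$j_c * state$s_c + params$j_dc * r_in * state$x + base
    else
      params$j_c * state$s_c * state$x + params$j_dc * r_in + base,
    none = params$j_c * state$s_c + params$j_dc * r_in + base,
    stop("unknown variant '", params$variant, "'", call. = FALSE)
  )
}

#' Time derivatives of the circuit state
#'
#' Deterministic part of the model equations, evaluated at the state's own
#' time:
#' \itemize{
#'   \item `dS_i/dt = -S_i/tau_nmda + (1 - S_i) * gamma * r_i` with
#'     `r_i = phi_decision(I_syn_i)` recomputed instantaneously;
#'   \item `dS_C/dt` analogous with `r_C`;
#'   \item `dr_C/dt = (phi_C(I_syn_C) - r_C)/tau_r` (relaxation mode) or
#'     `-r_C/tau_r + phi_C(I_syn_C)` (literal mode);
#'   \item `da/dt = -a/tau_a + a_1*r_C + a_0` (adaptation variant;
#'     0 otherwise);
#'   \item `dx/dt = (1 - x)/tau_d - u_0*u0_scale*x*r_pre` (STD variant;
#'     `r_pre` is `r_A + r_B` for the feedforward depression site and
#'     `r_C` for the recurrent site; 0 otherwise);
#'   \item noise currents carry their Ornstein--Uhlenbeck drift
#'     `-I_noise/noise_tau`; their diffusion is applied by the exact OU
#'     update inside [rk2_step()], never through these derivatives.
#' }
#'
#' @inheritParams decision_currents
#' @return Named numeric vector of derivatives for `s_a, s_b, s_c, r_c, a,
#'   x, i_noise_a, i_noise_b, i_noise_c`, with the instantaneous rates
#'   `r_a`, `r_b` attached as attribute `"rates"`.
#' @examples
#' derivatives(initial_state(), NULL, model_parameters())
#' @export
derivatives <- function(state, stimulus = NULL,
                        params = model_parameters()) {
  validate_state(state)
  i_dec <- decision_currents(state, stimulus, params)
  r_a <- phi_decision(i_dec[["a"]], params)
  r_b <- phi_decision(i_dec[["b"]], params)
  i_c <- confidence_current(state, stimulus, params)
  phi_c <- phi_confidence(i_c, params)

  d <- c(
    s_a = -state$s_a / params$tau_nmda + (1 - state$s_a) * params$gamma * r_a,
    s_b = -state$s_b / params$tau_nmda + (1 - state$s_b) * params$gamma * r_b,
    s_c = -state$s_c / params$tau_nmda +
      (1 - state$s_c) * params$gamma * state$r_c,
    r_c = if (params$rate_eq_mode == "relaxation")
      (phi_c - state$r_c) / params$tau_r
    else
      -state$r_c / params$tau_r + phi_c,
    a = if (params$variant == "adaptation")
      -state$a / params$tau_a + params$a_1 * state$r_c + params$a_0 else 0,
    x = if (params$variant == "std") {
      r_pre <- if (params$std_site == "feedforward") r_a + r_b else state$r_c
      (1 - state$x) / params$tau_d -
        params$u_0 * params$u0_scale * state$x * r_pre
    } else 0,
    i_noise_a = -state$i_noise_a / params$noise_tau,
    i_noise_b = -state$i_noise_b / params$noise_tau,
    i_noise_c = -state$i_noise_c / params$noise_tau
  )
  if (any(is.nan(d)))
    stop("non-finite derivative for state variable(s): ",
         paste(names(d)[is.nan(d)], collapse = ", "), call. = FALSE)
  attr(d, "rates") <- c(r_a = r_a, r_b = r_b)
  d
}

#' One midpoint Runge--Kutta step
#'
#' Advances the state by `params$dt` with the explicit midpoint
#' (second-order Runge--Kutta) method applied to the deterministic part of
#' the dynamics, with the noise currents frozen at their start-of-step
#' values during both stages. The noise currents are then updated with the
#' exact discrete Ornstein--Uhlenbeck transition using the supplied
#' standard-normal increments, so their stationary statistics are
#' independent of `dt`. After the step, NMDA gating variables are clamped
#' to `[0, 1]`, the depression variable to `(0, 1]`, and `r_C` to be
#' non-negative.
#'
#' @inheritParams decision_currents
#' @param noise_increments standard-normal increments for the three noise
#'   currents (A, B, C); `c(0, 0, 0)` gives a noise-free step
#' @return The next `network_state`.
#' @examples
#' st <- initial_state()
#' rk2_step(st, NULL, model_parameters())
#' @export
rk2_step <- function(state, stimulus = NULL, params = model_parameters(),
                     noise_increments = c(0, 0, 0)) {
  validate_state(state)
  dt <- params$dt
  vars <- c("s_a", "s_b", "s_c", "r_c", "a", "x")

  d1 <- derivatives(state, stimulus, params)
  mid <- state
  for (v in vars) mid[[v]] <- state[[v]] + 0.5 * dt * d1[[v]]
  mid$t <- state$t + 0.5 * dt
  d2 <- derivatives(mid, stimulus, params)

  nxt <- state
  for (v in vars) nxt[[v]] <- state[[v]] + dt * d2[[v]]
  nxt$t <- state$t + dt

  # exact OU transition for the noise currents
  decay <- exp(-dt / params$noise_tau)
  diff_sd <- params$noise_sigma * sqrt(1 - decay^2)
  nz <- c("i_noise_a", "i_noise_b", "i_noise_c")
  for (k in seq_along(nz))
    nxt[[nz[k]]] <- state[[nz[k]]] * decay + diff_sd * noise_increments[k]

  nxt$s_a <- min(max(nxt$s_a, 0), 1)
  nxt$s_b <- min(max(nxt$s_b, 0), 1)
  nxt$s_c <- min(max(nxt$s_c, 0), 1)
  nxt$x <- min(max(nxt$x, 1e-12), 1)
  nxt$r_c <- max(nxt$r_c, 0)
  nxt
}

#' Noise-free fixed points of the circuit
#'
#' Finds roots of the deterministic derivative field (noise currents held
#' at zero) with a quasi-Newton root finder, as an independent check on
#' long noise-free integrations.
#'
#' @param params a [model_parameters()] object
#' @param stimulus a [stimulus_spec()] or `NULL`; when supplied the
#'   stimulus is treated as permanently on
#' @param start a `network_state` used as the starting point
#' @return A list with the fixed-point `state`, the residual derivative
#'   norm `fnorm`, and the solver's convergence flag.
#' @examples
#' fp <- find_fixed_point(model_parameters(noise_sigma = 0))
#' fp$fnorm
#' @export
find_fixed_point <- function(params = model_parameters(),
                             stimulus = NULL,
                             start = initial_state(params)) {
  vars <- c("s_a", "s_b", "s_c", "r_c",
            if (params$variant == "adaptation") "a",
            if (params$variant == "std") "x")
  template <- start
  template$i_noise_a <- template$i_noise_b <- template$i_noise_c <- 0
  if (!is.null(stimulus)) # evaluate inside the epoch: stimulus always on
    template$t <- (stimulus$onset_s + stimulus$offset_s) / 2
  fn <- function(y) {
    st <- template
    for (k in seq_along(vars)) st[[vars[k]]] <- unname(y[k])
    unname(derivatives(st, stimulus, params)[vars])
  }
  y0 <- unname(vapply(vars, function(v) template[[v]], numeric(1)))
  sol <- pracma::fsolve(fn, y0, maxiter = 500, tol = 1e-12)
  st <- template
  for (k in seq_along(vars)) st[[vars[k]]] <- sol$x[k]
  list(state = st, fnorm = sqrt(sum(fn(sol$x)^2)),
       converged = sqrt(sum(fn(sol$x)^2)) < 1e-8)
}
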