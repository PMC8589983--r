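#' Model parameters for the decision--confidence circuit
#'
#' Builds the full parameter set of the reduced two-pool attractor decision
#' network and its confidence pool. Defaults are the published constants of
#' the model; any subset can be overridden by name.
#'
#' Units follow the mean-field convention: currents in nA, rates in Hz,
#' times in seconds. The F-I slope `c_e` converts current to rate
#' (`c_e * I` is in Hz when `I` is in nA), so the firing thresholds
#' `i_th` and `i_th_c` are quoted in Hz.
#'
#' Three quantities deserve comment because the printed constants of the
#' model are not dimensionally self-consistent:
#'
#' * `j_ext` (nA/Hz) is the external AMPA coupling. The default
#'   `5.2e-4` is the value of the underlying reduced decision model, for
#'   which the stimulus current `j_ext * mu_0 = 0.0156` nA is a modest
#'   bias on top of the 0.3255 nA background, producing the ramping
#'   activity and reaction-time distributions the circuit is known for.
#'   (A coupling of order 0.1 nA would saturate the F-I function at
#'   stimulus onset and abolish evidence accumulation.)
#' * `j_a_scale` multiplies the adaptation current `j_a * a`. At the
#'   printed magnitudes (`j_a = 0.001`, `a` of order 0.5) the adaptation
#'   current is below 1e-3 nA -- invisible next to the 0.1-0.5 nA
#'   feedforward drive -- so a scale factor is exposed; see the package
#'   vignette for the calibration argument behind the default.
#' * `u0_scale` plays the same role for the release fraction `u_0` of the
#'   short-term-depression variant.
#'
#' Setting `j_a_scale = 1` and `u0_scale = 1` recovers the literal printed
#' magnitudes.
#'
#' @param ... named overrides of any parameter listed below.
#'
#' @section Parameters:
#' \describe{
#'   \item{tau_nmda}{NMDA gating time constant, s (0.1)}
#'   \item{tau_a}{adaptation time constant, s (0.25)}
#'   \item{tau_r}{confidence rate time constant, s (0.002)}
#'   \item{tau_d}{short-term-depression recovery time constant, s (1)}
#'   \item{theta}{decision threshold, Hz (25)}
#'   \item{gamma}{NMDA gain per spike (0.641)}
#'   \item{j_ii, j_ij}{recurrent self-excitation / cross-inhibition, nA
#'     (0.2609, 0.0497)}
#'   \item{j_c}{confidence recurrent strength, nA (0.15)}
#'   \item{j_fc}{confidence-to-decision feedback, nA/Hz (2e-4)}
#'   \item{j_ext}{external coupling, nA/Hz (5.2e-4; see above)}
#'   \item{j_dc}{decision-to-confidence coupling, nA/Hz (0.015)}
#'   \item{j_a}{adaptation gain (0.001)}
#'   \item{j_a_scale}{multiplier on the adaptation current (default 1500;
#'     see above)}
#'   \item{c_e}{F-I slope, Hz/nA-equivalent (270)}
#'   \item{i_th, i_th_c}{F-I thresholds of decision / confidence pools,
#'     Hz (108, 108)}
#'   \item{g_e}{F-I curvature factor, s (0.154)}
#'   \item{a_1}{spike-driven adaptation strength (0.05)}
#'   \item{a_0}{subthreshold adaptation strength (0.03)}
#'   \item{mu_0}{stimulus strength, Hz (30)}
#'   \item{u_0}{STD release fraction (1e-4)}
#'   \item{u0_scale}{multiplier on `u_0` (default 1000, i.e. an effective
#'     release fraction of 0.1; see above)}
#'   \item{std_site}{where depression acts: `"feedforward"` depresses the
#'     decision-to-confidence synapses (default), `"recurrent"` the
#'     confidence recurrent synapses}
#'   \item{i_0, i_0c}{background currents, nA (0.3255, 0.2)}
#'   \item{dt}{integration step, s (5e-5)}
#'   \item{noise_sigma}{stationary SD of the Ornstein--Uhlenbeck noise
#'     currents, nA (0.005)}
#'   \item{noise_tau}{correlation time of the noise currents, s (0.05);
#'     together with `noise_sigma` this puts the model in the
#'     integration-limited regime in which errors arise from slow evidence
#'     fluctuations rather than from noise spikes at the threshold (see
#'     the vignette)}
#'   \item{variant}{confidence mechanism: `"adaptation"`, `"std"` or
#'     `"none"`}
#'   \item{rate_eq_mode}{`"relaxation"` (rate relaxes to the transfer
#'     function with time constant `tau_r`; default) or `"literal"`
#'     (leak plus transfer-function drive as printed in the source
#'     equations, which leaves `r_C` of order `tau_r * phi`)}
#' }
#'
#' @return An object of class `model_parameters` (a named list).
#' @examples
#' p <- model_parameters()
#' p_easy <- model_parameters(theta = 30, variant = "std")
#' @export
model_parameters <- function(...) {
  defaults <- list(
    tau_nmda    = 0.1,
    tau_a       = 0.25,
    tau_r       = 0.002,
    tau_d       = 1.0,
    theta       = 25,
    gamma       = 0.641,
    j_ii        = 0.2609,
    j_ij        = 0.0497,
    j_c         = 0.15,
    j_fc        = 0.0002,
    j_ext       = 5.2e-4,
    j_dc        = 0.015,
    j_a         = 0.001,
    j_a_scale   = 1500,
    c_e         = 270,
    i_th        = 108,
    g_e         = 0.154,
    i_th_c      = 108,
    a_1         = 0.05,
    a_0         = 0.03,
    mu_0        = 30,
    u_0         = 1e-4,
    u0_scale    = 1000,
    std_site    = "feedforward",
    i_0         = 0.3255,
    i_0c        = 0.2,
    dt          = 5e-5,
    noise_sigma = 0.005,
    noise_tau   = 0.05,
    variant     = "adaptation",
    rate_eq_mode = "relaxation"
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("all parameter overrides must be named", call. = FALSE)
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    defaults[names(overrides)] <- overrides
  }
  validate_model_parameters(structure(defaults, class = "model_parameters"))
}

validate_model_parameters <- function(p) {
  num_fields <- setdiff(names(p), c("variant", "rate_eq_mode", "std_site"))
  for (f in num_fields) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number",
           call. = FALSE)
    p[[f]] <- as.numeric(v)
  }
  pos <- c("tau_nmda", "tau_a", "tau_r", "tau_d", "dt", "gamma", "c_e",
           "theta", "g_e", "noise_tau")
  for (f in pos)
    if (p[[f]] <= 0)
      stop("parameter '", f, "' must be strictly positive", call. = FALSE)
  if (p$u_0 <= 0 || p$u_0 > 1)
    stop("parameter 'u_0' must lie in (0, 1]", call. = FALSE)
  if (p$noise_sigma < 0)
    stop("parameter 'noise_sigma' must be non-negative", call. = FALSE)
  if (p$j_a_scale < 0 || p$u0_scale < 0)
    stop("scale factors must be non-negative", call. = FALSE)
  p$variant <- match.arg(p$variant, c("adaptation", "std", "none"))
  p$rate_eq_mode <- match.arg(p$rate_eq_mode, c("relaxation", "literal"))
  p$std_site <- match.arg(p$std_site, c("feedforward", "recurrent"))
  p
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Decision--confidence circuit parameters\n")
  cat("  variant:", x$variant, "| rate equation:", x$rate_eq_mode, "\n")
  cat("  threshold:", x$theta, "Hz | dt:", x$dt * 1e3, "ms | noise sd:",
      x$noise_sigma, "nA\n")
  nm <- setdiff(names(x), c("variant", "rate_eq_mode", "std_site"))
  vals <- vapply(nm, function(f) format(x[[f]]), character(1))
  cat("  ", paste0(nm, " = ", vals, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Reaction-time trial protocol
#'
#' Timing of a single reaction-time trial. Time zero is stimulus onset;
#' the network receives only background input during the pre-stimulus
#' epoch and the biased stimulus during `[stim_onset, stim_offset)`.
#' A decision is the first sample after stimulus onset at which either
#' decision pool reaches the threshold; crossings are accepted up to
#' `detect_until` (decisions can occur shortly after stimulus offset
#' because the NMDA dynamics are slow).
#'
#' @param t_start trial start, s (default -0.2)
#' @param stim_onset stimulus onset, s (default 0)
#' @param stim_offset stimulus offset, s (default 1)
#' @param t_end trial end, s (default 1.5)
#' @param rc_window confidence-averaging window before the decision, s
#'   (default 0.010)
#' @param detect_until latest time at which a threshold crossing counts as
#'   a decision, s (default `t_end`)
#' @return An object of class `trial_protocol`.
#' @examples
#' trial_protocol()
#' @export
trial_protocol <- function(t_start = -0.2, stim_onset = 0, stim_offset = 1,
                           t_end = 1.5, rc_window = 0.010,
                           detect_until = t_end) {
  p <- list(t_start = t_start, stim_onset = stim_onset,
            stim_offset = stim_offset, t_end = t_end,
            rc_window = rc_window, detect_until = detect_until)
  for (f in names(p))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]))
      stop("protocol field '", f, "' must be a single finite number",
           call. = FALSE)
  if (!(p$t_start < p$stim_onset && p$stim_onset < p$stim_offset &&
        p$stim_offset <= p$detect_until && p$detect_until <= p$t_end))
    stop("protocol must satisfy t_start < stim_onset < stim_offset <= ",
         "detect_until <= t_end", call. = FALSE)
  if (p$rc_window <= 0)
    stop("rc_window must be positive", call. = FALSE)
  structure(p, class = "trial_protocol")
}

#' @export
print.trial_protocol <- function(x, ...) {
  cat("Reaction-time trial protocol (s): start", x$t_start,
      "| stimulus [", x$stim_onset, ",", x$stim_offset,
      ") | end", x$t_end, "| detect until", x$detect_until,
      "| rc window", x$rc_window, "\n")
  invisible(x)
}

#' Stimulus specification
#'
#' A motion stimulus of coherence `coherence_pct` percent favouring
#' `preferred_pool`. The preferred pool receives
#' `j_ext * mu_0 * (1 + c/100)` and the anti-preferred pool
#' `j_ext * mu_0 * (1 - c/100)` during the stimulus epoch.
#'
#' @param coherence_pct coherence in percent, in `[0, 100]`
#' @param preferred_pool `"A"` or `"B"`
#' @param onset_s,offset_s stimulus epoch bounds, s
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec(12.8, "A")
#' @export
stimulus_spec <- function(coherence_pct, preferred_pool = "A",
                          onset_s = 0, offset_s = 1) {
  if (!is.numeric(coherence_pct) || length(coherence_pct) != 1L ||
      !is.finite(coherence_pct) || coherence_pct < 0)
    stop("coherence_pct must be a single finite number >= 0", call. = FALSE)
  if (coherence_pct > 100)
    stop("coherence_pct must not exceed 100", call. = FALSE)
  preferred_pool <- match.arg(preferred_pool, c("A", "B"))
  if (!(onset_s < offset_s))
    stop("onset_s must be earlier than offset_s", call. = FALSE)
  structure(list(coherence_pct = coherence_pct,
                 preferred_pool = preferred_pool,
                 onset_s = onset_s, offset_s = offset_s),
            class = "stimulus_spec")
}

#' Experiment plan
#'
#' Layout of a multi-session experiment. Within each session, trials cycle
#' through the coherence levels in order and the preferred pool alternates
#' between successive cycles, so coherences and sides are balanced to
#' within one trial. Sessions differ only by their random-number streams;
#' they are the resampling unit for standard errors.
#'
#' @param coherences coherence levels in percent (default the canonical
#'   random-dot ladder `c(0, 3.2, 6.4, 12.8, 25.6, 51.2)`)
#' @param trials_per_session trials per session (default 500)
#' @param n_sessions number of sessions (default 10)
#' @param master_seed master seed from which every per-trial seed is
#'   derived (default 1)
#' @param variant confidence mechanism (default "adaptation")
#' @param sweep_a0,sweep_a1 optional grids of subthreshold / spike-driven
#'   adaptation strengths for [run_sweep()]
#' @param sweep_trials_per_session,sweep_n_sessions per-cell experiment
#'   size used by [run_sweep()] (defaults 100 and 1)
#' @return An object of class `experiment_plan`.
#' @examples
#' experiment_plan(trials_per_session = 10, n_sessions = 2)
#' @export
experiment_plan <- function(coherences = c(0, 3.2, 6.4, 12.8, 25.6, 51.2),
                            trials_per_session = 500, n_sessions = 10,
                            master_seed = 1,
                            variant = c("adaptation", "std", "none"),
                            sweep_a0 = NULL, sweep_a1 = NULL,
                            sweep_trials_per_session = 100,
                            sweep_n_sessions = 1) {
  variant <- match.arg(variant)
  if (!length(coherences) || any(!is.finite(coherences)) ||
      any(coherences < 0 | coherences > 100))
    stop("coherences must be a non-empty vector within [0, 100]",
         call. = FALSE)
  for (f in c("trials_per_session", "n_sessions", "master_seed",
              "sweep_trials_per_session", "sweep_n_sessions")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != round(v))
      stop("'", f, "' must be a positive integer", call. = FALSE)
  }
  structure(list(coherences = as.numeric(coherences),
                 trials_per_session = as.integer(trials_per_session),
                 n_sessions = as.integer(n_sessions),
                 master_seed = as.integer(master_seed),
                 variant = variant,
                 sweep_a0 = sweep_a0, sweep_a1 = sweep_a1,
                 sweep_trials_per_session = as.integer(sweep_trials_per_session),
                 sweep_n_sessions = as.integer(sweep_n_sessions)),
            class = "experiment_plan")
}

#' Per-trial seed derivation
#'
#' Deterministic counter scheme mapping (master seed, session, trial, sweep
#' cell) to the seed of one trial's noise stream. Seeds are congruential
#' combinations reduced modulo a Mersenne prime below 2^31 so that distinct
#' counters map to distinct streams for any experiment of realistic size.
#'
#' @param master_seed integer master seed
#' @param session_id,trial_id 1-based session and trial counters
#' @param cell_id 0-based sweep-cell counter (0 outside sweeps)
#' @return A single integer seed.
#' @examples
#' trial_seed(1, 1, 1)
#' @export
trial_seed <- function(master_seed, session_id, trial_id, cell_id = 0) {
  m <- 2147483629
  s <- (as.numeric(master_seed) %% m)
  s <- (s * 69069 + 101 + as.numeric(cell_id)) %% m
  s <- (s * 69069 + as.numeric(session_id)) %% m
  s <- (s * 69069 + as.numeric(trial_id)) %% m
  as.integer(s)
}
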