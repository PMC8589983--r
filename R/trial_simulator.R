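#' Simulate one reaction-time trial
#'
#' Integrates the circuit from `protocol$t_start` to `protocol$t_end` with
#' the midpoint Runge--Kutta scheme of [rk2_step()] (a compiled
#' implementation of the identical scheme), applying the biased stimulus
#' during `[stim_onset, stim_offset)`. The decision is the first threshold
#' crossing detected by [detect_decision()]; at the decision time four
#' confidence readouts are computed over the `rc_window` preceding it:
#' the confidence-pool rate `rc`, the summed decision rates `rc_sum`, the
#' absolute decision-rate difference `rc_absdiff`, and the total synaptic
#' input to the decision module `rc_totalinput`.
#'
#' All randomness comes from the standard-normal Ornstein--Uhlenbeck
#' increments drawn from `seed`, so a trial is reproducible bit-exactly
#' from `(params, protocol, stimulus, seed)`.
#'
#' @param params a [model_parameters()] object
#' @param protocol a [trial_protocol()] object
#' @param stimulus a [stimulus_spec()] object
#' @param seed non-negative integer seed for this trial's noise stream
#' @param keep_traces keep the full state traces in the result
#'   (default `FALSE`)
#' @param point_readout compute the auxiliary readouts at the decision
#'   sample only instead of averaging over `rc_window` (default `FALSE`)
#' @return An object of class `trial_result`: a list with `choice`
#'   (`"A"`, `"B"` or `"none"`), `correct`, `decision_time_s` (seconds from
#'   stimulus onset, `NA` if no decision), the four readouts, and `seed`.
#'   With `keep_traces = TRUE` a `traces` data frame is attached.
#' @examples
#' p <- model_parameters()
#' tr <- run_trial(p, trial_protocol(), stimulus_spec(51.2, "A"), seed = 7)
#' tr$choice
#' @export
run_trial <- function(params, protocol, stimulus, seed,
                      keep_traces = FALSE, point_readout = FALSE) {
  stopifnot(inherits(params, "model_parameters"),
            inherits(protocol, "trial_protocol"),
            inherits(stimulus, "stimulus_spec"))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed < 0 || seed != round(seed))
    stop("seed must be a single non-negative integer", call. = FALSE)

  n_steps <- round((protocol$t_end - protocol$t_start) / params$dt)
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(3 * n_steps), nrow = 3)

  init <- initial_state(params, t0 = protocol$t_start)
  sim <- simulate_trial_cpp(
    unclass(params), protocol$t_start, protocol$t_end,
    stimulus$onset_s, stimulus$offset_s,
    stimulus$coherence_pct, as.integer(stimulus$preferred_pool == "B"),
    z, keep_traces, unclass(init))

  dec <- detect_decision(sim$r_a, sim$r_b, protocol, theta = params$theta,
                         t = sim$t)
  res <- list(
    coherence_pct = stimulus$coherence_pct,
    preferred_pool = stimulus$preferred_pool,
    choice = dec$choice,
    correct = if (dec$choice == "none") NA
              else dec$choice == stimulus$preferred_pool,
    decision_time_s = if (dec$choice == "none") NA_real_
                      else dec$time - protocol$stim_onset,
    rc = NA_real_, rc_sum = NA_real_, rc_absdiff = NA_real_,
    rc_totalinput = NA_real_,
    seed = as.integer(seed)
  )
  if (dec$choice != "none") {
    res$rc <- readout_confidence(sim$r_c, dec$time, protocol, t = sim$t)
    win <- function(v) window_mean(v, sim$t, dec$time, protocol,
                                   point = point_readout)
    res$rc_sum <- win(sim$r_a + sim$r_b)
    res$rc_absdiff <- win(abs(sim$r_a - sim$r_b))
    res$rc_totalinput <- win(sim$i_a + sim$i_b)
  }
  if (keep_traces)
    res$traces <- data.frame(t = sim$t, r_a = sim$r_a, r_b = sim$r_b,
                             r_c = sim$r_c, i_a = sim$i_a, i_b = sim$i_b,
                             s_a = sim$s_a, s_b = sim$s_b, s_c = sim$s_c,
                             a = sim$a, x = sim$x)
  structure(res, class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf(
    "trial: c = %.1f%% (pref %s) -> choice %s%s", x$coherence_pct,
    x$preferred_pool, x$choice,
    if (x$choice == "none") "\n"
    else sprintf(" (%s) at %.0f ms, rc = %.1f Hz\n",
                 if (isTRUE(x$correct)) "correct" else "error",
                 1e3 * x$decision_time_s, x$rc)))
  invisible(x)
}

#' Detect the decision from the decision-pool rate traces
#'
#' The decision is the first sample time strictly after stimulus onset at
#' which `max(r_A, r_B)` reaches the threshold `theta`; the choice is the
#' pool crossing. Crossings are accepted up to `protocol$detect_until`.
#' If both pools reach threshold at the same sample, the pool with the
#' larger rate wins; an exact rate tie goes to pool A.
#'
#' @param r_a,r_b decision-pool rate traces, Hz, sampled on the trial grid
#' @param protocol a [trial_protocol()] object
#' @param theta decision threshold, Hz (default 25)
#' @param t sample times; defaults to the protocol grid at steps of
#'   `dt_default`
#' @param dt_default grid step used when `t` is missing, s
#' @return A list with `choice` (`"A"`, `"B"` or `"none"`) and `time`
#'   (absolute trial time of the crossing sample, `NA` if none).
#' @examples
#' pr <- trial_protocol()
#' t <- seq(pr$t_start, pr$t_end, by = 1e-3)
#' ramp <- pmax(0, 50 * (t - pr$stim_onset))
#' detect_decision(ramp, rep(1, length(t)), pr, t = t)
#' @export
detect_decision <- function(r_a, r_b, protocol, theta = 25, t = NULL,
                            dt_default = 5e-5) {
  if (length(r_a) != length(r_b))
    stop("rate traces must have equal length", call. = FALSE)
  if (is.null(t))
    t <- protocol$t_start + (seq_along(r_a) - 1L) * dt_default
  eligible <- t > protocol$stim_onset & t <= protocol$detect_until
  hit <- eligible & (pmax(r_a, r_b) >= theta)
  k <- which(hit)
  if (!length(k)) return(list(choice = "none", time = NA_real_))
  k <- k[1L]
  choice <- if (r_a[k] > r_b[k]) "A"
            else if (r_b[k] > r_a[k]) "B"
            else if (r_a[k] >= theta) "A" else "B"
  # both >= theta with equal rates falls through to "A" above
  if (r_a[k] < theta && r_b[k] >= theta) choice <- "B"
  if (r_b[k] < theta && r_a[k] >= theta) choice <- "A"
  list(choice = choice, time = t[k])
}

window_mean <- function(v, t, decision_time, protocol, point = FALSE) {
  if (decision_time < t[1L])
    stop("decision time precedes the trace", call. = FALSE)
  if (point) {
    k <- which.min(abs(t - decision_time))
    return(v[k])
  }
  lo <- max(decision_time - protocol$rc_window, protocol$stim_onset)
  sel <- t >= lo - 1e-12 & t <= decision_time + 1e-12
  mean(v[sel])
}

#' Confidence readout at the decision time
#'
#' The model's confidence report: the mean confidence-pool rate over the
#' `rc_window` (10 ms by default) preceding the decision. When the
#' decision falls within `rc_window` of stimulus onset the window is
#' clipped at onset.
#'
#' @param r_c confidence-pool rate trace, Hz
#' @param decision_time absolute trial time of the decision sample, s
#' @param protocol a [trial_protocol()] object
#' @param t sample times; defaults to the protocol grid at `dt_default`
#' @param dt_default grid step used when `t` is missing, s
#' @return Mean rate over the window, Hz.
#' @examples
#' pr <- trial_protocol()
#' t <- seq(pr$t_start, pr$t_end, by = 1e-3)
#' readout_confidence(rep(10, length(t)), 0.5, pr, t = t)
#' @export
readout_confidence <- function(r_c, decision_time, protocol, t = NULL,
                               dt_default = 5e-5) {
  if (is.null(t))
    t <- protocol$t_start + (seq_along(r_c) - 1L) * dt_default
  window_mean(r_c, t, decision_time, protocol)
}

#' Run a multi-session experiment
#'
#' Runs `plan$n_sessions` sessions of `plan$trials_per_session` trials.
#' Within a session, trials cycle through `plan$coherences` in order and
#' the preferred pool alternates between successive cycles (A on even
#' cycles, B on odd), so sides and coherences are balanced to within one
#' trial. Each trial's noise seed comes from [trial_seed()], so the whole
#' table is reproducible bit-exactly from the plan. Trials in which no
#' pool reaches threshold are retained with `choice = "none"` and missing
#' readouts.
#'
#' @param plan an [experiment_plan()] object
#' @param params a [model_parameters()] object; its `variant` is
#'   overridden by `plan$variant`
#' @param protocol a [trial_protocol()] object
#' @param cell_id 0-based sweep-cell index entering the seed derivation
#'   (0 outside sweeps)
#' @param verbose print per-session progress
#' @return A `trial_table` data frame with one row per trial and columns
#'   `session_id, trial_id, coherence_pct, preferred_pool, choice,
#'   correct, decision_time_s, rc, rc_sum, rc_absdiff, rc_totalinput,
#'   seed`.
#' @examples
#' plan <- experiment_plan(coherences = c(0, 51.2),
#'                         trials_per_session = 2, n_sessions = 1)
#' run_experiment(plan, model_parameters(), trial_protocol())
#' @export
run_experiment <- function(plan, params = model_parameters(),
                           protocol = trial_protocol(), cell_id = 0,
                           verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  params$variant <- plan$variant
  params <- validate_model_parameters(params)
  n_coh <- length(plan$coherences)
  n <- plan$n_sessions * plan$trials_per_session
  rows <- vector("list", n)
  k <- 0L
  for (s in seq_len(plan$n_sessions)) {
    no_dec <- 0L
    for (tr in seq_len(plan$trials_per_session)) {
      coh <- plan$coherences[((tr - 1L) %% n_coh) + 1L]
      cycle <- (tr - 1L) %/% n_coh
      pref <- if (cycle %% 2L == 0L) "A" else "B"
      stim <- stimulus_spec(coh, pref, protocol$stim_onset,
                            protocol$stim_offset)
      seed <- trial_seed(plan$master_seed, s, tr, cell_id)
      res <- tryCatch(
        run_trial(params, protocol, stim, seed),
        error = function(e)
          stop("trial failed (session ", s, ", trial ", tr, "): ",
               conditionMessage(e), call. = FALSE))
      if (res$choice == "none") no_dec <- no_dec + 1L
      k <- k + 1L
      rows[[k]] <- data.frame(
        session_id = s, trial_id = tr, coherence_pct = coh,
        preferred_pool = pref, choice = res$choice, correct = res$correct,
        decision_time_s = res$decision_time_s, rc = res$rc,
        rc_sum = res$rc_sum, rc_absdiff = res$rc_absdiff,
        rc_totalinput = res$rc_totalinput, seed = res$seed,
        stringsAsFactors = FALSE)
    }
    if (verbose)
      message(sprintf("session %d/%d done (%d/%d undecided)", s,
                      plan$n_sessions, no_dec, plan$trials_per_session))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Sweep the adaptation parameters
#'
#' Runs one scaled-down experiment per cell of the `(a_0, a_1)` grid given
#' by `plan$sweep_a0` and `plan$sweep_a1` (row-major: `a_0` is the outer
#' loop, `a_1` the inner). Each cell uses `plan$sweep_trials_per_session`
#' and `plan$sweep_n_sessions`, and a seed stream derived from the master
#' seed and the cell index, so cells are independent and reproducible.
#' Per-cell mean confidence by coherence is reduced to relative confidence
#' ([relative_rc()]) and a coding slope ([coding_slope()]).
#'
#' @inheritParams run_experiment
#' @return An object of class `sweep_result`: a list with `cells` (long
#'   data frame: `a_0, a_1, coherence_pct, mean_rc, relative_rc, n`) and
#'   `slopes` (`a_0, a_1, slope` in Hz per percent coherence).
#' @examples
#' plan <- experiment_plan(coherences = c(0, 51.2), sweep_a0 = 0.03,
#'                         sweep_a1 = 0.05, sweep_trials_per_session = 4)
#' \donttest{run_sweep(plan, model_parameters(), trial_protocol())}
#' @export
run_sweep <- function(plan, params = model_parameters(),
                      protocol = trial_protocol(), verbose = FALSE) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (is.null(plan$sweep_a0) || is.null(plan$sweep_a1) ||
      !length(plan$sweep_a0) || !length(plan$sweep_a1))
    stop("plan must carry non-empty sweep_a0 and sweep_a1 grids",
         call. = FALSE)
  cell_plan <- plan
  cell_plan$trials_per_session <- plan$sweep_trials_per_session
  cell_plan$n_sessions <- plan$sweep_n_sessions
  cells <- list(); slopes <- list()
  cell_id <- 0L
  for (a0 in plan$sweep_a0) {
    for (a1 in plan$sweep_a1) {
      pcell <- params
      pcell$a_0 <- a0
      pcell$a_1 <- a1
      tab <- run_experiment(cell_plan, pcell, protocol, cell_id = cell_id,
                            verbose = FALSE)
      dec <- tab[tab$choice != "none", , drop = FALSE]
      agg <- stats::aggregate(rc ~ coherence_pct, data = dec, FUN = mean)
      agg <- agg[order(agg$coherence_pct), ]
      nn <- as.vector(table(factor(dec$coherence_pct,
                                   levels = agg$coherence_pct)))
      rel <- relative_rc(agg$rc, agg$coherence_pct)
      sl <- coding_slope(rel, agg$coherence_pct)
      cells[[length(cells) + 1L]] <- data.frame(
        a_0 = a0, a_1 = a1, coherence_pct = agg$coherence_pct,
        mean_rc = agg$rc, relative_rc = rel, n = nn)
      slopes[[length(slopes) + 1L]] <- data.frame(a_0 = a0, a_1 = a1,
                                                  slope = sl)
      cell_id <- cell_id + 1L
      if (verbose)
        message(sprintf("sweep cell a_0 = %g, a_1 = %g: slope = %.4f",
                        a0, a1, sl))
    }
  }
  structure(list(cells = do.call(rbind, cells),
                 slopes = do.call(rbind, slopes),
                 a0_grid = plan$sweep_a0, a1_grid = plan$sweep_a1),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Adaptation-parameter sweep:", length(x$a0_grid), "x",
      length(x$a1_grid), "grid\n")
  print(x$slopes, row.names = FALSE)
  invisible(x)
}

#' Verify the threshold contract on simulated trials
#'
#' Re-runs trials with full traces and checks, for every decided trial,
#' that the winning pool's firing rate at the detected decision sample is
#' at or above the threshold and was below it at the preceding sample --
#' i.e. that detected decisions are genuine first crossings.
#'
#' @param params a [model_parameters()] object
#' @param protocol a [trial_protocol()] object
#' @param coherence_pct coherence of the probe trials, percent
#' @param n number of trials
#' @param master_seed seed from which the per-trial seeds are derived
#' @return A data frame with one row per trial: `seed`, `decided`,
#'   `rate_at_decision`, `rate_before`, and `ok` (the contract holds;
#'   `NA` for undecided trials).
#' @export
verify_threshold_contract <- function(params = model_parameters(),
                                      protocol = trial_protocol(),
                                      coherence_pct = 25.6, n = 200,
                                      master_seed = 1) {
  rows <- lapply(seq_len(n), function(i) {
    pref <- if (i %% 2L) "A" else "B"
    stim <- stimulus_spec(coherence_pct, pref, protocol$stim_onset,
                          protocol$stim_offset)
    seed <- trial_seed(master_seed, 1, i)
    tr <- run_trial(params, protocol, stim, seed, keep_traces = TRUE)
    if (tr$choice == "none")
      return(data.frame(seed = seed, decided = FALSE,
                        rate_at_decision = NA_real_,
                        rate_before = NA_real_, ok = NA))
    tt <- tr$traces
    t_dec <- tr$decision_time_s + protocol$stim_onset
    k <- which.min(abs(tt$t - t_dec))
    win <- if (tr$choice == "A") tt$r_a else tt$r_b
    data.frame(seed = seed, decided = TRUE,
               rate_at_decision = win[k], rate_before = win[k - 1L],
               ok = win[k] >= params$theta & win[k - 1L] < params$theta)
  })
  do.call(rbind, rows)
}
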