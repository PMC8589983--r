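# Expensive experiments are computed once per test session and shared
# between the behavioural property tests and the acceptance tests.
.run_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .run_cache, inherits = FALSE))
    assign(name, maker(), envir = .run_cache)
  get(name, envir = .run_cache, inherits = FALSE)
}

# the default experiment: adaptation variant, 10 sessions x 500 trials
default_run <- function() cached("default_run", function() {
  run_experiment(experiment_plan(master_seed = 1), model_parameters(),
                 trial_protocol())
})

# the same experiment under the short-term-depression variant
std_run <- function() cached("std_run", function() {
  run_experiment(experiment_plan(master_seed = 1, variant = "std"),
                 model_parameters(), trial_protocol())
})

# a small synthetic trial table with known structure, for analysis tests
make_table <- function(session_id, coherence_pct, correct, rc,
                       choice = NULL) {
  n <- max(length(session_id), length(coherence_pct), length(correct),
           length(rc))
  tab <- data.frame(
    session_id = rep_len(session_id, n),
    trial_id = seq_len(n),
    coherence_pct = rep_len(coherence_pct, n),
    preferred_pool = "A",
    choice = if (is.null(choice)) "A" else rep_len(choice, n),
    correct = rep_len(correct, n),
    decision_time_s = 0.5,
    rc = rep_len(rc, n),
    rc_sum = rep_len(rc, n) + 1,
    rc_absdiff = rep_len(rc, n) / 2,
    rc_totalinput = rep_len(rc, n) / 100,
    seed = seq_len(n),
    stringsAsFactors = FALSE)
  class(tab) <- c("trial_table", "data.frame")
  tab
}
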