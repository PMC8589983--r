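p0 <- model_parameters()

test_that("decision transfer function matches closed-form values", {
  # removable singularity c_e*I = i_th: limit is 1/g_e
  expect_equal(phi_decision(0.4, p0), 1 / 0.154, tolerance = 1e-10)
  # continuity across the singularity
  expect_equal(phi_decision(0.4 + 1e-9 / 270, p0),
               phi_decision(0.4, p0), tolerance = 1e-6)
  expect_equal(phi_decision(0.4 - 1e-9 / 270, p0),
               phi_decision(0.4, p0), tolerance = 1e-6)
  expect_equal(phi_decision(0.5, p0), 27 / (1 - exp(-0.154 * 27)),
               tolerance = 1e-12)
  # deeply subthreshold input: indistinguishable from zero
  expect_lt(phi_decision(0, p0), 1e-4)
  expect_true(all(phi_decision(seq(-1, 2, by = 0.01), p0) >= 0))
  expect_error(phi_decision(NA_real_, p0), "finite")
  expect_error(phi_decision(Inf, p0), "finite")
})

test_that("confidence transfer function is threshold-linear with a floor", {
  expect_equal(phi_confidence(0, p0), 0.5)
  expect_equal(phi_confidence(0.4, p0), 0.5)   # 270*0.4 - 108 = 0 < 0.5
  expect_equal(phi_confidence(0.5, p0), 27)
  expect_true(all(phi_confidence(seq(-1, 2, by = 0.01), p0) >= 0.5))
  expect_error(phi_confidence(NaN, p0), "finite")
})

test_that("external input splits the stimulus by coherence and conserves the total", {
  # spec'd arithmetic at the printed table coupling
  p_tab <- model_parameters(j_ext = 0.15, mu_0 = 30)
  expect_equal(unname(external_input(stimulus_spec(0, "A"), p_tab)),
               c(4.5, 4.5))
  expect_equal(unname(external_input(stimulus_spec(100, "A"), p_tab)),
               c(9, 0))
  expect_equal(unname(external_input(stimulus_spec(100, "B"), p_tab)),
               c(0, 9))
  # sum conservation for any coherence, default coupling
  for (cc in c(0, 3.2, 12.8, 51.2, 77.7, 100)) {
    ei <- external_input(stimulus_spec(cc, "A"), p0)
    expect_equal(sum(ei), 2 * p0$j_ext * p0$mu_0, tolerance = 1e-14)
  }
  expect_error(stimulus_spec(101, "A"), "100")
})

test_that("decision currents follow the circuit wiring and A/B symmetry", {
  st <- initial_state(p0)
  st$r_c <- 0
  ic <- decision_currents(st, NULL, p0)
  expect_equal(unname(ic), c(0.3255, 0.3255))
  st1 <- st; st1$s_a <- 1
  ic1 <- decision_currents(st1, NULL, p0)
  expect_equal(ic1[["a"]], 0.3255 + 0.2609)
  expect_equal(ic1[["b"]], 0.3255 - 0.0497)
  # swapping the gating variables swaps the currents
  st2 <- st1; st2$s_a <- st1$s_b; st2$s_b <- st1$s_a
  ic2 <- decision_currents(st2, NULL, p0)
  expect_equal(ic2[["a"]], ic1[["b"]])
  expect_equal(ic2[["b"]], ic1[["a"]])
})

test_that("confidence current depends on the variant as wired", {
  st <- initial_state(p0)
  st[c("s_a", "s_b", "s_c", "r_c", "a")] <- 0
  # zero state, full resources, STD variant: only the background survives
  p_std <- model_parameters(variant = "std")
  st_std <- st; st_std$x <- 1
  # decision pools at zero gating still fire phi(I_0) ~ 1 Hz; suppress via i_0
  p_quiet <- model_parameters(variant = "std", i_0 = -1)
  expect_equal(confidence_current(st_std, NULL, p_quiet), 0.2,
               tolerance = 1e-9)
  # r_a = r_b = 10 Hz worth of feedforward drive: 0.015*20 + 0.2 = 0.5 nA
  # (construct currents giving exactly 10 Hz through the transfer function)
  i_10 <- uniroot(function(i) phi_decision(i, p0) - 10, c(0.3, 0.6),
                  tol = 1e-14)$root
  st10 <- st
  st10$i_noise_a <- i_10 - p0$i_0
  st10$i_noise_b <- i_10 - p0$i_0
  expect_equal(confidence_current(st10, NULL, p0), 0.015 * 20 + 0.2,
               tolerance = 1e-6)
  # adaptation with a = 0 equals variant "none"
  p_none <- model_parameters(variant = "none")
  expect_equal(confidence_current(st10, NULL, p_none),
               confidence_current(st10, NULL, p0), tolerance = 1e-12)
  p_bad <- p0; p_bad$variant <- "bogus"
  expect_error(confidence_current(st10, NULL, p_bad), "variant")
})

test_that("derivative fixed points match their closed forms", {
  # adaptation: a_inf = tau_a * (A_1 r_C + A_0); at r_C = 0, 0.25*0.03
  st <- initial_state(p0)
  st$r_c <- 0; st$a <- p0$tau_a * p0$a_0
  d <- derivatives(st, NULL, p0)
  expect_equal(d[["a"]], 0, tolerance = 1e-12)
  expect_equal(p0$tau_a * p0$a_0, 0.0075)
  st$r_c <- 13; st$a <- p0$tau_a * (p0$a_1 * 13 + p0$a_0)
  expect_equal(derivatives(st, NULL, p0)[["a"]], 0, tolerance = 1e-12)
  # STD: x_inf = 1 / (1 + U_eff * tau_d * r_pre), recurrent site uses r_C
  p_std <- model_parameters(variant = "std", std_site = "recurrent")
  u_eff <- p_std$u_0 * p_std$u0_scale
  st2 <- initial_state(p_std)
  st2$r_c <- 20; st2$x <- 1 / (1 + u_eff * p_std$tau_d * 20)
  expect_equal(derivatives(st2, NULL, p_std)[["x"]], 0, tolerance = 1e-12)
  st2$r_c <- 0; st2$x <- 1
  expect_equal(derivatives(st2, NULL, p_std)[["x"]], 0, tolerance = 1e-12)
  # NMDA gating: S_inf = gamma r tau / (1 + gamma r tau) when r is fixed
  r <- 7.3
  s_inf <- p0$gamma * r * p0$tau_nmda / (1 + p0$gamma * r * p0$tau_nmda)
  st3 <- initial_state(p0)
  st3$s_c <- s_inf; st3$r_c <- r
  expect_equal(derivatives(st3, NULL, p0)[["s_c"]], 0, tolerance = 1e-12)
  st_bad <- initial_state(p0); st_bad$s_a <- NA_real_
  expect_error(derivatives(st_bad, NULL, p0), "s_a")
})

test_that("a noise-free fixed point is preserved by the integrator", {
  p <- model_parameters(noise_sigma = 0)
  fp <- suppressWarnings(find_fixed_point(p))
  expect_true(fp$converged)
  nxt <- rk2_step(fp$state, NULL, p)
  for (v in c("s_a", "s_b", "s_c", "r_c", "a", "x"))
    expect_equal(nxt[[v]], fp$state[[v]], tolerance = 1e-12)
})

test_that("gating variables stay bounded and rates non-negative over random steps", {
  set.seed(99)
  p <- model_parameters()
  stim <- stimulus_spec(25.6, "A", 0, 1)
  st <- initial_state(p, t0 = 0.5)
  for (i in 1:2000) {
    # random kicks emulate worst-case states between steps
    if (i %% 50 == 0) {
      st$s_a <- runif(1, -0.05, 1.05); st$s_b <- runif(1, -0.05, 1.05)
      st$s_c <- runif(1, -0.05, 1.05); st$r_c <- runif(1, 0, 120)
      st$a <- runif(1, 0, 1); st$x <- runif(1, 0.01, 1)
      st$s_a <- min(max(st$s_a, 0), 1); st$s_b <- min(max(st$s_b, 0), 1)
      st$s_c <- min(max(st$s_c, 0), 1)
      st$t <- runif(1, 0, 0.9)
    }
    st <- rk2_step(st, stim, p, rnorm(3))
    expect_true(st$s_a >= 0 && st$s_a <= 1)
    expect_true(st$s_b >= 0 && st$s_b <= 1)
    expect_true(st$s_c >= 0 && st$s_c <= 1)
    expect_true(st$x > 0 && st$x <= 1)
    expect_true(st$r_c >= 0)
  }
})

test_that("integrator clamps an overshooting gating variable", {
  p <- model_parameters(noise_sigma = 0)
  st <- initial_state(p)
  st$s_a <- 1
  st$i_noise_a <- 2   # huge drive -> large rate -> (1-S) term still >= 0
  nxt <- rk2_step(st, NULL, p)
  expect_lte(nxt$s_a, 1)
})

test_that("compiled trial integrator reproduces the reference stepper", {
  p <- model_parameters()
  n <- 300
  set.seed(3)
  z <- matrix(rnorm(3 * n), nrow = 3)
  # stimulus on for the whole segment: epoch gating at a grid-interior
  # boundary is exercised elsewhere, at full-trial tolerances
  stim <- stimulus_spec(25.6, "A", -0.25, 1)
  st <- initial_state(p, -0.2)
  sim <- confcircuit:::simulate_trial_cpp(unclass(p), -0.2, -0.2 + n * p$dt, -0.25, 1,
                            25.6, 0L, z, TRUE, unclass(st))
  for (k in seq_len(n)) st <- rk2_step(st, stim, p, z[, k])
  kk <- n + 1
  expect_equal(st$s_a, sim$s_a[kk], tolerance = 1e-8)
  expect_equal(st$s_b, sim$s_b[kk], tolerance = 1e-8)
  expect_equal(st$r_c, sim$r_c[kk], tolerance = 1e-6)
  expect_equal(st$a, sim$a[kk], tolerance = 1e-8)
  expect_equal(st$i_noise_a, sim$i_noise_a[kk], tolerance = 1e-12)
})

test_that("relabelling the pools with exchanged noise mirrors the trajectory exactly", {
  p <- model_parameters()
  pr <- trial_protocol()
  n <- round((pr$t_end - pr$t_start) / p$dt)
  set.seed(7)
  z <- matrix(rnorm(3 * n), nrow = 3)
  zs <- z[c(2, 1, 3), ]
  init <- unclass(initial_state(p, pr$t_start))
  simA <- confcircuit:::simulate_trial_cpp(unclass(p), pr$t_start, pr$t_end, 0, 1,
                             12.8, 0L, z, FALSE, init)
  simB <- confcircuit:::simulate_trial_cpp(unclass(p), pr$t_start, pr$t_end, 0, 1,
                             12.8, 1L, zs, FALSE, init)
  expect_identical(simA$r_a, simB$r_b)
  expect_identical(simA$r_b, simB$r_a)
  expect_identical(simA$r_c, simB$r_c)
})

test_that("noise-free trajectories converge at second order in dt", {
  pr <- trial_protocol(t_start = -0.1, stim_onset = 0, stim_offset = 0.4,
                      t_end = 0.4, detect_until = 0.4)
  endstate <- function(dt) {
    # i_0c raised so the confidence transfer stays off its floor kink
    p <- model_parameters(noise_sigma = 0, i_0c = 0.5, dt = dt)
    tr <- run_trial(p, pr, stimulus_spec(51.2, "A"), seed = 1,
                    keep_traces = TRUE)
    tt <- tr$traces
    unlist(tt[nrow(tt), c("s_a", "s_b", "s_c", "r_c", "a")])
  }
  e1 <- endstate(5e-5); e2 <- endstate(2.5e-5); e4 <- endstate(1.25e-5)
  order <- log2(max(abs(e1 - e2)) / max(abs(e2 - e4)))
  expect_gt(order, 1.6)
  expect_lt(order, 2.4)
})

test_that("noise-free endpoints land on independently root-found fixed points", {
  vars <- c("s_a", "s_b", "s_c", "r_c", "a", "x")
  settle <- function(p, coh, t_settle) {
    pr <- trial_protocol(t_start = -0.2, stim_onset = t_settle,
                         stim_offset = t_settle + 0.5,
                         t_end = t_settle + 0.5)
    stim_probe <- stimulus_spec(0, "A", t_settle, t_settle + 0.5)
    fstim <- NULL
    if (!is.null(coh)) {
      pr <- trial_protocol(t_start = -0.2, stim_onset = 0,
                           stim_offset = t_settle, t_end = t_settle)
      stim_probe <- stimulus_spec(coh, "A", 0, t_settle)
      fstim <- stimulus_spec(coh, "A", 0, 2 * t_settle)
    }
    tr <- run_trial(p, pr, stim_probe, seed = 1, keep_traces = TRUE)
    tt <- tr$traces
    k <- max(which(tt$t <= t_settle - 0.001))
    st <- initial_state(p)
    for (v in vars) st[[v]] <- tt[k, v]
    fp <- suppressWarnings(find_fixed_point(p, stimulus = fstim,
                                            start = st))
    expect_true(fp$converged)
    expect_lt(max(abs(unlist(st[vars]) - unlist(fp$state[vars]))), 1e-6)
  }
  settle(model_parameters(noise_sigma = 0), NULL, 5)
  settle(model_parameters(noise_sigma = 0, variant = "none"), NULL, 5)
  settle(model_parameters(noise_sigma = 0, variant = "std"), NULL, 12)
  # sustained-stimulus equilibria (the adaptation variant instead settles
  # into a slow adaptation limit cycle under a clamped stimulus)
  settle(model_parameters(noise_sigma = 0, variant = "none"), 51.2, 5)
  settle(model_parameters(noise_sigma = 0, variant = "std"), 51.2, 12)
})

test_that("parameter validation rejects bad values and unknown names", {
  expect_error(model_parameters(thetta = 30), "thetta")
  expect_error(model_parameters(tau_nmda = -1), "positive")
  expect_error(model_parameters(u_0 = 0), "u_0")
  expect_error(model_parameters(variant = "foo"))
  expect_equal(model_parameters(theta = 30)$theta, 30)
  # table constants are the defaults
  expect_equal(p0$tau_nmda, 0.1)
  expect_equal(p0$j_ii, 0.2609)
  expect_equal(p0$j_ij, 0.0497)
  expect_equal(p0$i_0, 0.3255)
  expect_equal(p0$gamma, 0.641)
  expect_equal(p0$u_0, 1e-4)
  expect_equal(p0$dt, 5e-5)
})
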