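test_that("delay1_step follows the first-order update and keeps its fixed point", {
  expect_equal(delay1_step(0, 8, delay_time = 5, dt = 1), 1.6)
  expect_equal(delay1_step(8, 8, delay_time = 3, dt = 0.25), 8)
  # one-step convergence when dt equals the time constant
  expect_equal(delay1_step(0, 2, delay_time = 0.5, dt = 0.5), 2)
  expect_error(delay1_step(0, 1, delay_time = 0, dt = 1), "delay_time")
  expect_error(delay1_step(0, 1, delay_time = 1, dt = -1), "dt")
})

test_that("delay initialisation honours its policy, including the dt-dependent default", {
  expect_equal(delay1_init(list(delay_time = 5, init_policy = "zero"), 8), 0)
  expect_equal(delay1_init(list(delay_time = 5, init_policy = "equilibrium"), 8), 8)
  expect_equal(delay1_init(list(delay_time = 5, init_policy = "explicit",
                                init_value = 3.5), 8), 3.5)
  # default: zero for slow delays, equilibrium for sub-step delays
  expect_equal(delay1_init(list(delay_time = 5, init_policy = "default"), 8, dt = 1), 0)
  expect_equal(delay1_init(list(delay_time = 0.5, init_policy = "default"), 8, dt = 1), 8)
  expect_equal(delay1_init(list(delay_time = 0.5, init_policy = "default"), 8, dt = 0.5), 0)
})

test_that("a model with all-zero inputs stays identically zero", {
  m <- sd_scale_inputs(japan_pricing_model(), 0)
  traj <- sd_simulate(m, sd_config(t_end = 20))
  expect_true(all(traj$values == 0))
})

test_that("equilibrium initialisation gives stationary algebra and an exactly linear stock", {
  m <- japan_pricing_model()
  traj <- sd_simulate(m, sd_config(), init_policy = "equilibrium")
  flow <- sd_series(traj, "new drug pricing decision variation")
  expect_equal(flow, rep(106.425, 51), tolerance = 1e-12)
  # every auxiliary series constant in time
  aux <- names(traj$kinds)[traj$kinds == "auxiliary"]
  spans <- apply(traj$values[, aux], 2, function(x) diff(range(x)))
  expect_true(all(spans == 0))
  stock <- sd_series(traj, "new drug pricing decision evaluation")
  expect_equal(stock, traj$times * 106.425, tolerance = 1e-12)
  expect_equal(stock[51], 5321.25, tolerance = 1e-9)
})

test_that("default initialisation converges onto the flow asymptote", {
  traj <- sd_simulate(japan_pricing_model(), sd_config())
  flow <- sd_series(traj, "new drug pricing decision variation")
  expect_lt(abs(flow[51] / 106.425 - 1), 0.001)
  expect_true(all(diff(flow) >= 0))
})

test_that("delay output follows its geometric closed form and integrates to input * T", {
  for (case in list(list(T = 5, dt = 1), list(T = 4, dt = 0.5),
                    list(T = 2.5, dt = 0.25))) {
    m <- single_delay_model(input = 8, delay_time = case$T)
    cfg <- sd_config(t_end = 40 * case$T, dt = case$dt)
    traj <- sd_simulate(m, cfg)
    out <- sd_series(traj, "out")
    n <- seq_along(out) - 1
    expect_equal(out, 8 - 8 * (1 - case$dt / case$T)^n, tolerance = 1e-12)
    # integrated deficit: sum (input - out) dt -> input * T, any dt < 2T
    deficit <- sum((8 - out) * case$dt)
    expect_equal(deficit, 8 * case$T, tolerance = 1e-6)
  }
})

test_that("trajectories scale linearly with all constant inputs", {
  for (seed in 1:20) {
    m <- generate_fixture_model(seed, n_constants = 3, n_auxiliaries = 4,
                                n_delays = 2)
    cfg <- sd_config(t_end = 20)
    base <- sd_simulate(m, cfg)
    lam <- 1 + seed / 7
    scaled <- sd_simulate(sd_scale_inputs(m, lam), cfg)
    expect_equal(scaled$values, lam * base$values, tolerance = 1e-12)
  }
})

test_that("asymptotics agree with long simulations and reject stock dependencies", {
  asym <- sd_asymptotics(japan_pricing_model())
  traj <- sd_simulate(japan_pricing_model(), sd_config(t_end = 100))
  for (v in c("value premium", "rare disease drug",
              "new drug pricing decision variation")) {
    expect_lt(abs(sd_at(traj, v, 100) / asym[[v]] - 1), 1e-6)
  }
  expect_false("new drug pricing decision evaluation" %in% names(asym))

  # delay-free model: asymptote equals a single dependency-ordered evaluation
  m <- toy_chain_model()
  a <- sd_asymptotics(m)
  expect_equal(unname(a[c("c", "b", "a")]), c(2, 3, 6))

  feedback <- sd_model(sd_aux("a", sd_ref("s", 0.1)),
                       sd_stock("s", inflow = "a", initial = 1))
  expect_error(sd_asymptotics(feedback), "depends on stock")
})

test_that("non-finite intermediates abort with the variable named", {
  m <- sd_model(sd_constant("huge", 1e308),
                sd_aux("blow", sd_ref("huge"), sd_ref("huge")),
                sd_stock("s", inflow = "blow"))
  expect_error(sd_simulate(m, sd_config(t_end = 2)), "'blow'")
})

test_that("save grid always includes both endpoints and honours save_every", {
  traj <- sd_simulate(toy_chain_model(), sd_config(t_end = 10, save_every = 4L))
  expect_equal(traj$times, c(0, 4, 8, 10))
  expect_error(sd_at(traj, "a", 3), "save grid")
  expect_equal(sd_at(traj, "b", 0), 3)
  expect_error(sd_series(traj, "nope"), "unknown variable")
})

test_that("simulation configs reject non-divisible horizons and bad steps", {
  expect_error(sd_config(t_end = 50, dt = 0.7), "positive integer")
  expect_error(sd_config(dt = 0), "positive")
  expect_error(sd_config(t_end = -1), "exceed")
  expect_error(sd_config(save_every = 0), "save_every")
})
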