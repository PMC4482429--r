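test_that("the pressure profile has a plateau, a linear shoulder and a cycle", {
  cfg <- sim_config(pressure_intensity = 2, pressure_plateau_radius = 5,
                    pressure_falloff_radius = 15, pressure_half_period = 2L)
  on_tick <- 1   # cycles start in the 'on' phase
  off_tick <- 3
  expect_equal(pressure_at(0, on_tick, cfg), 2)
  expect_equal(pressure_at(5, on_tick, cfg), 2)
  # forced by the linear decay: midpoint of the shoulder is half intensity
  expect_equal(pressure_at(10, on_tick, cfg), 1)
  expect_equal(pressure_at(20, on_tick, cfg), 0)
  expect_equal(pressure_at(c(0, 7, 30), off_tick, cfg), c(0, 0, 0))
  # explicit schedules override the alternating cycle
  cfg2 <- sim_config(pressure_intensity = 2, pressure_on_ticks = 1:12)
  expect_true(pressure_phase_on(12, cfg2))
  expect_false(pressure_phase_on(13, cfg2))
  # gaussian shoulder is monotone decreasing beyond the plateau
  cfg3 <- sim_config(pressure_profile = "gaussian", pressure_intensity = 1,
                     pressure_plateau_radius = 5, pressure_falloff_radius = 15)
  v <- pressure_at(seq(5, 25, by = 1), 1, cfg3)
  expect_true(all(diff(v) <= 0))
})

test_that("vessels constrict monotonically to full occlusion", {
  cfg <- sim_config(pressure_constriction_coeff = 1)
  expect_equal(constrict_vessels(1.2, 0, cfg), 1.2)
  expect_equal(constrict_vessels(1.2, 1, cfg), 0)     # p >= 1/c occludes
  expect_equal(constrict_vessels(1.2, 5, cfg), 0)     # clamped, never negative
  p <- seq(0, 1.2, by = 0.05)
  sizes <- constrict_vessels(rep(1, length(p)), p, cfg)
  expect_true(all(diff(sizes) <= 0))
})

test_that("vessel oxygen release follows size ratio and conserves bookkeeping", {
  cfg <- tiny_config()
  st <- init_state(cfg, 2)
  rel <- vessel_oxygen_release(st, cfg)
  expect_equal(rel, cfg$oxygen_production_rate * st$vessels$current_size /
                 mean(st$vessels$base_size))
  st$vessels$current_size[] <- 0
  expect_equal(sum(vessel_oxygen_release(st, cfg)), 0)

  # engine bookkeeping: with transport and sinks off, each tick adds exactly
  # the summed per-vessel release to the oxygen layer
  cfg2 <- tiny_config(oxygen_consumption_rate = 0,
                      oxygen_degradation_rate = 0,
                      oxygen_diffusion_fraction = 0,
                      recruitment_rate_N = 0, recruitment_rate_M = 0,
                      pressure_intensity = 0)
  st2 <- init_state(cfg2, 2)
  tot0 <- sum(st2$layers$oxygen)
  out <- step_sim(st2, cfg2, 1, record = FALSE)
  expect_equal(sum(out$layers$oxygen) - tot0,
               sum(vessel_oxygen_release(st2, cfg2)), tolerance = 1e-9)
})

test_that("the ischemia rule penalises below threshold and heals at or above", {
  cfg <- sim_config()
  thr <- cfg$oxygen_ischemia_threshold
  # exactly at threshold counts as perfused (boundary convention)
  r <- tissue_cell_update(life = 90, oxygen = thr + cfg$oxygen_consumption_rate,
                          config = cfg)
  expect_equal(r$life, 90 + cfg$heal_rate * cfg$oxygen_sensitivity)
  expect_equal(r$oxidase, 0)
  # below threshold: oxidase accumulates and life drops
  r2 <- tissue_cell_update(life = 90, oxygen = 0, config = cfg)
  expect_equal(r2$oxidase, cfg$oxidase_accumulation_rate)
  expect_equal(r2$life, 90 - cfg$ischemia_penalty * cfg$oxygen_sensitivity)
  # zero oxygen sensitivity removes the oxygen term entirely
  cfg0 <- config_update(cfg, "oxygen_sensitivity", 0)
  expect_equal(tissue_cell_update(life = 90, oxygen = 0, config = cfg0)$life, 90)
  expect_equal(tissue_cell_update(life = 90, oxygen = 99, config = cfg0)$life, 90)
})

test_that("reperfusion converts stored oxidase to a proportional ROS burst", {
  cfg <- sim_config(reperfusion_conversion_fraction = 1)
  o2 <- cfg$oxygen_ischemia_threshold + cfg$oxygen_consumption_rate
  r0 <- tissue_cell_update(life = 90, oxidase = 0, oxygen = o2, config = cfg)
  expect_equal(r0$ros_add, 0)
  r <- tissue_cell_update(life = 90, oxidase = 4, oxygen = o2, config = cfg)
  expect_equal(r$ros_add, cfg$reperfusion_ros_coeff * 4)
  expect_equal(r$oxidase, 0)   # full conversion on the reperfused tick
  # longer ischemia (more stored oxidase) gives a larger burst
  bursts <- vapply(1:6, function(q)
    tissue_cell_update(life = 90, oxidase = q, oxygen = o2,
                       config = cfg)$ros_add, numeric(1))
  expect_true(all(diff(bursts) > 0))
  # fractional conversion leaves the remainder stored
  cfg2 <- sim_config(reperfusion_conversion_fraction = 0.25)
  r2 <- tissue_cell_update(life = 90, oxidase = 4, oxygen = o2, config = cfg2)
  expect_equal(r2$oxidase, 3)
})

test_that("ROS injures stepwise through the insult counter", {
  cfg <- sim_config(ros_insult_limit = 3L, ros_insult_penalty = 9,
                    ros_event_threshold = 1, tnf_sensitivity = 0)
  o2 <- cfg$oxygen_ischemia_threshold + cfg$oxygen_consumption_rate
  # below threshold: no insults ever
  r <- tissue_cell_update(life = 50, insults = 0L, oxygen = o2, ros = 0.5,
                          config = cfg)
  expect_equal(r$insults, 0)
  # three above-threshold exposures: penalty lands exactly on the third
  life <- 50; ins <- 0L
  for (k in 1:3) {
    r <- tissue_cell_update(life = life, insults = ins, oxygen = o2, ros = 2,
                            config = cfg)
    life <- r$life; ins <- r$insults
  }
  expect_equal(ins, 0)
  expect_equal(life, 50 + 3 * cfg$heal_rate - 9)
  # ros_sensitivity = 0 disables ROS damage entirely
  cfg0 <- config_update(cfg, "ros_sensitivity", 0)
  r0 <- tissue_cell_update(life = 50, insults = 2L, oxygen = o2, ros = 100,
                           config = cfg0)
  expect_equal(r0$insults, 2)
})

test_that("ischemia-only pressure causes damage that does not grow after release", {
  cfg <- sim_config(grid_width = 40L, grid_height = 40L,
                    pressure_on_ticks = 1:12, reperfusion_ros_coeff = 0)
  tr <- run_sim(cfg, seed = 1, n_ticks = 150)
  d <- tr[["total-damage"]]
  expect_gt(max(d), 0)
  expect_lt(which.max(d), 20)          # damage peaks during/just after ischemia
  expect_true(all(diff(d[20:150]) <= 1e-9))  # no further damage after release
})

test_that("shorter pressure cycles ulcerate earlier at fixed ischemic time", {
  ulc <- vapply(c(2L, 6L, 12L), function(h) {
    cfg <- sim_config(grid_width = 50L, grid_height = 50L,
                      pressure_half_period = h)
    mean(vapply(1:2, function(s)
      as.numeric(attr(run_sim(cfg, seed = s, n_ticks = 900),
                      "ulceration_tick")), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ulc) > 0))
  # fewer reperfusion events (longest cycles) accumulate more overall damage
  dmg <- vapply(c(2L, 12L), function(h) {
    cfg <- sim_config(grid_width = 50L, grid_height = 50L,
                      pressure_half_period = h)
    run_sim(cfg, seed = 1, n_ticks = 900)[["total-damage"]][900]
  }, numeric(1))
  expect_gt(dmg[2], dmg[1])
})
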