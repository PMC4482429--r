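test_that("TNF damages and TGF heals tissue additively, with clamping", {
  cfg <- sim_config(tnf_damage_coeff = 0.5, tgf_heal_coeff = 0.25,
                    tnf_damage_saturation = 100)
  o2 <- cfg$oxygen_ischemia_threshold + cfg$oxygen_consumption_rate
  heal <- cfg$heal_rate
  # at full health with no mediators, clamping holds life at 100
  expect_equal(tissue_cell_update(life = 100, oxygen = o2, config = cfg)$life,
               100)
  # equal and opposite contributions cancel
  r <- tissue_cell_update(life = 80, oxygen = o2, tnf = 1, tgf = 2,
                          config = cfg)
  expect_equal(r$life, 80 + heal)
  # tnf_sensitivity = 0 makes TNF inert
  cfg0 <- config_update(cfg, "tnf_sensitivity", 0)
  r0 <- tissue_cell_update(life = 80, oxygen = o2, tnf = 50, config = cfg0)
  expect_equal(r0$life, 80 + heal)
  # the damage term saturates at tnf_damage_saturation
  cfgS <- sim_config(tnf_damage_coeff = 0.5, tnf_damage_saturation = 2)
  rA <- tissue_cell_update(life = 80, oxygen = o2, tnf = 2, config = cfgS)
  rB <- tissue_cell_update(life = 80, oxygen = o2, tnf = 200, config = cfgS)
  expect_equal(rA$life, rB$life)
  # life hitting zero kills the cell
  rD <- tissue_cell_update(life = 0.1, oxygen = o2, tnf = 10, config = cfg)
  expect_true(rD$died)
  expect_equal(rD$life, 0)
})

test_that("stressed cells release DAMPs scaled by the life drop", {
  cfg <- sim_config(damp_secretion_rate = 200, tnf_damage_coeff = 1,
                    tnf_damage_saturation = 100, heal_rate = 0)
  o2 <- cfg$oxygen_ischemia_threshold + cfg$oxygen_consumption_rate
  # rising or flat life releases nothing
  r <- tissue_cell_update(life = 80, oxygen = o2, config = sim_config())
  expect_equal(r$damp_add, 0)
  # a drop of 10 releases rate * 10/100
  r2 <- tissue_cell_update(life = 80, oxygen = o2, tnf = 10, config = cfg)
  expect_equal(80 - r2$life, 10)
  expect_equal(r2$damp_add, 200 * 10 / 100)
  # the alternative stress convention: any damaged cell releases
  cfgB <- config_update(cfg, "stress_mode", "below_max")
  rB <- tissue_cell_update(life = 80, oxygen = o2,
                           config = config_update(sim_config(),
                                                  "stress_mode", "below_max"))
  expect_gt(rB$damp_add, 0)
})

test_that("chemotaxis follows the gradient, breaks ties fairly, wanders blind", {
  # strict gradient: deterministic argmax
  expect_equal(chemotax_choice(c(0, 0, 0, 0, 0, 0, 0, 5), floor = 0.1), 8)
  # all-zero field: uniform over the 8 neighbours
  picks <- vapply(1:4000, function(s)
    chemotax_choice(rep(0, 8), floor = 0.1, seed = s), integer(1))
  expect_gt(chisq.test(table(factor(picks, levels = 1:8)))$p.value, 0.001)
  # all-equal positive field above the floor: uniform among the 8 ties
  picks2 <- vapply(1:4000, function(s)
    chemotax_choice(rep(3, 8), floor = 0.1, seed = s), integer(1))
  expect_gt(chisq.test(table(factor(picks2, levels = 1:8)))$p.value, 0.001)
  expect_equal(sort(unique(picks2)), 1:8)
})

test_that("neutrophils activate by DAMP threshold with the configured probability", {
  cfg <- inert_config(p_activate_N = 1, thr_damp_activate_N = 10,
                      neutrophil_activated_lifespan_bonus = 25L,
                      damp_degradation_rate = 0, damp_diffusion_fraction = 0)
  st <- init_state(cfg, 1)
  st <- place_leukocyte(st, kind = 1, state = 0, x = 10, y = 10)
  # below threshold: stays resting with probability 1
  st_lo <- set_layer(st, "damp", 5)
  out <- step_sim(st_lo, cfg, 1, record = FALSE)
  expect_equal(leuko_df(out)$state, 0L)
  # above threshold with p = 1: activates and gains lifespan
  st_hi <- set_layer(st, "damp", 50)
  out2 <- step_sim(st_hi, cfg, 1, record = FALSE)
  lk <- leuko_df(out2)
  expect_equal(lk$state, 1L)
  expect_equal(lk$lifespan, 1000L + 25L)
  # activated neutrophils secrete TNF at their site
  expect_equal(sum(out2$layers$tnf > 0), 1)
  # activation frequency tracks p_activate_N (Monte-Carlo vs Bernoulli)
  cfg3 <- config_update(cfg, "p_activate_N", 0.3)
  st3 <- set_layer(st, "damp", 50)
  for (k in 1:80) st3 <- place_leukocyte(st3, 1, 0, x = (k %% 18) + 1,
                                         y = (k %/% 18) * 4 + 1)
  hits <- 0; n <- 0
  for (s in 1:15) {
    st4 <- reseed_state(st3, s)
    o <- step_sim(st4, cfg3, 1, record = FALSE)
    hits <- hits + sum(leuko_df(o)$state == 1L)
    n <- n + nrow(leuko_df(o))
  }
  expect_gt(binom.test(hits, n, 0.3)$p.value, 0.001)
})

test_that("badly damaged adjacent tissue activates neutrophils directly", {
  cfg <- inert_config(p_activate_N = 1, thr_direct_damage_activation = 60,
                      o2_activation_threshold = 0)
  st <- init_state(cfg, 1)
  st$life[11, 11] <- 30    # damage 70 > 60
  st <- place_leukocyte(st, 1, 0, x = 10, y = 10)  # 0-based neighbour
  out <- step_sim(st, cfg, 1, record = FALSE)
  expect_equal(leuko_df(out)$state, 1L)
  # contact activation needs an oxygenated site
  cfg2 <- config_update(cfg, "o2_activation_threshold", 99)
  out2 <- step_sim(st, cfg2, 1, record = FALSE)
  expect_equal(leuko_df(out2)$state, 0L)
})

test_that("macrophages polarise by mediator thresholds and are reversible", {
  cfg <- inert_config(p_switch_M1 = 1, p_switch_M2 = 1,
                      thr_tnf_to_M1 = 1, thr_il1_to_M1 = 2, thr_il1_to_M2 = 6,
                      thr_tgf_to_M2 = 4,
                      tnf_degradation_rate = 0, il1_degradation_rate = 0,
                      tgf_degradation_rate = 0, tnf_diffusion_fraction = 0,
                      il1_diffusion_fraction = 0, tgf_diffusion_fraction = 0)
  base <- init_state(cfg, 1)
  base <- place_leukocyte(base, 2, 0, x = 10, y = 10)
  # all mediators below threshold: unchanged
  out <- step_sim(base, cfg, 1, record = FALSE)
  expect_equal(leuko_df(out)$state, 0L)
  # TNF above threshold: resting -> M1, which secretes IL-1
  out1 <- step_sim(set_layer(base, "tnf", 2), cfg, 1, record = FALSE)
  expect_equal(leuko_df(out1)$state, 1L)
  expect_gt(sum(out1$layers$il1), 0)
  # IL-1 just above the higher threshold targets M2, not M1
  out2 <- step_sim(set_layer(base, "il1", 6.5), cfg, 1, record = FALSE)
  expect_equal(leuko_df(out2)$state, 2L)
  # M2 secretes TGF
  expect_gt(sum(out2$layers$tgf), 0)
  # reversibility: an M2 in a high-TNF, low-TGF neighbourhood flips to M1
  stM2 <- place_leukocyte(init_state(cfg, 1), 2, 2, x = 10, y = 10)
  out3 <- step_sim(set_layer(stM2, "tnf", 5), cfg, 1, record = FALSE)
  expect_equal(leuko_df(out3)$state, 1L)
})

test_that("recruitment scales with vessel patency and lifespans are in range", {
  # occluded vessels and zero rates recruit nothing
  cfg0 <- tiny_config(recruitment_rate_N = 0, recruitment_rate_M = 0)
  st <- init_state(cfg0, 1)
  out <- step_sim(st, cfg0, 30, record = FALSE)
  expect_equal(length(out$leukocytes$kind), 0)

  cfg1 <- tiny_config(pressure_intensity = 1, pressure_half_period = 0L,
                      pressure_plateau_radius = 50,
                      pressure_falloff_radius = 50)
  st1 <- init_state(cfg1, 1)
  out1 <- step_sim(st1, cfg1, 10, record = FALSE)  # fully occluded everywhere
  expect_equal(length(out1$leukocytes$kind), 0)

  # expected standing population ~ rate * n_vessels * mean lifespan
  cfg2 <- tiny_config(pressure_intensity = 0, recruitment_rate_N = 0.2,
                      recruitment_rate_M = 0)
  st2 <- init_state(cfg2, 2)
  out2 <- step_sim(st2, cfg2, 400, record = TRUE)
  nv <- length(st2$vessels$x)
  expected <- 0.2 * nv * 15   # rate x vessels x mean resting lifespan
  lk <- leuko_df(out2$state)
  expect_gt(nrow(lk), 0.5 * expected)
  expect_lt(nrow(lk), 1.6 * expected)
  expect_true(all(lk$lifespan >= 10 & lk$lifespan <= 20))
  expect_true(all(lk$kind == 1L))
})

test_that("acute runs show neutrophil-then-M1-then-M2 sequencing; resolving runs clear neutrophils early", {
  cfg <- config_acute(0.3, grid_width = 50L, grid_height = 50L)
  first_at <- function(v, k = 2) { i <- which(v >= k); if (length(i)) i[1] else NA }
  n_ulc <- 0; n_res <- 0
  for (s in 1:8) {
    tr <- run_sim(cfg, seed = s, n_ticks = 600)
    if (is.na(attr(tr, "ulceration_tick"))) {
      n_res <- n_res + 1
      last_active <- max(c(0, which(tr[["activated-neutrophils"]] > 0)))
      expect_lt(last_active, 0.5 * 600)
    } else {
      n_ulc <- n_ulc + 1
      tN <- first_at(tr[["activated-neutrophils"]])
      tM1 <- first_at(tr[["m1-count"]])
      tM2 <- first_at(tr[["m2-count"]])
      expect_true(tN < tM1 && tM1 < tM2)
    }
  }
  expect_gt(n_ulc, 0)
  expect_gt(n_res, 0)
})

test_that("raising the M2-induction threshold increases tissue damage", {
  dmg <- vapply(c(4, 6, 10), function(v) {
    cfg <- config_acute(0.35, grid_width = 50L, grid_height = 50L,
                        thr_il1_to_M2 = v)
    mean(vapply(1:10, function(s)
      run_sim(cfg, seed = s, n_ticks = 600)[["total-damage"]][600],
      numeric(1)))
  }, numeric(1))
  expect_gt(cor(c(4, 6, 10), dmg, method = "spearman"), 0)
})
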