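make_state <- function(wg, e, ww, stage, er = 0, wo = 0,
                       post_puberty = FALSE) {
  structure(list(t = 0, wg = wg, e = e, ww = ww, er = er, wo = wo,
                 stage = as.integer(stage), post_puberty = post_puberty,
                 starving = FALSE), class = "deb_state")
}

test_that("an empty reserve mobilizes nothing", {
  p <- deb_params()
  fl <- compute_fluxes(make_state(1, 0, 10, 5), p, 25)
  expect_equal(fl$pC, 0)
  expect_equal(fl$pG, 0)
  expect_equal(fl$pR, 0)
  expect_gt(fl$pA, 0)
})

test_that("fluxes match the closed forms at the reference temperature", {
  p <- deb_params()
  # assimilation at WG = 1 g, c = 1: f * pAm
  fl <- compute_fluxes(make_state(1, 1000, 10, 5), p, 25)
  expect_equal(fl$pA, 0.9 * 4590)
  expect_equal(fl$pS, 310)
  # mobilization at full reserve density, kappa = 1 (stage <= VII)
  s <- make_state(1, p$Em, 10, 5)
  fl2 <- compute_fluxes(s, p, 25)
  pC_hand <- 3860 * (51180 * (4590 / 3860) + 310) / (51180 + 3860)
  expect_equal(fl2$pC, pC_hand)
  expect_equal(fl2$pG, pC_hand - 310)
  expect_equal(fl2$pR, 0)
  # at or above Em assimilation is clamped to mobilization
  expect_equal(fl2$pA, min(0.9 * 4590, pC_hand))
})

test_that("gonad demand is zero before stage VIII, at saturation, or dry", {
  p <- deb_params()
  expect_equal(gonad_demand(make_state(5, 1e4, 50, 6, er = 1e5), p)$pO, 0)
  # saturation: mG = mGm
  wo_sat <- p$mGm * 5 / p$cO
  gd <- gonad_demand(make_state(5, 1e4, 50, 9, er = 1e5, wo = wo_sat), p)
  expect_equal(gd$demand, 0)
  # supply-limited: empty buffer
  gd2 <- gonad_demand(make_state(5, 1e4, 50, 9, er = 0), p)
  expect_equal(gd2$dwo, 0)
  # otherwise positive, priced at EBO before puberty and EAO after
  gd3 <- gonad_demand(make_state(5, 1e4, 50, 9, er = 1e5), p)
  expect_gt(gd3$pO, 0)
  expect_equal(gd3$price, p$EBO)
  gd4 <- gonad_demand(make_state(5, 1e4, 50, 11, er = 1e5,
                                 post_puberty = TRUE), p)
  expect_equal(gd4$price, p$EAO)
})

test_that("the molt trigger fires at the stage threshold and rescales Ww", {
  p <- deb_params()
  # stage VIII, alpha_pre = 0.19: WC = 10 g on Ww = 50 g gives alpha = 0.2
  s <- make_state(7.9, 2.1 * p$muE, 50, 8)
  res <- check_molt(s, p)
  expect_false(is.null(res$event))
  expect_equal(res$state$ww, 100)            # WC / alpha_post
  expect_equal(res$state$stage, 9L)
  expect_equal(res$event$alpha_at_trigger, 0.2)
  expect_identical(state_alpha(res$state, p), p$alpha_post)  # exact reset
  expect_equal(state_wc(res$state, p), 10)   # WC conserved across the molt

  # just below threshold: alpha = 0.189, nothing happens
  s2 <- make_state(0.189 * 50 * p$beta, 0.189 * 50 * (1 - p$beta) * p$muE,
                   50, 8)
  res2 <- check_molt(s2, p)
  expect_null(res2$event)
  expect_identical(res2$state, s2)

  # tie rule: alpha exactly at the threshold molts
  s3 <- make_state(0.19 * 50, 0, 50, 8)
  expect_false(is.null(check_molt(s3, p)$event))
})

test_that("the stage-XI molt is terminal and sets post_puberty", {
  p <- deb_params()
  s <- make_state(0.16 * 100, 0, 100, 11)
  res <- check_molt(s, p)
  expect_true(res$state$post_puberty)
  expect_equal(res$state$stage, 11L)
  # no further molting once post-puberty
  s2 <- res$state
  s2$e <- s2$wg * 3000  # inflate alpha well past any threshold
  expect_null(check_molt(s2, p)$event)
})

test_that("a starved step freezes structure and raises the flag", {
  p <- deb_params(f = 1e-9)  # no food: nothing to pay maintenance with
  s <- make_state(2, 0, 20, 5)
  res <- deb_step(s, p, 25, 0.1)
  expect_true(res$state$starving)
  expect_equal(res$state$wg, 2)       # structure never shrinks
  expect_gt(res$fluxes$unpaid, 0)
  expect_error(deb_step(s, p, 25, 0), "dt")
})

test_that("maintenance shortfall drains the buffer before the reserve", {
  p <- deb_params(f = 1e-6)  # cut feeding so kappa*pC < pS
  s <- make_state(2, 10, 20, 9, er = 1e5)
  res <- deb_step(s, p, 25, 0.1)
  expect_gt(res$fluxes$er_draw, 0)
  expect_equal(res$fluxes$e_draw, 0)
  expect_false(res$state$starving)
})

test_that("each Euler step conserves energy to 1e-6 relative", {
  p <- deb_params()
  frc <- test_forcing()
  s <- initial_state(34, p, stage = 8)
  for (i in seq_len(300)) {  # 30 days at dt = 0.1
    temp <- frc$temp_c[floor(s$t) + 1]
    res <- deb_step(s, p, temp, 0.1)
    fl <- res$fluxes
    d_e <- res$state$e - s$e
    d_er <- res$state$er - s$er
    d_wg <- res$state$wg - s$wg
    d_wo <- res$state$wo - s$wo
    supplied <- fl$pA * 0.1
    price <- if (s$post_puberty) p$EAO else p$EBO
    used <- d_e + d_er + d_wg * p$EG + d_wo * price +
      (fl$pS * 0.1 - fl$unpaid)
    expect_lt(abs(supplied - used) / max(supplied, 1), 1e-6)
    s <- res$state
  }
})

test_that("wet weight is constant between molts and jumps only at them", {
  p <- deb_params()
  traj <- deb_simulate(34, p, test_forcing(), 50, stage = 8)
  molts <- molt_events(traj)
  expect_equal(nrow(molts), 2)
  jumps <- which(diff(traj$ww) != 0)
  # Ww changes exactly on the days flagged as molt days
  expect_equal(sort(traj$day[jumps + 1]), sort(ceiling(molts$day)))
  expect_true(all(traj$molted[jumps + 1] == 1))
  # alpha rises monotonically within each intermolt in a fed run
  for (seg in split(seq_len(nrow(traj)), cumsum(traj$molted))) {
    if (length(seg) > 1) expect_true(all(diff(traj$alpha[seg]) > -1e-12))
  }
})

test_that("molt events conserve carbon weight and respect thresholds", {
  p <- deb_params()
  traj <- deb_simulate(12.88, p, warm_forcing(), 130, stage = 7)
  molts <- molt_events(traj)
  expect_equal(nrow(molts), 5)
  expect_true(all(molts$ww_after > molts$ww_before))
  expect_true(all(molts$alpha_at_trigger >=
                    p$alpha_pre[molts$stage_from] - 1e-12))
  # Ww_after = WC_at_trigger / alpha_post, i.e. alpha resets exactly
  expect_equal(molts$ww_after,
               molts$alpha_at_trigger * molts$ww_before / p$alpha_post)
})

test_that("halving the step changes the 180-day outcome by less than 1%", {
  p <- deb_params()
  frc <- test_forcing()
  a <- deb_simulate(p$ww_stage1, p, frc, 180, dt = 0.1, stage = 1)
  b <- deb_simulate(p$ww_stage1, p, frc, 180, dt = 0.05, stage = 1)
  fa <- a$ww_total[nrow(a)]; fb <- b$ww_total[nrow(b)]
  expect_lt(abs(fa - fb) / fa, 0.01)
})

test_that("lowering kappa never grows structure or starves reproduction", {
  frc <- test_forcing()
  run <- function(k) {
    p <- deb_params(kappa = c(juvenile = k, subadult = k, adult = k))
    deb_simulate(34, p, frc, 30, stage = 8)
  }
  ks <- c(1.0, 0.8, 0.6)
  runs <- lapply(ks, run)
  wg_final <- vapply(runs, function(tr) tr$wg[nrow(tr)], numeric(1))
  pr_cum <- vapply(runs, function(tr) sum(tr$p_r), numeric(1))
  expect_true(all(diff(wg_final) < 0))   # lower kappa, less structure
  expect_true(all(diff(pr_cum) > 0))     # lower kappa, more reproduction
})

test_that("ovarian density never exceeds its maximum", {
  p <- deb_params(nuG = 0.5, mGm = 0.05)
  traj <- deb_simulate(28.79, p, test_forcing(), 120, stage = 8)
  expect_true(all(traj$wo * p$cO / traj$wg <= p$mGm + 1e-9))
  expect_gt(max(traj$wo), 0)
})

test_that("the production stepper matches an hourly brute-force reference", {
  p <- deb_params()
  frc <- test_forcing()
  traj <- deb_simulate(34, p, frc, 30, stage = 8)
  ref <- ref_hourly_simulate(34, 8, p, frc, 30)
  expect_lt(abs(traj$wc[31] - ref$wc[31]) / ref$wc[31], 0.005)
  expect_lt(abs(traj$ww_total[31] - ref$final_total) / ref$final_total,
            0.005)
  expect_equal(nrow(molt_events(traj)), ref$n_molts)
})

test_that("simulate handles degenerate horizons and short forcing", {
  p <- deb_params()
  frc <- test_forcing(30)
  tr0 <- deb_simulate(34, p, frc, 0, stage = 8)
  expect_equal(nrow(tr0), 1)
  expect_equal(tr0$ww, 34)
  expect_identical(tr0$alpha, p$alpha_post)
  expect_error(deb_simulate(34, p, frc, 60, stage = 8), "forcing covers")
})

test_that("simulation reruns are identical", {
  p <- deb_params()
  frc <- test_forcing()
  a <- deb_simulate(28.79, p, frc, 60, stage = 8)
  b <- deb_simulate(28.79, p, frc, 60, stage = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
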