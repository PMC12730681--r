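#' Initial state of a freshly molted crab
#'
#' Builds the model state for an individual assumed to have just completed a
#' molt: the carbon weight is `alpha_post * Ww0`, split into structure and
#' reserve with the full-reserve ratio `beta` (`WG = beta * WC0`,
#' `E = (1 - beta) * WC0 * muE`), with empty reproduction buffer and ovary.
#' The molt stage is taken from `stage` if supplied, otherwise inferred from
#' the initial wet weight against a stage table (see [build_stage_table()]
#' and [infer_initial_stage()]).
#'
#' @param ww0 Initial somatic wet weight (g), strictly positive.
#' @param p A `deb_params` object.
#' @param stage Optional integer molt stage 1-11 overriding inference.
#' @param stage_table Optional stage table from [build_stage_table()], used
#'   when `stage` is missing.
#' @return A `deb_state` list with fields `t`, `wg` (structure, g carbon),
#'   `e` (reserve, J), `ww` (wet weight, g), `er` (reproduction buffer, J),
#'   `wo` (ovary, g), `stage`, `post_puberty`, `starving`.
#' @examples
#' s <- initial_state(100, deb_params(), stage = 8)
#' state_wc(s)     # 10
#' state_alpha(s)  # 0.1
#' @export
initial_state <- function(ww0, p, stage = NULL, stage_table = NULL) {
  if (!is.numeric(ww0) || length(ww0) != 1 || ww0 <= 0) {
    stop("initial wet weight must be a single positive number", call. = FALSE)
  }
  if (is.null(stage)) {
    if (is.null(stage_table)) {
      stop("supply either `stage` or a `stage_table` to place the ",
           "individual on the molt cycle", call. = FALSE)
    }
    stage <- infer_initial_stage(ww0, stage_table)
  }
  stage <- as.integer(stage)
  if (stage < 1 || stage > 11) stop("stage must be 1-11", call. = FALSE)
  wc0 <- p$alpha_post * ww0
  structure(
    list(t = 0, wg = p$beta * wc0, e = (1 - p$beta) * wc0 * p$muE,
         ww = ww0, er = 0, wo = 0, stage = stage,
         post_puberty = FALSE, starving = FALSE),
    class = "deb_state"
  )
}

#' Carbon weight and molting indicator of a state
#'
#' The carbon weight is the sum of structural weight and reserve weight
#' (`WC = WG + E/muE`); the ovary is excluded. The molting indicator is
#' `alpha = WC / Ww`.
#'
#' @param s A `deb_state`.
#' @param p A `deb_params` (for `muE`).
#' @return A single number.
#' @export
state_wc <- function(s, p = deb_params()) s$wg + s$e / p$muE

#' @rdname state_wc
#' @export
state_alpha <- function(s, p = deb_params()) state_wc(s, p) / s$ww

#' Instantaneous energy fluxes
#'
#' Evaluates the DEB fluxes at a given state and temperature:
#' assimilation `pA = f * pAm * c * WG^(2/3)` (clamped to the mobilization
#' flux while the reserve density sits at or above `Em`), mobilization
#' `pC = [E] * (EG * (pAm/Em) * c * WG^(2/3) + pM * c * WG) /
#' (EG + kappa * [E])`, somatic maintenance `pS = pM * c * WG`, structural
#' growth `pG = max(kappa * pC - pS, 0)`, reproductive-channel flow
#' `pR = (1 - kappa) * pC`, and the ovarian conversion flux `pO` (see
#' [gonad_demand()]), all in J d^-1.
#'
#' @param s A `deb_state`.
#' @param p A `deb_params`.
#' @param temp_c Ambient temperature, degC.
#' @return A named list: `pA`, `pC`, `pS`, `pG`, `pR`, `pO`, `shortfall`
#'   (unmet maintenance demand, J d^-1), `kappa` and `c` (the Arrhenius
#'   factor).
#' @export
compute_fluxes <- function(s, p, temp_c) {
  cc <- arrhenius_factor(temp_c + 273.15, p)
  k <- kappa_schedule(p, s$stage, s$post_puberty)
  ed <- s$e / s$wg
  sa <- s$wg^(2 / 3)
  pC <- ed * (p$EG * (p$pAm / p$Em) * cc * sa + p$pM * cc * s$wg) /
    (p$EG + k * ed)
  pA <- p$f * p$pAm * cc * sa
  if (ed >= p$Em) pA <- min(pA, pC)
  pS <- p$pM * cc * s$wg
  pG <- max(k * pC - pS, 0)
  shortfall <- max(pS - k * pC, 0)
  pR <- (1 - k) * pC
  gd <- gonad_demand(s, p, cc = cc)
  list(pA = pA, pC = pC, pS = pS, pG = pG, pR = pR, pO = gd$pO,
       shortfall = shortfall, kappa = k, c = cc)
}

#' Demand-driven ovarian conversion
#'
#' Converts reproduction-buffer energy into ovarian tissue. Densities are
#' carbon-weight ratios relative to structural weight: the reproductive
#' reserve density `mER = (ER/muE)/WG` and the reproductive material density
#' `mG = (WO * cO)/WG`. The mass demand is
#' `nuG * c(T) * mER * max(mGm - mG, 0) * WG` (g d^-1); the energy price per
#' gram is `EBO` before the puberty molt and `EAO` after it. The realized
#' flux is supply-limited by the buffer: `pO = min(demand * price, ER/dt)`.
#' Stages I-VII (kappa = 1) have zero demand: no ovarian investment before
#' stage VIII.
#'
#' @param s A `deb_state`.
#' @param p A `deb_params`.
#' @param temp_c Ambient temperature (degC); ignored when `cc` is given.
#' @param cc Optional precomputed Arrhenius factor.
#' @return A list: `demand` (g d^-1), `price` (J g^-1), `pO` (J d^-1) and
#'   `dwo` (realized ovary growth, g d^-1).
#' @export
gonad_demand <- function(s, p, temp_c = NULL, cc = NULL) {
  if (is.null(cc)) {
    cc <- if (is.null(temp_c)) 1 else arrhenius_factor(temp_c + 273.15, p)
  }
  price <- if (s$post_puberty) p$EAO else p$EBO
  if (s$stage < 8 && !s$post_puberty) {
    return(list(demand = 0, price = price, pO = 0, dwo = 0))
  }
  m_er <- (s$er / p$muE) / s$wg
  m_g <- (s$wo * p$cO) / s$wg
  demand <- p$nuG * cc * m_er * max(p$mGm - m_g, 0) * s$wg
  pO <- min(demand * price, s$er / p$dt)
  list(demand = demand, price = price, pO = pO, dwo = pO / price)
}

#' Molting trigger
#'
#' Fires a molt when the carbon-to-wet-weight ratio reaches the
#' stage-specific pre-molt threshold (`alpha >= alpha_pre[stage]`; ties
#' molt). The wet weight jumps to `WC / alpha_post` (carbon weight is
#' conserved across the event, so `alpha` resets exactly to `alpha_post`) and
#' the stage advances. The stage-XI molt is the puberty molt: it sets
#' `post_puberty` and ends molting; the simulation may continue for ovarian
#' growth.
#'
#' @param s A `deb_state`.
#' @param p A `deb_params`.
#' @return A list with the (possibly updated) `state` and `event`, a one-row
#'   tibble (`day`, `stage_from`, `stage_to`, `ww_before`, `ww_after`,
#'   `alpha_at_trigger`) or `NULL` when no molt fired.
#' @export
check_molt <- function(s, p) {
  if (s$post_puberty) return(list(state = s, event = NULL))
  wc <- s$wg + s$e / p$muE
  alpha <- wc / s$ww
  if (alpha < p$alpha_pre[s$stage]) return(list(state = s, event = NULL))
  ww_new <- wc / p$alpha_post
  stage_from <- s$stage
  if (s$stage == 11L) s$post_puberty <- TRUE else s$stage <- s$stage + 1L
  event <- tibble::tibble(day = s$t, stage_from = stage_from,
                          stage_to = s$stage, ww_before = s$ww,
                          ww_after = ww_new, alpha_at_trigger = alpha)
  s$ww <- ww_new
  list(state = s, event = event)
}

#' Advance the state by one Euler step
#'
#' Explicit (forward Euler) update of reserve, structure, reproduction
#' buffer and ovary over `dt`, followed by the molt check. When the somatic
#' allocation cannot cover maintenance (`kappa * pC < pS`) the shortfall is
#' drawn first from the reproduction buffer, then from reserve; structure is
#' never resorbed, and an unpayable deficit raises the sticky `starving`
#' flag instead of killing the individual.
#'
#' When a step triggers a molt it is redone as two half-steps (recursively,
#' down to `dt/16`) so the threshold crossing is localized well within the
#' step; the reported fluxes are then averages over the sub-steps, keeping
#' the per-step energy ledger exact.
#'
#' @param s A `deb_state`.
#' @param p A `deb_params`.
#' @param temp_c Ambient temperature over the step, degC.
#' @param dt Step length, d (positive).
#' @param min_dt Finest sub-step used to localize a molt crossing.
#' @return A list: `state` (advanced state), `fluxes` (as in
#'   [compute_fluxes()], plus the energy actually drawn from the buffer and
#'   reserve for maintenance, `er_draw` and `e_draw`, and any `unpaid`
#'   maintenance, all in J), and `molt` (event tibble or `NULL`).
#' @export
deb_step <- function(s, p, temp_c, dt = p$dt, min_dt = dt / 16) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  res <- euler_substep(s, p, temp_c, dt)
  if (is.null(res$molt) || dt <= min_dt * (1 + 1e-9)) return(res)
  # a molt fired inside this step: redo it as two half-steps to localize
  # the crossing (each half re-checks the trigger)
  r1 <- deb_step(s, p, temp_c, dt / 2, min_dt)
  r2 <- deb_step(r1$state, p, temp_c, dt / 2, min_dt)
  f1 <- r1$fluxes; f2 <- r2$fluxes
  rates <- c("pA", "pC", "pS", "pG", "pR", "pO", "shortfall")
  fl <- f2
  for (nm in rates) fl[[nm]] <- (f1[[nm]] + f2[[nm]]) / 2
  for (nm in c("er_draw", "e_draw", "unpaid")) fl[[nm]] <- f1[[nm]] + f2[[nm]]
  list(state = r2$state, fluxes = fl,
       molt = dplyr::bind_rows(r1$molt, r2$molt))
}

euler_substep <- function(s, p, temp_c, dt) {
  cc <- arrhenius_factor(temp_c + 273.15, p)
  k <- kappa_schedule(p, s$stage, s$post_puberty)
  ed <- s$e / s$wg
  sa <- s$wg^(2 / 3)
  pC <- ed * (p$EG * (p$pAm / p$Em) * cc * sa + p$pM * cc * s$wg) /
    (p$EG + k * ed)
  pA <- p$f * p$pAm * cc * sa
  if (ed >= p$Em) pA <- min(pA, pC)
  pS <- p$pM * cc * s$wg
  pG <- max(k * pC - pS, 0)
  shortfall <- max(pS - k * pC, 0)
  pR <- (1 - k) * pC

  e_new <- s$e + (pA - pC) * dt
  er_new <- s$er + pR * dt
  er_draw <- 0; e_draw <- 0; unpaid <- 0
  if (shortfall > 0) {
    need <- shortfall * dt
    er_draw <- min(er_new, need)
    er_new <- er_new - er_draw
    e_draw <- min(max(e_new, 0), need - er_draw)
    e_new <- e_new - e_draw
    unpaid <- need - er_draw - e_draw
    if (unpaid > 1e-12) s$starving <- TRUE
  }
  if (e_new < 0) e_new <- 0
  s$wg <- s$wg + (pG / p$EG) * dt

  pO <- 0
  if (k < 1 && (s$stage >= 8 || s$post_puberty)) {
    price <- if (s$post_puberty) p$EAO else p$EBO
    m_er <- (er_new / p$muE) / s$wg
    m_g <- (s$wo * p$cO) / s$wg
    demand <- p$nuG * cc * m_er * max(p$mGm - m_g, 0) * s$wg
    pO <- min(demand * price, er_new / dt)
    er_new <- er_new - pO * dt
    s$wo <- s$wo + (pO / price) * dt
  }
  s$e <- e_new
  s$er <- er_new
  s$t <- s$t + dt

  res <- check_molt(s, p)
  list(state = res$state,
       fluxes = list(pA = pA, pC = pC, pS = pS, pG = pG, pR = pR, pO = pO,
                     shortfall = shortfall, kappa = k, c = cc,
                     er_draw = er_draw, e_draw = e_draw, unpaid = unpaid),
       molt = res$event)
}

#' Simulate a growth trajectory
#'
#' Runs the finite-difference model from an initial wet weight over a daily
#' temperature forcing, recording daily snapshots and every molt event. The
#' reported total wet weight is `ww_total = Ww + WO` (somatic wet weight
#' plus ovary). The run is deterministic given its inputs.
#'
#' @param ww0 Initial somatic wet weight (g) of a freshly molted individual.
#' @param p A `deb_params`.
#' @param forcing A `deb_forcing` covering at least `[0, horizon]` days.
#' @param horizon Simulation length, whole days (`horizon = 0` returns only
#'   the initial state).
#' @param dt Euler step (d); should divide one day evenly.
#' @param stage,stage_table Passed to [initial_state()]. When both are
#'   `NULL`, a stage table is built from a reference run over `forcing`.
#' @return A `deb_trajectory`: a tibble with one row per day (`day`,
#'   `temp_c`, `stage`, `ww`, `wo`, `ww_total`, `wc`, `alpha`, `e`, `wg`,
#'   `er`, `p_a`, `p_c`, `p_s`, `p_g`, `p_r`, `p_o`, `molted`, `starving`)
#'   and attributes `molts` (event tibble), `params`, `dt`.
#' @examples
#' frc <- seasonal_forcing(horizon = 60)
#' traj <- deb_simulate(34, deb_params(), frc, horizon = 50, stage = 8)
#' molt_events(traj)
#' @export
deb_simulate <- function(ww0, p, forcing, horizon, dt = p$dt,
                         stage = NULL, stage_table = NULL) {
  stopifnot(inherits(forcing, "deb_forcing"))
  if (horizon < 0) stop("horizon must be non-negative", call. = FALSE)
  if (max(forcing$day) < horizon) {
    stop("forcing covers ", max(forcing$day), " days but the simulation ",
         "horizon is ", horizon, " days", call. = FALSE)
  }
  if (is.null(stage) && is.null(stage_table)) {
    stage_table <- build_stage_table(p, forcing)
  }
  s <- initial_state(ww0, p, stage = stage, stage_table = stage_table)

  n <- round(horizon / dt)
  tt <- (seq_len(n) - 1) * dt
  temps <- forcing_at(forcing, tt)
  day_temps <- forcing_at(forcing, seq(0, horizon))

  nd <- horizon + 1
  col <- function() numeric(nd)
  out <- list(day = seq(0, horizon), temp_c = day_temps, stage = integer(nd),
              ww = col(), wo = col(), ww_total = col(), wc = col(),
              alpha = col(), e = col(), wg = col(), er = col(),
              p_a = col(), p_c = col(), p_s = col(), p_g = col(),
              p_r = col(), p_o = col(), molted = integer(nd),
              starving = logical(nd))
  molts <- list()
  snap <- function(i, s, fl, molted) {
    wc <- s$wg + s$e / p$muE
    out$stage[i] <<- s$stage
    out$ww[i] <<- s$ww; out$wo[i] <<- s$wo
    out$ww_total[i] <<- s$ww + s$wo
    out$wc[i] <<- wc; out$alpha[i] <<- wc / s$ww
    out$e[i] <<- s$e; out$wg[i] <<- s$wg; out$er[i] <<- s$er
    out$p_a[i] <<- fl$pA; out$p_c[i] <<- fl$pC; out$p_s[i] <<- fl$pS
    out$p_g[i] <<- fl$pG; out$p_r[i] <<- fl$pR; out$p_o[i] <<- fl$pO
    out$molted[i] <<- molted; out$starving[i] <<- s$starving
  }
  fl0 <- compute_fluxes(s, p, day_temps[1])
  snap(1, s, fl0, 0L)

  next_day <- 1
  molted_since <- 0L
  for (i in seq_len(n)) {
    res <- deb_step(s, p, temps[i], dt)
    s <- res$state
    if (!is.null(res$molt)) {
      molts[[length(molts) + 1]] <- res$molt
      molted_since <- 1L
    }
    if (s$t >= next_day - 1e-9) {
      snap(next_day + 1, s, res$fluxes, molted_since)
      next_day <- next_day + 1
      molted_since <- 0L
    }
  }
  traj <- tibble::as_tibble(out)
  attr(traj, "molts") <- if (length(molts)) dplyr::bind_rows(molts) else
    tibble::tibble(day = numeric(), stage_from = integer(),
                   stage_to = integer(), ww_before = numeric(),
                   ww_after = numeric(), alpha_at_trigger = numeric())
  attr(traj, "params") <- p
  attr(traj, "dt") <- dt
  class(traj) <- c("deb_trajectory", class(traj))
  traj
}

#' Molt events of a trajectory
#'
#' @param traj A `deb_trajectory`.
#' @return The molt-event tibble recorded during the simulation.
#' @export
molt_events <- function(traj) {
  stopifnot(inherits(traj, "deb_trajectory"))
  attr(traj, "molts")
}
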