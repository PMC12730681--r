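#' Synthetic oxygen-consumption experiment
#'
#' Generates the ROC-versus-temperature table of the Arrhenius experiment:
#' five size groups measured at five temperatures, with the true Arrhenius
#' law `ROC(T) = R25 * exp(TA/298.15 - TA/T)` and multiplicative lognormal
#' noise. Mass-specific ROC decreases with crab size, so the group baseline
#' `R25` declines from the smallest to the largest group.
#'
#' @param ta_true True Arrhenius temperature, K.
#' @param groups Number of size groups.
#' @param temps Experimental temperatures, degC.
#' @param cv Lognormal coefficient of variation of the noise (0 = exact).
#' @param seed RNG seed; the output is a pure function of the arguments.
#' @param r25 Baselines at 25 degC (mg O2 g^-1 h^-1), one per group,
#'   decreasing with size.
#' @return A tibble with columns `group`, `temp_c`, `roc`.
#' @export
gen_roc <- function(ta_true = 5482, groups = 5,
                    temps = c(7, 13, 19, 25, 31), cv = 0.05, seed = 1,
                    r25 = seq(1.6, 0.6, length.out = groups)) {
  stopifnot(length(temps) >= 2, cv >= 0, length(r25) == groups)
  grid <- tidyr::expand_grid(group = seq_len(groups), temp_c = temps)
  withr::with_seed(seed, {
    noise <- rlnorm_cv(nrow(grid), cv)
    grid$roc <- r25[grid$group] *
      exp(ta_true / 298.15 - ta_true / (grid$temp_c + 273.15)) * noise
  })
  grid
}

#' Synthetic starvation time series
#'
#' Carbon weight decays exponentially from `wc0` to the structural plateau
#' `beta_true * wc0` as the reserve empties; ROC tracks the instantaneous
#' energy loss plus a maintenance floor. Additive gaussian noise on the
#' carbon weight.
#'
#' @param wc0 Initial carbon weight, g.
#' @param beta_true True structural fraction of `wc0`, in (0, 1).
#' @param decay_rate Reserve depletion rate, d^-1.
#' @param days Series length, d; sampled every other day like the
#'   experimental design. Must reach the plateau (>= 8 d).
#' @param sd Gaussian standard deviation of the carbon-weight noise, g.
#' @param seed RNG seed.
#' @param pm_true Maintenance rate used for the ROC floor, J g^-1 d^-1.
#' @param p A `deb_params` for `muE` and `oxycal`.
#' @return A tibble with columns `day`, `wc` (g), `roc` (mg O2 g^-1 h^-1).
#' @export
gen_starvation <- function(wc0 = 10, beta_true = 0.79, decay_rate = 0.4,
                           days = 16, sd = 0, seed = 1, pm_true = 310,
                           p = deb_params()) {
  stopifnot(wc0 > 0, beta_true > 0, beta_true < 1, sd >= 0)
  if (days < 8) stop("series must span the ~8 d plateau", call. = FALSE)
  day <- seq(0, days, by = 2)
  wc_true <- wc0 * (beta_true + (1 - beta_true) * exp(-decay_rate * day))
  # energy loss rate per g structure plus the maintenance floor, as ROC
  loss <- p$muE * wc0 * (1 - beta_true) * decay_rate *
    exp(-decay_rate * day) / (beta_true * wc0)
  roc <- (pm_true + loss) / p$oxycal * 1000 / 24  # g/g/d -> mg/g/h
  withr::with_seed(seed, {
    wc <- wc_true + stats::rnorm(length(day), 0, sd)
  })
  tibble::tibble(day = day, wc = wc, roc = roc)
}

#' Synthetic feeding experiment
#'
#' Assimilated energy scales with structural weight to the 2/3 power:
#' `assim = pAm_true * wg^(2/3)` with multiplicative lognormal noise.
#'
#' @param pAm_true True maximum assimilation rate, J g^-2/3 d^-1.
#' @param n Number of individuals (>= 3).
#' @param wg_range Structural-weight range (g); individuals are spaced
#'   log-evenly across it.
#' @param cv Lognormal coefficient of variation (0 = exact).
#' @param seed RNG seed.
#' @return A tibble with columns `wg`, `assim`.
#' @export
gen_feeding <- function(pAm_true = 4590, n = 8, wg_range = c(0.5, 15),
                        cv = 0.1, seed = 1) {
  stopifnot(n >= 3, cv >= 0)
  wg <- exp(seq(log(wg_range[1]), log(wg_range[2]), length.out = n))
  withr::with_seed(seed, {
    assim <- pAm_true * wg^(2 / 3) * rlnorm_cv(n, cv)
  })
  tibble::tibble(wg = wg, assim = assim)
}

#' Synthetic molt-pair table
#'
#' Wet and carbon weights of freshly molted individuals obeying
#' `wc = alpha_post_true * ww` with multiplicative lognormal noise.
#'
#' @param alpha_post_true True post-molt carbon-to-wet-weight ratio.
#' @param n Number of individuals.
#' @param ww_range Wet-weight range, g.
#' @param cv Lognormal coefficient of variation.
#' @param seed RNG seed.
#' @return A tibble with columns `ww`, `wc`.
#' @export
gen_molt_pairs <- function(alpha_post_true = 0.1, n = 10,
                           ww_range = c(5, 250), cv = 0.05, seed = 1) {
  stopifnot(n >= 3, cv >= 0)
  ww <- exp(seq(log(ww_range[1]), log(ww_range[2]), length.out = n))
  withr::with_seed(seed, {
    wc <- alpha_post_true * ww * rlnorm_cv(n, cv)
  })
  tibble::tibble(ww = ww, wc = wc)
}

#' Synthetic growth observations from a known trajectory
#'
#' Runs the simulator, samples total wet weight and ovary mass at the given
#' days, and applies multiplicative lognormal noise. The noise-free
#' trajectory is attached so recovery tests can compare against truth.
#'
#' @param p A `deb_params`.
#' @param forcing A `deb_forcing`.
#' @param ww0,stage,horizon Scenario passed to [deb_simulate()].
#' @param sample_days Days at which observations are taken (within the
#'   horizon).
#' @param cv Lognormal coefficient of variation (0 = exact).
#' @param seed RNG seed.
#' @return A tibble with columns `day`, `ww_total`, `wo`; the generating
#'   `deb_trajectory` is attached as attribute `truth`.
#' @export
gen_observations <- function(p, forcing, ww0, stage = NULL, horizon = NULL,
                             sample_days, cv = 0.1, seed = 1) {
  if (is.null(horizon)) horizon <- ceiling(max(sample_days))
  if (any(sample_days > horizon)) {
    stop("sample days must lie within the horizon", call. = FALSE)
  }
  traj <- deb_simulate(ww0, p, forcing, horizon, stage = stage)
  idx <- match(round(sample_days), traj$day)
  withr::with_seed(seed, {
    obs <- tibble::tibble(
      day = traj$day[idx],
      ww_total = traj$ww_total[idx] * rlnorm_cv(length(idx), cv),
      wo = traj$wo[idx] * rlnorm_cv(length(idx), cv)
    )
  })
  attr(obs, "truth") <- traj
  obs
}

# lognormal noise with unit mean and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
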