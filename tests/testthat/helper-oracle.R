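# Shared fixtures and an independent brute-force reference stepper.
#
# The reference implementation below is deliberately written from the model
# equations as a plain hourly Euler loop, without reusing any of the
# package's stepping code, so that agreement between the two is an actual
# cross-check and not a tautology.

test_forcing <- function(horizon = 185) seasonal_forcing(horizon = horizon)

warm_forcing <- function(horizon = 185) {
  seasonal_forcing(t_min = 18, t_max = 31, horizon = horizon)
}

# hourly brute-force Euler reference; returns final state and daily WC/Ww
ref_hourly_simulate <- function(ww0, stage, p, forcing, horizon, dt = 1 / 24) {
  wc <- p$alpha_post * ww0
  wg <- p$beta * wc
  e <- (1 - p$beta) * wc * p$muE
  ww <- ww0; er <- 0; wo <- 0; postpub <- FALSE
  n <- round(horizon / dt)
  temp_fun <- stats::approxfun(forcing$day, forcing$temp_c)
  days <- numeric(horizon + 1); wcs <- numeric(horizon + 1)
  wws <- numeric(horizon + 1)
  wcs[1] <- wc; wws[1] <- ww
  nmolt <- 0
  for (i in seq_len(n)) {
    temp <- temp_fun((i - 1) * dt)
    cc <- exp(p$TA / p$T_ref - p$TA / (temp + 273.15))
    k <- if (postpub) p$kappa[["adult"]] else if (stage <= 7)
      p$kappa[["juvenile"]] else p$kappa[["subadult"]]
    ed <- e / wg
    pC <- ed * (p$EG * (p$pAm / p$Em) * cc * wg^(2 / 3) +
                  p$pM * cc * wg) / (p$EG + k * ed)
    pA <- p$f * p$pAm * cc * wg^(2 / 3)
    if (ed >= p$Em) pA <- min(pA, pC)
    pS <- p$pM * cc * wg
    pG <- max(k * pC - pS, 0)
    e <- e + (pA - pC) * dt
    er <- er + (1 - k) * pC * dt
    if (k * pC < pS) {
      need <- (pS - k * pC) * dt
      take <- min(er, need); er <- er - take
      e <- max(e - (need - take), 0)
    }
    if (e < 0) e <- 0
    wg <- wg + pG / p$EG * dt
    if (k < 1 && (stage >= 8 || postpub)) {
      price <- if (postpub) p$EAO else p$EBO
      dem <- p$nuG * cc * (er / p$muE / wg) *
        max(p$mGm - wo * p$cO / wg, 0) * wg
      pO <- min(dem * price, er / dt)
      er <- er - pO * dt
      wo <- wo + pO / price * dt
    }
    wcur <- wg + e / p$muE
    if (!postpub && wcur / ww >= p$alpha_pre[stage]) {
      ww <- wcur / p$alpha_post
      nmolt <- nmolt + 1
      if (stage == 11) postpub <- TRUE else stage <- stage + 1
    }
    if (i %% round(1 / dt) == 0) {
      d <- i * dt
      wcs[d + 1] <- wg + e / p$muE
      wws[d + 1] <- ww
    }
  }
  list(wc = wcs, ww = wws, wo = wo, n_molts = nmolt,
       final_total = ww + wo)
}
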