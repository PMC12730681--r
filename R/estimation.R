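#' Estimate the Arrhenius temperature from oxygen-consumption data
#'
#' For each size group, regresses the natural logarithm of the
#' mass-specific oxygen consumption rate (ROC) on the reciprocal of the
#' absolute temperature by ordinary least squares; the group's Arrhenius
#' temperature is the negated slope. The overall estimate is the unweighted
#' mean across groups, with the sample standard deviation as dispersion.
#'
#' @param data Data frame with columns `group` (size-group id), `temp_c`
#'   (water temperature, degC) and `roc` (ROC, mg O2 g^-1 h^-1).
#' @return A `deb_arrhenius` object: list with `TA` (K), `sd` (K), `n_groups`
#'   and `groups`, a tibble of per-group slopes and fits. [generics::tidy()]
#'   returns the per-group table, [generics::glance()] the summary row.
#' @examples
#' roc <- gen_roc(ta_true = 5482, cv = 0, seed = 1)
#' estimate_arrhenius(roc)$TA
#' @export
estimate_arrhenius <- function(data) {
  stopifnot(all(c("group", "temp_c", "roc") %in% names(data)))
  if (any(data$roc <= 0)) stop("ROC values must be positive", call. = FALSE)
  fit_one <- function(d) {
    if (length(unique(d$temp_c)) < 2) {
      stop("each size group needs at least two distinct temperatures",
           call. = FALSE)
    }
    inv_t <- 1 / (d$temp_c + 273.15)
    m <- stats::lm(log(d$roc) ~ inv_t)
    tibble::tibble(TA = -unname(stats::coef(m)[2]),
                   r_squared = r_squared_quiet(m),
                   n = nrow(d))
  }
  groups <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup()
  out <- list(TA = mean(groups$TA),
              sd = if (nrow(groups) > 1) stats::sd(groups$TA) else NA_real_,
              n_groups = nrow(groups), groups = groups)
  class(out) <- "deb_arrhenius"
  out
}

#' @export
print.deb_arrhenius <- function(x, ...) {
  cat(sprintf("Arrhenius temperature: TA = %.0f K (sd %.0f, %d groups)\n",
              x$TA, x$sd, x$n_groups))
  invisible(x)
}

#' Estimate the maximum surface-specific assimilation rate
#'
#' Regresses the assimilated energy rate on structural weight to the 2/3
#' power. The through-origin fit (default) matches the surface-area scaling
#' assumption `pA = pAm * WG^(2/3)`; a free intercept is available for
#' diagnostic use and is reported when requested.
#'
#' @param data Data frame with columns `wg` (structural weight, g) and
#'   `assim` (assimilated energy, J d^-1); at least 3 individuals.
#' @param through_origin Force the regression through the origin?
#' @return A one-row tibble: `pAm` (slope, J g^-2/3 d^-1), `intercept`,
#'   `r_squared`, `n`.
#' @export
estimate_assimilation <- function(data, through_origin = TRUE) {
  stopifnot(all(c("wg", "assim") %in% names(data)))
  if (nrow(data) < 3) stop("need at least 3 individuals", call. = FALSE)
  if (stats::sd(data$wg) == 0) {
    stop("degenerate spread: all structural weights identical",
         call. = FALSE)
  }
  x <- data$wg^(2 / 3)
  m <- if (through_origin) stats::lm(data$assim ~ 0 + x) else
    stats::lm(data$assim ~ x)
  co <- stats::coef(m)
  tibble::tibble(pAm = unname(co[["x"]]),
                 intercept = if (through_origin) 0 else unname(co[[1]]),
                 r_squared = r_squared_quiet(m),
                 n = nrow(data))
}

#' Estimate reserve partitioning from a starvation time series
#'
#' After long enough starvation the carbon weight stabilizes at the
#' structural weight as the reserves empty. The structural weight is the
#' mean carbon weight from `plateau_day` onward; `beta = WG / WC0` is the
#' structure share of the initial carbon weight; the maximum reserve
#' density follows as `Em = (WC0 - WG) * muE / WG`; and the maintenance
#' rate is the oxygen-energy equivalent times the mean plateau ROC.
#'
#' @param data Data frame with columns `day`, `wc` (carbon weight, g) and
#'   `roc` (ROC, mg O2 g^-1 h^-1).
#' @param plateau_day First day of the carbon-weight plateau (default 8).
#' @param p A `deb_params` supplying `muE` and `oxycal`.
#' @return A one-row tibble: `beta`, `Em` (J g^-1), `pM` (J g^-1 d^-1),
#'   `wg` (plateau carbon weight, g), `wc0`, `n_plateau`; the plateau
#'   sub-series is attached as attribute `plateau`.
#' @export
estimate_starvation <- function(data, plateau_day = 8, p = deb_params()) {
  stopifnot(all(c("day", "wc", "roc") %in% names(data)))
  plateau <- data[data$day >= plateau_day, , drop = FALSE]
  if (nrow(plateau) == 0) {
    stop("series ends before the plateau day (", plateau_day, ")",
         call. = FALSE)
  }
  wc0 <- data$wc[which.min(data$day)]
  wg <- mean(plateau$wc)
  roc_g_d <- mean(plateau$roc) * 24 / 1000  # mg/g/h -> g O2/g/d
  out <- tibble::tibble(beta = wg / wc0,
                        Em = (wc0 - wg) * p$muE / wg,
                        pM = p$oxycal * roc_g_d,
                        wg = wg, wc0 = wc0, n_plateau = nrow(plateau))
  attr(out, "plateau") <- tibble::as_tibble(plateau)
  out
}

#' Estimate the post-molt carbon-to-wet-weight ratio
#'
#' Through-origin regression of carbon weight on wet weight across freshly
#' molted individuals; the slope is `alpha_post`.
#'
#' @param data Data frame with columns `ww` (wet weight, g) and `wc`
#'   (carbon weight, g); at least 3 individuals.
#' @param through_origin Force the regression through the origin?
#' @return A one-row tibble: `alpha_post`, `r_squared`, `n`.
#' @export
estimate_alpha_post <- function(data, through_origin = TRUE) {
  stopifnot(all(c("ww", "wc") %in% names(data)))
  if (nrow(data) < 3) stop("need at least 3 individuals", call. = FALSE)
  if (stats::sd(data$ww) == 0) {
    stop("degenerate spread: all wet weights identical", call. = FALSE)
  }
  m <- if (through_origin) stats::lm(wc ~ 0 + ww, data = data) else
    stats::lm(wc ~ ww, data = data)
  slope <- unname(stats::coef(m)[["ww"]])
  tibble::tibble(alpha_post = slope, r_squared = r_squared_quiet(m),
                 n = nrow(data))
}

#' Post-molt weight bands per molt stage
#'
#' Runs a reference simulation from a small freshly molted stage-I juvenile
#' and records the post-molt wet weight at which each stage is entered. The
#' upper edge of a stage's band is the midpoint between its post-molt weight
#' and the next stage's; the band table maps an observed initial wet weight
#' to a molt stage (see [infer_initial_stage()]). Deterministic given
#' parameters and forcing.
#'
#' @param p A `deb_params`.
#' @param forcing A `deb_forcing`; the reference run uses its full span.
#' @param ww_stage1 Wet weight (g) of the reference stage-I individual.
#' @param horizon Reference-run length (defaults to the forcing span).
#' @return A `deb_stage_table` tibble: `stage`, `ww_postmolt` (g),
#'   `ww_upper` (band upper edge, g; `Inf` for the last recorded stage).
#' @export
build_stage_table <- function(p, forcing, ww_stage1 = p$ww_stage1,
                              horizon = NULL) {
  if (is.null(horizon)) horizon <- floor(max(forcing$day))
  traj <- deb_simulate(ww_stage1, p, forcing, horizon, stage = 1)
  molts <- molt_events(traj)
  if (nrow(molts) < 2) {
    stop("reference run produced fewer than 2 molts; extend the forcing ",
         "or enlarge ww_stage1", call. = FALSE)
  }
  entered <- molts[molts$stage_to > molts$stage_from, , drop = FALSE]
  tab <- tibble::tibble(stage = c(1L, entered$stage_to),
                        ww_postmolt = c(ww_stage1, entered$ww_after))
  upper <- c((tab$ww_postmolt[-1] + tab$ww_postmolt[-nrow(tab)]) / 2, Inf)
  tab$ww_upper <- upper
  class(tab) <- c("deb_stage_table", class(tab))
  tab
}

#' Infer the molt stage of an individual from its wet weight
#'
#' Picks the smallest stage whose post-molt weight band contains the wet
#' weight, clamped to stages 1-10 for simulation starts (a stage above the
#' table's coverage is clamped with a warning).
#'
#' @param ww0 Observed initial wet weight (g).
#' @param stage_table A `deb_stage_table` from [build_stage_table()].
#' @return An integer stage in 1-10.
#' @export
infer_initial_stage <- function(ww0, stage_table) {
  if (is.null(stage_table) || nrow(stage_table) == 0) {
    stop("empty stage table", call. = FALSE)
  }
  idx <- which(ww0 < stage_table$ww_upper)
  if (length(idx) == 0) {
    warning("initial wet weight above all stage bands; clamping to stage 10")
    return(10L)
  }
  min(as.integer(stage_table$stage[idx[1]]), 10L)
}

#' Calibrate the gonad module against ovary-mass milestones
#'
#' Grid search (coarse log-spaced grid with one local refinement pass) over
#' the gonad growth coefficient `nuG` and the maximum reproductive-material
#' density `mGm`, minimizing the summed squared log-error of the simulated
#' ovary mass at the target days. Because the ovary drains only the
#' reproduction buffer, candidate runs share the same growth and molt
#' schedule; only the ovary trajectory differs.
#'
#' @param p A `deb_params` (its `nuG`, `mGm` are ignored during the search).
#' @param forcing A `deb_forcing`.
#' @param targets Data frame with columns `day` and `wo` (ovary mass, g),
#'   at least one row.
#' @param ww0 Initial wet weight of the calibration scenario.
#' @param stage Initial molt stage of the calibration scenario.
#' @param horizon Simulation length (defaults to the last target day).
#' @param nu_bounds,mgm_bounds Search intervals for `nuG` (log-spaced) and
#'   `mGm` (linear).
#' @param n_coarse,n_refine Grid sizes of the two passes.
#' @return A list: `nuG`, `mGm`, `objective` (summed squared log-error),
#'   `fit` (tibble of target day, observed and simulated ovary mass), and
#'   `params` (a copy of `p` carrying the calibrated pair).
#' @export
calibrate_gonad <- function(p, forcing, targets, ww0 = p$ww_stage1,
                            stage = 1, horizon = NULL,
                            nu_bounds = c(0.001, 0.3),
                            mgm_bounds = c(0.1, 1.0),
                            n_coarse = c(12, 10), n_refine = c(7, 7)) {
  stopifnot(all(c("day", "wo") %in% names(targets)))
  if (nrow(targets) == 0) stop("empty target list", call. = FALSE)
  if (any(targets$wo <= 0)) stop("target ovary masses must be positive",
                                 call. = FALSE)
  if (is.null(horizon)) horizon <- ceiling(max(targets$day))

  objective <- function(nu, mgm) {
    pp <- p; pp$nuG <- nu; pp$mGm <- mgm
    traj <- deb_simulate(ww0, pp, forcing, horizon, stage = stage)
    sim <- traj$wo[match(round(targets$day), traj$day)]
    if (any(is.na(sim)) || any(sim <= 0)) return(list(err = Inf, sim = sim))
    list(err = sum(log(sim / targets$wo)^2), sim = sim)
  }
  search <- function(nus, mgms) {
    best <- list(err = Inf)
    for (nu in nus) for (mgm in mgms) {
      o <- objective(nu, mgm)
      if (o$err < best$err) best <- list(err = o$err, nu = nu, mgm = mgm,
                                         sim = o$sim)
    }
    best
  }
  nus <- exp(seq(log(nu_bounds[1]), log(nu_bounds[2]),
                 length.out = n_coarse[1]))
  mgms <- seq(mgm_bounds[1], mgm_bounds[2], length.out = n_coarse[2])
  best <- search(nus, mgms)
  if (!is.finite(best$err)) {
    stop("no feasible gonad fit inside the search bounds", call. = FALSE)
  }
  # local refinement around the coarse optimum, staying inside the bounds
  nu_lo <- max(nu_bounds[1], best$nu / 2)
  nu_hi <- min(nu_bounds[2], best$nu * 2)
  mg_step <- diff(mgm_bounds) / (n_coarse[2] - 1)
  mg_lo <- max(mgm_bounds[1], best$mgm - mg_step)
  mg_hi <- min(mgm_bounds[2], best$mgm + mg_step)
  best2 <- search(exp(seq(log(nu_lo), log(nu_hi), length.out = n_refine[1])),
                  seq(mg_lo, mg_hi, length.out = n_refine[2]))
  if (best2$err < best$err) best <- best2

  pp <- p; pp$nuG <- best$nu; pp$mGm <- best$mgm
  list(nuG = best$nu, mGm = best$mgm, objective = best$err,
       fit = tibble::tibble(day = targets$day, wo_target = targets$wo,
                            wo_sim = best$sim),
       params = pp)
}

# r-squared without the 'essentially perfect fit' warning on noiseless data
r_squared_quiet <- function(m) {
  suppressWarnings(summary(m)$r.squared)
}
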