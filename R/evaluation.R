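#' Goodness-of-fit statistics for simulated against observed series
#'
#' Computes the coefficient of determination (squared Pearson correlation,
#' `R^2 = 1` denotes perfect correspondence), the Nash-Sutcliffe model
#' efficiency (`ME = 1 - sum((O - P)^2) / sum((O - mean(O))^2)`; `ME = 1`
#' is perfect, `ME = 0` no better than the observed mean), Theil's
#' inequality coefficient in the bounded-denominator form
#' `U = RMSE / (sqrt(mean(O^2)) + sqrt(mean(P^2)))` (`U = 0` ideal), and the
#' root-mean-square error. Pairs are expected at the observed sampling days,
#' with the simulated series already evaluated there.
#'
#' @param data Data frame holding the paired series.
#' @param observed,predicted Column names (tidy-eval) of the observed and
#'   simulated values.
#' @param drop_first Drop the first pair (the shared initial value) before
#'   computing the statistics, as is usual when the simulation is started
#'   from the first observation.
#' @param theil Variant of Theil's U: `"bounded"` (denominator
#'   `sqrt(mean(O^2)) + sqrt(mean(P^2))`) or `"rmse_obs"` (denominator
#'   `sqrt(mean(O^2))`).
#' @return A one-row `deb_fit_report` tibble: `n`, `r_squared`, `me`,
#'   `theil_u`, `rmse`.
#' @examples
#' goodness_of_fit(data.frame(o = c(1, 2, 3), s = c(1, 2, 4)), o, s)
#' @export
goodness_of_fit <- function(data, observed, predicted, drop_first = FALSE,
                            theil = c("bounded", "rmse_obs")) {
  theil <- match.arg(theil)
  o <- rlang::eval_tidy(rlang::enquo(observed), data)
  p <- rlang::eval_tidy(rlang::enquo(predicted), data)
  keep <- !is.na(o) & !is.na(p)
  o <- o[keep]; p <- p[keep]
  if (length(o) != length(p)) stop("series lengths differ", call. = FALSE)
  if (drop_first && length(o) > 1) { o <- o[-1]; p <- p[-1] }
  n <- length(o)
  if (n < 2) stop("need at least 2 paired values", call. = FALSE)
  if (stats::sd(o) == 0) {
    stop("observed series has zero variance; R^2 is undefined",
         call. = FALSE)
  }
  rmse <- sqrt(mean((p - o)^2))
  denom <- switch(theil,
                  bounded = sqrt(mean(o^2)) + sqrt(mean(p^2)),
                  rmse_obs = sqrt(mean(o^2)))
  out <- tibble::tibble(
    n = n,
    r_squared = if (stats::sd(p) == 0) NA_real_ else stats::cor(o, p)^2,
    me = 1 - sum((o - p)^2) / sum((o - mean(o))^2),
    theil_u = rmse / denom,
    rmse = rmse
  )
  class(out) <- c("deb_fit_report", class(out))
  out
}

#' One-sided perturbation sensitivity index
#'
#' The Majkowski-style index for a daily response series under a +/-
#' perturbation pair: `SI = 100 * mean((|y+ - y0| + |y- - y0|) / y0) / 2`
#' (percent), averaging the two one-sided relative deviations over the
#' simulated days.
#'
#' @param base,up,down Numeric vectors: the response under the reference,
#'   increased and decreased parameter value.
#' @return The sensitivity index, percent.
#' @examples
#' t <- 1:10
#' sensitivity_index(t, 1.1 * t, 0.9 * t)  # 10
#' @export
sensitivity_index <- function(base, up, down) {
  stopifnot(length(base) == length(up), length(base) == length(down))
  100 * mean((abs(up - base) + abs(down - base)) / base) / 2
}

#' One-at-a-time parameter sensitivity analysis
#'
#' Perturbs each parameter by +/- `perturbation` (default 10%), reruns the
#' simulation, and reports the sensitivity index of the predicted carbon
#' weight (`WC`, the response variable) across the simulated days (day 0,
#' where all runs coincide, is excluded). `"alpha_pre"` scales the whole
#' pre-molt threshold vector. Parameters whose perturbed run fails are
#' reported as `NA` with a warning; the others continue.
#'
#' @param p A `deb_params`.
#' @param ww0,forcing,horizon,stage The simulation scenario (see
#'   [deb_simulate()]).
#' @param parameters Character vector of parameter names to perturb; any
#'   scalar field of `p` plus `"kappa_subadult"`, `"kappa_adult"` and
#'   `"alpha_pre"`.
#' @param perturbation Relative perturbation (0.1 = +/-10%).
#' @return A `deb_sensitivity` tibble sorted by decreasing index:
#'   `parameter`, `si_pct`.
#' @export
sensitivity_analysis <- function(p, ww0, forcing, horizon, stage = NULL,
                                 parameters = c("pAm", "f", "EG", "Em",
                                                "pM", "TA", "muE"),
                                 perturbation = 0.1) {
  stage_table <- if (is.null(stage)) build_stage_table(p, forcing) else NULL
  run <- function(pp) {
    traj <- deb_simulate(ww0, pp, forcing, horizon, stage = stage,
                         stage_table = stage_table)
    traj$wc[-1]
  }
  perturb <- function(pp, name, fac) {
    if (name == "alpha_pre") {
      pp$alpha_pre <- pp$alpha_pre * fac
    } else if (name == "kappa_subadult") {
      pp$kappa[["subadult"]] <- pp$kappa[["subadult"]] * fac
    } else if (name == "kappa_adult") {
      pp$kappa[["adult"]] <- pp$kappa[["adult"]] * fac
    } else {
      pp[[name]] <- pp[[name]] * fac
    }
    validate_params(pp)
    pp
  }
  base <- run(p)
  si <- purrr::map_dbl(parameters, function(nm) {
    tryCatch({
      up <- run(perturb(p, nm, 1 + perturbation))
      dn <- run(perturb(p, nm, 1 - perturbation))
      sensitivity_index(base, up, dn)
    }, error = function(e) {
      warning("perturbed run failed for `", nm, "`: ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
  })
  out <- tibble::tibble(parameter = parameters, si_pct = si) |>
    dplyr::arrange(dplyr::desc(.data$si_pct))
  class(out) <- c("deb_sensitivity", class(out))
  out
}
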