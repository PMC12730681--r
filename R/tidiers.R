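#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trajectory into long format
#'
#' @param x A `deb_trajectory`.
#' @param series Which daily series to keep.
#' @param ... Unused.
#' @return A long tibble with columns `day`, `series`, `value`.
#' @export
#' @method tidy deb_trajectory
tidy.deb_trajectory <- function(x, series = c("ww_total", "ww", "wo", "wc",
                                              "alpha", "wg", "e", "er"),
                                ...) {
  series <- match.arg(series, several.ok = TRUE)
  tibble::as_tibble(x)[, c("day", series)] |>
    tidyr::pivot_longer(-"day", names_to = "series", values_to = "value")
}

#' Summarize a trajectory
#'
#' @param x A `deb_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: horizon, molt count, final stage, final total
#'   wet weight, final ovary mass, puberty-molt day (`NA` if not reached)
#'   and whether starvation occurred.
#' @export
#' @method glance deb_trajectory
glance.deb_trajectory <- function(x, ...) {
  molts <- molt_events(x)
  pub <- molts$day[molts$stage_from == 11L]
  tibble::tibble(
    horizon = max(x$day),
    n_molts = nrow(molts),
    final_stage = x$stage[nrow(x)],
    ww_total_final = x$ww_total[nrow(x)],
    wo_final = x$wo[nrow(x)],
    puberty_day = if (length(pub)) pub[1] else NA_real_,
    starved = any(x$starving)
  )
}

#' @export
#' @method tidy deb_arrhenius
tidy.deb_arrhenius <- function(x, ...) x$groups

#' @export
#' @method glance deb_arrhenius
glance.deb_arrhenius <- function(x, ...) {
  tibble::tibble(TA = x$TA, sd = x$sd, n_groups = x$n_groups)
}

#' @export
print.deb_trajectory <- function(x, ...) {
  g <- glance.deb_trajectory(x)
  cat(sprintf(
    "<deb_trajectory> %d days, %d molts, final stage %s, total %.2f g (ovary %.2f g)\n",
    g$horizon, g$n_molts, stage_to_roman(g$final_stage), g$ww_total_final,
    g$wo_final))
  NextMethod()
}
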