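#' Write a trajectory (and its molt events) to delimited text
#'
#' The trajectory file uses the columns
#' `day, temp_C, stage, Ww, WO, Ww_total, WC, alpha, E, WG, ER, molted`;
#' the optional molt-event sidecar holds
#' `day, stage_from, stage_to, Ww_before, Ww_after`.
#'
#' @param traj A `deb_trajectory`.
#' @param path Output CSV path.
#' @param molt_path Optional path for the molt-event sidecar.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, molt_path = NULL) {
  stopifnot(inherits(traj, "deb_trajectory"))
  out <- data.frame(day = traj$day, temp_C = traj$temp_c,
                    stage = stage_to_roman(traj$stage), Ww = traj$ww,
                    WO = traj$wo, Ww_total = traj$ww_total, WC = traj$wc,
                    alpha = traj$alpha, E = traj$e, WG = traj$wg,
                    ER = traj$er, molted = traj$molted)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(molt_path)) {
    m <- molt_events(traj)
    utils::write.csv(
      data.frame(day = m$day, stage_from = stage_to_roman(m$stage_from),
                 stage_to = stage_to_roman(m$stage_to),
                 Ww_before = m$ww_before, Ww_after = m$ww_after),
      molt_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read observed growth or ovary records
#'
#' Delimited text (comma or tab) with a `day` column and at least one of
#' `Ww_total` (or `ww_total`) and `WO` (or `wo`).
#'
#' @param path Path to the file.
#' @return A tibble with columns `day` and whichever of `ww_total`, `wo`
#'   are present.
#' @export
read_observations <- function(path) {
  line1 <- readLines(path, n = 1)
  sep <- if (grepl("\t", line1)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"day" %in% names(df)) stop("missing `day` column", call. = FALSE)
  keep <- intersect(c("day", "ww_total", "wo"), names(df))
  if (length(keep) < 2) {
    stop("need a `Ww_total` and/or `WO` column", call. = FALSE)
  }
  tibble::as_tibble(df[keep])
}
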