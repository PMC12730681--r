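#' Default DEB parameter set for the swimming crab
#'
#' Constructs the parameter set driving the bioenergetic model. Defaults are
#' the values estimated for pond-cultured *Portunus trituberculatus* from
#' oxygen-consumption, starvation, feeding, molt-ratio and ovarian energy
#' budget experiments. All rate parameters refer to the reference temperature
#' `T_ref` (25 degC, the temperature at which they were measured) and are
#' corrected elsewhere with a single Arrhenius factor.
#'
#' @param TA Arrhenius temperature (K). Slope of ln(rate) against 1/T.
#' @param T_ref Reference temperature (K) at which rates are expressed.
#' @param pAm Maximum surface-specific assimilation rate
#'   (J g^-2/3 d^-1 at `T_ref`), scaling with structural weight to the 2/3
#'   power.
#' @param f Scaled functional response in `[0, 1]`; 0.9 represents
#'   near-ad-libitum pond feeding.
#' @param AE Assimilation efficiency (dimensionless). Informational: the
#'   assimilation experiment folds it into `pAm`.
#' @param pM Structural-weight-specific somatic maintenance rate
#'   (J g^-1 d^-1 at `T_ref`).
#' @param EG Specific cost of structure (J per g structural weight grown).
#' @param Em Maximum reserve density (J per g structural weight). Acts as a
#'   soft cap: assimilation is clamped while the reserve density sits at or
#'   above `Em`.
#' @param muE Energy content of reserve (J per g reserve carbon).
#' @param beta Reference ratio of structural weight to carbon weight at full
#'   reserve (dimensionless); used to split the initial carbon weight into
#'   structure and reserve.
#' @param kappa Named numeric of length 3: the fraction of mobilized reserve
#'   routed to the soma in each allocation phase — `juvenile` (stages I-VII),
#'   `subadult` (stages VIII-XI, before the puberty molt) and `adult` (after
#'   the puberty molt).
#' @param alpha_pre Numeric of length 11: stage-specific pre-molt thresholds
#'   on the carbon-to-wet-weight ratio `alpha = WC/Ww`; a molt fires when
#'   `alpha >= alpha_pre[stage]`.
#' @param alpha_post Post-molt carbon-to-wet-weight ratio; the wet weight
#'   jumps to `WC / alpha_post` at each molt.
#' @param EBO Energy cost per g ovary before the puberty molt (J g^-1).
#' @param EAO Energy cost per g ovary after the puberty molt (J g^-1).
#' @param mGm Maximum reproductive-material density (g ovary carbon per g
#'   structural weight). Calibrated; see [calibrate_gonad()].
#' @param nuG Gonad growth coefficient (d^-1). Calibrated; see
#'   [calibrate_gonad()].
#' @param cO Ovary carbon fraction (g carbon per g ovary wet mass).
#' @param oxycal Oxygen-energy equivalent (J per g O2); used only by the
#'   starvation estimator.
#' @param dt Integration step (d) of the explicit Euler scheme.
#' @param ww_stage1 Default wet weight (g) of a freshly molted stage-I
#'   juvenile; anchors the reference run behind [build_stage_table()].
#'
#' @return An object of class `deb_params`: a validated named list.
#' @examples
#' p <- deb_params()
#' p$TA
#' kappa_schedule(p, stage = 9)
#' @export
deb_params <- function(TA = 5482,
                       T_ref = 298.15,
                       pAm = 4590,
                       f = 0.9,
                       AE = 0.95,
                       pM = 310,
                       EG = 51180,
                       Em = 3860,
                       muE = 18750,
                       beta = 0.79,
                       kappa = c(juvenile = 1.0, subadult = 0.9, adult = 0.2),
                       alpha_pre = c(0.27, 0.44, 0.30, 0.30, 0.30, 0.26,
                                     0.21, 0.19, 0.16, 0.15, 0.15),
                       alpha_post = 0.1,
                       EBO = 36690,
                       EAO = 66200,
                       mGm = 0.93,
                       nuG = 0.008,
                       cO = 0.4,
                       oxycal = 15496,
                       dt = 0.1,
                       ww_stage1 = 0.02) {
  p <- list(TA = TA, T_ref = T_ref, pAm = pAm, f = f, AE = AE, pM = pM,
            EG = EG, Em = Em, muE = muE, beta = beta, kappa = kappa,
            alpha_pre = alpha_pre, alpha_post = alpha_post, EBO = EBO,
            EAO = EAO, mGm = mGm, nuG = nuG, cO = cO, oxycal = oxycal,
            dt = dt, ww_stage1 = ww_stage1)
  class(p) <- "deb_params"
  validate_params(p)
  p
}

#' Validate a DEB parameter set
#'
#' Checks positivity, unit-interval and ordering constraints. In particular
#' every pre-molt threshold must exceed the post-molt ratio (otherwise a molt
#' would fire immediately after the previous one) and the three kappa phases
#' must be non-increasing.
#'
#' @param p A `deb_params` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "deb_params"))
  pos <- c("TA", "T_ref", "pAm", "pM", "EG", "Em", "muE", "EBO", "EAO",
           "mGm", "nuG", "cO", "oxycal", "dt", "ww_stage1")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0) {
      stop("parameter `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  frac <- c("f", "AE", "beta", "alpha_post")
  for (nm in frac) {
    if (p[[nm]] <= 0 || p[[nm]] > 1) {
      stop("parameter `", nm, "` must lie in (0, 1]", call. = FALSE)
    }
  }
  if (length(p$alpha_pre) != 11) {
    stop("`alpha_pre` must hold one threshold per stage I-XI", call. = FALSE)
  }
  if (any(p$alpha_pre <= p$alpha_post) || any(p$alpha_pre >= 1)) {
    stop("every `alpha_pre` must lie in (alpha_post, 1)", call. = FALSE)
  }
  if (length(p$kappa) != 3 ||
      !all(names(p$kappa) == c("juvenile", "subadult", "adult"))) {
    stop("`kappa` must be named c(juvenile=, subadult=, adult=)",
         call. = FALSE)
  }
  if (any(p$kappa <= 0) || any(p$kappa > 1) || is.unsorted(rev(p$kappa))) {
    stop("`kappa` values must lie in (0, 1] and be non-increasing across ",
         "the juvenile, subadult and adult phases", call. = FALSE)
  }
  invisible(p)
}

#' Stage-dependent energy allocation fraction
#'
#' Returns the kappa-rule fraction of mobilized reserve routed to somatic
#' maintenance and growth. Stages I-VII allocate everything to the soma
#' (no ovarian investment), stages VIII-XI route 10% to the reproductive
#' channel (slow ovarian development), and after the puberty molt the somatic
#' share drops to the adult value (rapid ovarian growth). The switch happens
#' instantaneously at the molt creating the stage transition.
#'
#' @param p A `deb_params` object.
#' @param stage Integer molt stage, 1-11.
#' @param post_puberty Has the stage-XI (puberty) molt occurred?
#' @return A single kappa value.
#' @examples
#' kappa_schedule(deb_params(), 9)           # 0.9
#' kappa_schedule(deb_params(), 11, TRUE)    # 0.2
#' @export
kappa_schedule <- function(p, stage, post_puberty = FALSE) {
  stopifnot(stage >= 1, stage <= 11)
  if (post_puberty) {
    unname(p$kappa[["adult"]])
  } else if (stage <= 7) {
    unname(p$kappa[["juvenile"]])
  } else {
    unname(p$kappa[["subadult"]])
  }
}

#' Read and write parameter files
#'
#' Parameter sets serialize to a flat YAML mapping mirroring the field names
#' of [deb_params()]; reading one back reproduces the values bit-for-bit.
#'
#' @param p A `deb_params` object.
#' @param path File path of the YAML parameter file.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a validated `deb_params` object.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "deb_params"))
  x <- unclass(p)
  x$kappa <- as.list(x$kappa)
  writeLines(yaml::as.yaml(x, precision = 17), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  x$kappa <- unlist(x$kappa)
  x$alpha_pre <- as.numeric(x$alpha_pre)
  do.call(deb_params, x)
}

#' @export
print.deb_params <- function(x, ...) {
  cat("<deb_params>\n")
  cat(sprintf("  TA = %g K, T_ref = %g K, pAm = %g J g^-2/3 d^-1, f = %g\n",
              x$TA, x$T_ref, x$pAm, x$f))
  cat(sprintf("  pM = %g, EG = %g, Em = %g, muE = %g J g^-1; beta = %g\n",
              x$pM, x$EG, x$Em, x$muE, x$beta))
  cat(sprintf("  kappa: juvenile %g | subadult %g | adult %g\n",
              x$kappa[["juvenile"]], x$kappa[["subadult"]],
              x$kappa[["adult"]]))
  cat("  alpha_pre (I-XI):", paste(format(x$alpha_pre), collapse = " "), "\n")
  cat(sprintf("  alpha_post = %g; EBO = %g, EAO = %g J g^-1\n",
              x$alpha_post, x$EBO, x$EAO))
  cat(sprintf("  gonad: nuG = %g d^-1, mGm = %g, cO = %g\n",
              x$nuG, x$mGm, x$cO))
  cat(sprintf("  dt = %g d\n", x$dt))
  invisible(x)
}

#' Roman-numeral molt stage labels
#'
#' Stages are integers 1-11 internally; Roman numerals (I-XI) are used at
#' input/output boundaries only.
#'
#' @param stage Integer stage index (1-11).
#' @param label Roman numeral label ("I".."XI").
#' @return The converted label or index.
#' @examples
#' stage_to_roman(8)     # "VIII"
#' roman_to_stage("XI")  # 11
#' @export
stage_to_roman <- function(stage) {
  as.character(utils::as.roman(stage))
}

#' @rdname stage_to_roman
#' @export
roman_to_stage <- function(label) {
  out <- as.integer(utils::as.roman(label))
  if (any(is.na(out))) stop("unparseable stage label", call. = FALSE)
  out
}
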