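#' Literature observations of post-duplication gene shuffling
#'
#' Ships with the package as a plain-text fixture: for each taxon and
#' duplication age, the reported percentage of duplicates either
#' structurally lost (`structural`) or diverged in expression
#' (`functional`), as ranges in million years and percent.
#'
#' @return data frame: taxon, mode, time_low, time_high, percent_low,
#'   percent_high
#' @export
shuffling_observations <- function() {
  path <- system.file("extdata", "shuffling_observations.tsv",
                      package = "polyfate", mustWork = TRUE)
  read_tsv(path)
}

#' Fit a logarithmic shuffling curve
#'
#' Fits `percent = a + b * ln(time)` by (weighted) least squares to the
#' midpoints of interval observations; predictions are clamped to
#' [0, 100].  The weight of an observation is `1 / max(hw, 1)^2` where
#' `hw` is the half-width of its percent range, so tighter literature
#' estimates count more; point observations get the floor half-width of
#' one percentage point.
#'
#' @param observations data frame as from [shuffling_observations()]
#' @param mode one of `"structural"`, `"functional"`, `"total"` (total
#'   pools both modes into one curve)
#' @param weighted use inverse-squared half-width weights
#' @param min_halfwidth floor on the percent half-width used in weights
#' @return object of class `shuffling_curve`: a, b, fit_residual
#'   (root-mean-square, percent), mode, data
#' @export
fit_curve <- function(observations,
                      mode = c("total", "structural", "functional"),
                      weighted = TRUE, min_halfwidth = 1) {
  mode <- match.arg(mode)
  obs <- if (mode == "total") observations else
    observations[observations$mode == mode, , drop = FALSE]
  if (nrow(obs) < 2L) {
    stop("need at least 2 observations to fit a curve", call. = FALSE)
  }
  stopifnot(all(obs$time_low > 0), all(obs$time_low <= obs$time_high),
            all(obs$percent_low <= obs$percent_high),
            all(obs$percent_high <= 100))
  t_mid <- (obs$time_low + obs$time_high) / 2
  y_mid <- (obs$percent_low + obs$percent_high) / 2
  hw <- pmax((obs$percent_high - obs$percent_low) / 2, min_halfwidth)
  w <- if (weighted) 1 / hw^2 else rep(1, nrow(obs))
  fit <- stats::lm(y_mid ~ log(t_mid), weights = w)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  structure(list(mode = mode, a = a, b = b,
                 fit_residual = sqrt(mean(stats::resid(fit)^2)),
                 t_range = range(t_mid),
                 data = data.frame(t = t_mid, percent = y_mid,
                                   weight = w)),
            class = "shuffling_curve")
}

#' Predict percent shuffled at given divergence times
#'
#' @param curve a fitted [fit_curve()] object
#' @param t divergence times in million years
#' @return data frame: t, percent (clamped to [0, 100]), extrapolated
#'   (TRUE below the earliest or above the latest observed time)
#' @export
predict_shuffling <- function(curve, t) {
  stopifnot(inherits(curve, "shuffling_curve"), all(t > 0))
  raw <- curve$a + curve$b * log(t)
  data.frame(t = t,
             percent = pmin(pmax(raw, 0), 100),
             extrapolated = t < curve$t_range[1] | t > curve$t_range[2])
}

#' @export
print.shuffling_curve <- function(x, ...) {
  cat(sprintf(
    "shuffling curve [%s]: percent = %.2f + %.2f ln(t), rms %.2f%%\n",
    x$mode, x$a, x$b, x$fit_residual))
  invisible(x)
}

#' Invert the shuffling curve: time to reach a shuffling level
#'
#' Solves `level = a + b * ln(t)` for `t = exp((level - a) / b)` on the
#' unclamped curve.
#'
#' @param curve a fitted [fit_curve()] object with positive slope
#' @param level percent shuffled, in (0, 100]
#' @return list with `time` (million years) and `extrapolated` (TRUE
#'   when the solution lies outside the observed time range)
#' @export
time_at_level <- function(curve, level) {
  stopifnot(inherits(curve, "shuffling_curve"))
  if (curve$b <= 0) {
    stop("curve slope must be positive to invert", call. = FALSE)
  }
  if (level <= 0 || level > 100) {
    stop("level must lie in (0, 100]", call. = FALSE)
  }
  t <- exp((level - curve$a) / curve$b)
  list(time = t,
       extrapolated = t < curve$t_range[1] || t > curve$t_range[2])
}
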