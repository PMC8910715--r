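#' Fit a calibration curve for one compound
#'
#' Ordinary least squares line response = slope * concentration +
#' intercept over the standards; optional 1/x weighting for
#' heteroscedastic responses.
#'
#' @param concentration,response standard series (>= 3 distinct
#'   concentrations).
#' @param compound optional compound name carried through.
#' @param weighting "none" (default) or "1/x".
#' @return List of class `calibration_curve`: `compound`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
fit_calibration <- function(concentration, response, compound = NA_character_,
                            weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  if (length(unique(concentration)) < 3L) {
    stop("need at least 3 distinct standard concentrations")
  }
  w <- if (weighting == "1/x") 1 / pmax(concentration, min(concentration[concentration > 0])) else NULL
  fit <- stats::lm(response ~ concentration, weights = w)
  structure(list(compound = compound,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "calibration_curve")
}

#' Quantify a concentration from a peak area
#'
#' Inverts the calibration line: (area - intercept) / slope, times the
#' dilution factor. Negative results are floored at 0 and flagged as
#' below the limit of quantification.
#'
#' @param curve a `calibration_curve`.
#' @param peak_area observed response(s).
#' @param dilution multiplicative dilution factor (default 1).
#' @return data.frame `concentration`, `below_loq`.
#' @export
quantify_hormone <- function(curve, peak_area, dilution = 1) {
  if (curve$slope == 0) stop("calibration slope is zero")
  conc <- (peak_area - curve$intercept) / curve$slope * dilution
  below <- conc < 0
  data.frame(concentration = pmax(conc, 0), below_loq = below)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom, two-sided
#' (the robust default at n = 3 per group); set `pooled = TRUE` for the
#' classic equal-variance test.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param pooled use the pooled-variance test instead (default FALSE).
#' @return List `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b, pooled = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Significance stars
#'
#' `**` for p < 0.01, `*` for p < 0.05, empty otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of stars.
#' @export
stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
}

#' Per-replicate fold-change range of class totals
#'
#' Pairs dwarf and tall class totals by replicate index and reports the
#' minimum and maximum dwarf/tall ratio — the style in which class-level
#' hormone shifts are reported (e.g. "1.41- to 1.66-fold higher").
#'
#' @param tall,dwarf class totals per replicate (equal lengths, paired by
#'   index).
#' @return Named vector `min`, `max`.
#' @export
fold_change_range <- function(tall, dwarf) {
  if (length(tall) != length(dwarf)) stop("replicate counts differ")
  if (any(tall == 0)) stop("zero tall class total: ratio undefined")
  r <- dwarf / tall
  c(min = min(r), max = max(r))
}

#' Class totals per group and replicate
#'
#' @param panel hormone table (`compound`, `class`, `group`, `replicate`,
#'   `concentration`).
#' @return data.frame `class`, `group`, `replicate`, `total`.
#' @export
hormone_class_totals <- function(panel) {
  agg <- stats::aggregate(concentration ~ class + group + replicate,
                          data = panel, FUN = sum)
  names(agg)[names(agg) == "concentration"] <- "total"
  agg
}

#' Group comparison report per hormone class
#'
#' Means and standard errors per group, per-replicate fold-change range,
#' Welch t-test and significance stars for each class — the tabular
#' equivalent of a barplot-with-stars hormone figure.
#'
#' @param panel hormone table (see [hormone_class_totals()]).
#' @return data.frame per class: group means/SEs, `fold_min`, `fold_max`,
#'   `t`, `p`, `stars`.
#' @export
hormone_class_report <- function(panel) {
  tot <- hormone_class_totals(panel)
  out <- lapply(split(tot, tot$class), function(d) {
    d <- d[order(d$replicate), ]
    tall <- d$total[d$group == "tall"]
    dwarf <- d$total[d$group == "dwarf"]
    fr <- fold_change_range(tall, dwarf)
    tt <- welch_t_test(dwarf, tall)
    data.frame(class = d$class[1L],
               mean_tall = mean(tall),
               se_tall = stats::sd(tall) / sqrt(length(tall)),
               mean_dwarf = mean(dwarf),
               se_dwarf = stats::sd(dwarf) / sqrt(length(dwarf)),
               fold_min = fr[["min"]], fold_max = fr[["max"]],
               t = tt$t, p = tt$p, stars = stars(tt$p))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
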