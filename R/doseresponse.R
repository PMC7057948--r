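#' Blank-correct and OD-normalise plate-reader time courses
#'
#' Implements the standard reporter normalisation: at every time point the
#' mean fluorescence and mean absorbance of the blank (medium-only) wells
#' are subtracted from each sample well, and the corrected fluorescence is
#' divided by the corrected OD600, giving absolute normalised fluorescence
#' in AFU/OD. Time points whose corrected OD falls at or below `od_floor`
#' are masked (`NA`): dividing by near-zero biomass amplifies noise without
#' bound.
#'
#' @param courses Long-format data.frame with columns `well`, `system`,
#'   `inducer`, `concentration_M`, `time_min`, `fluorescence`, `od600`,
#'   `is_blank`.
#' @param od_floor Minimum corrected OD for a usable point; default 0.01.
#' @return The input with an added `norm_fl` column (AFU/OD, `NA` where
#'   masked); blank wells get `NA`.
#' @export
normalize_measurements <- function(courses, od_floor = 0.01) {
  req <- c("well", "time_min", "fluorescence", "od600", "is_blank")
  if (!all(req %in% names(courses))) {
    stop("missing columns: ", paste(setdiff(req, names(courses)),
                                    collapse = ", "))
  }
  blanks <- courses[courses$is_blank, , drop = FALSE]
  if (!nrow(blanks)) stop("no blank wells present; cannot blank-correct")
  blank_fl <- tapply(blanks$fluorescence, blanks$time_min, mean)
  blank_od <- tapply(blanks$od600, blanks$time_min, mean)

  key <- as.character(courses$time_min)
  fl_corr <- courses$fluorescence - blank_fl[key]
  od_corr <- courses$od600 - blank_od[key]
  norm <- ifelse(od_corr > od_floor, fl_corr / od_corr, NA_real_)
  norm[courses$is_blank] <- NA_real_
  courses$norm_fl <- as.numeric(norm)

  for (w in unique(courses$well[!courses$is_blank])) {
    if (all(is.na(courses$norm_fl[courses$well == w]))) {
      stop("all time points masked for well ", w,
           " (corrected OD never above floor)")
    }
  }
  courses
}

#' Read normalised fluorescence at the minimal induction interval
#'
#' For each sample well, returns the normalised fluorescence at the sampled
#' time nearest `t_window` minutes after inducer addition. The nearest
#' sample must lie within half the sampling interval of the target; no
#' interpolation is performed, mirroring how values "recorded 80 min after"
#' induction are read off a 5-min acquisition grid. The 80-min default is
#' the minimal induction interval: late enough for reporter synthesis and
#' maturation, early enough that inducer catabolism has not yet distorted
#' the dose-response.
#'
#' @param courses Normalised long-format data (see
#'   [normalize_measurements()]).
#' @param t_window Target time in minutes; default 80.
#' @return data.frame with one row per sample well: `well`, `system`,
#'   `inducer`, `concentration_M`, `time_min` (the sample actually used),
#'   `norm_fl`.
#' @export
extract_induction_window <- function(courses, t_window = 80) {
  if (!"norm_fl" %in% names(courses)) {
    stop("normalised channel missing; run normalize_measurements() first")
  }
  samples <- courses[!courses$is_blank, , drop = FALSE]
  rows <- list()
  for (w in unique(samples$well)) {
    cw <- samples[samples$well == w, , drop = FALSE]
    cw <- cw[order(cw$time_min), , drop = FALSE]
    dt <- if (nrow(cw) > 1L) stats::median(diff(cw$time_min)) else Inf
    i <- which.min(abs(cw$time_min - t_window))
    if (abs(cw$time_min[i] - t_window) > dt / 2) {
      stop("well ", w, ": no sample within half a sampling interval of t = ",
           t_window, " min")
    }
    rows[[length(rows) + 1L]] <- cw[i, c("well", "system", "inducer",
                                         "concentration_M", "time_min",
                                         "norm_fl")]
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Build a dose-response dataset from windowed measurements
#'
#' @param points data.frame with `concentration_M` and `norm_fl` (e.g. from
#'   [extract_induction_window()]); may carry `system`.
#' @return Object of class `dose_response`: list with `system_id`, `points`
#'   (columns `I`, `RFP`), `b_min_obs` (mean of the uninduced wells) and
#'   `b_min_sd` (their standard deviation, 0 for a single well).
#' @export
dose_response_dataset <- function(points) {
  I <- points$concentration_M
  RFP <- points$norm_fl
  if (any(I < 0)) stop("negative inducer concentration")
  if (!any(I == 0)) stop("at least one uninduced (I = 0) point is required")
  un <- RFP[I == 0]
  structure(
    list(
      system_id = if ("system" %in% names(points)) points$system[1] else NA,
      points = data.frame(I = I, RFP = RFP),
      b_min_obs = mean(un, na.rm = TRUE),
      b_min_sd = if (sum(!is.na(un)) > 1L) stats::sd(un, na.rm = TRUE) else 0
    ),
    class = "dose_response"
  )
}

#' Hill dose-response model
#'
#' `RFP(I) = b_max * I^h / (K_m^h + I^h) + b_min`. `b_max` is the amplitude
#' of the inducible component, `K_m` the inducer concentration giving
#' half-maximal activation, `h` the Hill coefficient and `b_min` the basal
#' output of the uninduced cells.
#'
#' @param I Inducer concentrations (molar).
#' @param b_max,K_m,h,b_min Hill parameters.
#' @return Predicted normalised fluorescence.
#' @export
hill_model <- function(I, b_max, K_m, h, b_min) {
  ifelse(I > 0, b_max * I^h / (K_m^h + I^h), 0) + b_min
}

#' Fit the Hill model to a dose-response dataset
#'
#' Non-linear least squares via Levenberg-Marquardt
#' ([minpack.lm::nlsLM()]) with box constraints. Initialisation:
#' `b_min` at the uninduced mean, `b_max` at `max(RFP) - b_min`, `h = 1`,
#' and `K_m` at the best point of a log-spaced grid over the observed
#' concentration range (evaluated at the initial `b_min`/`b_max`/`h`).
#' Bounds: `h` in [0.1, 10], `K_m` in [min I>0 / 100, max I * 100].
#' Parameter standard deviations come from the covariance of the fit.
#' Optimiser failure is reported via `converged = FALSE`, never as an
#' exception, so a screen over many systems can mark one as not determined
#' and continue.
#'
#' @param dataset `dose_response` object from [dose_response_dataset()].
#' @param h_bounds,K_m_factor Bound controls (defaults as above).
#' @return Object of class `hill_fit`: list with `b_max`, `b_min`, `K_m`,
#'   `h` (each with `.sd` companion), `mu`, `sigma_mu`, `converged`, `sse`,
#'   `b_min_sd_obs` (replicate spread of the uninduced wells) and the
#'   underlying `nls` object in `$fit`.
#' @export
fit_hill <- function(dataset, h_bounds = c(0.1, 10), K_m_factor = 100) {
  pts <- dataset$points[stats::complete.cases(dataset$points), , drop = FALSE]
  I <- pts$I
  RFP <- pts$RFP
  if (any(!is.finite(RFP))) stop("non-finite fluorescence values")
  nz <- sort(unique(I[I > 0]))
  if (length(nz) < 4L) {
    stop("need >= 4 distinct non-zero inducer concentrations, got ",
         length(nz))
  }

  b_min0 <- dataset$b_min_obs
  b_max0 <- max(RFP) - b_min0
  if (b_max0 <= 0) b_max0 <- max(RFP) * 0.1 + 1e-9
  km_lo <- min(nz) / K_m_factor
  km_hi <- max(nz) * K_m_factor
  km_grid <- exp(seq(log(min(nz)), log(max(nz)), length.out = 25))
  sse_at <- function(km) {
    sum((RFP - hill_model(I, b_max0, km, 1, b_min0))^2)
  }
  km0 <- km_grid[which.min(vapply(km_grid, sse_at, numeric(1)))]

  res <- list(converged = FALSE, b_max = NA_real_, b_max_sd = NA_real_,
              b_min = NA_real_, b_min_sd = NA_real_, K_m = NA_real_,
              K_m_sd = NA_real_, h = NA_real_, h_sd = NA_real_,
              mu = NA_real_, sigma_mu = NA_real_, sse = NA_real_,
              b_min_sd_obs = dataset$b_min_sd, fit = NULL)
  class(res) <- "hill_fit"

  fit <- tryCatch(
    minpack.lm::nlsLM(
      RFP ~ hill_model(I, b_max, K_m, h, b_min),
      data = data.frame(I = I, RFP = RFP),
      start = list(b_max = b_max0, K_m = km0, h = 1, b_min = b_min0),
      lower = c(b_max = 1e-12, K_m = km_lo, h = h_bounds[1],
                b_min = 0),
      upper = c(b_max = Inf, K_m = km_hi, h = h_bounds[2], b_min = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(res)

  cf <- stats::coef(fit)
  sds <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) {
    stats::setNames(rep(NA_real_, 4), names(cf))
  })
  res$converged <- TRUE
  res$b_max <- unname(cf["b_max"]); res$b_max_sd <- unname(sds["b_max"])
  res$b_min <- unname(cf["b_min"]); res$b_min_sd <- unname(sds["b_min"])
  res$K_m <- unname(cf["K_m"]); res$K_m_sd <- unname(sds["K_m"])
  res$h <- unname(cf["h"]); res$h_sd <- unname(sds["h"])
  res$sse <- sum(stats::resid(fit)^2)
  res$fit <- fit
  if (res$h <= h_bounds[1] + 1e-9 || res$h >= h_bounds[2] - 1e-9 ||
      diff(range(RFP)) < .Machine$double.eps^0.5 * max(abs(RFP), 1)) {
    res$degenerate <- TRUE
  }
  if (res$b_min > 0) {
    dr <- dynamic_range(res, b_min_sd = dataset$b_min_sd)
    res$mu <- dr$mu
    res$sigma_mu <- dr$sigma_mu
  }
  res
}

#' Dynamic range of an inducible system with propagated uncertainty
#'
#' The dynamic range is the fold increase from basal to maximal output,
#' `mu = b_max / b_min`, and its standard deviation is propagated from the
#' relative uncertainties of the two levels:
#' `sigma_mu = mu * sqrt((sigma_bmax/b_max)^2 + (sigma_bmin/b_min)^2)`.
#' `sigma_bmax` is taken from the fit covariance; `sigma_bmin` from the
#' replicate spread of the uninduced wells (pass it explicitly, or it falls
#' back to the fit's own `b_min` uncertainty).
#'
#' @param fit `hill_fit` object.
#' @param b_min_sd Standard deviation of the uninduced normalised
#'   fluorescence replicates.
#' @return list with `mu` and `sigma_mu`.
#' @export
dynamic_range <- function(fit, b_min_sd = NULL) {
  if (!isTRUE(fit$converged)) stop("fit did not converge; dynamic range ND")
  if (!is.finite(fit$b_min) || fit$b_min <= 0) {
    stop("b_min <= 0: dynamic range not determined (ND)")
  }
  s_bmax <- if (is.finite(fit$b_max_sd)) fit$b_max_sd else 0
  s_bmin <- if (!is.null(b_min_sd)) b_min_sd else
    if (is.finite(fit$b_min_sd)) fit$b_min_sd else 0
  mu <- fit$b_max / fit$b_min
  sigma_mu <- mu * sqrt((s_bmax / fit$b_max)^2 + (s_bmin / fit$b_min)^2)
  list(mu = mu, sigma_mu = sigma_mu)
}

#' Relative response on a 0-100% scale
#'
#' `rel(I) = 100 * (RFP(I) - RFP_uninduced) / b_max`: the uninduced level
#' maps to 0% and the fitted maximal amplitude to 100%. When no converged
#' fit with a defined `b_max` exists (e.g. saturation was never reached at
#' soluble concentrations), the observation at the highest tested
#' concentration is set to 100% instead (`fallback = TRUE`).
#'
#' @param dataset `dose_response` object.
#' @param fit `hill_fit`, or `NULL` to force the fallback scaling.
#' @return data.frame with `I`, `RFP`, `rel_pct` and attribute `fallback`.
#' @export
relative_response <- function(dataset, fit = NULL) {
  pts <- dataset$points
  un <- dataset$b_min_obs
  fallback <- is.null(fit) || !isTRUE(fit$converged) ||
    !is.finite(fit$b_max) || fit$b_max <= 0
  if (fallback) {
    top <- mean(pts$RFP[pts$I == max(pts$I)], na.rm = TRUE)
    denom <- top - un
    if (!is.finite(denom) || denom == 0) {
      stop("cannot scale: highest-concentration response equals uninduced")
    }
  } else {
    denom <- fit$b_max
  }
  out <- data.frame(I = pts$I, RFP = pts$RFP,
                    rel_pct = 100 * (pts$RFP - un) / denom)
  attr(out, "fallback") <- fallback
  out
}

#' Fold induction of a reporter
#'
#' @param induced_norm Normalised fluorescence with inducer (AFU/OD).
#' @param uninduced_norm Normalised fluorescence without inducer; must be
#'   positive.
#' @return `induced_norm / uninduced_norm`.
#' @export
fold_induction <- function(induced_norm, uninduced_norm) {
  if (any(uninduced_norm <= 0)) {
    stop("uninduced normalised fluorescence must be positive")
  }
  induced_norm / uninduced_norm
}

#' Intracellular metabolite concentration from a pellet extraction
#'
#' The wet pellet volume is `V_pellet = pellet_wet_mass / cell_density`
#' (density 1.105 g/mL for non-PHB-accumulating cells). The extract
#' concentration is scaled back by the dilution the extraction solvent
#' imposed:
#' `C_intracellular = ((V_pellet + V_solvent) / V_pellet) * C_extract`.
#' The dilution factor is always >= 1, so the intracellular concentration
#' is never below the extract concentration.
#'
#' @param pellet_wet_mass Wet pellet mass in g.
#' @param V_solvent Extraction solvent volume in mL.
#' @param C_extract Metabolite concentration in the extract (molar).
#' @param cell_density Cell density in g/mL; default 1.105.
#' @return Intracellular concentration (molar).
#' @export
intracellular_concentration <- function(pellet_wet_mass, V_solvent,
                                        C_extract, cell_density = 1.105) {
  if (pellet_wet_mass <= 0 || V_solvent < 0 || C_extract < 0 ||
      cell_density <= 0) {
    stop("masses, volumes and concentrations must be positive")
  }
  V_pellet <- pellet_wet_mass / cell_density
  ((V_pellet + V_solvent) / V_pellet) * C_extract
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("hill_fit: not converged (ND)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "hill_fit: b_max = %.4g +/- %.2g, b_min = %.4g +/- %.2g\n          K_m = %.4g +/- %.2g M, h = %.3g +/- %.2g\n",
    x$b_max, x$b_max_sd, x$b_min, x$b_min_sd, x$K_m, x$K_m_sd, x$h, x$h_sd))
  if (is.finite(x$mu)) {
    cat(sprintf("          dynamic range mu = %.4g +/- %.2g (fold)\n",
                x$mu, x$sigma_mu))
  }
  invisible(x)
}
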