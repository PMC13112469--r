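#' Dose-response table
#'
#' @param concentrations Strictly increasing positive doses (stated units,
#'   e.g. mg/mL).
#' @param responses Response fractions in \[0, 1\] (fraction inhibited).
#' @param counts Optional replicate counts per dose; when present the
#'   probit fit uses a binomial likelihood.
#' @return Object of class `dose_response`.
#' @export
dose_response <- function(concentrations, responses, counts = NULL) {
  stopifnot(length(concentrations) == length(responses))
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE))
    stop("concentrations must be strictly increasing")
  if (any(responses < 0 | responses > 1))
    stop("responses must lie in [0, 1]")
  if (!is.null(counts)) {
    stopifnot(length(counts) == length(responses), all(counts >= 1))
  }
  structure(list(concentrations = concentrations, responses = responses,
                 counts = counts), class = "dose_response")
}

#' Simulate a probit-shaped dose-response curve
#'
#' Generates responses from \eqn{\Phi(\beta_1(\log_{10} c - \log_{10}
#' IC_{50}))}, optionally with binomial sampling noise — the synthetic
#' stand-in for a scavenging-assay curve with a known half-maximal
#' inhibitory concentration.
#'
#' @param ic50 True IC50 (same units as `concentrations`).
#' @param slope Probit slope \eqn{\beta_1} on the log10 scale.
#' @param concentrations Dose grid; default 8 doses geometrically spanning
#'   two decades around `ic50`.
#' @param n Replicates per dose; `NULL` for noiseless fractions.
#' @return A [dose_response()].
#' @export
simulate_dose_response <- function(ic50, slope = 2.2,
                                   concentrations = ic50 * 10^seq(-1, 1,
                                                                  length.out = 8),
                                   n = NULL) {
  p <- pnorm(slope * (log10(concentrations) - log10(ic50)))
  if (is.null(n)) return(dose_response(concentrations, p))
  y <- rbinom(length(p), n, p)
  dose_response(concentrations, y / n, counts = rep(n, length(p)))
}

#' Probit IC50 estimation
#'
#' Fits \eqn{response = \Phi(\beta_0 + \beta_1 \log_{10} c)}: by binomial
#' maximum likelihood (probit link) when replicate counts are available,
#' and by least squares on the fractions otherwise.  The half-maximal
#' inhibitory concentration is \eqn{IC_{50} = 10^{-\beta_0/\beta_1}} with a
#' delta-method standard error.  If no observed response brackets 50%, the
#' estimate is flagged as an extrapolation.
#'
#' @param data A [dose_response()] with at least 3 doses and non-constant
#'   responses.
#' @return Object of class `ic50_fit`: `ic50`, `se`, `beta0`, `beta1`,
#'   `extrapolated`, `fit`.
#' @export
probit_ic50 <- function(data) {
  stopifnot(inherits(data, "dose_response"))
  x <- log10(data$concentrations)
  p <- data$responses
  if (length(x) < 3) stop("need at least 3 doses")
  if (length(unique(p)) == 1) stop("flat dose-response: cannot fit a probit")
  if (!is.null(data$counts)) {
    succ <- round(p * data$counts)
    fit <- glm(cbind(succ, data$counts - succ) ~ x,
               family = binomial(link = "probit"))
    b <- coef(fit)
    V <- vcov(fit)
  } else {
    pc <- pmin(pmax(p, 1e-3), 1 - 1e-3)
    start_fit <- lm(qnorm(pc) ~ x)
    fit <- nls(p ~ pnorm(b0 + b1 * x),
               start = list(b0 = coef(start_fit)[[1]],
                            b1 = coef(start_fit)[[2]]),
               control = nls.control(maxiter = 200, tol = 1e-10,
                                     minFactor = 1e-12,
                                     scaleOffset = 1))
    b <- coef(fit)
    V <- vcov(fit)
  }
  b0 <- b[[1]]; b1 <- b[[2]]
  if (abs(b1) < 1e-12) stop("degenerate probit slope")
  log_ic50 <- -b0 / b1
  ic50 <- 10^log_ic50
  # delta method on log10 IC50 -> IC50
  grad <- ic50 * log(10) * c(-1 / b1, b0 / b1^2)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  extrap <- !(min(p) <= 0.5 && max(p) >= 0.5)
  if (extrap)
    warning("50% response not bracketed by the data: IC50 is an extrapolation")
  structure(list(ic50 = ic50, se = se, beta0 = b0, beta1 = b1,
                 extrapolated = extrap, fit = fit), class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("IC50 = %.4g +/- %.2g (probit slope %.3g)%s\n", x$ic50, x$se,
              x$beta1, if (x$extrapolated) "  [extrapolated]" else ""))
  invisible(x)
}

#' Linear calibration curve
#'
#' Ordinary least squares through standards, e.g. a Trolox (0-500 µM)
#' antioxidant-capacity curve or an L-histidine TNBSA curve.
#'
#' @param x Standard concentrations (>= 2 distinct values).
#' @param y Measured signals.
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `fit`.
#' @export
linear_calibration <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 2) stop("need >= 2 distinct standard levels")
  fit <- lm(y ~ x)
  # direct R^2 (summary.lm warns on exact fits)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot < 1e-300) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  r2 <- min(max(r2, 0), 1)
  structure(list(slope = coef(fit)[["x"]],
                 intercept = coef(fit)[["(Intercept)"]],
                 r_squared = r2, fit = fit), class = "calibration_curve")
}

#' Quantify an unknown against a calibration curve
#'
#' Inverts the fitted line: \eqn{x = (y - intercept)/slope}.
#'
#' @param curve A [linear_calibration()] result.
#' @param y_obs Observed signal(s).
#' @return Estimated concentration(s).
#' @export
quantify <- function(curve, y_obs) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (abs(curve$slope) < 1e-12)
    stop("zero calibration slope: cannot quantify")
  (y_obs - curve$intercept) / curve$slope
}

#' Percent inhibition relative to a control
#'
#' \eqn{100 (control - treated)/control}; the conventional reduction of a
#' positive-cell percentage relative to its control.  Antitone in
#' `treated`, bounded above by 100.
#'
#' @param control Control value (> 0, percent).
#' @param treated Treated value (percent).
#' @return Percent inhibition (full precision; round for reporting).
#' @export
#' @examples
#' inhibition_percent(62.1, 33.4)   # 46.2 -> reported as 46%
inhibition_percent <- function(control, treated) {
  if (any(control <= 0)) stop("control must be > 0")
  if (any(control > 100 | treated < 0 | treated > 100))
    stop("percentages must lie in [0, 100]")
  100 * (control - treated) / control
}

#' Per-treatment inhibition table
#'
#' Applies [inhibition_percent()] to every non-control row against the
#' control at the same timepoint, and flags rows whose inhibition exceeds
#' `flag_threshold`.
#'
#' @param table Data frame with columns `treatment`, `timepoint`,
#'   `percent_positive`.
#' @param control_label Treatment label of the control rows.
#' @param flag_threshold Flag inhibitions strictly greater than this.
#' @return Data frame with `inhibition`, `inhibition_rounded`, `flagged`
#'   columns added (control rows excluded).
#' @export
inhibition_table <- function(table, control_label = "Control",
                             flag_threshold = 70) {
  needed <- c("treatment", "timepoint", "percent_positive")
  if (!all(needed %in% names(table)))
    stop("table must have columns: ", paste(needed, collapse = ", "))
  out <- NULL
  for (tp in unique(table$timepoint)) {
    sub <- table[table$timepoint == tp, , drop = FALSE]
    ctrl <- sub$percent_positive[sub$treatment == control_label]
    if (length(ctrl) != 1)
      stop("control row missing (or duplicated) at timepoint ", tp)
    trt <- sub[sub$treatment != control_label, , drop = FALSE]
    if (nrow(trt)) {
      trt$inhibition <- inhibition_percent(ctrl, trt$percent_positive)
      trt$inhibition_rounded <- round(trt$inhibition)
      trt$flagged <- trt$inhibition > flag_threshold
      out <- rbind(out, trt)
    }
  }
  if (is.null(out))
    out <- cbind(table[0, , drop = FALSE], inhibition = numeric(),
                 inhibition_rounded = numeric(), flagged = logical())
  rownames(out) <- NULL
  out
}

#' ROS-positive THP-1 macrophage percentages
#'
#' The flow-cytometry CellRox-positive cell percentages for PMA-activated
#' THP-1 macrophages exposed to PGAL, PGAL-His and free histidine, as
#' printed in the study (input data for [inhibition_table()]).
#'
#' @return Data frame with `treatment`, `timepoint` (hours),
#'   `percent_positive`.
#' @export
ros_cellrox <- function() {
  path <- system.file("extdata", "ros_cellrox.csv", package = "polybind")
  utils::read.table(path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
}

#' Reported binding free-energy components
#'
#' The published component energies (kJ/mol) for the best PGAL-histidine
#' complexes in the two protonation states — the inputs whose sum the
#' decomposition identity reproduces.
#'
#' @return Data frame with `complex`, `dG_solv`, `dG_coul`, `dG_nonelec`,
#'   `dG_b_reported`.
#' @export
reported_energy_components <- function() {
  path <- system.file("extdata", "reported_energy_components.csv",
                      package = "polybind")
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE)
  for (cl in c("dG_solv", "dG_coul", "dG_nonelec", "dG_b_reported"))
    tab[[cl]] <- as.numeric(tab[[cl]])
  tab
}
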