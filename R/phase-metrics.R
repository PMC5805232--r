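#' Compute stepping phases from heel-strike times
#'
#' The left-right stepping phase of gait cycle i is the step time of one leg
#' (role A) normalized by the concurrent stride time of the other leg
#' (role B), expressed in degrees of the 360-degree gait cycle:
#'
#' \deqn{\varphi_i = 360 \cdot \frac{t_{A,i} - t_{B,i}}{t_{B,i+1} - t_{B,i}}}
#'
#' where `t_A`, `t_B` are heel-strike times and events interleave as
#' `t_B,i < t_A,i < t_B,i+1`. In perfectly anti-phased stepping every phase
#' equals 180 degrees. The `side` argument selects which physical leg plays
#' role A: `"RreL"` is right step relative to left stride, `"LreR"` the
#' converse. Phases are dimensionless, hence invariant under any shift or
#' positive rescaling of the time axis.
#'
#' Leading role-A events before the first role-B strike and trailing role-A
#' events after the last role-B strike cannot form a complete
#' (B, A, B) triple; they are dropped with a warning.
#'
#' @param hs A [heel_strike_series()].
#' @param side `"RreL"` or `"LreR"`.
#' @return A `phase_series`: numeric vector of phases in degrees with
#'   attributes `side` and `trial_id`.
#' @examples
#' hs <- heel_strike_series(c(0, 1.0, 2.0), c(0.25, 1.75))
#' compute_phase_series(hs, "RreL")  # 90 and 270 degrees
#' @export
compute_phase_series <- function(hs, side = c("RreL", "LreR")) {
  stopifnot(inherits(hs, "heel_strike_series"))
  side <- match.arg(side)
  roles <- side_roles(hs, side)
  A <- roles$A
  B <- roles$B

  n_lead <- sum(A <= B[1])
  if (n_lead > 0) {
    warning(n_lead, " leading role-A event(s) before the first role-B strike dropped",
            call. = FALSE)
    A <- A[A > B[1]]
  }
  n_phi <- min(length(A), length(B) - 1L)
  if (length(A) > n_phi) {
    warning(length(A) - n_phi,
            " trailing role-A event(s) after the last usable role-B stride dropped",
            call. = FALSE)
    A <- A[seq_len(n_phi)]
  }
  if (n_phi < 2) {
    stop("insufficient data: fewer than 2 computable phases (need >= 3 role-B ",
         "strikes with interleaved role-A strikes)", call. = FALSE)
  }
  i <- seq_len(n_phi)
  bad <- which(!(A[i] > B[i] & A[i] < B[i + 1]))
  if (length(bad) > 0) {
    stop("interleaving violated at gait cycle ", bad[1],
         ": role-A strike at ", format(A[bad[1]], digits = 10),
         " s is not strictly inside the role-B stride (",
         format(B[bad[1]], digits = 10), ", ",
         format(B[bad[1] + 1], digits = 10), ") s", call. = FALSE)
  }
  phi <- 360 * (A[i] - B[i]) / (B[i + 1] - B[i])
  phase_series(phi, side = side, trial_id = hs$trial_id)
}

#' Construct a phase series directly from phase values
#'
#' @param phi Numeric vector of stepping phases in degrees, each strictly
#'   inside (0, 360).
#' @param side Phase convention label: `"RreL"`, `"LreR"`, or `"average"`.
#' @param trial_id Character trial label.
#' @return A `phase_series` object.
#' @export
phase_series <- function(phi, side = "RreL", trial_id = "trial") {
  phi <- as.numeric(phi)
  if (anyNA(phi) || any(phi <= 0 | phi >= 360)) {
    stop("phases must be strictly inside (0, 360) degrees", call. = FALSE)
  }
  structure(phi, side = side, trial_id = as.character(trial_id)[1],
            class = c("phase_series", "numeric"))
}

#' @export
print.phase_series <- function(x, ...) {
  cat("Phase series (", attr(x, "side"), ", '", attr(x, "trial_id"), "'): ",
      length(x), " phases, mean ", format(mean(unclass(x)), digits = 5),
      " deg\n", sep = "")
  print(as.numeric(x), ...)
  invisible(x)
}

#' Phase Coordination Index of a phase vector
#'
#' The PCI combines a consistency term (the coefficient of variation of the
#' phases, in percent) and an accuracy term (the mean absolute deviation of
#' the phases from the ideal 180 degrees, normalized to 180 degrees, in
#' percent):
#'
#' \deqn{PCI = \varphi_{CV} + P_{\varphi ABS}
#'   = 100\,\frac{sd(\varphi)}{mean(\varphi)}
#'   + 100\,\frac{mean(|\varphi - 180|)}{180}}
#'
#' Lower values mean better bilateral coordination; PCI is zero exactly when
#' every phase equals 180 degrees. The standard deviation uses the sample
#' (n - 1) normalization throughout the package.
#'
#' @param phi A `phase_series` or bare numeric vector of phases (degrees),
#'   length at least 2.
#' @return PCI in percent (scalar). Use [pci_components()] for the two
#'   addends.
#' @examples
#' compute_pci(c(180, 180, 180))   # 0
#' compute_pci(c(170, 190))        # 13.41 percent
#' @export
compute_pci <- function(phi) {
  pci_components(phi)$pci
}

#' @rdname compute_pci
#' @return For `pci_components()`, a list with elements `phi_cv`,
#'   `p_phi_abs` and `pci` (all percent).
#' @export
pci_components <- function(phi) {
  phi <- as.numeric(phi)
  if (length(phi) < 2) {
    stop("insufficient data: PCI needs at least 2 phase values", call. = FALSE)
  }
  m <- mean(phi)
  phi_cv <- 100 * stats::sd(phi) / m
  p_phi_abs <- 100 * mean(abs(phi - 180)) / 180
  list(phi_cv = phi_cv, p_phi_abs = p_phi_abs, pci = phi_cv + p_phi_abs)
}

#' Cumulative PCI series of a phase vector
#'
#' Position j of the cumulative series holds the PCI computed from the first
#' j + 1 phases, so a trial of N strides yields N - 1 PCI values and position
#' j corresponds to a stride count of j + 1 (`strides()` returns that
#' mapping). Each position is a pure function of the phase prefix it
#' summarizes.
#'
#' @param phi A `phase_series` or numeric phase vector, length >= 2.
#' @return A [pci_series()] of length `length(phi) - 1`.
#' @examples
#' s <- cumulative_pci_series(c(175, 185, 178, 183))
#' strides(s)  # 2 3 4
#' @export
cumulative_pci_series <- function(phi) {
  x <- as.numeric(phi)
  if (length(x) < 2) {
    stop("insufficient data: need at least 2 phases for a PCI series",
         call. = FALSE)
  }
  n <- length(x)
  # each prefix is recomputed directly: numerically safer than running-sum
  # updates when the variance is tiny relative to the mean
  vals <- vapply(2:n, function(k) {
    m <- mean(x[1:k])
    100 * stats::sd(x[1:k]) / m + 100 * mean(abs(x[1:k] - 180)) / 180
  }, numeric(1))
  pci_series(vals,
             side = attr(phi, "side") %||% "RreL",
             trial_id = attr(phi, "trial_id") %||% "trial")
}

#' Construct a cumulative-statistic series
#'
#' Container for a cumulative PCI (or PCI-like) series: position j holds the
#' statistic computed from the first j + 1 strides.
#'
#' @param values Numeric vector of non-negative statistic values (percent).
#' @param side Convention label: `"RreL"`, `"LreR"`, `"average"`, or a metric
#'   name for non-PCI statistics (e.g. `"stride_time_cv"`).
#' @param trial_id Character trial/participant label.
#' @return An object of class `pci_series`.
#' @export
pci_series <- function(values, side = "RreL", trial_id = "trial") {
  values <- as.numeric(values)
  if (anyNA(values) || any(values < 0)) {
    stop("cumulative series values must be non-negative and free of NA",
         call. = FALSE)
  }
  structure(values, side = side, trial_id = as.character(trial_id)[1],
            class = c("pci_series", "numeric"))
}

#' Stride counts associated with each position of a cumulative series
#'
#' @param x A `pci_series`.
#' @return Integer vector: position j maps to stride count j + 1.
#' @export
strides <- function(x) {
  stopifnot(inherits(x, "pci_series"))
  seq_along(x) + 1L
}

#' @export
print.pci_series <- function(x, ...) {
  cat("Cumulative series (", attr(x, "side"), ", '", attr(x, "trial_id"),
      "'): ", length(x), " values (strides 2..", length(x) + 1L,
      "), end value ", format(unclass(x)[length(x)], digits = 5), "\n",
      sep = "")
  print(as.numeric(x), ...)
  invisible(x)
}

#' Element-wise average of two cumulative PCI series
#'
#' Forms the "average PCI" series from the RreL and LreR series of the same
#' trial.
#'
#' @param rrel,lrer `pci_series` objects of equal length.
#' @return A `pci_series` with `side = "average"`.
#' @export
average_pci_series <- function(rrel, lrer) {
  stopifnot(inherits(rrel, "pci_series"), inherits(lrer, "pci_series"))
  if (length(rrel) != length(lrer)) {
    stop("length mismatch: RreL series has ", length(rrel),
         " values, LreR series has ", length(lrer), call. = FALSE)
  }
  pci_series((as.numeric(rrel) + as.numeric(lrer)) / 2,
             side = "average", trial_id = attr(rrel, "trial_id"))
}

#' Cumulative coefficient-of-variation series of any positive-valued metric
#'
#' Generalizes the cumulative-PCI construction to other stride-level metrics
#' (e.g. stride-to-stride time): position j holds
#' `100 * sd(x[1..j+1]) / mean(x[1..j+1])`, so the POS detector can be
#' applied to, say, the stride-time CV.
#'
#' @param x Numeric vector (length >= 2) with positive mean over every
#'   prefix.
#' @param trial_id Character label.
#' @return A `pci_series` with `side = "cv"`.
#' @examples
#' cumulative_cv_series(c(1, 1.1, 1.05, 0.98))
#' @export
cumulative_cv_series <- function(x, trial_id = "trial") {
  x <- as.numeric(x)
  if (length(x) < 2) {
    stop("insufficient data: need at least 2 values", call. = FALSE)
  }
  n <- length(x)
  means <- cumsum(x)[2:n] / (2:n)
  if (any(means <= 0)) {
    stop("cumulative CV undefined: some prefix has non-positive mean",
         call. = FALSE)
  }
  vals <- vapply(2:n, function(k) 100 * stats::sd(x[1:k]) / mean(x[1:k]),
                 numeric(1))
  pci_series(vals, side = "cv", trial_id = trial_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
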