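#' Heel-strike event series for one walking trial
#'
#' Bundles the ordered heel-strike (HS) event times of the left and right
#' foot, in seconds, for a single walking trial. Stepping phases are computed
#' from these events by [compute_phase_series()], with either physical leg in
#' the "step" role depending on the `side` convention (RreL: right step
#' relative to left stride; LreR: left step relative to right stride).
#'
#' @param times_left Numeric vector of left-heel-strike times (seconds),
#'   strictly increasing.
#' @param times_right Numeric vector of right-heel-strike times (seconds),
#'   strictly increasing.
#' @param trial_id Character label for the trial.
#' @return An object of class `heel_strike_series`.
#' @examples
#' hs <- heel_strike_series(times_left = c(0, 1.07, 2.14),
#'                          times_right = c(0.535, 1.605),
#'                          trial_id = "demo")
#' compute_phase_series(hs, side = "RreL")
#' @export
heel_strike_series <- function(times_left, times_right, trial_id = "trial") {
  times_left <- as.numeric(times_left)
  times_right <- as.numeric(times_right)
  check_increasing(times_left, "times_left")
  check_increasing(times_right, "times_right")
  structure(
    list(times_left = times_left, times_right = times_right,
         trial_id = as.character(trial_id)[1]),
    class = "heel_strike_series"
  )
}

check_increasing <- function(x, what) {
  if (length(x) == 0 || anyNA(x)) {
    stop("malformed input: '", what, "' must be non-empty and free of NA",
         call. = FALSE)
  }
  if (length(x) > 1 && any(diff(x) <= 0)) {
    bad <- which(diff(x) <= 0)[1] + 1L
    stop("malformed input: '", what, "' is not strictly increasing at event ",
         bad, call. = FALSE)
  }
  invisible(x)
}

#' @export
print.heel_strike_series <- function(x, ...) {
  cat("Heel-strike series '", x$trial_id, "': ",
      length(x$times_left), " left / ", length(x$times_right),
      " right events, duration ",
      format(max(c(x$times_left, x$times_right)) -
             min(c(x$times_left, x$times_right)), digits = 4),
      " s\n", sep = "")
  invisible(x)
}

# Map a side convention to (role A = stepping leg, role B = striding leg).
side_roles <- function(hs, side) {
  side <- match.arg(side, c("RreL", "LreR"))
  if (side == "RreL") {
    list(A = hs$times_right, B = hs$times_left)
  } else {
    list(A = hs$times_left, B = hs$times_right)
  }
}
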