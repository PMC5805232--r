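#' Simulation configuration for virtual gait participants
#'
#' Defaults emulate comfortable walking in young healthy adults: stride
#' times drawn around 1.07 s with 0.02 s within-participant SD, stepping
#' phases scattered around the anti-phase ideal of 180 degrees, 50 strides
#' per participant, and whole-trial PCI values constrained to the
#' young-healthy band.
#'
#' @param n_participants Number of virtual participants (default 20).
#' @param n_strides Strides (phase values) per participant (default 50).
#' @param stride_mean_s Mean stride duration in seconds (default 1.07).
#' @param stride_sd_s Within-participant stride-duration SD in seconds
#'   (default 0.02).
#' @param phase_noise_sd_deg SD of the Gaussian phase noise around 180
#'   degrees (default 4).
#' @param phase_mean_band_deg Length-2 numeric: accepted band for the mean
#'   phase, must contain 180 (default `c(178, 182)`).
#' @param target_pci_range_pct Length-2 numeric: accepted band for the
#'   whole-trial PCI in percent (default `c(2, 5)`, spanning reported
#'   young-to-elderly healthy means).
#' @param max_rejections Rejection-sampling budget per participant
#'   (default 1000).
#' @param seed Optional integer master seed; `NA` leaves the RNG state
#'   untouched.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 20L,
                              n_strides = 50L,
                              stride_mean_s = 1.07,
                              stride_sd_s = 0.02,
                              phase_noise_sd_deg = 4,
                              phase_mean_band_deg = c(178, 182),
                              target_pci_range_pct = c(2, 5),
                              max_rejections = 1000L,
                              seed = NA_integer_) {
  cfg <- list(n_participants = as.integer(n_participants),
              n_strides = as.integer(n_strides),
              stride_mean_s = stride_mean_s,
              stride_sd_s = stride_sd_s,
              phase_noise_sd_deg = phase_noise_sd_deg,
              phase_mean_band_deg = as.numeric(phase_mean_band_deg),
              target_pci_range_pct = as.numeric(target_pci_range_pct),
              max_rejections = as.integer(max_rejections),
              seed = seed)
  with(cfg, {
    stopifnot(n_participants >= 1, n_strides >= 3,
              stride_mean_s > 0, stride_sd_s > 0, phase_noise_sd_deg >= 0,
              length(phase_mean_band_deg) == 2,
              phase_mean_band_deg[1] <= 180, phase_mean_band_deg[2] >= 180,
              length(target_pci_range_pct) == 2,
              target_pci_range_pct[1] >= 0, target_pci_range_pct[2] <= 20,
              target_pci_range_pct[1] < target_pci_range_pct[2] ||
                all(target_pci_range_pct == 0))
  })
  structure(cfg, class = "simulation_config")
}

#' Simulate one leg's stride durations
#'
#' Draws `n_strides` durations from Normal(`stride_mean_s`, `stride_sd_s`);
#' non-positive draws (vanishingly rare at the defaults) are redrawn.
#'
#' @param cfg A [simulation_config()].
#' @param n Number of durations to draw (default `cfg$n_strides`).
#' @return Numeric vector of positive stride durations in seconds.
#' @export
simulate_stride_times <- function(cfg = simulation_config(),
                                  n = cfg$n_strides) {
  st <- stats::rnorm(n, cfg$stride_mean_s, cfg$stride_sd_s)
  while (any(st <= 0)) {
    bad <- st <= 0
    st[bad] <- stats::rnorm(sum(bad), cfg$stride_mean_s, cfg$stride_sd_s)
  }
  st
}

#' Simulate a stepping-phase vector under normative constraints
#'
#' Draws `n_strides` phases as 180 + Gaussian noise and rejection-resamples
#' the whole vector until (a) its mean lies inside `phase_mean_band_deg`
#' and (b) its whole-vector PCI lies inside `target_pci_range_pct`. Whole
#' vectors (never single elements) are resampled so the accepted noise stays
#' serially unstructured. Phases must also stay inside (0, 360).
#'
#' @param cfg A [simulation_config()].
#' @return Numeric phase vector in degrees.
#' @export
simulate_phase_values <- function(cfg = simulation_config()) {
  for (attempt in seq_len(cfg$max_rejections)) {
    phi <- 180 + stats::rnorm(cfg$n_strides, 0, cfg$phase_noise_sd_deg)
    if (any(phi <= 0 | phi >= 360)) next
    m <- mean(phi)
    if (m < cfg$phase_mean_band_deg[1] || m > cfg$phase_mean_band_deg[2]) next
    pci <- compute_pci(phi)
    if (pci < cfg$target_pci_range_pct[1] ||
        pci > cfg$target_pci_range_pct[2]) next
    return(phi)
  }
  stop("rejection budget of ", cfg$max_rejections, " exhausted: with phase ",
       "noise SD ", cfg$phase_noise_sd_deg, " deg no vector met mean band [",
       paste(cfg$phase_mean_band_deg, collapse = ", "), "] deg and PCI band [",
       paste(cfg$target_pci_range_pct, collapse = ", "), "] %; adjust ",
       "phase_noise_sd_deg or the bands", call. = FALSE)
}

#' Build heel-strike event times from stride times and phases
#'
#' Role-B (striding leg) events start at time 0 and accumulate the stride
#' durations; each role-A (stepping leg) event is placed inside its stride
#' at the fraction prescribed by the phase:
#' `t_A,i = t_B,i + phi_i / 360 * stride_i`. Recomputing phases from the
#' returned events reproduces the generating phases to floating-point
#' accuracy.
#'
#' @param stride_times Positive stride durations (role-B leg), seconds.
#' @param phi Phase vector in degrees, same length, each inside (0, 360).
#' @param side Which convention `phi` encodes: `"RreL"` makes the left leg
#'   role B (default), `"LreR"` the right leg.
#' @param trial_id Character label.
#' @return A [heel_strike_series()].
#' @export
simulate_heel_strikes <- function(stride_times, phi, side = c("RreL", "LreR"),
                                  trial_id = "sim") {
  side <- match.arg(side)
  stopifnot(length(stride_times) == length(phi), all(stride_times > 0))
  if (any(phi <= 0 | phi >= 360)) {
    stop("generated phases must lie strictly inside (0, 360) degrees",
         call. = FALSE)
  }
  tB <- c(0, cumsum(stride_times))
  tA <- tB[seq_along(phi)] + phi / 360 * stride_times
  if (side == "RreL") {
    heel_strike_series(times_left = tB, times_right = tA, trial_id = trial_id)
  } else {
    heel_strike_series(times_left = tA, times_right = tB, trial_id = trial_id)
  }
}

#' Simulate one virtual participant
#'
#' Combines [simulate_stride_times()], [simulate_phase_values()] and
#' [simulate_heel_strikes()], then derives both phase conventions and their
#' cumulative PCI series from the event times. The generated phases drive
#' the RreL convention; the complementary LreR phases follow from the same
#' events. Because the complementary convention needs one extra stride to
#' yield as many phases, the trial contains `n_strides + 1` striding-leg
#' strides and both conventions are truncated to exactly `n_strides`
#' phases. Participants whose complementary phase vector falls outside the
#' mean or PCI band (rare, by symmetry) are redrawn within the same
#' rejection budget.
#'
#' @param cfg A [simulation_config()].
#' @param id Participant label.
#' @return A `simulated_participant`: list with `heel_strikes`, `phi_RreL`,
#'   `phi_LreR`, `pci_RreL`, `pci_LreR`, `pci_avg`, `final_pci_pct` (end
#'   value of the average series) and `config` snapshot.
#' @export
simulate_participant <- function(cfg = simulation_config(), id = "sim01") {
  n <- cfg$n_strides
  for (attempt in seq_len(cfg$max_rejections)) {
    st <- simulate_stride_times(cfg, n = n + 1L)
    phi <- simulate_phase_values(cfg)
    repeat {  # one spare phase for the extra stride
      phi_extra <- 180 + stats::rnorm(1, 0, cfg$phase_noise_sd_deg)
      if (phi_extra > 0 && phi_extra < 360) break
    }
    hs <- simulate_heel_strikes(st, c(phi, phi_extra), side = "RreL",
                                trial_id = id)
    phi_rrel <- phase_series(compute_phase_series(hs, "RreL")[seq_len(n)],
                             side = "RreL", trial_id = id)
    phi_lrer <- suppressWarnings(compute_phase_series(hs, "LreR"))
    phi_lrer <- phase_series(phi_lrer[seq_len(n)], side = "LreR",
                             trial_id = id)
    m2 <- mean(phi_lrer)
    pci2 <- compute_pci(phi_lrer)
    if (m2 < cfg$phase_mean_band_deg[1] || m2 > cfg$phase_mean_band_deg[2] ||
        pci2 < cfg$target_pci_range_pct[1] ||
        pci2 > cfg$target_pci_range_pct[2]) next
    pci_rrel <- cumulative_pci_series(phi_rrel)
    pci_lrer <- cumulative_pci_series(phi_lrer)
    pci_avg <- average_pci_series(pci_rrel, pci_lrer)
    return(structure(
      list(id = id, heel_strikes = hs,
           phi_RreL = phi_rrel, phi_LreR = phi_lrer,
           pci_RreL = pci_rrel, pci_LreR = pci_lrer, pci_avg = pci_avg,
           final_pci_pct = as.numeric(pci_avg[length(pci_avg)]),
           config = cfg),
      class = "simulated_participant"))
  }
  stop("rejection budget exhausted while matching the complementary phase ",
       "convention to the normative bands", call. = FALSE)
}

#' @export
print.simulated_participant <- function(x, ...) {
  cat("Simulated participant '", x$id, "': ", length(x$phi_RreL),
      " strides, final average PCI ", format(x$final_pci_pct, digits = 4),
      " %\n", sep = "")
  invisible(x)
}

#' Simulate a cohort of virtual participants
#'
#' Generates `cfg$n_participants` independent participants. The master seed
#' (from `cfg$seed` or the `seed` argument) deterministically spawns one
#' sub-seed per participant, recorded on each participant as `seed` so any
#' one can be replayed in isolation.
#'
#' @param cfg A [simulation_config()].
#' @param seed Optional integer master seed overriding `cfg$seed`.
#' @return A list of `simulated_participant` objects (class
#'   `simulated_cohort`), with the master seed stored as an attribute.
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_participants = 3), seed = 7)
#' sapply(cohort, function(p) p$final_pci_pct)
#' @export
simulate_cohort <- function(cfg = simulation_config(), seed = cfg$seed) {
  if (!is.na(seed)) set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, cfg$n_participants)
  ids <- sprintf("sim%02d", seq_len(cfg$n_participants))
  cohort <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    set.seed(sub_seeds[i])
    p <- simulate_participant(cfg, id = ids[i])
    p$seed <- sub_seeds[i]
    cohort[[i]] <- p
  }
  structure(cohort, names = ids, master_seed = seed,
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort: ", length(x), " participants, ",
      length(x[[1]]$phi_RreL), " strides each (master seed ",
      attr(x, "master_seed"), ")\n", sep = "")
  invisible(x)
}
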