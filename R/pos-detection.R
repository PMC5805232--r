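#' Detector configuration
#'
#' Parameters of the two-stage point-of-stabilization detector.
#'
#' @param K Moving-window size in series positions (default 15).
#' @param cv_threshold Stability criterion on the raw coefficient of
#'   variation sd/mean of the windowed values (default 0.05). A window with
#'   CV less than or equal to the threshold counts as stable.
#' @param min_length Minimum series length required by the detector
#'   (default `K`).
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(K = 15L, cv_threshold = 0.05, min_length = K) {
  K <- as.integer(K)
  if (K < 3) stop("K must be at least 3", call. = FALSE)
  if (!(cv_threshold > 0 && cv_threshold < 1)) {
    stop("cv_threshold must lie in (0, 1)", call. = FALSE)
  }
  min_length <- max(as.integer(min_length), K)
  structure(list(K = K, cv_threshold = cv_threshold, min_length = min_length),
            class = "detector_config")
}

#' Coefficient of variation of a window of values
#'
#' Raw (not percent) ratio sd/mean with the sample (n - 1) standard
#' deviation. A zero-mean window has no defined CV; `NaN`/`Inf` is returned
#' and treated as unstable by the detector.
#'
#' @param values Numeric vector, length >= 2.
#' @return sd(values)/mean(values).
#' @export
window_cv <- function(values) {
  if (length(values) < 2) {
    stop("window_cv needs at least 2 values", call. = FALSE)
  }
  stats::sd(values) / mean(values)
}

#' Is a window of values stable under the CV criterion?
#'
#' @param values Numeric window.
#' @param cfg A [detector_config()].
#' @return `TRUE` iff the window CV is defined and `<= cfg$cv_threshold`
#'   (the boundary counts as stable). An undefined CV (zero mean) counts as
#'   unstable.
#' @export
is_stable <- function(values, cfg = detector_config()) {
  cv <- window_cv(values)
  is.finite(cv) && cv <= cfg$cv_threshold
}

# round half away from zero (positions are positive, so floor(x + 0.5))
round_half_up <- function(x) floor(x + 0.5)

#' Evenly dispersed window positions from S to the series end
#'
#' K strictly increasing integer positions, the first at `S` and the last at
#' `N`, obtained by rounding K evenly spaced real positions on \[S, N\]
#' (half away from zero). Rare rounding collisions are resolved by pushing
#' the later index up by one. For a series of 50 values, `S = 21` gives the
#' near-step-2 pattern 21, 23, 25, ..., 50.
#'
#' @param S Leftmost position (integer >= 1).
#' @param N Rightmost position (series length).
#' @param K Number of positions.
#' @return Integer vector of K positions, or `NULL` when the span `N - S + 1`
#'   is smaller than K (caller falls back to consecutive semantics).
#' @export
dispersed_indices <- function(S, N, K) {
  S <- as.integer(S); N <- as.integer(N); K <- as.integer(K)
  if (N - S + 1L < K) return(NULL)
  idx <- as.integer(round_half_up(seq(S, N, length.out = K)))
  for (j in seq_len(K - 1L) + 1L) {
    if (idx[j] <= idx[j - 1L]) idx[j] <- idx[j - 1L] + 1L
  }
  idx
}

new_roi <- function(indices, values, option, S) {
  structure(list(indices = indices, values = values, option = option, S = S),
            class = "pos_roi")
}

trace_row <- function(stage, option, S, k, indices, cv, stable) {
  data.frame(stage = stage, option = option, S = S, window_size = k,
             first = indices[1], last = indices[length(indices)],
             cv = cv, stable = stable, stringsAsFactors = FALSE)
}

#' Stage 1: backward search for the region of instability
#'
#' Starting from the rightmost window (`S = N - K + 1`) and moving left one
#' position at a time, finds the first window whose values violate the CV
#' stability criterion — the region of interest (RoI) passed to stage 2.
#' Two window shapes are searched: `"consecutive"` takes the K consecutive
#' positions `S..S+K-1`; `"dispersed"` takes K positions evenly dispersed
#' from S to the series end.
#'
#' @param series A [pci_series()] or numeric vector.
#' @param cfg A [detector_config()].
#' @param option `"consecutive"` or `"dispersed"`.
#' @return A list with elements `roi` (a RoI object, or `NULL` when every
#'   window down to S = 1 is stable) and `trace` (one row per window
#'   tested).
#' @export
stage1_backward_search <- function(series, cfg = detector_config(),
                                   option = c("consecutive", "dispersed")) {
  option <- match.arg(option)
  x <- as.numeric(series)
  N <- length(x)
  K <- cfg$K
  if (N < cfg$min_length) {
    stop("insufficient data: series has ", N, " values but the detector ",
         "requires at least ", cfg$min_length, call. = FALSE)
  }
  trace <- vector("list", N - K + 1L)
  for (S in seq(N - K + 1L, 1L)) {
    idx <- if (option == "consecutive") S:(S + K - 1L)
           else dispersed_indices(S, N, K)
    w <- x[idx]
    cv <- window_cv(w)
    stable <- is.finite(cv) && cv <= cfg$cv_threshold
    trace[[N - K + 2L - S]] <- trace_row("stage1", option, S, K, idx, cv, stable)
    if (!stable) {
      return(list(roi = new_roi(idx, w, option, S),
                  trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)])))
    }
  }
  list(roi = NULL, trace = do.call(rbind, trace))
}

#' Stage 2: localize the point of stabilization inside the RoI
#'
#' High-resolution fine-tuning. The K RoI values form the working window
#' (for a dispersed RoI the dispersed values are compressed into a
#' contiguous working vector, and the result is mapped back through the
#' dispersed index list). At each iteration the sub-window omitting the
#' leftmost element is tested: if it is stable the working window shrinks
#' from the right (the left sub-window is taken), otherwise it shrinks from
#' the left (the tested right sub-window is taken). After exactly K - 2
#' iterations the window has size 2 and the right element's original series
#' position is returned as the stabilization onset.
#'
#' @param roi A RoI as produced by [stage1_backward_search()].
#' @param cfg A [detector_config()].
#' @return A list with `position` (series position of the POS) and `trace`.
#' @export
stage2_localize <- function(roi, cfg = detector_config()) {
  stopifnot(inherits(roi, "pos_roi"))
  v <- roi$values
  idx <- roi$indices
  trace <- list()
  while (length(v) > 2L) {
    k <- length(v)
    right <- 2:k
    cv <- window_cv(v[right])
    stable <- is.finite(cv) && cv <= cfg$cv_threshold
    trace[[length(trace) + 1L]] <-
      trace_row("stage2", roi$option, idx[2], k - 1L, idx[right], cv, stable)
    if (stable) {           # instability lives on the left: drop the rightmost
      v <- v[1:(k - 1L)]
      idx <- idx[1:(k - 1L)]
    } else {                # zoom into the unstable right sub-window
      v <- v[right]
      idx <- idx[right]
    }
  }
  list(position = idx[2], trace = do.call(rbind, trace))
}

#' Detect the point of stabilization of a cumulative series
#'
#' Runs the two-stage backward search for both window options (consecutive
#' and dispersed), localizes a POS for each, and reports the maximum of the
#' two as the POS, in stride units (series position + 1). An option whose
#' windows are stable everywhere contributes the minimal POS of 2 strides —
#' stability from the first window onward means no additional strides change
#' the estimate. If an option's very first (rightmost) window is already
#' unstable, the series never stabilized within the trial: the POS is still
#' localized inside that window, but `stabilized` is set to `FALSE` and a
#' warning is emitted that the trial may be too short.
#'
#' @param series A [pci_series()] (or numeric vector, interpreted with the
#'   same position -> stride count + 1 mapping).
#' @param cfg A [detector_config()].
#' @param warn Emit the too-short-trial warning (default TRUE).
#' @return A `pos_result`: list with `pos` (strides), `pos_by_option`
#'   (named strides per window option), `stabilized` flag and `trace` (every
#'   window tested, with CV and verdict).
#' @examples
#' set.seed(1)
#' s <- cumulative_pci_series(180 + rnorm(50, sd = 4))
#' detect_pos(s)
#' @export
detect_pos <- function(series, cfg = detector_config(), warn = TRUE) {
  x <- as.numeric(series)
  N <- length(x)
  options <- c("consecutive", "dispersed")
  pos_by_option <- setNames(numeric(2), options)
  stabilized <- TRUE
  traces <- list()
  for (op in options) {
    s1 <- stage1_backward_search(x, cfg, op)
    traces[[length(traces) + 1L]] <- s1$trace
    if (is.null(s1$roi)) {
      pos_by_option[[op]] <- 2  # stable throughout: earliest defined value
      next
    }
    if (s1$roi$S == N - cfg$K + 1L) {
      stabilized <- FALSE
      if (warn) {
        warning("rightmost ", op, " window is already unstable; the trial ",
                "may be too short for the series to stabilize", call. = FALSE)
      }
    }
    s2 <- stage2_localize(s1$roi, cfg)
    traces[[length(traces) + 1L]] <- s2$trace
    pos_by_option[[op]] <- s2$position + 1  # series position -> stride count
  }
  structure(
    list(pos = max(pos_by_option),
         pos_by_option = pos_by_option,
         stabilized = stabilized,
         trace = do.call(rbind, traces),
         trial_id = attr(series, "trial_id") %||% "trial",
         side = attr(series, "side") %||% NA_character_,
         config = cfg),
    class = "pos_result"
  )
}

#' @export
print.pos_result <- function(x, ...) {
  cat("POS for '", x$trial_id, "'",
      if (!is.na(x$side)) paste0(" (", x$side, ")"), ": ",
      x$pos, " strides", if (!x$stabilized) "  [NOT stabilized]", "\n",
      "  consecutive-window option: ", x$pos_by_option[["consecutive"]],
      "   dispersed-window option: ", x$pos_by_option[["dispersed"]], "\n",
      "  windows tested: ", nrow(x$trace), "\n", sep = "")
  invisible(x)
}

#' Sensitivity of the detected POS to the window size K
#'
#' Reruns [detect_pos()] for each candidate window size and tabulates the
#' result. A series too short for some K yields an `NA` row flagged in
#' `note` rather than an error.
#'
#' @param series A [pci_series()] or numeric vector.
#' @param K_values Integer vector of window sizes (each >= 3).
#' @param cfg Base [detector_config()]; its `cv_threshold` is reused.
#' @return A data frame with columns `K`, `pos`, `pos_consecutive`,
#'   `pos_dispersed`, `stabilized`, `note`.
#' @export
sweep_block_size <- function(series, K_values, cfg = detector_config()) {
  rows <- lapply(as.integer(K_values), function(K) {
    if (K < 3) stop("every K must be at least 3", call. = FALSE)
    if (length(series) < K) {
      return(data.frame(K = K, pos = NA_real_, pos_consecutive = NA_real_,
                        pos_dispersed = NA_real_, stabilized = NA,
                        note = "series shorter than K",
                        stringsAsFactors = FALSE))
    }
    r <- detect_pos(series, detector_config(K = K,
                                            cv_threshold = cfg$cv_threshold),
                    warn = FALSE)
    data.frame(K = K, pos = r$pos,
               pos_consecutive = r$pos_by_option[["consecutive"]],
               pos_dispersed = r$pos_by_option[["dispersed"]],
               stabilized = r$stabilized, note = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
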