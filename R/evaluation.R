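#' True and absolute error of a PCI estimate against the trial-final value
#'
#' The true error is the signed relative difference between the PCI
#' estimated at a reference stride and the PCI at the end of the trial,
#' `TE = (PCI_ref - PCI_end) / PCI_end`; the absolute error is `AE = |TE|`.
#' Both are returned as fractions; multiply by 100 when reporting percent.
#'
#' @param pci_at_ref PCI value (percent) at the reference stride.
#' @param pci_end PCI value (percent) at the trial end; must be non-zero.
#' @return Signed (`true_error`) or absolute (`absolute_error`) relative
#'   error as a fraction.
#' @examples
#' true_error(2.0, 2.5)      # -0.2
#' absolute_error(2.0, 2.5)  #  0.2
#' @export
true_error <- function(pci_at_ref, pci_end) {
  if (any(pci_end == 0)) {
    stop("true error undefined: trial-final PCI is zero", call. = FALSE)
  }
  (pci_at_ref - pci_end) / pci_end
}

#' @rdname true_error
#' @export
absolute_error <- function(pci_at_ref, pci_end) {
  abs(true_error(pci_at_ref, pci_end))
}

#' Trial-final PCI of a cumulative series
#'
#' Two conventions are in use: the raw end value (used for true/absolute
#' errors against a reference stride) and the mean of the last three values
#' (a smoother reference used for POS-aligned error profiles).
#'
#' @param series A [pci_series()] or numeric vector.
#' @param method `"end"` (last value) or `"last3"` (mean of last 3 values).
#' @return Scalar PCI in percent.
#' @export
final_pci <- function(series, method = c("end", "last3")) {
  method <- match.arg(method)
  x <- as.numeric(series)
  need <- if (method == "end") 1L else 3L
  if (length(x) < need) {
    stop("insufficient data: final_pci(method = \"", method, "\") needs at ",
         "least ", need, " values", call. = FALSE)
  }
  if (method == "end") x[length(x)] else mean(x[(length(x) - 2L):length(x)])
}

#' Error of the PCI estimate at a fixed stride count
#'
#' Evaluates the true and absolute error of the cumulative PCI at a given
#' stride count against the trial-final (end) value — e.g. the error
#' committed by stopping a trial at the cohort-mean POS of 23 strides.
#'
#' @param series A [pci_series()].
#' @param stride Stride count (>= 2, at most the series' last stride).
#' @param pos Optional detected POS (strides) to record alongside.
#' @return A one-row data frame: `participant_id`, `pos`, `stride`,
#'   `pci_at_ref`, `pci_end`, `te`, `ae` (errors as fractions).
#' @export
error_at_fixed_stride <- function(series, stride, pos = NA_real_) {
  stopifnot(inherits(series, "pci_series"))
  stride <- as.integer(stride)
  pos_idx <- stride - 1L  # stride count j+1 lives at series position j
  if (pos_idx < 1L || pos_idx > length(series)) {
    stop("stride ", stride, " outside the series range [2, ",
         length(series) + 1L, "]", call. = FALSE)
  }
  ref <- as.numeric(series)[pos_idx]
  endv <- final_pci(series, "end")
  te <- true_error(ref, endv)
  data.frame(participant_id = attr(series, "trial_id") %||% NA_character_,
             pos = as.numeric(pos), stride = stride,
             pci_at_ref = ref, pci_end = endv, te = te, ae = abs(te),
             stringsAsFactors = FALSE)
}

#' POS-aligned absolute-error profile of a cohort
#'
#' Aligns every participant's cumulative PCI series to their detected POS
#' and, for each offset i in `-20..20` strides, averages over participants
#' the absolute error between the PCI at stride POS + i and the
#' participant's final PCI (mean of the last three values). Series are
#' padded by replicating their first and last values so offsets reaching
#' past either end stay defined. The profile is reported in percent.
#'
#' @param cohort A list in which each element has components `series` (a
#'   [pci_series()]) and `pos` (detected POS in strides).
#' @param group_label Character label attached to the profile.
#' @param offsets Integer offsets in strides (default -20..20).
#' @return A data frame with columns `offset` and `mean_ae_pct`, the group
#'   label as attribute `group_label`.
#' @export
aligned_error_profile <- function(cohort, group_label = "group",
                                  offsets = -20:20) {
  stopifnot(length(cohort) > 0)
  per_part <- vapply(cohort, function(p) {
    x <- as.numeric(p$series)
    fin <- final_pci(p$series, "last3")
    idx <- (p$pos + offsets) - 1L           # strides -> series positions
    idx <- pmin(pmax(idx, 1L), length(x))   # replicate-pad both ends
    abs(true_error(x[idx], fin))
  }, numeric(length(offsets)))
  profile <- data.frame(offset = offsets,
                        mean_ae_pct = 100 * rowMeans(per_part))
  attr(profile, "group_label") <- group_label
  profile
}

#' Cohort summary table of POS and error metrics
#'
#' Mean and SD (n - 1 normalization) of the detected POS, the trial PCI,
#' and the absolute and true errors, one row per group — the layout of a
#' per-group performance table. Errors are reported in percent.
#'
#' @param records A data frame of per-participant error records as produced
#'   by [error_at_fixed_stride()] (columns `pos`, `pci_end`, `te`, `ae`),
#'   optionally with a `group` column.
#' @param group Optional character vector of group labels (recycled);
#'   overrides any `group` column.
#' @return A data frame with one row per group: `group`, `n`, `pos_mean`,
#'   `pos_sd`, `pci_mean`, `pci_sd`, `ae_mean_pct`, `ae_sd_pct`,
#'   `te_mean_pct`, `te_sd_pct`.
#' @export
cohort_summary <- function(records, group = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (!is.null(group)) {
    records$group <- rep_len(as.character(group), nrow(records))
  } else if (is.null(records$group)) {
    records$group <- "all"
  }
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  rows <- lapply(split(records, records$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g),
               pos_mean = mean(g$pos), pos_sd = sd0(g$pos),
               pci_mean = mean(g$pci_end), pci_sd = sd0(g$pci_end),
               ae_mean_pct = 100 * mean(g$ae), ae_sd_pct = 100 * sd0(g$ae),
               te_mean_pct = 100 * mean(g$te), te_sd_pct = 100 * sd0(g$te),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
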