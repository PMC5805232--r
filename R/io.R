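#' Read heel-strike event times from a delimited text file
#'
#' Two dialects are accepted (comma- or tab-separated, header required):
#' * **long** — columns `time_s` and `leg`, with `leg` in `{L, R}`; rows
#'   out of time order are sorted with a warning;
#' * **wide** — columns `left_s` and `right_s`, one event per cell, ragged
#'   columns padded with empty cells / NA.
#'
#' @param path Path to a CSV/TSV file.
#' @param dialect `"auto"` (default, decided from the header), `"long"` or
#'   `"wide"`.
#' @param trial_id Trial label (default: file name without extension).
#' @return A [heel_strike_series()].
#' @export
read_heel_strikes <- function(path, dialect = c("auto", "long", "wide"),
                              trial_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read_delim_auto(path)
  if (is.null(trial_id)) {
    trial_id <- sub("\\.[^.]*$", "", basename(path))
  }
  cols <- tolower(names(df))
  if (dialect == "auto") {
    dialect <- if (all(c("time_s", "leg") %in% cols)) "long"
    else if (all(c("left_s", "right_s") %in% cols)) "wide"
    else stop("cannot infer dialect of '", path, "': expected columns ",
              "time_s+leg (long) or left_s+right_s (wide), found: ",
              paste(names(df), collapse = ", "), call. = FALSE)
  }
  if (dialect == "long") {
    need <- match(c("time_s", "leg"), cols)
    if (anyNA(need)) stop("long dialect needs columns time_s and leg",
                          call. = FALSE)
    tm <- suppressWarnings(as.numeric(df[[need[1]]]))
    if (anyNA(tm)) {
      stop("non-numeric time_s value at line ", which(is.na(tm))[1] + 1L,
           " of '", path, "'", call. = FALSE)
    }
    leg <- toupper(trimws(as.character(df[[need[2]]])))
    bad <- which(!leg %in% c("L", "R"))
    if (length(bad) > 0) {
      stop("unknown leg label '", df[[need[2]]][bad[1]], "' at line ",
           bad[1] + 1L, " of '", path, "' (expected L or R)", call. = FALSE)
    }
    if (is.unsorted(tm, strictly = FALSE)) {
      warning("rows of '", path, "' were not in time order; sorted",
              call. = FALSE)
      o <- order(tm)
      tm <- tm[o]; leg <- leg[o]
    }
    heel_strike_series(tm[leg == "L"], tm[leg == "R"], trial_id)
  } else {
    need <- match(c("left_s", "right_s"), cols)
    if (anyNA(need)) stop("wide dialect needs columns left_s and right_s",
                          call. = FALSE)
    num <- function(col, name) {
      raw <- df[[col]]
      keep <- !(is.na(raw) | trimws(as.character(raw)) == "")
      v <- suppressWarnings(as.numeric(raw[keep]))
      if (anyNA(v)) {
        stop("non-numeric ", name, " value at line ",
             which(keep)[which(is.na(v))[1]] + 1L, " of '", path, "'",
             call. = FALSE)
      }
      v
    }
    heel_strike_series(num(need[1], "left_s"), num(need[2], "right_s"),
                       trial_id)
  }
}

#' Write heel-strike event times as delimited text
#'
#' @param hs A [heel_strike_series()].
#' @param path Output path; `.tsv` extension selects tab separation.
#' @param dialect `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_heel_strikes <- function(hs, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  if (dialect == "wide") {
    n <- max(length(hs$times_left), length(hs$times_right))
    df <- data.frame(left_s = c(hs$times_left,
                                rep(NA, n - length(hs$times_left))),
                     right_s = c(hs$times_right,
                                 rep(NA, n - length(hs$times_right))))
  } else {
    df <- data.frame(time_s = c(hs$times_left, hs$times_right),
                     leg = c(rep("L", length(hs$times_left)),
                             rep("R", length(hs$times_right))))
    df <- df[order(df$time_s), ]
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, na = "",
                     quote = FALSE)
  invisible(path)
}

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, blank.lines.skip = FALSE,
                    na.strings = c("NA", ""))
}

#' Read a multi-participant table of cumulative PCI vectors
#'
#' One participant per column, one cumulative value per row; the first row
#' holds participant ids. Delimited text (CSV/TSV) is canonical; `.xlsx`
#' files with the same layout (one sheet per side is also tolerated via
#' `sheet`) are read through the readxl package when installed. Trailing
#' blank cells in a column are trimmed, so ragged columns are allowed;
#' all-blank columns are skipped with a warning.
#'
#' @param path Path to a CSV/TSV/XLSX file.
#' @param side Side label stamped on every returned series.
#' @param sheet Sheet name or index for xlsx input.
#' @return A named list of [pci_series()] objects.
#' @export
read_pci_table <- function(path, side = "RreL", sheet = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet,
                                           col_types = "text"))
  } else {
    df <- read_delim_auto(path)
  }
  out <- list()
  for (j in seq_along(df)) {
    raw <- as.character(df[[j]])
    keep <- !(is.na(raw) | trimws(raw) == "")
    last <- if (any(keep)) max(which(keep)) else 0L
    if (last == 0L) {
      warning("column '", names(df)[j], "' of '", path,
              "' is empty; skipped", call. = FALSE)
      next
    }
    raw <- raw[seq_len(last)]
    if (any(!keep[seq_len(last)])) {
      stop("blank cell inside column '", names(df)[j], "' at row ",
           which(!keep[seq_len(last)])[1] + 1L, " of '", path, "'",
           call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v)) {
      stop("non-numeric cell in column '", names(df)[j], "', row ",
           which(is.na(v))[1] + 1L, " of '", path, "'", call. = FALSE)
    }
    out[[names(df)[j]]] <- pci_series(v, side = side,
                                      trial_id = names(df)[j])
  }
  out
}

#' Write a list of cumulative PCI series as a delimited table
#'
#' Inverse of [read_pci_table()]: participants in columns, first row the
#' participant ids, ragged columns padded with blanks. Values are written
#' at full precision so a read/write round trip is lossless.
#'
#' @param series_list Named list of [pci_series()] (or numeric vectors).
#' @param path Output path; `.tsv` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_pci_table <- function(series_list, path) {
  stopifnot(length(series_list) > 0)
  if (is.null(names(series_list)) || any(names(series_list) == "")) {
    names(series_list) <- sprintf("p%02d", seq_along(series_list))
  }
  n <- max(vapply(series_list, length, 0L))
  cols <- lapply(series_list, function(s) {
    x <- format(as.numeric(s), digits = 17, trim = TRUE, scientific = FALSE)
    c(x, rep("", n - length(s)))
  })
  df <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detect the POS for every series of a multi-participant table
#'
#' Convenience wrapper: applies [detect_pos()] to each series and collects
#' the per-participant results in a table.
#'
#' @param series_list Named list of [pci_series()], as returned by
#'   [read_pci_table()].
#' @param cfg A [detector_config()].
#' @return A data frame with columns `id`, `pos`, `pos_consecutive`,
#'   `pos_dispersed`, `stabilized`.
#' @export
detect_pos_table <- function(series_list, cfg = detector_config()) {
  rows <- lapply(names(series_list), function(id) {
    r <- detect_pos(series_list[[id]], cfg, warn = FALSE)
    data.frame(id = id, pos = r$pos,
               pos_consecutive = r$pos_by_option[["consecutive"]],
               pos_dispersed = r$pos_by_option[["dispersed"]],
               stabilized = r$stabilized, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the simulate -> PCI -> detect -> evaluate pipeline
#'
#' Simulates a cohort, writes its heel-strike and PCI tables, detects the
#' POS of every participant's series for all three conventions (RreL, LreR,
#' average), evaluates errors at a fixed reference stride, and writes the
#' summary tables. Every artifact directory gets a `config.yaml` snapshot
#' (including the seed) and a `log.json` with one record per stage.
#'
#' @param sim_cfg A [simulation_config()].
#' @param det_cfg A [detector_config()].
#' @param out_dir Output directory (created if missing). `NULL` runs the
#'   pipeline without writing files.
#' @param ref_stride Reference stride for the fixed-stride error (default
#'   23).
#' @param seed Master seed (overrides `sim_cfg$seed`).
#' @return A list with `cohort`, `pos` (per-participant, per-side table),
#'   `records` (error records at `ref_stride` on the average series),
#'   `summary` (per-side POS means and the error summary) and `paths`.
#' @export
run_pipeline <- function(sim_cfg = simulation_config(),
                         det_cfg = detector_config(),
                         out_dir = NULL, ref_stride = 23L,
                         seed = sim_cfg$seed) {
  log <- list()
  stamp <- function(stage, ...) {
    log[[length(log) + 1L]] <<- c(list(stage = stage), list(...))
  }
  cohort <- simulate_cohort(sim_cfg, seed = seed)
  stamp("simulate", n = length(cohort))

  sides <- c("RreL", "LreR", "average")
  pos_tab <- do.call(rbind, lapply(cohort, function(p) {
    series <- list(RreL = p$pci_RreL, LreR = p$pci_LreR,
                   average = p$pci_avg)
    do.call(rbind, lapply(sides, function(sd) {
      r <- detect_pos(series[[sd]], det_cfg, warn = FALSE)
      data.frame(id = p$id, side = sd, pos = r$pos,
                 pos_consecutive = r$pos_by_option[["consecutive"]],
                 pos_dispersed = r$pos_by_option[["dispersed"]],
                 stabilized = r$stabilized, stringsAsFactors = FALSE)
    }))
  }))
  rownames(pos_tab) <- NULL
  stamp("detect", windows = det_cfg$K, threshold = det_cfg$cv_threshold)

  records <- do.call(rbind, lapply(cohort, function(p) {
    pos <- pos_tab$pos[pos_tab$id == p$id & pos_tab$side == "average"]
    error_at_fixed_stride(p$pci_avg, ref_stride, pos = pos)
  }))
  rownames(records) <- NULL
  pos_means <- stats::aggregate(pos ~ side, data = pos_tab, FUN = mean)
  summary <- list(pos_by_side = pos_means,
                  errors = cohort_summary(records, group = "simulated"))
  stamp("evaluate", ref_stride = ref_stride)

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    for (nm in names(cohort)) {
      write_heel_strikes(cohort[[nm]]$heel_strikes,
                         p(paste0("heel_strikes_", nm, ".csv")))
    }
    write_pci_table(lapply(cohort, `[[`, "pci_RreL"), p("pci_RreL.csv"))
    write_pci_table(lapply(cohort, `[[`, "pci_LreR"), p("pci_LreR.csv"))
    write_pci_table(lapply(cohort, `[[`, "pci_avg"), p("pci_average.csv"))
    utils::write.table(pos_tab, p("pos.csv"), sep = ",", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(records, p("errors.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(summary$errors, p("summary.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
    cfg_dump <- unclass(sim_cfg)
    cfg_dump$seed <- if (is.na(seed)) "none" else as.integer(seed)
    cfg_dump$detector <- unclass(det_cfg)
    yaml::write_yaml(cfg_dump, p("config.yaml"))
    jsonlite::write_json(log, p("log.json"), auto_unbox = TRUE)
    paths <- list(dir = out_dir, config = p("config.yaml"),
                  log = p("log.json"))
    stamp("write", dir = out_dir)
  }
  list(cohort = cohort, pos = pos_tab, records = records, summary = summary,
       paths = paths, log = log)
}
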