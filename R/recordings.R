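# Core data model: sweeps, stimulus protocols, cell records and cohorts, plus
# tab-delimited readers/writers. Units are fixed package-wide: mV, pA, ms,
# MOhm, Hz, um (mediolateral distance), mm (dorsoventral depth from bregma).

PROTOCOL_KINDS <- c("current_step", "current_ramp", "zap", "opto_pulse",
                    "opto_train", "paired_ap", "none")

CELL_CLASSES <- c("L2_SC", "L2_PC", "L3_PC", "L5a_PC", "L5b_PC",
                  "L1_IN", "L2_IN_FS", "L2_IN_LTS")

LAYERS <- c("L1", "L2", "L3", "L5a", "L5b")

# layer implied by each cell class
CLASS_LAYER <- c(L2_SC = "L2", L2_PC = "L2", L3_PC = "L3", L5a_PC = "L5a",
                 L5b_PC = "L5b", L1_IN = "L1", L2_IN_FS = "L2",
                 L2_IN_LTS = "L2")

#' Describe a stimulus protocol
#'
#' A protocol records what was injected (or flashed) during a sweep: the kind
#' of stimulus, its onset relative to the sweep start, and kind-specific
#' parameters.
#'
#' @param kind one of `"current_step"`, `"current_ramp"`, `"zap"`,
#'   `"opto_pulse"`, `"opto_train"`, `"paired_ap"`, `"none"`.
#' @param onset_ms stimulus onset, ms from sweep start (>= 0).
#' @param ... kind-specific parameters. Steps: `amplitude_pa`, `duration_ms`.
#'   Ramps: `slope_pa_per_s`, `duration_ms`. ZAP: `min_hz`, `max_hz`,
#'   `duration_ms`, `amplitude_pa`. Opto pulse: `pulse_ms`. Opto train:
#'   `frequency_hz` (10 or 20), `n_pulses`, `pulse_ms`. Paired AP:
#'   `amplitude_na`, `pulse_ms`.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(kind, onset_ms = 0, ...) {
  kind <- match.arg(kind, PROTOCOL_KINDS)
  if (!is.numeric(onset_ms) || length(onset_ms) != 1L || onset_ms < 0)
    stop("onset_ms must be a single non-negative number")
  pars <- list(...)
  if (kind == "opto_train") {
    if (is.null(pars$frequency_hz) ||
        !(pars$frequency_hz %in% c(10, 20)))
      stop("opto_train requires frequency_hz in {10, 20}")
    if (is.null(pars$n_pulses)) pars$n_pulses <- 10
  }
  structure(list(kind = kind, onset_ms = onset_ms, parameters = pars),
            class = "stimulus_protocol")
}

#' Construct a sweep
#'
#' A sweep is one time-aligned pair of membrane-potential and command-current
#' traces recorded from a single cell, with its stimulus protocol.
#'
#' @param voltage membrane potential samples, mV.
#' @param current command current samples, pA (same length as `voltage`).
#' @param time_step sampling interval, ms per sample (> 0).
#' @param protocol a [stimulus_protocol()].
#' @param cell_id opaque cell identifier.
#' @param sweep_index non-negative integer index within a protocol repeat set.
#' @param condition condition label (e.g. `"baseline"`, `"gabazine"`).
#' @return an object of class `sweep`.
#' @export
sweep <- function(voltage, current, time_step,
                  protocol = stimulus_protocol("none"),
                  cell_id = "cell", sweep_index = 0L,
                  condition = "baseline") {
  voltage <- as.numeric(voltage)
  current <- as.numeric(current)
  if (length(voltage) != length(current))
    stop("format error: voltage and current must have identical length")
  if (length(voltage) < 2L)
    stop("format error: a sweep needs at least 2 samples")
  if (!all(is.finite(voltage)) || !all(is.finite(current)))
    stop("format error: all samples must be finite")
  if (!is.numeric(time_step) || length(time_step) != 1L || time_step <= 0)
    stop("sampling error: time_step must be a single positive number")
  if (!inherits(protocol, "stimulus_protocol"))
    stop("protocol must be a stimulus_protocol")
  dur <- (length(voltage) - 1L) * time_step
  if (protocol$onset_ms > dur)
    stop("protocol onset lies beyond the sweep duration")
  structure(list(voltage = voltage, current = current,
                 time_step = time_step, protocol = protocol,
                 cell_id = as.character(cell_id),
                 sweep_index = as.integer(sweep_index),
                 condition = as.character(condition)),
            class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> cell %s, %d samples @ %.4g ms (%.1f ms), protocol %s\n",
              x$cell_id, length(x$voltage), x$time_step,
              sweep_duration(x), x$protocol$kind))
  invisible(x)
}

#' Sweep duration in ms
#' @param s a [sweep()].
#' @return duration `(n - 1) * time_step`, ms.
#' @export
sweep_duration <- function(s) (length(s$voltage) - 1L) * s$time_step

#' Time axis of a sweep
#' @param s a [sweep()].
#' @return vector of sample times, ms, starting at 0.
#' @export
sweep_times <- function(s) (seq_along(s$voltage) - 1L) * s$time_step

#' Inclusion rule for recorded cells
#'
#' A recording is included when the resting membrane potential is at or below
#' -50 mV and the series resistance is at or below 50 MOhm.
#'
#' @param resting_vm_mV resting membrane potential, mV.
#' @param series_resistance_MOhm series resistance, MOhm.
#' @return logical vector.
#' @export
is_included <- function(resting_vm_mV, series_resistance_MOhm) {
  resting_vm_mV <= -50 & series_resistance_MOhm <= 50
}

#' Construct a table of cell records
#'
#' @param cell_id character vector of identifiers.
#' @param cell_class one of the recognised classes per cell (see
#'   `fancircuit:::CELL_CLASSES`).
#' @param ml_distance_um soma distance from the parasubiculum border, um
#'   (larger = more lateral).
#' @param dv_depth_mm depth of the encompassing slice ventral to bregma, mm.
#' @param resting_vm_mV,series_resistance_MOhm recording quality metadata used
#'   by the inclusion rule.
#' @param layer cortical layer; defaults to the layer implied by `cell_class`.
#' @return data frame with one row per cell and an `included` flag.
#' @export
cell_record <- function(cell_id, cell_class, ml_distance_um, dv_depth_mm,
                        resting_vm_mV, series_resistance_MOhm,
                        layer = NULL) {
  cell_class <- as.character(cell_class)
  bad <- setdiff(unique(cell_class), CELL_CLASSES)
  if (length(bad))
    stop("validation error: unknown cell_class: ", paste(bad, collapse = ", "))
  if (is.null(layer)) layer <- unname(CLASS_LAYER[cell_class])
  if (any(layer != unname(CLASS_LAYER[cell_class])))
    stop("validation error: cell_class inconsistent with layer")
  if (any(ml_distance_um < 0)) stop("ml_distance_um must be >= 0")
  data.frame(cell_id = as.character(cell_id), cell_class = cell_class,
             layer = layer,
             ml_distance_um = as.numeric(ml_distance_um),
             dv_depth_mm = as.numeric(dv_depth_mm),
             resting_vm_mV = as.numeric(resting_vm_mV),
             series_resistance_MOhm = as.numeric(series_resistance_MOhm),
             included = is_included(resting_vm_mV, series_resistance_MOhm),
             stringsAsFactors = FALSE)
}

#' Bundle cells and their sweeps into a cohort
#'
#' @param cells a data frame from [cell_record()].
#' @param sweeps named list mapping `cell_id` to a list of [sweep()] objects.
#' @param conditions optional named character vector mapping `cell_id` to a
#'   condition label.
#' @return an object of class `cohort`.
#' @export
cohort <- function(cells, sweeps = list(), conditions = NULL) {
  stopifnot(is.data.frame(cells))
  if (length(sweeps)) {
    orphan <- setdiff(names(sweeps), cells$cell_id)
    if (length(orphan))
      stop("sweeps reference unknown cells: ", paste(orphan, collapse = ", "))
    for (id in names(sweeps)) {
      sw <- sweeps[[id]]
      key <- vapply(sw, function(s)
        paste(s$protocol$kind, s$condition, s$sweep_index), "")
      if (anyDuplicated(key))
        stop("duplicate sweep index within protocol x condition for cell ", id)
    }
  }
  if (is.null(conditions))
    conditions <- setNames(rep("baseline", nrow(cells)), cells$cell_id)
  structure(list(cells = cells, sweeps = sweeps, conditions = conditions),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d cells (%d included), %d cells with sweeps\n",
              nrow(x$cells), sum(x$cells$included), length(x$sweeps)))
  invisible(x)
}

# ---- on-disk formats -------------------------------------------------------
# Sweep file: tab-delimited, header time_ms / voltage_mV / current_pA, with a
# sidecar <stem>.meta of key=value lines carrying cell_id, condition,
# sweep_index, time_step_ms and the protocol fields.

#' Write a sweep to a tab-delimited file plus sidecar
#'
#' @param s a [sweep()].
#' @param path destination file path; a sidecar `<stem>.meta` is written next
#'   to it.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(s, path) {
  stopifnot(inherits(s, "sweep"))
  df <- data.frame(time_ms = sprintf("%.10g", sweep_times(s)),
                   voltage_mV = sprintf("%.10g", s$voltage),
                   current_pA = sprintf("%.10g", s$current))
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("I/O error: cannot write ", path)
  meta <- c(
    paste0("cell_id=", s$cell_id),
    paste0("condition=", s$condition),
    paste0("sweep_index=", s$sweep_index),
    paste0("time_step_ms=", sprintf("%.10g", s$time_step)),
    paste0("protocol.kind=", s$protocol$kind),
    paste0("protocol.onset_ms=", sprintf("%.10g", s$protocol$onset_ms)))
  pars <- s$protocol$parameters
  for (nm in names(pars))
    meta <- c(meta, paste0("protocol.", nm, "=", sprintf("%.10g", pars[[nm]])))
  writeLines(meta, meta_path(path))
  invisible(path)
}

meta_path <- function(path) paste0(sub("\\.[^./]*$", "", path), ".meta")

read_meta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  vals <- vapply(kv, `[`, "", 2L)
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

#' Read a sweep written by [write_sweep()]
#'
#' The time column is verified to be uniform (relative tolerance 1e-6) and
#' collapsed to a single `time_step`.
#'
#' @param path path to the sweep file; the `<stem>.meta` sidecar must exist.
#' @return a [sweep()].
#' @export
read_sweep <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  mp <- meta_path(path)
  if (!file.exists(mp)) stop("format error: missing sidecar ", mp)
  df <- read.delim(path, check.names = FALSE)
  need <- c("time_ms", "voltage_mV", "current_pA")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("format error: missing column ", paste(miss, collapse = ", "))
  if (nrow(df) < 2L) stop("format error: fewer than 2 rows")
  dtv <- diff(df$time_ms)
  dt <- median(dtv)
  if (dt <= 0 || any(abs(dtv - dt) > 1e-6 * dt))
    stop("sampling error: non-uniform time base in ", path)
  meta <- read_meta(mp)
  kind <- if (!is.na(meta["protocol.kind"])) meta[["protocol.kind"]] else "none"
  parnames <- grep("^protocol\\.", names(meta), value = TRUE)
  parnames <- setdiff(parnames, c("protocol.kind", "protocol.onset_ms"))
  pars <- lapply(meta[parnames], as.numeric)
  names(pars) <- sub("^protocol\\.", "", parnames)
  prot <- do.call(stimulus_protocol, c(
    list(kind = kind,
         onset_ms = as.numeric(meta[["protocol.onset_ms"]])), pars))
  sweep(df$voltage_mV, df$current_pA, time_step = dt, protocol = prot,
        cell_id = meta[["cell_id"]],
        sweep_index = as.integer(meta[["sweep_index"]]),
        condition = meta[["condition"]])
}

#' Write a cohort: manifest plus one file pair per sweep
#'
#' @param ch a [cohort()].
#' @param dir output directory (created if needed). The manifest is written to
#'   `manifest.tsv`; sweeps to `<cell_id>__<protocol>__<condition>__<index>.tsv`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(ch, dir) {
  stopifnot(inherits(ch, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(ch$cells[, c("cell_id", "cell_class", "layer", "ml_distance_um",
                           "dv_depth_mm", "resting_vm_mV",
                           "series_resistance_MOhm")],
              file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (id in names(ch$sweeps)) {
    for (s in ch$sweeps[[id]]) {
      fn <- sprintf("%s__%s__%s__%03d.tsv", id, s$protocol$kind,
                    s$condition, s$sweep_index)
      write_sweep(s, file.path(dir, fn))
    }
  }
  invisible(dir)
}

#' Read a cohort from a manifest and a sweep directory
#'
#' Cells failing the inclusion rule are retained with `included = FALSE`.
#' Sweep files whose cell id is absent from the manifest raise a warning and
#' are skipped.
#'
#' @param manifest path to the tab-delimited manifest.
#' @param sweep_dir directory holding sweep `.tsv` files and `.meta` sidecars;
#'   may be empty.
#' @return a [cohort()].
#' @export
read_cohort <- function(manifest, sweep_dir = dirname(manifest)) {
  mf <- read.delim(manifest, check.names = FALSE)
  need <- c("cell_id", "cell_class", "layer", "ml_distance_um", "dv_depth_mm",
            "resting_vm_mV", "series_resistance_MOhm")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    stop("format error: manifest missing column ",
         paste(miss, collapse = ", "))
  cells <- cell_record(mf$cell_id, mf$cell_class, mf$ml_distance_um,
                       mf$dv_depth_mm, mf$resting_vm_mV,
                       mf$series_resistance_MOhm, layer = mf$layer)
  sweeps <- list()
  files <- if (dir.exists(sweep_dir))
    setdiff(list.files(sweep_dir, pattern = "\\.tsv$", full.names = TRUE),
            file.path(sweep_dir, "manifest.tsv")) else character()
  for (f in files) {
    s <- read_sweep(f)
    if (!s$cell_id %in% cells$cell_id) {
      warning("orphan sweep file (unknown cell ", s$cell_id, "): ", f)
      next
    }
    sweeps[[s$cell_id]] <- c(sweeps[[s$cell_id]], list(s))
  }
  cohort(cells, sweeps)
}
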