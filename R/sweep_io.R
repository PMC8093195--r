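#' Construct a single patch-clamp sweep
#'
#' A sweep pairs a membrane-voltage trace with the injected current (current
#' clamp) or the command voltage (voltage clamp), sampled at a fixed rate,
#' together with the stimulus epoch annotation.
#'
#' @param voltage numeric vector, membrane potential in mV (current clamp) or
#'   recorded current in pA (voltage clamp; see `clamp_mode`).
#' @param current numeric vector, injected current in pA (current clamp) or
#'   command potential in mV (voltage clamp). Same length as `voltage`.
#' @param sampling_rate sampling rate in Hz.
#' @param cell_id,protocol_id identifiers.
#' @param layer_label one of `"L2&3"`, `"L3c"`, `"L5"`, `"unknown"`.
#' @param clamp_mode `"current"` or `"voltage"`.
#' @param stim_onset,stim_offset stimulus epoch in seconds.
#' @param amplitude stimulus amplitude (pA in current clamp, mV step in
#'   voltage clamp), or `NA` if unknown.
#' @return An object of class `sweep_record`.
#' @export
sweep_record <- function(voltage, current, sampling_rate,
                         cell_id = "cell", protocol_id = "protocol",
                         layer_label = "unknown",
                         clamp_mode = c("current", "voltage"),
                         stim_onset = 0, stim_offset = NULL,
                         amplitude = NA_real_) {
  clamp_mode <- match.arg(clamp_mode)
  voltage <- as.numeric(voltage)
  current <- as.numeric(current)
  if (length(voltage) != length(current))
    stop("voltage and current series must have equal length (",
         length(voltage), " vs ", length(current), ")")
  if (length(voltage) < 2L) stop("sweep must contain at least 2 samples")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (!layer_label %in% c("L2&3", "L3c", "L5", "unknown"))
    stop("layer_label must be one of 'L2&3', 'L3c', 'L5', 'unknown'")
  duration <- length(voltage) / sampling_rate
  if (is.null(stim_offset)) stim_offset <- duration
  if (!(stim_onset >= 0 && stim_onset < stim_offset && stim_offset <= duration + 1e-9))
    stop("stimulus epoch invalid: need 0 <= stim_onset < stim_offset <= duration")
  structure(list(
    cell_id = cell_id, layer_label = layer_label, protocol_id = protocol_id,
    sampling_rate = sampling_rate, voltage = voltage, current = current,
    clamp_mode = clamp_mode, stim_onset = stim_onset, stim_offset = stim_offset,
    amplitude = amplitude
  ), class = "sweep_record")
}

#' Time base of a sweep
#' @param sweep a `sweep_record`.
#' @return numeric vector of sample times in seconds (first sample at t = 0).
#' @export
sweep_time <- function(sweep) {
  (seq_along(sweep$voltage) - 1) / sweep$sampling_rate
}

#' @export
print.sweep_record <- function(x, ...) {
  cat(sprintf("<sweep_record> %s/%s [%s clamp] %d samples @ %g Hz, step %g (%g-%g s)\n",
              x$cell_id, x$protocol_id, x$clamp_mode, length(x$voltage),
              x$sampling_rate, x$amplitude, x$stim_onset, x$stim_offset))
  invisible(x)
}

#' Construct an ordered collection of sweeps from one cell and protocol
#'
#' @param sweeps list of `sweep_record` objects sharing `cell_id`,
#'   `protocol_id`, `sampling_rate` and `clamp_mode`.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps) {
  if (!is.list(sweeps)) stop("sweeps must be a list of sweep_record objects")
  if (length(sweeps) > 0) {
    ok <- vapply(sweeps, inherits, logical(1), "sweep_record")
    if (!all(ok)) stop("all elements must be sweep_record objects")
    ids <- unique(vapply(sweeps, `[[`, character(1), "cell_id"))
    if (length(ids) != 1L)
      stop("all sweeps in a set must share one cell_id (got: ",
           paste(ids, collapse = ", "), ")")
    prot <- unique(vapply(sweeps, `[[`, character(1), "protocol_id"))
    if (length(prot) != 1L)
      stop("all sweeps in a set must share one protocol_id")
    fs <- unique(vapply(sweeps, `[[`, numeric(1), "sampling_rate"))
    if (length(fs) != 1L) stop("all sweeps in a set must share sampling_rate")
    cm <- unique(vapply(sweeps, `[[`, character(1), "clamp_mode"))
    if (length(cm) != 1L) stop("all sweeps in a set must share clamp_mode")
  }
  structure(list(sweeps = sweeps), class = "sweep_set")
}

#' @export
length.sweep_set <- function(x) length(x$sweeps)

#' @export
`[[.sweep_set` <- function(x, i) x$sweeps[[i]]

#' @export
print.sweep_set <- function(x, ...) {
  if (length(x) == 0) { cat("<sweep_set> empty\n"); return(invisible(x)) }
  cat(sprintf("<sweep_set> %s/%s: %d sweeps, amplitudes %s\n",
              x[[1]]$cell_id, x[[1]]$protocol_id, length(x),
              paste(sweep_amplitudes(x), collapse = ", ")))
  invisible(x)
}

#' Per-sweep stimulus amplitudes of a sweep set
#' @param set a `sweep_set`.
#' @return numeric vector of amplitudes.
#' @export
sweep_amplitudes <- function(set) {
  vapply(set$sweeps, `[[`, numeric(1), "amplitude")
}

.header_keys <- c("cell_id", "layer", "protocol_id", "sampling_rate_hz",
                  "clamp_mode", "stim_onset_s", "stim_offset_s", "amplitude")

.write_one_sweep <- function(sw, path) {
  hdr <- c(
    paste0("# cell_id: ", sw$cell_id),
    paste0("# layer: ", sw$layer_label),
    paste0("# protocol_id: ", sw$protocol_id),
    paste0("# sampling_rate_hz: ", format(sw$sampling_rate, digits = 15)),
    paste0("# clamp_mode: ", sw$clamp_mode),
    paste0("# stim_onset_s: ", format(sw$stim_onset, digits = 15)),
    paste0("# stim_offset_s: ", format(sw$stim_offset, digits = 15)),
    paste0("# amplitude: ", format(sw$amplitude, digits = 15)),
    "voltage_mV\tcurrent_pA"
  )
  body <- paste(formatC(sw$voltage, format = "g", digits = 9),
                formatC(sw$current, format = "g", digits = 9), sep = "\t")
  writeLines(c(hdr, body), path)
  path
}

.read_one_sweep <- function(path) {
  lines <- readLines(path)
  hidx <- grep("^# ", lines)
  if (length(hidx) == 0) stop("malformed sweep file (no header block): ", path)
  kv <- list()
  for (l in lines[hidx]) {
    m <- regmatches(l, regexec("^# ([^:]+): ?(.*)$", l))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  missing <- setdiff(.header_keys, names(kv))
  if (length(missing) > 0)
    stop("sweep file header missing field(s): ", paste(missing, collapse = ", "),
         " in ", path)
  fs <- suppressWarnings(as.numeric(kv$sampling_rate_hz))
  if (is.na(fs) || fs <= 0)
    stop("sweep file field 'sampling_rate_hz' invalid in ", path)
  colhdr <- grep("^voltage_mV\tcurrent_pA$", lines)
  if (length(colhdr) != 1) stop("malformed sweep file (no column header): ", path)
  data_lines <- lines[(colhdr + 1):length(lines)]
  data_lines <- data_lines[nzchar(data_lines)]
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 2))
    stop("inconsistent column lengths in ", path,
         " (line with ", nc[which(nc != 2)[1]], " fields)")
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  i <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(v) || anyNA(i))
    stop("non-numeric or missing value in column '",
         if (anyNA(v)) "voltage_mV" else "current_pA", "' of ", path)
  sweep_record(v, i, fs,
               cell_id = kv$cell_id, protocol_id = kv$protocol_id,
               layer_label = kv$layer,
               clamp_mode = kv$clamp_mode,
               stim_onset = as.numeric(kv$stim_onset_s),
               stim_offset = as.numeric(kv$stim_offset_s),
               amplitude = as.numeric(kv$amplitude))
}

#' Write a sweep set as a manifest plus per-sweep text files
#'
#' The canonical on-disk format is a plain-text manifest CSV with columns
#' `sweep_file`, `protocol_id`, `amplitude`, referring to per-sweep files
#' (key:value header block plus tab-separated `voltage_mV` and `current_pA`
#' columns) stored next to the manifest.
#'
#' @param sweeps a `sweep_set`.
#' @param path path of the manifest file to create (its directory is created
#'   if needed; sweep files are written alongside).
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(sweeps, path) {
  if (!inherits(sweeps, "sweep_set")) sweeps <- sweep_set(sweeps)
  dir <- dirname(path)
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory for ", path)
  stem <- sub("\\.[^.]*$", "", basename(path))
  rows <- data.frame(sweep_file = character(0), protocol_id = character(0),
                     amplitude = numeric(0))
  for (k in seq_len(length(sweeps))) {
    sw <- sweeps[[k]]
    fn <- sprintf("%s_%03d.sweep", stem, k)
    .write_one_sweep(sw, file.path(dir, fn))
    rows <- rbind(rows, data.frame(sweep_file = fn, protocol_id = sw$protocol_id,
                                   amplitude = sw$amplitude))
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a sweep set from a manifest file
#'
#' @param path path to a manifest CSV written by [write_sweep_table()].
#' @param protocol optional protocol id to select when the manifest holds
#'   several protocols.
#' @return A `sweep_set`.
#' @export
read_sweep_table <- function(path, protocol = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sweep_file", "protocol_id", "amplitude")
  miss <- setdiff(need, names(man))
  if (length(miss) > 0)
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(protocol)) man <- man[man$protocol_id == protocol, , drop = FALSE]
  if (nrow(man) > 0 && length(unique(man$protocol_id)) > 1)
    stop("manifest holds multiple protocols (",
         paste(unique(man$protocol_id), collapse = ", "),
         "); pass `protocol` to select one")
  sweeps <- lapply(man$sweep_file, function(f)
    .read_one_sweep(file.path(dirname(path), f)))
  for (k in seq_along(sweeps)) sweeps[[k]]$amplitude <- man$amplitude[k]
  sweep_set(sweeps)
}

#' Detect a rectangular stimulus epoch in a current-clamp sweep
#'
#' Baseline is taken from the initial samples; onset/offset are the first and
#' last samples where the current deviates from baseline by more than
#' `threshold_pa`; amplitude is the median in-step current minus baseline.
#'
#' @param sweep a current-clamp `sweep_record`.
#' @param threshold_pa deviation threshold in pA (default 10).
#' @param baseline_frac fraction of the initial trace used for the baseline
#'   estimate (default 0.1).
#' @return list with `stim_onset`, `stim_offset` (s), `amplitude` (pA) and
#'   `detected` (FALSE for a flagged zero-amplitude epoch).
#' @export
detect_stimulus_epoch <- function(sweep, threshold_pa = 10, baseline_frac = 0.1) {
  stopifnot(inherits(sweep, "sweep_record"))
  if (sweep$clamp_mode != "current")
    stop("detect_stimulus_epoch requires a current-clamp sweep")
  i <- sweep$current
  nb <- max(2L, floor(length(i) * baseline_frac))
  base <- median(i[seq_len(nb)])
  dev <- which(abs(i - base) > threshold_pa)
  if (length(dev) == 0)
    return(list(stim_onset = 0, stim_offset = 0, amplitude = 0, detected = FALSE))
  on <- dev[1]; off <- dev[length(dev)]
  amp <- median(i[on:off]) - base
  list(stim_onset = (on - 1) / sweep$sampling_rate,
       stim_offset = off / sweep$sampling_rate,
       amplitude = amp, detected = TRUE)
}
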