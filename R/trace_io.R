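#' Write sweep families to the canonical on-disk format
#'
#' The canonical format is plain text: one tab-delimited sweep table per cell
#' (`<cell_id>.tsv`, columns `sweep_id`, `time_s`, `voltage_mV`, long format)
#' plus a single JSON sidecar (`metadata.json`) holding every sweep's
#' [current_protocol()] and labels. Voltages and times are written with
#' 17 significant digits so the round trip is lossless for doubles.
#'
#' @param cells list of cell records as returned by [generate_cohort()]
#'   (`$cells`): each a list with `cell_id`, `group_label` and `sweeps` (a
#'   named list of [voltage_trace()] keyed by step amplitude).
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_sweeps <- function(cells, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  if (!dir.exists(path)) stopf("cannot create output directory '%s'", path)
  meta <- list()
  for (cell in cells) {
    stopifnot(!is.null(cell$cell_id), !is.null(cell$sweeps))
    steps <- names(cell$sweeps)
    if (anyDuplicated(steps))
      stopf("cell %s has duplicate sweeps at step %s", cell$cell_id,
            steps[duplicated(steps)][1])
    tabs <- lapply(cell$sweeps, function(tr) {
      validate_trace(tr)
      data.table::data.table(
        sweep_id = tr$sweep_id,
        time_s = sprintf("%.17g", tr$time),
        voltage_mV = sprintf("%.17g", tr$voltage))
    })
    tab <- data.table::rbindlist(tabs)
    data.table::fwrite(tab, file.path(path, paste0(cell$cell_id, ".tsv")),
                       sep = "\t")
    meta[[cell$cell_id]] <- list(
      cell_id = cell$cell_id,
      group_label = cell$group_label %||% "unknown",
      sweeps = lapply(cell$sweeps, function(tr)
        unclass(tr$protocol))
    )
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read sweep families from the canonical format
#'
#' Inverse of [write_sweeps()]. Every invariant the reader can check is
#' checked: metadata keys present, one sweep per (cell, step), steps on the
#' 13-value grid, uniform time grid consistent with the declared sampling
#' rate.
#'
#' @param path directory written by [write_sweeps()].
#' @return list of cell records (`cell_id`, `group_label`, `sweeps`).
#' @export
read_sweeps <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file)) stopf("missing metadata.json in '%s'", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = FALSE)
  cells <- vector("list", length(meta))
  names(cells) <- names(meta)
  for (cid in names(meta)) {
    m <- meta[[cid]]
    for (key in c("cell_id", "group_label", "sweeps"))
      if (is.null(m[[key]])) stopf("metadata for cell '%s' lacks key '%s'", cid, key)
    f <- file.path(path, paste0(cid, ".tsv"))
    if (!file.exists(f)) stopf("missing sweep table for cell '%s'", cid)
    tab <- data.table::fread(f, sep = "\t", colClasses = list(character = "sweep_id"))
    if (!all(c("sweep_id", "time_s", "voltage_mV") %in% names(tab)))
      stopf("sweep table for cell '%s' lacks required columns", cid)
    sweeps <- list()
    for (sid in unique(tab$sweep_id)) {
      pm <- m$sweeps[[sid]]
      if (is.null(pm)) stopf("no protocol metadata for cell '%s' sweep '%s'", cid, sid)
      proto <- do.call(current_protocol, pm[setdiff(names(pm), character(0))])
      if (!is.null(sweeps[[sid]]))
        stopf("duplicate sweep '%s' for cell '%s'", sid, cid)
      sub <- tab[tab$sweep_id == sid, ]
      sweeps[[sid]] <- voltage_trace(
        time = sub$time_s, voltage = sub$voltage_mV, protocol = proto,
        cell_id = cid, sweep_id = sid, group_label = m$group_label)
    }
    if (anyDuplicated(names(sweeps)))
      stopf("duplicate sweeps for cell '%s'", cid)
    if (!all(as.numeric(names(sweeps)) %in% step_grid()))
      stopf("cell '%s' has sweeps off the 13-value step grid", cid)
    cells[[cid]] <- list(cell_id = cid, group_label = m$group_label,
                         sweeps = sweeps)
  }
  cells
}

#' Anti-aliased decimation of a voltage trace
#'
#' Reduces the sampling rate by an integer factor after a zero-phase
#' frequency-domain low-pass at the new Nyquist frequency (a brick-wall FFT
#' filter, so passband amplitudes are preserved exactly and no phase delay
#' is introduced). Protocol metadata is updated to the new rate.
#'
#' @param trace a [voltage_trace()].
#' @param target_rate target sampling rate in Hz; must divide the current
#'   rate.
#' @return a decimated [voltage_trace()].
#' @export
decimate_trace <- function(trace, target_rate) {
  validate_trace(trace)
  fs <- trace$protocol$sampling_rate
  if (target_rate == fs) return(trace)
  q <- fs / target_rate
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stopf("target_rate (%g Hz) must divide the sampling rate (%g Hz)", target_rate, fs)
  q <- as.integer(round(q))
  v <- trace$voltage
  n <- length(v)
  V <- fft(v)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  V[f >= target_rate / 2] <- 0
  v <- Re(fft(V, inverse = TRUE)) / n
  v <- v[seq(1, n, by = q)]
  proto <- trace$protocol
  proto$sampling_rate <- target_rate
  voltage_trace(time = (seq_along(v) - 1) / target_rate + trace$time[1],
                voltage = v, protocol = proto, cell_id = trace$cell_id,
                sweep_id = trace$sweep_id, group_label = trace$group_label,
                ground_truth = trace$ground_truth)
}

# Block-mean decimation: each output sample is the mean of q consecutive
# input samples, timestamped at the block center. Unbiased for signals much
# slower than the block and free of filter ringing at discontinuities; used
# by the AHP fit. The trailing partial block is dropped.
block_decimate_trace <- function(trace, target_rate) {
  fs <- trace$protocol$sampling_rate
  q <- fs / target_rate
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stopf("target_rate (%g Hz) must divide the sampling rate (%g Hz)", target_rate, fs)
  q <- as.integer(round(q))
  if (q == 1L) return(trace)
  n <- (length(trace$voltage) %/% q) * q
  v <- colMeans(matrix(trace$voltage[seq_len(n)], nrow = q))
  t0 <- trace$time[1] + (q - 1) / (2 * fs)
  proto <- trace$protocol
  proto$sampling_rate <- target_rate
  voltage_trace(time = t0 + (seq_along(v) - 1) / target_rate, voltage = v,
                protocol = proto, cell_id = trace$cell_id,
                sweep_id = trace$sweep_id, group_label = trace$group_label,
                ground_truth = trace$ground_truth)
}
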