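#' Read and write delimited-text kinematics
#'
#' Tab-separated files with columns `time_s`, `x_cm`, `y_cm`, `z_cm`.
#' Gaps (non-increasing or missing timestamps) are rejected at ingestion.
#'
#' @param path file path.
#' @return `read_kinematics()` returns a kinematic trace `data.frame`
#'   (`time`, `x`, `y`, `z`).
#' @export
read_kinematics <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  need <- c("time_s", "x_cm", "y_cm", "z_cm")
  if (!all(need %in% names(d)))
    stop("kinematics file must have columns ", paste(need, collapse = ", "))
  out <- data.frame(time = d$time_s, x = d$x_cm, y = d$y_cm, z = d$z_cm)
  if (anyNA(out)) stop("missing values in kinematics file ", path)
  if (any(diff(out$time) <= 0))
    stop("timestamps not strictly increasing in ", path)
  out
}

#' @param kin kinematic trace (`time`, `x`, `y`, `z`).
#' @rdname read_kinematics
#' @export
write_kinematics <- function(kin, path) {
  d <- data.frame(time_s = kin$time, x_cm = kin$x, y_cm = kin$y, z_cm = kin$z)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write delimited-text signal traces
#'
#' Tab-separated files with columns `time_s` and `value`; the sampling
#' rate is recovered from the median timestamp increment and must be
#' uniform.
#'
#' @param path file path.
#' @return `read_signal()` returns a `signal_trace`.
#' @export
read_signal <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("signal file must have columns time_s, value")
  dt <- diff(d$time_s)
  if (any(dt <= 0)) stop("timestamps not strictly increasing in ", path)
  if (max(abs(dt - median(dt))) > median(dt) * 1e-3)
    stop("non-uniform sampling in ", path)
  signal_trace(d$value, rate = 1 / median(dt), t0 = d$time_s[1L])
}

#' @param sig a `signal_trace`.
#' @rdname read_signal
#' @export
write_signal <- function(sig, path) {
  d <- data.frame(time_s = signal_times(sig), value = sig$x)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a registration path to JSON
#'
#' @param path a `registration_path`.
#' @param file destination file.
#' @return `read_registration_path()` returns a `registration_path`.
#' @export
write_registration_path <- function(path, file) {
  jsonlite::write_json(
    list(ref_idx = path$ref_idx, query_idx = path$query_idx,
         total_cost = path$total_cost, normalized_cost = path$normalized_cost,
         n_ref = path$n_ref, n_query = path$n_query),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_registration_path
#' @export
read_registration_path <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(ref_idx = as.integer(j$ref_idx),
                 query_idx = as.integer(j$query_idx),
                 total_cost = j$total_cost,
                 normalized_cost = j$normalized_cost,
                 n_ref = as.integer(j$n_ref), n_query = as.integer(j$n_query)),
            class = "registration_path")
}

#' Write a synthetic session to a directory
#'
#' One kinematics file and two signal files per trial, plus a JSON sidecar
#' (`session.json`) holding the generator parameters and per-trial ground
#' truth (onsets and phase boundaries), so a session can be regenerated or
#' audited from disk.
#'
#' @param session an `ecog_session`.
#' @param dir destination directory (created if needed).
#' @return `read_session()` returns a list with `manifest` and `trials`
#'   (each `kin`, `ecog`, `emg`).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(session$trials)
  for (i in seq_len(n)) {
    tr <- session$trials[[i]]
    write_kinematics(tr$kin, file.path(dir, sprintf("trial%03d_kin.tsv", i)))
    write_signal(tr$ecog, file.path(dir, sprintf("trial%03d_ecog.tsv", i)))
    write_signal(tr$emg, file.path(dir, sprintf("trial%03d_emg.tsv", i)))
  }
  truth <- lapply(session$trials, function(tr)
    list(true_onset = tr$true_onset, phases = as.list(tr$phases),
         durations = as.list(tr$durations)))
  jsonlite::write_json(
    list(params = unclass(session$params), n_trials = n, ground_truth = truth),
    file.path(dir, "session.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "session.json"),
                                  simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  n <- manifest$n_trials
  trials <- lapply(seq_len(n), function(i) list(
    kin = read_kinematics(file.path(dir, sprintf("trial%03d_kin.tsv", i))),
    ecog = read_signal(file.path(dir, sprintf("trial%03d_ecog.tsv", i))),
    emg = read_signal(file.path(dir, sprintf("trial%03d_emg.tsv", i)))
  ))
  list(manifest = manifest, trials = trials)
}
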