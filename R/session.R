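## Session container and on-disk format.
##
## A session is one animal-day: multichannel LFP with M1/DLS region labels,
## sorted single units, pre/train/post period boundaries, per-10 s movement
## flags and reach-trial touch times. On disk a session is a plain
## directory: metadata.json + lfp.f32 (row-major float32, channels x
## samples) + units/trials/movement CSVs -- inspectable, diffable and
## language-neutral.

#' Construct a single-unit record
#' @param unit_id character id.
#' @param region `"M1"` or `"DLS"`.
#' @param spike_times strictly increasing spike times in seconds.
#' @export
unit <- function(unit_id, region, spike_times) {
  structure(list(unit_id = as.character(unit_id),
                 region = region,
                 spike_times = as.numeric(spike_times)),
            class = "cs_unit")
}

#' Construct a recording session
#'
#' Times are in seconds from recording start; periods are half-open
#' `[start, end)` intervals. Movement flags are logical vectors per period,
#' one per 10 s window aligned to the period start.
#'
#' @param session_id character id.
#' @param sampling_rate LFP sampling rate (Hz).
#' @param lfp numeric matrix, channels x samples.
#' @param channel_region character vector, one of `"M1"`/`"DLS"` per channel.
#' @param units list of [unit()] records.
#' @param periods named list with elements `pre`, `train`, `post`, each
#'   `c(start_s, end_s)`.
#' @param movement named list (`pre`, `post`, optionally `train`) of logical
#'   vectors.
#' @param trials data.frame with columns `trial_id`, `touch_time_s` (may be
#'   empty).
#' @param day_index integer day of training, >= 1.
#' @param validate check invariants (default TRUE).
#' @export
session <- function(session_id, sampling_rate, lfp, channel_region,
                    units = list(), periods, movement = list(),
                    trials = empty_trials(), day_index = 1L,
                    validate = TRUE) {
  s <- structure(list(session_id = as.character(session_id),
                      sampling_rate = as.numeric(sampling_rate),
                      lfp = lfp,
                      channel_region = as.character(channel_region),
                      units = units,
                      periods = periods,
                      movement = movement,
                      trials = trials,
                      day_index = as.integer(day_index)),
                 class = "cs_session")
  if (validate) validate_session(s)
  s
}

empty_trials <- function() {
  data.frame(trial_id = character(0), touch_time_s = numeric(0))
}

#' Validate a session against its invariants
#'
#' Checks region labels, spike-time ordering and range, and period layout
#' (`pre < train < post`, non-overlapping). Errors name the offending
#' field.
#' @param s a [session()].
#' @return the session, invisibly.
#' @export
validate_session <- function(s) {
  if (!inherits(s, "cs_session")) stop("not a cs_session")
  if (!is.matrix(s$lfp)) stop("lfp: must be a channels x samples matrix")
  if (length(s$channel_region) != nrow(s$lfp))
    stop("channel_region: length must equal number of LFP channels")
  bad <- setdiff(unique(s$channel_region), c("M1", "DLS"))
  if (length(bad))
    stop("channel_region: unknown region label ", paste(bad, collapse = ","))
  dur <- ncol(s$lfp) / s$sampling_rate
  for (u in s$units) {
    st <- u$spike_times
    if (length(st) && (any(diff(st) <= 0)))
      stop("units: spike_times not strictly increasing for unit ", u$unit_id)
    if (length(st) && (min(st) < 0 || max(st) > dur))
      stop("units: spike time outside [0, ", dur, "] for unit ", u$unit_id)
    if (!u$region %in% c("M1", "DLS"))
      stop("units: unknown region for unit ", u$unit_id)
  }
  need <- c("pre", "train", "post")
  if (!all(need %in% names(s$periods)))
    stop("periods: must contain pre, train, post")
  p <- s$periods
  for (nm in need) {
    if (p[[nm]][2] <= p[[nm]][1]) stop("periods: ", nm, " empty or reversed")
  }
  if (!(p$pre[2] <= p$train[1] && p$train[2] <= p$post[1]))
    stop("periods: must be ordered pre < train < post without overlap")
  if (p$post[2] > dur + 1e-9)
    stop("periods: post extends past recording end")
  invisible(s)
}

#' @export
print.cs_session <- function(x, ...) {
  cat(sprintf("<session %s day %d: %d ch (%d M1 / %d DLS), %.0f Hz, %.0f s, %d units, %d trials>\n",
              x$session_id, x$day_index, nrow(x$lfp),
              sum(x$channel_region == "M1"), sum(x$channel_region == "DLS"),
              x$sampling_rate, ncol(x$lfp) / x$sampling_rate,
              length(x$units), nrow(x$trials)))
  invisible(x)
}

#' Write a session directory
#'
#' Layout: `metadata.json`, `lfp.f32` (little-endian float32, row-major
#' channels x samples), `units.csv`, `trials.csv`, `movement.csv`.
#' Round-trip safe: spike times survive exactly (decimal text), LFP to
#' float32 precision.
#'
#' @param s a validated [session()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_session <- function(s, path) {
  validate_session(s)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(session_id = s$session_id,
               sampling_rate = s$sampling_rate,
               n_channels = nrow(s$lfp),
               n_samples = ncol(s$lfp),
               channel_region = s$channel_region,
               periods = s$periods,
               day_index = s$day_index,
               format_version = 1L)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(file.path(path, "lfp.f32"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.numeric(t(s$lfp)), con, size = 4L, endian = "little")
  udf <- do.call(rbind, lapply(s$units, function(u) {
    if (!length(u$spike_times)) return(NULL)
    ## 17 significant digits: doubles survive the text round trip exactly
    data.frame(unit_id = u$unit_id, region = u$region,
               spike_time_s = sprintf("%.17g", u$spike_times))
  }))
  if (is.null(udf))
    udf <- data.frame(unit_id = character(0), region = character(0),
                      spike_time_s = numeric(0))
  ## keep silent units discoverable on re-read
  hdr <- do.call(rbind, lapply(s$units, function(u)
    data.frame(unit_id = u$unit_id, region = u$region)))
  if (is.null(hdr))
    hdr <- data.frame(unit_id = character(0), region = character(0))
  utils::write.csv(udf, file.path(path, "units.csv"), row.names = FALSE)
  utils::write.csv(hdr, file.path(path, "unit_table.csv"), row.names = FALSE)
  utils::write.csv(s$trials, file.path(path, "trials.csv"), row.names = FALSE)
  mv <- do.call(rbind, lapply(names(s$movement), function(nm) {
    v <- s$movement[[nm]]
    if (!length(v)) return(NULL)
    data.frame(period = nm,
               window_start_s = s$periods[[nm]][1] + 10 * (seq_along(v) - 1),
               moving = as.integer(v))
  }))
  if (is.null(mv))
    mv <- data.frame(period = character(0), window_start_s = numeric(0),
                     moving = integer(0))
  utils::write.csv(mv, file.path(path, "movement.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a session directory written by [write_session()]
#' @param path session directory.
#' @return a validated [session()].
#' @export
read_session <- function(path) {
  mf <- file.path(path, "metadata.json")
  if (!file.exists(mf)) stop("missing metadata.json in ", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  n_ch <- meta$n_channels; n_s <- meta$n_samples
  lf <- file.path(path, "lfp.f32")
  sz <- file.info(lf)$size
  if (is.na(sz)) stop("missing lfp.f32 in ", path)
  if (sz != 4 * n_ch * n_s)
    stop("lfp.f32 size mismatch: expected ", 4 * n_ch * n_s, " bytes, got ", sz)
  con <- file(lf, "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, "numeric", n = n_ch * n_s, size = 4L, endian = "little")
  lfp <- matrix(v, nrow = n_ch, byrow = TRUE)
  udf <- utils::read.csv(file.path(path, "units.csv"),
                         colClasses = c(unit_id = "character",
                                        spike_time_s = "character"))
  udf$spike_time_s <- as.numeric(udf$spike_time_s)
  hdr_f <- file.path(path, "unit_table.csv")
  hdr <- if (file.exists(hdr_f))
    utils::read.csv(hdr_f, colClasses = c(unit_id = "character"))
  else unique(udf[c("unit_id", "region")])
  units <- lapply(seq_len(nrow(hdr)), function(i) {
    sel <- udf$unit_id == hdr$unit_id[i]
    unit(hdr$unit_id[i], hdr$region[i], udf$spike_time_s[sel])
  })
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            colClasses = c(trial_id = "character"))
  mv <- utils::read.csv(file.path(path, "movement.csv"))
  periods <- lapply(meta$periods, as.numeric)
  movement <- list()
  for (nm in unique(mv$period)) {
    sel <- mv$period == nm
    movement[[nm]] <- as.logical(mv$moving[sel][order(mv$window_start_s[sel])])
  }
  session(meta$session_id, meta$sampling_rate, lfp,
          meta$channel_region, units, periods, movement, trials,
          meta$day_index)
}

## interval helpers shared across modules -------------------------------

## half-open interval matrix [n x 2]; tolerate empty
as_intervals <- function(x) {
  if (is.null(x) || length(x) == 0) return(matrix(numeric(0), 0, 2))
  if (is.matrix(x)) x else matrix(x, ncol = 2, byrow = TRUE)
}

## total duration of a set of intervals
interval_duration <- function(iv) {
  iv <- as_intervals(iv)
  if (!nrow(iv)) return(0)
  sum(iv[, 2] - iv[, 1])
}

## intersect two sets of sorted, disjoint half-open intervals
interval_intersect <- function(a, b) {
  a <- as_intervals(a); b <- as_intervals(b)
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1], b[, 1]); hi <- pmin(a[i, 2], b[, 2])
    keep <- hi > lo
    if (any(keep)) out <- rbind(out, cbind(lo[keep], hi[keep]))
  }
  out[order(out[, 1]), , drop = FALSE]
}

## merge overlapping/adjacent intervals
interval_union <- function(iv) {
  iv <- as_intervals(iv)
  if (nrow(iv) < 2) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else out <- rbind(out, iv[i, ])
  }
  out
}

## which times fall inside any half-open interval
in_intervals <- function(t, iv) {
  iv <- as_intervals(iv)
  if (!nrow(iv)) return(rep(FALSE, length(t)))
  ans <- rep(FALSE, length(t))
  for (i in seq_len(nrow(iv))) ans <- ans | (t >= iv[i, 1] & t < iv[i, 2])
  ans
}
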