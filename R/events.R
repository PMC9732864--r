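EVENT_TYPES <- c("spike", "ripple", "fast_ripple")
RATE_COLS <- c(spike = "spike_rate", ripple = "ripple_rate", fast_ripple = "fr_rate")
PATHOLOGIES <- c("FCD", "ganglioglioma", "DNET", "low_grade_glioma", "PXA", "cavernoma")

#' Build the bipolar montage of an array
#'
#' Pairs every two layout-adjacent electrodes along the chosen direction.
#' `"row"` pairs neighbouring columns within each row (the default, and
#' the convention used throughout the package); `"column"` pairs
#' neighbouring rows within each column. Ordering is deterministic
#' (row-major).
#'
#' @param array an [electrode_array()], fully localized if midpoints are
#'   to be computed.
#' @param direction `"row"` or `"column"`.
#' @return A data frame with one row per bipolar channel: `channel_id`,
#'   electrode indices `electrode_a`/`electrode_b`, and midpoint
#'   coordinates `mid_x`/`mid_y`/`mid_z` (NA when either electrode is not
#'   localized).
#' @export
build_montage <- function(array, direction = c("row", "column")) {
  stopifnot(inherits(array, "electrode_array"))
  direction <- match.arg(direction)
  nr <- array$n_rows; nc <- array$n_cols
  if (direction == "row") {
    if (nc < 2L) stop("row montage needs at least 2 columns")
    r <- rep(seq_len(nr), each = nc - 1L)
    c1 <- rep(seq_len(nc - 1L), times = nr)
    a <- (r - 1L) * nc + c1
    b <- a + 1L
  } else {
    if (nr < 2L) stop("column montage needs at least 2 rows")
    r1 <- rep(seq_len(nr - 1L), each = nc)
    cc <- rep(seq_len(nc), times = nr - 1L)
    a <- (r1 - 1L) * nc + cc
    b <- a + nc
  }
  mids <- matrix(NA_real_, length(a), 3L)
  ok <- stats::complete.cases(array$coordinates[a, , drop = FALSE]) &
    stats::complete.cases(array$coordinates[b, , drop = FALSE])
  if (any(ok)) {
    mids[ok, ] <- bipolar_midpoint(array$coordinates[a[ok], , drop = FALSE],
                                   array$coordinates[b[ok], , drop = FALSE])
  }
  data.frame(channel_id = sprintf("%s_ch%02d", array$array_id, seq_along(a)),
             electrode_a = a, electrode_b = b,
             mid_x = mids[, 1L], mid_y = mids[, 2L], mid_z = mids[, 3L],
             stringsAsFactors = FALSE)
}

#' Per-channel biomarker rates from timestamped event logs
#'
#' Events are counted per channel and event type within the (typically
#' 60 s) epoch and normalized to events per minute. Channels listed in the
#' montage but without events get rate 0; artifactual channels are dropped
#' entirely and carry no rates downstream.
#'
#' @param events data frame with columns `patient_id`, `recording_id`,
#'   `channel_id`, `event_type` (one of spike/ripple/fast_ripple),
#'   `time_s`, and optionally `epoch_length_s`.
#' @param montage data frame of included channels with columns
#'   `patient_id`, `recording_id`, `channel_id`.
#' @param artifacts optional data frame (same key columns) of channels to
#'   exclude as artifactual.
#' @param epoch_length_s epoch length used for channels without events and
#'   when the log carries none (default 60).
#' @return Data frame keyed by `patient_id`, `recording_id`, `channel_id`
#'   with `spike_rate`, `ripple_rate`, `fr_rate` (events/min) and
#'   `epoch_min`.
#' @export
compute_rates <- function(events, montage, artifacts = NULL, epoch_length_s = 60) {
  if (epoch_length_s <= 0) stop("epoch length must be positive")
  keyof <- function(d) paste(d$patient_id, d$recording_id, d$channel_id, sep = "\r")
  mk <- keyof(montage)
  if (anyDuplicated(mk)) stop("montage contains duplicate channels")
  if (nrow(events) > 0L) {
    if (!all(events$event_type %in% EVENT_TYPES))
      stop("unknown event_type; must be one of: ", paste(EVENT_TYPES, collapse = ", "))
    if (any(events$time_s < 0)) stop("negative event times are invalid")
    ev_epoch <- if ("epoch_length_s" %in% names(events)) events$epoch_length_s else
      rep(epoch_length_s, nrow(events))
    if (any(events$time_s >= ev_epoch))
      stop("event times must lie within the epoch (time_s < epoch_length_s)")
    ek <- keyof(events)
    if (!all(ek %in% mk)) {
      bad <- unique(events$channel_id[!(ek %in% mk)])
      stop("events on unknown channel(s): ", paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  out <- montage[, c("patient_id", "recording_id", "channel_id")]
  out$epoch_min <- epoch_length_s / 60
  for (ty in EVENT_TYPES) out[[RATE_COLS[[ty]]]] <- 0
  if (nrow(events) > 0L) {
    ek <- keyof(events)
    ev_epoch <- if ("epoch_length_s" %in% names(events)) events$epoch_length_s else
      rep(epoch_length_s, nrow(events))
    # per-channel epoch length (must be unique within a channel)
    agg <- tapply(ev_epoch, ek, function(v) {
      if (length(unique(v)) > 1L) stop("inconsistent epoch_length_s within a channel")
      v[1L]
    })
    idx <- match(names(agg), mk)
    out$epoch_min[idx] <- as.numeric(agg) / 60
    for (ty in EVENT_TYPES) {
      sel <- events$event_type == ty
      if (!any(sel)) next
      cnt <- table(ek[sel])
      j <- match(names(cnt), mk)
      out[[RATE_COLS[[ty]]]][j] <- as.numeric(cnt) / out$epoch_min[j]
    }
  }
  if (!is.null(artifacts) && nrow(artifacts) > 0L) {
    out <- out[!(mk %in% keyof(artifacts)), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Summary table of biomarker rates by group
#'
#' Mirrors the usual descriptive table: per group, the number of included
#' channels, total event counts, and the mean/SD of rates computed over
#' channels on which at least one event of the respective type was
#' recorded. Groups in which a biomarker never occurred get `NA`
#' mean/SD (the table's em-dash convention).
#'
#' @param records channel-record data frame with rate columns and the
#'   grouping column.
#' @param by name of the grouping column (default `"pathology"`).
#' @return Data frame, one row per group x event type.
#' @export
summarize_rates <- function(records, by = "pathology") {
  if (nrow(records) == 0L) stop("no channel records to summarize")
  if (!by %in% names(records)) stop("grouping column '", by, "' not found")
  epoch_min <- if ("epoch_min" %in% names(records)) records$epoch_min else
    rep(1, nrow(records))
  groups <- unique(records[[by]])
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- records[[by]] == g
    do.call(rbind, lapply(EVENT_TYPES, function(ty) {
      r <- records[[RATE_COLS[[ty]]]][sel]
      tot <- sum(r * epoch_min[sel])
      pos <- r[r > 0]
      data.frame(group = g, event_type = ty, n_channels = sum(sel),
                 total_events = tot,
                 mean_rate = if (length(pos)) mean(pos) else NA_real_,
                 sd_rate = if (length(pos) > 1L) stats::sd(pos) else NA_real_,
                 n_active = length(pos), stringsAsFactors = FALSE)
    }))
  }))
  names(out)[1L] <- by
  rownames(out) <- NULL
  out
}

#' Distance to the electrode with the most events
#'
#' For each patient and event type with at least one event, finds the
#' channel with the highest rate and reports that rate together with the
#' channel's distance to the lesion edge (the distance family used for all
#' additional analyses). Ties are broken by the lowest channel id.
#'
#' @param records channel-record data frame with `patient_id`,
#'   `channel_id`, `d_edge_mm` and the rate columns.
#' @return Data frame with `patient_id`, `event_type`, `max_rate`,
#'   `distance_mm`, `channel_id`.
#' @export
dmax <- function(records) {
  need <- c("patient_id", "channel_id", "d_edge_mm")
  if (!all(need %in% names(records))) stop("records must carry ", paste(need, collapse = ", "))
  patients <- unique(records$patient_id)
  out <- list()
  for (p in patients) {
    sel <- records[records$patient_id == p, , drop = FALSE]
    if (nrow(sel) == 0L) stop("patient ", p, " has no included channels")
    # deterministic tie-break: order by channel id, which.max takes the first
    ord_rec <- sel$recording_id %||% rep("", nrow(sel))
    sel <- sel[order(ord_rec, sel$channel_id), , drop = FALSE]
    for (ty in EVENT_TYPES) {
      r <- sel[[RATE_COLS[[ty]]]]
      if (is.null(r) || max(r) <= 0) next
      i <- which.max(r)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = p, event_type = ty, max_rate = r[i],
        distance_mm = sel$d_edge_mm[i], channel_id = sel$channel_id[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(patient_id = character(), event_type = character(),
                      max_rate = numeric(), distance_mm = numeric(),
                      channel_id = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
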