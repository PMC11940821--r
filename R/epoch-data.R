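#' Construct an epoch-count series for one child, device and position
#'
#' An `epoch_series` holds one channel's activity counts: the per-epoch count
#' vector recorded by one device (MW8 or GT3X) at one wear position (wrist or
#' hip) on one child, together with the epoch length and the series start
#' time. Timestamps are stored internally as seconds since the series start;
#' epoch `i` spans the half-open interval
#' `[offset[i], offset[i] + epoch_seconds)`.
#'
#' @param child_id Identifier of the child (coerced to character).
#' @param device `"MW8"` or `"GT3X"`.
#' @param position `"wrist"` or `"hip"`.
#' @param counts Numeric vector of non-negative activity counts, one per
#'   epoch. Counts are not required to be integers: the GT3X vector-magnitude
#'   output need not be whole-valued.
#' @param epoch_seconds Epoch length in seconds (default 30).
#' @param start_time `POSIXct` start of the first epoch (default the Unix
#'   epoch, which is adequate when only relative timing matters).
#' @param offsets Optional numeric vector of epoch start offsets in seconds
#'   from `start_time`; defaults to contiguous epochs
#'   `0, epoch_seconds, 2 * epoch_seconds, ...`.
#' @param allow_negative Permit negative counts (default `FALSE`). Device
#'   counts are never negative; this exists solely so series built from the
#'   synthetic `normal` family, whose tails can cross zero, can be carried.
#'
#' @return An object of class `epoch_series`.
#' @examples
#' epoch_series("c01", "MW8", "wrist", counts = c(120, 95, 410))
#' @export
epoch_series <- function(child_id, device, position, counts,
                         epoch_seconds = 30,
                         start_time = as.POSIXct("1970-01-01", tz = "UTC"),
                         offsets = NULL, allow_negative = FALSE) {
  assert_device(device)
  assert_position(position)
  counts <- as.numeric(counts)
  if (any(is.na(counts))) abort("`counts` must not contain missing values")
  if (!allow_negative && any(counts < 0)) {
    abort(paste0(
      "negative count at epoch ", which(counts < 0)[1],
      ": counts must be non-negative"
    ))
  }
  if (!is.numeric(epoch_seconds) || length(epoch_seconds) != 1 ||
      epoch_seconds <= 0) {
    abort("`epoch_seconds` must be a single positive number")
  }
  if (is.null(offsets)) {
    offsets <- (seq_along(counts) - 1) * epoch_seconds
  }
  offsets <- as.numeric(offsets)
  if (length(offsets) != length(counts)) {
    abort("`offsets` must have one entry per epoch")
  }
  if (is.unsorted(offsets, strictly = TRUE) && length(offsets) > 1) {
    ord <- order(offsets)
    offsets <- offsets[ord]
    counts <- counts[ord]
  }
  structure(
    list(
      child_id = as.character(child_id),
      device = device,
      position = position,
      epoch_seconds = epoch_seconds,
      start_time = start_time,
      offsets = offsets,
      counts = counts
    ),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> child %s, %s @ %s: %d epochs of %gs starting %s\n",
    x$child_id, x$device, x$position, length(x$counts), x$epoch_seconds,
    format(x$start_time, "%Y-%m-%dT%H:%M:%S")
  ))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' Read and write epoch-count CSV files
#'
#' The epoch CSV format mirrors the delimited exports of the vendor software
#' (MotionWare, ActiLife): one row per epoch with columns
#' `child_id,device,position,timestamp,count`, timestamps in ISO-8601. On
#' reading, rows are grouped into one [epoch_series] per
#' (child, device, position) triple and ordered by time within each series.
#'
#' @param path Path to a CSV file.
#' @param epoch_seconds Epoch length in seconds assumed for the file
#'   (default 30).
#' @return `read_epoch_csv()` returns a list of [epoch_series];
#'   `write_epoch_csv()` returns `path` invisibly. Writing then reading
#'   reproduces the series content field for field.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_epoch_csv(list(epoch_series("c01", "MW8", "wrist", c(10, 20))), tmp)
#' read_epoch_csv(tmp)
#' @export
read_epoch_csv <- function(path, epoch_seconds = 30) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- suppressWarnings(readr::read_csv( # columns are validated just below
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      device = readr::col_character(),
      position = readr::col_character(),
      timestamp = readr::col_datetime(),
      count = readr::col_double()
    )
  ))
  required <- c("child_id", "device", "position", "timestamp", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "epoch CSV is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (any(df$count < 0, na.rm = TRUE)) {
    abort(paste0(
      "negative count at row ", which(df$count < 0)[1], " of ", path
    ))
  }
  if (nrow(df) == 0) return(list())
  df <- dplyr::arrange(df, .data$child_id, .data$device, .data$position,
                       .data$timestamp)
  keys <- dplyr::distinct(df, .data$child_id, .data$device, .data$position)
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- dplyr::filter(
      df,
      .data$child_id == keys$child_id[i],
      .data$device == keys$device[i],
      .data$position == keys$position[i]
    )
    start <- sub$timestamp[1]
    epoch_series(
      child_id = keys$child_id[i],
      device = keys$device[i],
      position = keys$position[i],
      counts = sub$count,
      epoch_seconds = epoch_seconds,
      start_time = start,
      offsets = as.numeric(difftime(sub$timestamp, start, units = "secs"))
    )
  })
}

#' @rdname read_epoch_csv
#' @param series A list of [epoch_series] objects (a single series is
#'   accepted and wrapped).
#' @export
write_epoch_csv <- function(series, path) {
  if (inherits(series, "epoch_series")) series <- list(series)
  stopifnot(all(vapply(series, inherits, logical(1), "epoch_series")))
  rows <- lapply(series, function(s) {
    tibble::tibble(
      child_id = s$child_id,
      device = s$device,
      position = s$position,
      timestamp = format(s$start_time + s$offsets,
                         "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      count = s$counts
    )
  })
  df <- dplyr::bind_rows(rows)
  if (nrow(df) == 0) {
    df <- tibble::tibble(
      child_id = character(), device = character(), position = character(),
      timestamp = character(), count = numeric()
    )
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Build and read direct-observation behaviour protocols
#'
#' A behaviour protocol records, for each child, which of the six directed
#' behaviours was performed between which observed start and stop times
#' (documented by an observer with a stopwatch). Intervals are half-open
#' `[start, stop)` and must not overlap within a child.
#'
#' @param child_id,behaviour,start,stop Vectors of equal length: child
#'   identifier, canonical behaviour name (see [behaviour_levels()]), and
#'   `POSIXct` (or ISO-8601 string) start/stop times.
#' @return A tibble of class `behaviour_protocol` with columns `child_id`,
#'   `behaviour` (factor in rank order), `start`, `stop`.
#' @examples
#' behaviour_protocol(
#'   child_id = "c01", behaviour = "sprinting",
#'   start = "1970-01-01 00:00:00", stop = "1970-01-01 00:10:00"
#' )
#' @export
behaviour_protocol <- function(child_id, behaviour, start, stop) {
  to_time <- function(x) {
    if (inherits(x, "POSIXct")) return(x)
    as.POSIXct(x, tz = "UTC")
  }
  out <- tibble::tibble(
    child_id = as.character(child_id),
    behaviour = behaviour_factor(behaviour),
    start = to_time(start),
    stop = to_time(stop)
  )
  if (any(is.na(out$start)) || any(is.na(out$stop))) {
    abort("protocol start/stop times failed to parse")
  }
  bad <- which(out$stop <= out$start)
  if (length(bad) > 0) {
    abort(paste0("protocol record ", bad[1], ": stop must be after start"))
  }
  for (cid in unique(out$child_id)) {
    sub <- out[out$child_id == cid, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1 &&
        any(as.numeric(sub$start[-1]) < as.numeric(sub$stop[-nrow(sub)]))) {
      abort(paste0("overlapping protocol intervals for child ", cid))
    }
  }
  class(out) <- c("behaviour_protocol", class(out))
  out
}

#' @rdname behaviour_protocol
#' @param path Path to a protocol CSV with header
#'   `child_id,behaviour,start,stop`.
#' @export
read_protocol_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      child_id = readr::col_character(),
      behaviour = readr::col_character(),
      start = readr::col_datetime(),
      stop = readr::col_datetime()
    )
  ))
  missing_cols <- setdiff(c("child_id", "behaviour", "start", "stop"),
                          names(df))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "protocol CSV is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  behaviour_protocol(df$child_id, df$behaviour, df$start, df$stop)
}

#' @rdname behaviour_protocol
#' @param protocol A `behaviour_protocol`.
#' @export
write_protocol_csv <- function(protocol, path) {
  df <- tibble::tibble(
    child_id = protocol$child_id,
    behaviour = as.character(protocol$behaviour),
    start = format(protocol$start, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    stop = format(protocol$stop, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  readr::write_csv(df, path)
  invisible(path)
}

# Canonical empty labelled-counts tibble; the shared currency of the package.
# `epoch` is the time-order index within a (child, channel, behaviour) bout;
# it is what channel pairing aligns on, making pairing row-order invariant.
empty_labeled_counts <- function() {
  tibble::tibble(
    child_id = character(),
    device = character(),
    position = character(),
    behaviour = behaviour_factor(character()),
    epoch = integer(),
    count = numeric()
  )
}

#' Extract behaviour-labelled epoch counts from series and protocol
#'
#' Matches observed behaviour intervals to a channel's epoch grid. An epoch is
#' labelled with a behaviour if and only if its full `[start, end)` span lies
#' inside the behaviour's observed `[start, stop)` interval; partial epochs at
#' the interval boundaries are excluded (conservative with respect to observer
#' timing error), and epochs covered by no interval are dropped.
#'
#' When `series` is a list, segments are extracted per series and concatenated,
#' reproducing the pooling of same-behaviour periods across children that the
#' calibration operates on.
#'
#' @param series An [epoch_series] or a list of them.
#' @param protocol A [behaviour_protocol].
#' @return A tibble of labelled counts with columns `child_id`, `device`,
#'   `position`, `behaviour`, `count`, one row per labelled epoch.
#' @examples
#' s <- epoch_series("c01", "MW8", "wrist", counts = rep(100, 30))
#' p <- behaviour_protocol("c01", "play_on_floor",
#'                         "1970-01-01 00:00:00", "1970-01-01 00:10:00")
#' nrow(extract_segments(s, p)) # 20 fully contained 30-s epochs
#' @export
extract_segments <- function(series, protocol) {
  if (is.list(series) && !inherits(series, "epoch_series")) {
    out <- lapply(series, extract_segments, protocol = protocol)
    return(dplyr::bind_rows(empty_labeled_counts(), out))
  }
  stopifnot(inherits(series, "epoch_series"))
  recs <- protocol[protocol$child_id == series$child_id, , drop = FALSE]
  if (nrow(recs) == 0 || length(series$counts) == 0) {
    return(empty_labeled_counts())
  }
  recs <- recs[order(recs$start), , drop = FALSE]
  ep <- series$epoch_seconds
  epoch_start <- as.numeric(series$start_time) + series$offsets
  epoch_end <- epoch_start + ep
  series_lo <- min(epoch_start)
  series_hi <- max(epoch_end)
  pieces <- lapply(seq_len(nrow(recs)), function(i) {
    lo <- as.numeric(recs$start[i])
    hi <- as.numeric(recs$stop[i])
    inside <- epoch_start >= lo & epoch_end <= hi
    if (!any(inside) && (hi <= series_lo || lo >= series_hi)) {
      warn(sprintf(
        "protocol interval %s [%s, %s) lies outside the %s/%s series for child %s; no epochs labelled",
        as.character(recs$behaviour[i]),
        format(recs$start[i], "%H:%M:%S"), format(recs$stop[i], "%H:%M:%S"),
        series$device, series$position, series$child_id
      ))
    }
    tibble::tibble(
      child_id = series$child_id,
      device = series$device,
      position = series$position,
      behaviour = behaviour_factor(
        rep(as.character(recs$behaviour[i]), sum(inside))
      ),
      count = series$counts[inside]
    )
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) return(empty_labeled_counts())
  # epoch index in time order within each behaviour bout (records were
  # processed in start order, epochs in time order within each record)
  out <- out |>
    dplyr::group_by(.data$behaviour) |>
    dplyr::mutate(epoch = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("child_id", "device", "position", "behaviour", "epoch",
                  "count")
  dplyr::bind_rows(empty_labeled_counts(), out)
}

#' Check labelled bout durations against the protocol's 8-10 minute rule
#'
#' The observation protocol targets 8 to 10 minutes of each behaviour per
#' child (activities shorter than 8 minutes were repeated). This summarises
#' the labelled duration per child, channel and behaviour and flags cells
#' outside the limits.
#'
#' @param labeled A labelled-counts tibble from [extract_segments()] or
#'   [generate_cohort()].
#' @param epoch_seconds Epoch length in seconds (default 30).
#' @param min_minutes,max_minutes Duration limits in minutes (defaults 8, 10).
#' @return A tibble with one row per (child, device, position, behaviour):
#'   `n_epochs`, `minutes`, `within_limits`.
#' @export
validate_durations <- function(labeled, epoch_seconds = 30,
                               min_minutes = 8, max_minutes = 10) {
  if (nrow(labeled) == 0) abort("`labeled` must be non-empty")
  labeled |>
    dplyr::group_by(.data$child_id, .data$device, .data$position,
                    .data$behaviour) |>
    dplyr::summarise(n_epochs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      minutes = .data$n_epochs * epoch_seconds / 60,
      within_limits = .data$minutes >= min_minutes &
        .data$minutes <= max_minutes
    )
}
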