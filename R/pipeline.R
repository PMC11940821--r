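#' Lay a labelled cohort out as epoch series plus observation protocol
#'
#' Turns a labelled-counts table (for example a [generate_cohort()] draw)
#' into per-channel [epoch_series] with a matching [behaviour_protocol]:
#' each child performs the behaviours in intensity rank order, with a rest
#' gap between bouts (rest epochs carry no counts — only labelled bouts
#' exist in the data). Extracting segments from the emitted series with the
#' emitted protocol reproduces the labelled counts exactly.
#'
#' @param labeled A labelled-counts tibble.
#' @param epoch_seconds Epoch length in seconds (default 30).
#' @param rest_seconds Gap between consecutive bouts (default 180, the
#'   protocol's minimum 3-minute rest).
#' @param day_start Timestamp of each child's first bout.
#' @return A list with `series` (list of [epoch_series]) and `protocol`.
#' @export
cohort_to_series <- function(labeled, epoch_seconds = 30, rest_seconds = 180,
                             day_start = as.POSIXct("1970-01-01 09:00:00",
                                                    tz = "UTC")) {
  if (nrow(labeled) == 0) {
    return(list(series = list(),
                protocol = behaviour_protocol(character(), character(),
                                              as.POSIXct(character()),
                                              as.POSIXct(character()))))
  }
  series <- list()
  prot <- list()
  for (cid in unique(labeled$child_id)) {
    child <- labeled[labeled$child_id == cid, ]
    # one shared timeline per child: bout lengths must agree across channels
    lens <- child |>
      dplyr::count(.data$device, .data$position, .data$behaviour) |>
      dplyr::group_by(.data$behaviour) |>
      dplyr::summarise(n_ep = unique(.data$n), .groups = "drop")
    offset <- 0
    bout_at <- numeric(0)
    for (b in levels(lens$behaviour)) {
      row <- lens[as.character(lens$behaviour) == b, ]
      if (nrow(row) == 0) next
      bout_at[[b]] <- offset
      prot[[length(prot) + 1]] <- tibble::tibble(
        child_id = cid, behaviour = b,
        start = day_start + offset,
        stop = day_start + offset + row$n_ep * epoch_seconds
      )
      offset <- offset + row$n_ep * epoch_seconds + rest_seconds
    }
    chans <- dplyr::distinct(child, .data$device, .data$position)
    for (i in seq_len(nrow(chans))) {
      chan <- child[child$device == chans$device[i] &
                      child$position == chans$position[i], ]
      offs <- numeric(0)
      cnts <- numeric(0)
      for (b in names(bout_at)) {
        bc <- chan$count[as.character(chan$behaviour) == b]
        offs <- c(offs, bout_at[[b]] + (seq_along(bc) - 1) * epoch_seconds)
        cnts <- c(cnts, bc)
      }
      series[[length(series) + 1]] <- epoch_series(
        child_id = cid, device = chans$device[i],
        position = chans$position[i], counts = cnts,
        epoch_seconds = epoch_seconds, start_time = day_start,
        offsets = offs, allow_negative = TRUE
      )
    }
  }
  prot <- dplyr::bind_rows(prot)
  list(
    series = series,
    protocol = behaviour_protocol(prot$child_id, prot$behaviour,
                                  prot$start, prot$stop)
  )
}

cutoff_table_to_list <- function(tab) {
  out <- list(
    device = tab$device,
    position = tab$position,
    cuts = as.list(tab$cuts),
    sed_range = as.list(tab$sed_range),
    ci_method = tab$ci_method
  )
  if (!is.null(tab$results)) {
    out$results <- lapply(tab$results, function(r) {
      list(
        scheme = r$scheme, cutoff = r$cutoff, direction = r$direction,
        sensitivity = r$sensitivity, specificity = r$specificity,
        youden_j = r$youden_j, auc = r$auc,
        auc_ci = as.list(r$auc_ci), ci_method = r$ci_method,
        n_pos = r$n_pos, n_neg = r$n_neg,
        accuracy_band = r$accuracy_band
      )
    })
  }
  out
}

#' Read a cut-off table back from its JSON representation
#'
#' @param path Path to a JSON file written by [run_pipeline()] or
#'   [render_report()] with `format = "json"`.
#' @return A list of `cutoff_table` objects.
#' @export
read_cutoffs_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  tabs <- if (!is.null(raw$channels)) raw$channels else raw
  lapply(tabs, function(x) {
    tab <- manual_cutoff_table(
      x$device, x$position,
      vpa = x$cuts$vpa, mvpa = x$cuts$mvpa,
      lmvpa = x$cuts$lmvpa, moa = x$cuts$moa
    )
    tab$ci_method <- x$ci_method
    if (!is.null(x$results)) {
      tab$results <- lapply(x$results, function(r) {
        r$auc_ci <- unlist(r$auc_ci)
        r
      })
    }
    tab
  })
}

#' Render calibration reports in the published table layout
#'
#' One row per intensity class per channel, in the layout of the calibration
#' tables: cut-off with its direction, sensitivity and specificity as whole
#' percentages, AUC and its confidence interval to 2 decimals, and the
#' accuracy band. The SED row carries the count range and NA for
#' sensitivity, specificity and AUC — the sedentary band is derived from the
#' neighbouring cut-offs, not from a ROC problem of its own. Rounding is
#' presentation-only; internal values keep full precision.
#'
#' @param cutoffs A `cutoff_table` or list of them (with per-scheme results,
#'   i.e. from [calibrate_channel()]).
#' @param format `"md"`, `"csv"` or `"json"`.
#' @return A single character string holding the document.
#' @export
render_report <- function(cutoffs, format = c("md", "csv", "json")) {
  format <- match.arg(format)
  if (inherits(cutoffs, "cutoff_table")) cutoffs <- list(cutoffs)
  if (length(cutoffs) == 0) abort("`cutoffs` must be non-empty")
  if (format == "json") {
    return(jsonlite::toJSON(
      list(channels = lapply(cutoffs, cutoff_table_to_list)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    ))
  }
  rows <- dplyr::bind_rows(lapply(cutoffs, report_rows))
  if (format == "csv") {
    return(readr::format_csv(rows))
  }
  # markdown
  hdr <- paste(
    "| device | position | class | cut-off (counts) | sensitivity (%) |",
    "specificity (%) | AUC | 95% CI | band |"
  )
  sep <- paste0("|", paste(rep("---|", 9), collapse = ""))
  fmt_na <- function(x) ifelse(is.na(x), "NA", x)
  body <- apply(rows, 1, function(r) {
    paste0("| ", paste(fmt_na(r), collapse = " | "), " |")
  })
  paste(c(hdr, sep, body), collapse = "\n")
}

report_rows <- function(tab) {
  if (is.null(tab$results)) {
    abort("report rendering needs per-scheme results; run calibrate_channel()")
  }
  fmt_row <- function(r) {
    tibble::tibble(
      device = tab$device,
      position = tab$position,
      class = r$scheme,
      cutoff = paste0(r$direction, format(r$cutoff, trim = TRUE)),
      sensitivity_pct = as.character(round(100 * r$sensitivity)),
      specificity_pct = as.character(round(100 * r$specificity)),
      auc = sprintf("%.2f", r$auc),
      ci = sprintf("%.2f to %.2f", r$auc_ci[["low"]], r$auc_ci[["high"]]),
      band = r$accuracy_band
    )
  }
  sed <- tibble::tibble(
    device = tab$device, position = tab$position, class = "SED",
    cutoff = sprintf("%s-%s", format(tab$sed_range[["low"]], trim = TRUE),
                     format(tab$sed_range[["high"]], trim = TRUE)),
    sensitivity_pct = NA_character_, specificity_pct = NA_character_,
    auc = NA_character_, ci = NA_character_, band = NA_character_
  )
  dplyr::bind_rows(
    fmt_row(tab$results$VPA),
    fmt_row(tab$results$MVPA),
    fmt_row(tab$results$LMVPA),
    sed,
    fmt_row(tab$results$MOA)
  )
}

#' Run the full calibration pipeline end to end
#'
#' Simulate (or load), calibrate, classify, compare: generates a synthetic
#' cohort from `config` (or extracts labelled counts from an epoch CSV plus
#' protocol CSV), calibrates every complete channel, summarises time in class
#' for the pooled epochs of each channel under its own cut-offs, and compares
#' devices at every position carrying both. All artifacts embed the seed, and
#' repeated runs with the same configuration are byte-identical.
#'
#' @param out_dir Directory for artifacts (`cutoffs.json`, `report.md`,
#'   `compare.json`); created if needed.
#' @param config A [cohort_config()] used when no input files are given; its
#'   seed drives all randomness.
#' @param counts_csv,protocol_csv Optional paths to an epoch CSV and protocol
#'   CSV; when both are given they replace the synthetic cohort.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @return Invisibly, a list with `labeled`, `cutoffs` (per channel),
#'   `time_in_class`, `comparisons`, and the artifact `paths`.
#' @export
run_pipeline <- function(out_dir, config = cohort_config(),
                         counts_csv = NULL, protocol_csv = NULL,
                         ci_method = c("delong", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (!is.null(counts_csv) || !is.null(protocol_csv)) {
    if (is.null(counts_csv) || is.null(protocol_csv)) {
      abort("provide both `counts_csv` and `protocol_csv`, or neither")
    }
    for (p in c(counts_csv, protocol_csv)) {
      if (!file.exists(p)) abort(paste0("input file not found: ", p))
    }
    labeled <- extract_segments(read_epoch_csv(counts_csv),
                                read_protocol_csv(protocol_csv))
  } else {
    labeled <- generate_cohort(config)
  }
  if (nrow(labeled) == 0) abort("no labelled epochs to calibrate on")

  chans <- dplyr::distinct(labeled, .data$device, .data$position)
  complete <- vapply(seq_len(nrow(chans)), function(i) {
    have <- labeled$behaviour[labeled$device == chans$device[i] &
                                labeled$position == chans$position[i]]
    length(setdiff(behaviour_levels(), as.character(have))) == 0
  }, logical(1))
  chans <- chans[complete, , drop = FALSE]
  if (nrow(chans) == 0) abort("no channel has all six behaviours")

  cutoffs <- lapply(seq_len(nrow(chans)), function(i) {
    calibrate_channel(labeled, chans$device[i], chans$position[i],
                      ci_method = ci_method, seed = config$seed)
  })
  names(cutoffs) <- paste(chans$device, chans$position, sep = "_")

  # classification needs a monotone table; channels whose calibrated cut-offs
  # cross (possible when stationary behaviours overlap heavily) are skipped
  tic <- lapply(names(cutoffs), function(nm) {
    tab <- cutoffs[[nm]]
    if (length(validate_cutoff_table(tab)) > 0) return(NULL)
    chan <- labeled[labeled$device == tab$device &
                      labeled$position == tab$position, ]
    s <- epoch_series("pooled", tab$device, tab$position, chan$count,
                      epoch_seconds = config$epoch_seconds,
                      allow_negative = TRUE)
    dplyr::mutate(time_in_class(classify_epochs(s, tab)), channel = nm)
  })
  tic <- dplyr::bind_rows(tic)

  comparisons <- list()
  for (pos in position_levels()) {
    sub <- labeled[labeled$position == pos, ]
    if (all(device_levels() %in% unique(sub$device))) {
      comparisons[[pos]] <- compare_devices(labeled, pos)
    }
  }

  paths <- list(
    cutoffs = file.path(out_dir, "cutoffs.json"),
    report = file.path(out_dir, "report.md"),
    compare = file.path(out_dir, "compare.json")
  )
  payload <- list(
    seed = config$seed,
    family = config$family,
    n_children = config$n_children,
    ci_method = ci_method,
    channels = lapply(cutoffs, cutoff_table_to_list)
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             paths$cutoffs)
  writeLines(render_report(cutoffs, "md"), paths$report)
  cmp_payload <- list(
    seed = config$seed,
    positions = lapply(comparisons, function(cc) {
      list(position = cc$position, n_pairs = cc$n_pairs,
           n_dropped = cc$n_dropped, rho = cc$rho,
           fit = list(kind = cc$fit$kind, degree = cc$fit$degree,
                      coefficients = cc$fit$coefficients,
                      r_squared = cc$fit$r_squared))
    })
  )
  writeLines(jsonlite::toJSON(cmp_payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             paths$compare)
  invisible(list(
    labeled = labeled,
    cutoffs = cutoffs,
    time_in_class = tic,
    comparisons = comparisons,
    paths = paths
  ))
}
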