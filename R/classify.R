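#' Validate the monotone ordering of a cut-off table
#'
#' Epoch classification partitions the count axis only when the four cut-offs
#' are strictly decreasing from vigorous down to motionless and the MOA
#' cut-off is non-negative: `vpa > mvpa > lmvpa > moa >= 0`.
#'
#' @param cutoffs A `cutoff_table` from [calibrate_channel()], or any list
#'   with a named `cuts` vector (`vpa`, `mvpa`, `lmvpa`, `moa`).
#' @return Character vector of violations; empty when the table is valid.
#' @examples
#' tab <- manual_cutoff_table("MW8", "wrist",
#'                            vpa = 787, mvpa = 408, lmvpa = 215, moa = 118)
#' validate_cutoff_table(tab)
#' @export
validate_cutoff_table <- function(cutoffs) {
  cuts <- cutoffs$cuts
  stopifnot(all(c("vpa", "mvpa", "lmvpa", "moa") %in% names(cuts)))
  violations <- character()
  pairs <- list(c("vpa", "mvpa"), c("mvpa", "lmvpa"), c("lmvpa", "moa"))
  for (p in pairs) {
    if (!(cuts[[p[1]]] > cuts[[p[2]]])) {
      violations <- c(violations, paste0(
        p[1], " cut-off (", cuts[[p[1]]], ") must exceed ", p[2],
        " cut-off (", cuts[[p[2]]], ")"
      ))
    }
  }
  if (cuts[["moa"]] < 0) {
    violations <- c(violations, "moa cut-off must be non-negative")
  }
  violations
}

#' Build a cut-off table from four known thresholds
#'
#' Convenience constructor for applying previously calibrated (for example,
#' published) cut-offs to new recordings without rerunning the ROC analysis.
#'
#' @param device,position Channel the thresholds were calibrated for.
#' @param vpa,mvpa,lmvpa,moa The four cut-offs, counts per epoch.
#' @return A `cutoff_table` (without per-scheme ROC results).
#' @export
manual_cutoff_table <- function(device, position, vpa, mvpa, lmvpa, moa) {
  assert_device(device)
  assert_position(position)
  structure(
    list(
      device = device,
      position = position,
      cuts = c(vpa = vpa, mvpa = mvpa, lmvpa = lmvpa, moa = moa),
      sed_range = c(low = moa, high = lmvpa),
      results = NULL,
      ci_method = NA_character_
    ),
    class = "cutoff_table"
  )
}

#' Classify epochs into intensity classes with a cut-off table
#'
#' Applies the calibrated thresholds to an unlabeled epoch series. The class
#' bands partition the count axis:
#'
#' * `VPA` — count strictly above the VPA cut-off;
#' * `MPA_band` — above the MVPA cut-off, up to and including the VPA cut-off;
#' * `LPA_band` — above the LMVPA cut-off, up to and including the MVPA
#'   cut-off;
#' * `SED` — from the MOA cut-off (inclusive) up to the LMVPA cut-off
#'   (inclusive);
#' * `MOA` — count strictly below the MOA cut-off.
#'
#' The middle bands are named `MPA_band`/`LPA_band` rather than with
#' behaviour names: without observed context these are threshold-delimited
#' count bands, not behaviours.
#'
#' @param series An [epoch_series] whose device and position match `cutoffs`.
#' @param cutoffs A monotone `cutoff_table`.
#' @return A list of class `classified_series` with the `series` and a
#'   `classes` factor of one class per epoch.
#' @examples
#' tab <- manual_cutoff_table("MW8", "wrist", 787, 408, 215, 118)
#' s <- epoch_series("c01", "MW8", "wrist", c(800, 118, 117, 300))
#' classify_epochs(s, tab)$classes
#' @export
classify_epochs <- function(series, cutoffs) {
  stopifnot(inherits(series, "epoch_series"))
  if (series$device != cutoffs$device || series$position != cutoffs$position) {
    abort(sprintf(
      "series channel (%s/%s) does not match cut-off table (%s/%s)",
      series$device, series$position, cutoffs$device, cutoffs$position
    ))
  }
  violations <- validate_cutoff_table(cutoffs)
  if (length(violations) > 0) {
    abort(paste0("cut-off table is not monotone: ", violations[1]))
  }
  cuts <- cutoffs$cuts
  x <- series$counts
  classes <- dplyr::case_when(
    x > cuts[["vpa"]] ~ "VPA",
    x > cuts[["mvpa"]] ~ "MPA_band",
    x > cuts[["lmvpa"]] ~ "LPA_band",
    x >= cuts[["moa"]] ~ "SED",
    TRUE ~ "MOA"
  )
  structure(
    list(
      series = series,
      classes = factor(classes,
                       levels = c("VPA", "MPA_band", "LPA_band", "SED", "MOA"))
    ),
    class = "classified_series"
  )
}

#' Summarise time spent in each intensity class
#'
#' @param classified A `classified_series` from [classify_epochs()].
#' @return A tibble with one row per intensity class: `n_epochs`, `minutes`
#'   and `proportion`. For an empty series all minutes are 0, proportions are
#'   reported as 0 and the `empty` flag is set.
#' @export
time_in_class <- function(classified) {
  stopifnot(inherits(classified, "classified_series"))
  ep <- classified$series$epoch_seconds
  tab <- table(classified$classes)
  n <- sum(tab)
  tibble::tibble(
    class = names(tab),
    n_epochs = as.integer(tab),
    minutes = as.integer(tab) * ep / 60,
    proportion = if (n == 0) 0 else as.integer(tab) / n,
    empty = n == 0
  )
}
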