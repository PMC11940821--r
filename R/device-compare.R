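#' Pair MW8 and GT3X epochs recorded at the same position
#'
#' Aligns the two devices' labelled epochs at one wear position by
#' (child, behaviour, epoch index within the bout). Epochs present on one
#' device but not the other (for example a channel one epoch short) are
#' dropped; the number of drops is attached as the `"n_dropped"` attribute.
#'
#' @param labeled A labelled-counts tibble containing both devices at
#'   `position`.
#' @param position `"wrist"` or `"hip"`.
#' @return A tibble with columns `child_id`, `position`, `behaviour`,
#'   `epoch`, `count_mw8`, `count_gt3x`, one row per paired epoch.
#' @export
pair_channels <- function(labeled, position) {
  assert_position(position)
  sub <- labeled[labeled$position == position, ]
  for (dev in device_levels()) {
    if (!any(sub$device == dev)) {
      abort(paste0("device ", dev, " has no epochs at position ", position))
    }
  }
  # the epoch column (time order within bout) is the alignment key; data
  # without one fall back to row order within each cell
  if ("epoch" %in% names(sub)) {
    indexed <- sub
  } else {
    indexed <- sub |>
      dplyr::group_by(.data$child_id, .data$device, .data$behaviour) |>
      dplyr::mutate(epoch = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  wide <- indexed |>
    dplyr::select("child_id", "position", "behaviour", "epoch",
                  "device", "count") |>
    tidyr::pivot_wider(names_from = "device", values_from = "count")
  paired <- wide |>
    dplyr::filter(!is.na(.data$MW8), !is.na(.data$GT3X)) |>
    dplyr::rename(count_mw8 = "MW8", count_gt3x = "GT3X") |>
    dplyr::arrange(.data$child_id, .data$behaviour, .data$epoch)
  attr(paired, "n_dropped") <- nrow(wide) - nrow(paired)
  paired
}

#' Spearman rank correlation between paired device counts
#'
#' Standard rank correlation with average ranks for ties, computed on epochs
#' pooled across all behaviours (the monotonic-agreement summary used when
#' the two devices' count scales differ systematically).
#'
#' @param paired A tibble from [pair_channels()], or any data frame with
#'   `count_mw8` and `count_gt3x` columns.
#' @return A single number in `[-1, 1]`; `NA` with a warning when either
#'   margin is constant (the correlation is then undefined).
#' @export
spearman_rho <- function(paired) {
  x <- paired$count_mw8
  y <- paired$count_gt3x
  if (length(x) < 3) abort("need at least 3 pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("a margin is constant; Spearman correlation is undefined")
    return(NA_real_)
  }
  unname(cor(x, y, method = "spearman"))
}

#' Least-squares relationship between the paired devices
#'
#' Fits `count_gt3x` on `count_mw8` by ordinary least squares: linear for the
#' wrist pairing, polynomial (default degree 2) for the hip pairing, where
#' the relationship bends.
#'
#' @param paired A tibble from [pair_channels()].
#' @param kind `"linear"` or `"polynomial"`.
#' @param degree Polynomial degree; forced to 1 for `kind = "linear"`,
#'   must be >= 2 for `kind = "polynomial"`.
#' @return A list of class `fit_result`: `kind`, `degree`, `coefficients`
#'   (intercept first, then increasing powers), `r_squared`, `n`.
#' @export
fit_relationship <- function(paired, kind = c("linear", "polynomial"),
                             degree = if (match.arg(kind) == "linear") 1 else 2) {
  kind <- match.arg(kind)
  if (kind == "linear") degree <- 1
  if (kind == "polynomial" && degree < 2) {
    abort("polynomial fits need degree >= 2")
  }
  x <- paired$count_mw8
  y <- paired$count_gt3x
  if (length(x) <= degree + 1) {
    abort("need more points than coefficients")
  }
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  if (any(is.na(coef(fit)))) abort("rank-deficient design")
  # exact relationships are legitimate inputs; summary.lm warns on them
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(
      kind = kind,
      degree = degree,
      coefficients = unname(coef(fit)),
      r_squared = r2,
      n = length(x)
    ),
    class = "fit_result"
  )
}

#' Log-transform counts for plotting
#'
#' `log10(count + 1)`: the offset of 1 keeps zero epochs (not uncommon for
#' stationary behaviours) finite and makes the lower end of the count scale
#' visible on a log axis.
#'
#' @param counts Non-negative numeric vector.
#' @return `log10(counts + 1)`.
#' @examples
#' log1_counts(c(0, 9, 999))
#' @export
log1_counts <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  log10(counts + 1)
}

#' Boxplot statistics of counts per channel and behaviour
#'
#' Median, quartiles and whiskers at `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR`
#' (clamped to the observed range), per (device, position, behaviour) cell —
#' the numbers behind the per-behaviour distribution boxplots.
#'
#' @param labeled A labelled-counts tibble.
#' @return A tibble with columns `device`, `position`, `behaviour`, `q1`,
#'   `median`, `q3`, `whisker_low`, `whisker_high`, `n_epochs`.
#' @export
boxplot_stats <- function(labeled) {
  if (nrow(labeled) == 0) abort("`labeled` must be non-empty")
  labeled |>
    dplyr::group_by(.data$device, .data$position, .data$behaviour) |>
    dplyr::summarise(
      q1 = quantile(.data$count, 0.25, names = FALSE),
      median = median(.data$count),
      q3 = quantile(.data$count, 0.75, names = FALSE),
      whisker_low = max(min(.data$count),
                        quantile(.data$count, 0.25, names = FALSE) -
                          1.5 * stats::IQR(.data$count)),
      whisker_high = min(max(.data$count),
                         quantile(.data$count, 0.75, names = FALSE) +
                           1.5 * stats::IQR(.data$count)),
      n_epochs = dplyr::n(),
      .groups = "drop"
    )
}

#' Compare the two devices at one wear position
#'
#' Bundles the between-device summaries for one position: paired epochs,
#' Spearman rank correlation, the least-squares relationship (linear at the
#' wrist, polynomial at the hip by default), and per-cell boxplot statistics.
#'
#' @param labeled A labelled-counts tibble with both devices at `position`.
#' @param position `"wrist"` or `"hip"`.
#' @param kind,degree Passed to [fit_relationship()]; defaults follow the
#'   position (`linear` at wrist, degree-2 `polynomial` at hip).
#' @return A list with `position`, `n_pairs`, `n_dropped`, `rho`, `fit`, and
#'   `boxplot_stats`.
#' @export
compare_devices <- function(labeled, position,
                            kind = if (position == "wrist") "linear"
                                   else "polynomial",
                            degree = if (kind == "linear") 1 else 2) {
  paired <- pair_channels(labeled, position)
  list(
    position = position,
    n_pairs = nrow(paired),
    n_dropped = attr(paired, "n_dropped"),
    rho = spearman_rho(paired),
    fit = fit_relationship(paired, kind = kind, degree = degree),
    boxplot_stats = boxplot_stats(labeled[labeled$position == position, ])
  )
}
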