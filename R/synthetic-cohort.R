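#' Published per-behaviour activity-count moments for the four channels
#'
#' Mean and standard deviation of activity counts per 30-second epoch for each
#' of the six directed behaviours, as reported for 3-year-old children wearing
#' MotionWatch 8 (MW8, uni-axial mode) and ActiGraph GT3X (vector magnitude)
#' simultaneously at the non-dominant wrist and the hip. These moments are the
#' default parameterisation of [generate_cohort()] and the input to the
#' closed-form surrogate [gaussian_mixture_auc()].
#'
#' Counts scale very differently across channels: the GT3X vector magnitude
#' runs roughly 6-10 times higher than the uni-axial MW8, and both devices
#' read lower at the hip than at the wrist for every behaviour.
#'
#' @return A tibble with columns `device`, `position`, `behaviour`, `mean`,
#'   `sd` (counts per 30 s), 24 rows (2 devices x 2 positions x 6 behaviours).
#' @examples
#' channel_moments()
#' @export
channel_moments <- function() {
  b <- behaviour_levels() # screen, recumbent, crafts, floor, walk, sprint
  cell <- function(device, position, means, sds) {
    tibble::tibble(
      device = device, position = position,
      behaviour = behaviour_factor(b), mean = means, sd = sds
    )
  }
  dplyr::bind_rows(
    cell("GT3X", "wrist",
         c(540.6, 998.0, 1329.0, 2359.8, 4677.3, 9017.8),
         c(724.8, 1198.2, 736.1, 818.6, 1875.3, 2745.2)),
    cell("MW8", "wrist",
         c(62.9, 110.7, 128.9, 291.1, 672.2, 1419.2),
         c(97.4, 142.1, 95.0, 143.9, 309.8, 457.5)),
    cell("GT3X", "hip",
         c(137.2, 253.5, 291.8, 1044.1, 1964.7, 2240.0),
         c(260.3, 479.1, 317.7, 550.4, 753.4, 586.6)),
    cell("MW8", "hip",
         c(10.2, 19.9, 16.0, 80.3, 533.6, 1172.3),
         c(30.9, 47.4, 29.3, 85.6, 250.5, 357.9))
  )
}

#' Configure a synthetic calibration cohort
#'
#' Bundles the study conditions the generator emulates: 30 children each
#' performing the six behaviours for 8-10 minutes while wearing four channels
#' (MW8 and GT3X at wrist and hip), with per-epoch counts drawn from a chosen
#' distribution family matched to the per-channel behaviour moments, and
#' same-position device pairs coupled through a Gaussian copula.
#'
#' @param n_children Number of children (default 30).
#' @param duration_minutes Length-2 numeric range of bout durations in
#'   minutes; each (child, behaviour) bout length is drawn uniformly from it
#'   and floored to whole epochs (default `c(8, 10)`).
#' @param epoch_seconds Epoch length in seconds (default 30).
#' @param family Count-distribution family: `"normal"` (moments exact, may
#'   produce negative counts; rank-based analyses unaffected),
#'   `"truncated_normal"` (normal left-truncated at zero),
#'   `"lognormal"` or `"zero_inflated_gamma"` (both moment-matched;
#'   right-skewed, non-negative — closer to real count distributions).
#' @param params Tibble of per-channel behaviour moments in the format of
#'   [channel_moments()] (the default). Channels present in `params` are the
#'   channels generated; all six behaviours must be present per channel.
#' @param cross_device_rank_correlation Target Spearman correlation between
#'   same-position device pairs, in `[0, 1]` (default 0.9). Internally
#'   converted to the latent Gaussian correlation `2 sin(pi * rho / 6)` so
#'   the copula's population rank correlation equals the configured value.
#' @param zero_inflation Probability of a structural zero epoch: a single
#'   number or a named vector over behaviours (default 0). Applied for the
#'   `zero_inflated_gamma` family; the continuous component's mean is
#'   rescaled so the cell mean is preserved.
#' @param child_effect_sd Child-level random intercept, expressed as a
#'   fraction of the cell sd and shared across a child's epochs within a
#'   (channel, behaviour) cell (default 0: epochs exchangeable within cell).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_children = 30,
                          duration_minutes = c(8, 10),
                          epoch_seconds = 30,
                          family = c("normal", "truncated_normal",
                                     "lognormal", "zero_inflated_gamma"),
                          params = channel_moments(),
                          cross_device_rank_correlation = 0.9,
                          zero_inflation = 0,
                          child_effect_sd = 0,
                          seed = 1L) {
  family <- match.arg(family)
  if (!is.numeric(n_children) || length(n_children) != 1 || n_children < 0) {
    abort("`n_children` must be a single non-negative number")
  }
  if (length(duration_minutes) != 2 || any(duration_minutes <= 0) ||
      duration_minutes[1] > duration_minutes[2]) {
    abort("`duration_minutes` must be an increasing positive range")
  }
  if (cross_device_rank_correlation < 0 || cross_device_rank_correlation > 1) {
    abort("`cross_device_rank_correlation` must lie in [0, 1]")
  }
  params <- tibble::as_tibble(params)
  needed <- c("device", "position", "behaviour", "mean", "sd")
  if (!all(needed %in% names(params))) {
    abort("`params` must have columns device, position, behaviour, mean, sd")
  }
  params$behaviour <- behaviour_factor(params$behaviour)
  if (any(params$sd < 0) || any(params$mean < 0)) {
    abort("`params` means and sds must be non-negative")
  }
  chans <- dplyr::distinct(params, .data$device, .data$position)
  for (i in seq_len(nrow(chans))) {
    have <- params$behaviour[params$device == chans$device[i] &
                               params$position == chans$position[i]]
    missing_b <- setdiff(behaviour_levels(), as.character(have))
    if (length(missing_b) > 0) {
      abort(paste0(
        "channel ", chans$device[i], "/", chans$position[i],
        " is missing behaviour(s): ", paste(missing_b, collapse = ", ")
      ))
    }
  }
  zi <- zero_inflation
  if (length(zi) == 1 && is.null(names(zi))) {
    zi <- setNames(rep(as.numeric(zi), 6), behaviour_levels())
  }
  if (!all(names(zi) %in% behaviour_levels()) ||
      any(zi < 0) || any(zi >= 1)) {
    abort("`zero_inflation` must be probabilities in [0, 1) named by behaviour")
  }
  zi_full <- setNames(rep(0, 6), behaviour_levels())
  zi_full[names(zi)] <- zi
  if (family %in% c("lognormal", "zero_inflated_gamma") &&
      any(params$mean <= 0)) {
    abort(paste0("family '", family, "' requires strictly positive means"))
  }
  structure(
    list(
      n_children = as.integer(n_children),
      duration_minutes = as.numeric(duration_minutes),
      epoch_seconds = epoch_seconds,
      family = family,
      params = params,
      cross_device_rank_correlation = cross_device_rank_correlation,
      zero_inflation = zi_full,
      child_effect_sd = child_effect_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Quantile transform of copula uniforms for one cell.
# All families are parameterised by the cell (mean, sd); lognormal and gamma
# by moment matching. sd = 0 degenerates to the constant mean in every family.
cell_quantile <- function(u, mean, sd, family, p_zero = 0) {
  if (sd == 0 && p_zero == 0) return(rep(mean, length(u)))
  switch(family,
    normal = qnorm(u, mean, sd),
    truncated_normal = {
      p0 <- pnorm(0, mean, sd)
      qnorm(p0 + u * (1 - p0), mean, sd)
    },
    lognormal = {
      s2 <- log(1 + (sd / mean)^2)
      qlnorm(u, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    },
    zero_inflated_gamma = {
      m_c <- mean / (1 - p_zero) # continuous-part mean preserving cell mean
      if (sd == 0) {
        out <- rep(m_c, length(u))
      } else {
        shape <- (m_c / sd)^2
        rate <- m_c / sd^2
        out <- qgamma(pmax((u - p_zero) / (1 - p_zero), 0), shape, rate = rate)
      }
      out[u < p_zero] <- 0
      out
    },
    abort(paste0("unknown family: ", family))
  )
}

#' Generate a synthetic behaviour-labelled cohort
#'
#' Emits behaviour-labelled epoch counts for every channel in the
#' configuration. For each (child, behaviour), one bout length is drawn
#' uniformly from the duration range and shared by all channels, so epochs
#' align across devices and positions. Within each position, the MW8/GT3X
#' pair shares a latent per-epoch intensity through a Gaussian copula at the
#' configured rank correlation; counts are then obtained by the family's
#' quantile transform with the cell's mean and sd.
#'
#' Only labelled bouts are emitted: the rest breaks between activities carry
#' no behaviour label and are of no use to the calibration, so they are not
#' simulated.
#'
#' @param config A [cohort_config()].
#' @return A labelled-counts tibble (`child_id`, `device`, `position`,
#'   `behaviour`, `count`), identical for identical configurations and seeds.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_children = 2, seed = 42))
#' dplyr::count(cohort, device, position)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_children == 0) return(empty_labeled_counts())
  rho_latent <- 2 * sin(pi * config$cross_device_rank_correlation / 6)
  positions <- unique(config$params$position)
  withr::with_seed(config$seed, {
    pieces <- list()
    for (c_i in seq_len(config$n_children)) {
      cid <- sprintf("child%02d", c_i)
      for (b in behaviour_levels()) {
        mins <- runif(1, config$duration_minutes[1], config$duration_minutes[2])
        n_ep <- floor(mins * 60 / config$epoch_seconds)
        if (n_ep == 0) next
        for (pos in positions) {
          cell <- config$params[config$params$position == pos &
                                  config$params$behaviour == b, ]
          devs <- cell$device
          # latent epoch intensities: correlated standard normals per device
          z1 <- rnorm(n_ep)
          z <- list(z1)
          if (length(devs) > 1) {
            for (k in 2:length(devs)) {
              z[[k]] <- rho_latent * z1 +
                sqrt(1 - rho_latent^2) * rnorm(n_ep)
            }
          }
          for (k in seq_along(devs)) {
            row <- cell[k, ]
            mu <- row$mean
            if (config$child_effect_sd > 0) {
              mu <- max(mu + rnorm(1, 0, config$child_effect_sd * row$sd), 0)
            }
            counts <- cell_quantile(
              pnorm(z[[k]]), mu, row$sd, config$family,
              p_zero = config$zero_inflation[[b]]
            )
            pieces[[length(pieces) + 1]] <- tibble::tibble(
              child_id = cid, device = row$device, position = pos,
              behaviour = behaviour_factor(rep(b, n_ep)),
              epoch = seq_len(n_ep), count = counts
            )
          }
        }
      }
    }
    dplyr::bind_rows(empty_labeled_counts(), pieces)
  })
}

#' Accumulate raw high-frequency samples into per-epoch activity counts
#'
#' Implements the MW8 count rule: within each second, take the highest of the
#' `sampling_hz` samples; the per-second maxima are then accumulated
#' (summed) over the length of each epoch.
#'
#' @param samples Numeric vector of non-negative raw samples; its length must
#'   span a whole number of seconds, and the seconds a whole number of epochs.
#' @param sampling_hz Samples per second (default 50).
#' @param epoch_seconds Epoch length in seconds (default 30).
#' @return Numeric vector of one count per epoch.
#' @examples
#' counts_from_raw(rep(1, 50 * 30)) # one epoch, per-second max 1, count 30
#' @export
counts_from_raw <- function(samples, sampling_hz = 50, epoch_seconds = 30) {
  if (any(samples < 0)) abort("raw samples must be non-negative")
  n <- length(samples)
  if (n %% sampling_hz != 0) {
    abort("`samples` must span a whole number of seconds")
  }
  n_sec <- n / sampling_hz
  if (n_sec %% epoch_seconds != 0) {
    abort("`samples` must span a whole number of epochs")
  }
  sec_max <- apply(matrix(samples, nrow = sampling_hz), 2, max)
  as.numeric(colSums(matrix(sec_max, nrow = epoch_seconds)))
}

#' Summarise empirical per-cell count moments
#'
#' Computes, for each (device, position, behaviour) cell, the pooled mean and
#' sample sd of epoch counts and the mean per-child labelled duration — the
#' same summary layout the calibration's descriptive table uses.
#'
#' @param labeled A labelled-counts tibble.
#' @param epoch_seconds Epoch length in seconds (default 30).
#' @return A tibble with columns `device`, `position`, `behaviour`,
#'   `n_children`, `n_epochs`, `mean`, `sd`, `minutes` (mean per-child
#'   duration), and `single_epoch` flagging cells whose sd is reported as 0
#'   because they hold a single epoch.
#' @export
empirical_moments <- function(labeled, epoch_seconds = 30) {
  if (nrow(labeled) == 0) abort("`labeled` must be non-empty")
  labeled |>
    dplyr::group_by(.data$device, .data$position, .data$behaviour) |>
    dplyr::summarise(
      n_children = dplyr::n_distinct(.data$child_id),
      n_epochs = dplyr::n(),
      mean = mean(.data$count),
      sd = ifelse(dplyr::n() > 1, sd(.data$count), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      minutes = .data$n_epochs / .data$n_children * epoch_seconds / 60,
      single_epoch = .data$n_epochs == 1
    )
}
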