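#' Composite intensity class schemes for One-vs-Rest calibration
#'
#' The six ordered behaviours are collapsed into nested composite classes for
#' One-vs-Rest (OvR) binarisation:
#'
#' * `VPA` — vigorous PA: sprinting vs all five other behaviours;
#' * `MVPA` — moderate-vigorous PA: sprinting + floorball/walk vs the rest;
#' * `LMVPA` — light-moderate-vigorous PA: the three mobile behaviours vs
#'   the three stationary ones (this cut separates mobile from stationary PA);
#' * `MOA` — motionless alert: sedentary screen time vs all other behaviours,
#'   with the *below*-threshold direction (low counts are positive).
#'
#' The sedentary band (SED) is not a ROC problem of its own: it is the count
#' range between the MOA cut-off and the LMVPA cut-off.
#'
#' @param name One of `"VPA"`, `"MVPA"`, `"LMVPA"`, `"MOA"`.
#' @return A list of class `class_scheme` with elements `name`,
#'   `positive_set`, `negative_set` and `direction`
#'   (`"above_threshold_positive"` or `"below_threshold_positive"`).
#' @examples
#' class_scheme("LMVPA")$positive_set
#' @export
class_scheme <- function(name = c("VPA", "MVPA", "LMVPA", "MOA")) {
  name <- match.arg(name)
  lev <- behaviour_levels()
  positive <- switch(name,
    VPA = "sprinting",
    MVPA = c("sprinting", "floorball_walk"),
    LMVPA = c("sprinting", "floorball_walk", "play_on_floor"),
    MOA = "sedentary_screen_time"
  )
  structure(
    list(
      name = name,
      positive_set = positive,
      negative_set = setdiff(lev, positive),
      direction = if (name == "MOA") "below_threshold_positive"
                  else "above_threshold_positive"
    ),
    class = "class_scheme"
  )
}

#' @rdname class_scheme
#' @return `ovr_schemes()` returns the four schemes as a named list.
#' @export
ovr_schemes <- function() {
  setNames(lapply(c("VPA", "MVPA", "LMVPA", "MOA"), class_scheme),
           c("VPA", "MVPA", "LMVPA", "MOA"))
}

#' Binarise labelled counts for ROC analysis
#'
#' `binarize_ovr()` builds the One-vs-Rest problem for a composite scheme:
#' label 1 for epochs whose behaviour is in the scheme's positive set, 0
#' otherwise; scores are the counts, negated internally when the scheme's
#' direction is below-threshold-positive so that higher scores always favour
#' the positive class. `binarize_ovo()` builds a One-vs-One problem from two
#' disjoint behaviour sets, retaining only their epochs.
#'
#' @param labeled A labelled-counts tibble (typically one channel).
#' @param scheme A [class_scheme()].
#' @return A list with `scores`, `labels` (0/1 integer), `direction`, and
#'   `sign` (+1, or -1 when scores were negated).
#' @export
binarize_ovr <- function(labeled, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  beh <- as.character(labeled$behaviour)
  labels <- as.integer(beh %in% scheme$positive_set)
  if (all(labels == 1) || all(labels == 0)) {
    abort(paste0(
      "degenerate problem for scheme ", scheme$name,
      ": need epochs from both the positive and the negative set"
    ))
  }
  sgn <- if (scheme$direction == "below_threshold_positive") -1 else 1
  list(scores = sgn * labeled$count, labels = labels,
       direction = scheme$direction, sign = sgn)
}

#' @rdname binarize_ovr
#' @param class_a,class_b Disjoint character vectors of behaviour names;
#'   epochs in `class_a` are labelled 1.
#' @export
binarize_ovo <- function(labeled, class_a, class_b) {
  class_a <- as.character(behaviour_factor(class_a))
  class_b <- as.character(behaviour_factor(class_b))
  if (length(intersect(class_a, class_b)) > 0) {
    abort("`class_a` and `class_b` must be disjoint behaviour sets")
  }
  beh <- as.character(labeled$behaviour)
  keep <- beh %in% c(class_a, class_b)
  labels <- as.integer(beh[keep] %in% class_a)
  if (!any(labels == 1) || !any(labels == 0)) {
    abort("both behaviour sets must be present in the data")
  }
  list(scores = labeled$count[keep], labels = labels,
       direction = "above_threshold_positive", sign = 1)
}

#' ROC curve over observed count thresholds
#'
#' Sweeps candidate thresholds — the unique observed scores plus one sentinel
#' below the minimum and one above the maximum — and records sensitivity and
#' specificity at each, under the convention that an epoch is predicted
#' positive iff its score strictly exceeds the threshold. Candidate cut-offs
#' are observed score values (not midpoints) because calibrated cut-offs are
#' reported on the raw count scale of the data distribution.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 vector of the same length; both values must be present.
#' @return A tibble with columns `threshold`, `sensitivity`, `specificity`,
#'   ordered by increasing threshold.
#' @examples
#' roc_curve(c(3, 5, 1, 4), c(1, 1, 0, 0))
#' @export
roc_curve <- function(scores, labels) {
  check_binary_problem(scores, labels)
  thr <- sort(unique(scores))
  thr <- c(thr[1] - 1, thr, thr[length(thr)] + 1)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg <= t), numeric(1))
  tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec)
}

check_binary_problem <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have the same length")
  }
  if (!all(labels %in% c(0, 1))) abort("`labels` must be 0/1")
  if (!any(labels == 1) || !any(labels == 0)) {
    abort("need at least one epoch in each class")
  }
  invisible(TRUE)
}

#' Youden-optimal cut-off from a ROC curve
#'
#' Selects the threshold maximising the Youden index
#' `J = sensitivity + specificity - 1`, the best compromise between
#' sensitivity and specificity without prioritising either. Ties are broken
#' toward the smallest threshold (the most sensitive of the tied points); the
#' tie-break rule is fixed and documented rather than data-dependent.
#'
#' @param roc A tibble from [roc_curve()].
#' @return A list with `cutoff`, `sensitivity`, `specificity`, `youden_j`,
#'   and `tie` (TRUE when several thresholds attained the maximal J).
#' @examples
#' youden_cutoff(roc_curve(c(10, 11, 1, 2), c(1, 1, 0, 0)))
#' @export
youden_cutoff <- function(roc) {
  if (nrow(roc) == 0) abort("`roc` must be non-empty")
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  pick <- best[which.min(roc$threshold[best])]
  list(
    cutoff = roc$threshold[pick],
    sensitivity = roc$sensitivity[pick],
    specificity = roc$specificity[pick],
    youden_j = j[pick],
    tie = length(best) > 1
  )
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = (# concordant (pos, neg) pairs + 0.5 x ties) / (n_pos x n_neg)`,
#' computed via midranks; identical to the trapezoidal area under the ROC
#' curve and to the probability that a random positive epoch scores above a
#' random negative one.
#'
#' @inheritParams roc_curve
#' @return A single number in `[0, 1]`.
#' @examples
#' auc(c(3, 5, 1, 4), c(1, 1, 0, 0)) # 3 of 4 pairs concordant: 0.75
#' @export
auc <- function(scores, labels) {
  check_binary_problem(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confidence interval for the AUC
#'
#' The default is the DeLong placement-based variance estimator (fast and
#' deterministic); a stratified percentile bootstrap (resampling positives
#' and negatives separately) is available as an alternative. Intervals are
#' clipped to `[0, 1]`.
#'
#' @inheritParams roc_curve
#' @param level Confidence level in (0, 1) (default 0.95).
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap (ignored for DeLong).
#' @return A list with `low`, `high`, `method`, `level`.
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "bootstrap"),
                   n_boot = 2000, seed = 1L) {
  method <- match.arg(method)
  check_binary_problem(scores, labels)
  if (level <= 0 || level >= 1) abort("`level` must lie in (0, 1)")
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (method == "delong") {
    if (length(pos) < 2 || length(neg) < 2) {
      abort("DeLong interval needs at least 2 epochs per class")
    }
    # placements: V10_i = P-hat(pos_i > random neg), V01_j analogous
    v10 <- vapply(pos, function(x) mean(x > neg) + 0.5 * mean(x == neg),
                  numeric(1))
    v01 <- vapply(neg, function(y) mean(pos > y) + 0.5 * mean(pos == y),
                  numeric(1))
    a <- mean(v10)
    se <- sqrt(var(v10) / length(pos) + var(v01) / length(neg))
    z <- qnorm(1 - (1 - level) / 2)
    lo <- a - z * se
    hi <- a + z * se
  } else {
    a <- auc(scores, labels)
    reps <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_boot), function(i) {
        p <- sample(pos, replace = TRUE)
        n <- sample(neg, replace = TRUE)
        auc(c(p, n), c(rep(1L, length(p)), rep(0L, length(n))))
      }, numeric(1))
    })
    qs <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    lo <- qs[1]
    hi <- qs[2]
  }
  list(low = max(0, lo), high = min(1, hi), method = method, level = level)
}

#' Discrimination accuracy band for an AUC value
#'
#' Standard interpretation bands: at least 0.90 outstanding, 0.80 up to 0.90
#' excellent, 0.70 up to 0.80 acceptable (fair), below 0.70 poor (an AUC of
#' 0.5 is no better than guessing).
#'
#' @param auc_value Numeric vector of AUC values in `[0, 1]`.
#' @return Character vector of bands.
#' @examples
#' accuracy_band(c(0.95, 0.85, 0.75, 0.5))
#' @export
accuracy_band <- function(auc_value) {
  if (any(auc_value < 0 | auc_value > 1)) {
    abort("AUC values must lie in [0, 1]")
  }
  dplyr::case_when(
    auc_value >= 0.90 ~ "outstanding",
    auc_value >= 0.80 ~ "excellent",
    auc_value >= 0.70 ~ "acceptable",
    TRUE ~ "poor"
  )
}

#' Calibrate all four One-vs-Rest cut-offs for one channel
#'
#' Runs the full OvR calibration for one (device, position) channel: for each
#' of the VPA, MVPA, LMVPA and MOA schemes, binarise the pooled labelled
#' epochs, sweep the ROC curve, select the Youden-optimal cut-off, and
#' estimate the AUC with a confidence interval and accuracy band. Epochs are
#' pooled across children, mirroring the concatenation of same-behaviour
#' periods the calibration design prescribes.
#'
#' Mobile-class cut-offs are reported with the "count strictly above"
#' direction; the MOA cut-off is reported on the original count scale with
#' the "count strictly below" direction. The sedentary range is the closed
#' count interval `[moa_cut, lmvpa_cut]`.
#'
#' @param labeled A labelled-counts tibble containing the channel.
#' @param device,position Channel selector.
#' @param ci_method,level,n_boot,seed Passed to [auc_ci()].
#' @return An object of class `cutoff_table`: a list with `device`,
#'   `position`, `cuts` (named vpa/mvpa/lmvpa/moa), `sed_range`, and
#'   `results`, a named list of per-scheme results (cutoff, direction,
#'   sensitivity, specificity, youden_j, auc, auc_ci, n_pos, n_neg,
#'   accuracy_band).
#' @export
calibrate_channel <- function(labeled, device, position,
                              ci_method = c("delong", "bootstrap"),
                              level = 0.95, n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  assert_device(device)
  assert_position(position)
  chan <- labeled[labeled$device == device & labeled$position == position, ]
  have <- unique(as.character(chan$behaviour))
  missing_b <- setdiff(behaviour_levels(), have)
  if (length(missing_b) > 0) {
    abort(paste0(
      "channel ", device, "/", position, " is missing behaviour(s): ",
      paste(missing_b, collapse = ", ")
    ))
  }
  results <- lapply(ovr_schemes(), function(scheme) {
    bin <- binarize_ovr(chan, scheme)
    roc <- roc_curve(bin$scores, bin$labels)
    yj <- youden_cutoff(roc)
    a <- auc(bin$scores, bin$labels)
    ci <- auc_ci(bin$scores, bin$labels, level = level,
                 method = ci_method, n_boot = n_boot, seed = seed)
    # report the cut-off on the original count scale; for the MOA scheme the
    # internal scores are negated, so "> t" internally means "< -t" in counts
    list(
      scheme = scheme$name,
      cutoff = bin$sign * yj$cutoff,
      direction = if (bin$sign < 0) "<" else ">",
      sensitivity = yj$sensitivity,
      specificity = yj$specificity,
      youden_j = yj$youden_j,
      auc = a,
      auc_ci = c(low = ci$low, high = ci$high),
      ci_method = ci$method,
      n_pos = sum(bin$labels == 1),
      n_neg = sum(bin$labels == 0),
      accuracy_band = accuracy_band(a),
      tie = yj$tie
    )
  })
  cuts <- c(
    vpa = results$VPA$cutoff,
    mvpa = results$MVPA$cutoff,
    lmvpa = results$LMVPA$cutoff,
    moa = results$MOA$cutoff
  )
  structure(
    list(
      device = device,
      position = position,
      cuts = cuts,
      sed_range = c(low = unname(cuts["moa"]), high = unname(cuts["lmvpa"])),
      results = results,
      ci_method = ci_method
    ),
    class = "cutoff_table"
  )
}

#' @export
print.cutoff_table <- function(x, ...) {
  cat(sprintf("<cutoff_table> %s @ %s (CI: %s)\n",
              x$device, x$position, x$ci_method))
  for (r in x$results) {
    cat(sprintf(
      "  %-5s %s%g  sens %.0f%%  spec %.0f%%  AUC %.2f (%.2f-%.2f) %s\n",
      r$scheme, r$direction, r$cutoff, 100 * r$sensitivity,
      100 * r$specificity, r$auc, r$auc_ci[["low"]], r$auc_ci[["high"]],
      r$accuracy_band
    ))
  }
  cat(sprintf("  SED   %g-%g\n", x$sed_range[["low"]], x$sed_range[["high"]]))
  invisible(x)
}

#' Closed-form surrogate AUC under per-behaviour normal models
#'
#' Treats each behaviour's counts as an independent normal distribution with
#' the given cell mean and sd, and evaluates the scheme's One-vs-Rest AUC as
#' the equal-weight average over (positive, negative) behaviour pairs of the
#' normal pair AUC `Phi((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))`.
#' Equal weighting reflects the near-equal bout durations of the protocol.
#' For below-threshold schemes the difference is flipped, so low-scoring
#' positives count as concordant. A zero-variance pair with equal means
#' contributes 0.5.
#'
#' This surrogate is exact for the `normal` generator family with equal cell
#' sizes, which makes it the deterministic oracle the Monte-Carlo calibration
#' is checked against.
#'
#' @param params Moments tibble (as [channel_moments()]) restricted to one
#'   (device, position) channel, covering all six behaviours.
#' @param scheme A [class_scheme()].
#' @return A single number in `[0, 1]`.
#' @examples
#' wrist_mw8 <- dplyr::filter(channel_moments(),
#'                            device == "MW8", position == "wrist")
#' gaussian_mixture_auc(wrist_mw8, class_scheme("VPA"))
#' @export
gaussian_mixture_auc <- function(params, scheme) {
  stopifnot(inherits(scheme, "class_scheme"))
  params <- tibble::as_tibble(params)
  if (nrow(dplyr::distinct(params, .data$device, .data$position)) != 1) {
    abort("`params` must describe exactly one (device, position) channel")
  }
  beh <- as.character(params$behaviour)
  missing_b <- setdiff(behaviour_levels(), beh)
  if (length(missing_b) > 0) {
    abort(paste0("missing behaviour(s): ", paste(missing_b, collapse = ", ")))
  }
  mu <- setNames(params$mean, beh)
  sg <- setNames(params$sd, beh)
  sgn <- if (scheme$direction == "below_threshold_positive") -1 else 1
  pair_auc <- function(p, q) {
    delta <- sgn * (mu[[p]] - mu[[q]])
    pooled <- sqrt(sg[[p]]^2 + sg[[q]]^2)
    if (pooled == 0) {
      if (delta == 0) 0.5 else as.numeric(delta > 0)
    } else {
      pnorm(delta / pooled)
    }
  }
  vals <- outer(scheme$positive_set, scheme$negative_set,
                Vectorize(pair_auc))
  mean(vals)
}
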