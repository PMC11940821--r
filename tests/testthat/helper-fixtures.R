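# Shared fixtures, built in code.

# A small balanced labelled-counts table: `n` epochs per behaviour for one
# channel, counts drawn so behaviours are cleanly ordered.
balanced_channel <- function(n = 5, device = "MW8", position = "wrist",
                             child_id = "c01") {
  b <- behaviour_levels()
  tibble::tibble(
    child_id = child_id,
    device = device,
    position = position,
    behaviour = behaviour_factor(rep(b, each = n)),
    count = as.numeric(rep(seq_along(b) * 100, each = n)) +
      rep(seq_len(n), times = length(b))
  )
}

# Labelled counts with exactly the given counts per behaviour.
labeled_from <- function(..., device = "MW8", position = "wrist") {
  cells <- list(...)
  dplyr::bind_rows(lapply(names(cells), function(b) {
    tibble::tibble(
      child_id = "c01", device = device, position = position,
      behaviour = behaviour_factor(rep(b, length(cells[[b]]))),
      count = as.numeric(cells[[b]])
    )
  }))
}

# Brute-force AUC: double loop over all (positive, negative) pairs.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden scan over every candidate threshold (all observed scores
# plus sentinels), independent of roc_curve()/youden_cutoff().
youden_bruteforce <- function(scores, labels) {
  thr <- sort(unique(c(scores, min(scores) - 1, max(scores) + 1)))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  j <- vapply(thr, function(t) mean(pos > t) + mean(neg <= t) - 1, numeric(1))
  max(j)
}

small_config <- function(n_children = 6, seed = 99, ...) {
  cohort_config(n_children = n_children, seed = seed, ...)
}
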