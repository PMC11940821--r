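test_that("OvR binarisation partitions epochs by the scheme's positive set", {
  lab <- balanced_channel(n = 3)
  vpa <- binarize_ovr(lab, class_scheme("VPA"))
  expect_equal(sum(vpa$labels), 3)
  expect_equal(vpa$labels,
               as.integer(lab$behaviour == "sprinting"))

  lmvpa <- binarize_ovr(lab, class_scheme("LMVPA"))
  expect_setequal(
    unique(as.character(lab$behaviour[lmvpa$labels == 1])),
    c("sprinting", "floorball_walk", "play_on_floor")
  )

  moa <- binarize_ovr(lab, class_scheme("MOA"))
  expect_equal(moa$direction, "below_threshold_positive")
  expect_equal(moa$scores, -lab$count) # negated so high scores favour MOA
  expect_setequal(unique(as.character(lab$behaviour[moa$labels == 1])),
                  "sedentary_screen_time")

  only_sprint <- lab[lab$behaviour == "sprinting", ]
  expect_error(binarize_ovr(only_sprint, class_scheme("VPA")), "degenerate")
})

test_that("OvO binarisation retains only the two classes and rejects overlap", {
  lab <- balanced_channel(n = 4)
  bin <- binarize_ovo(lab, "sprinting", "floorball_walk")
  expect_length(bin$scores, 8)
  expect_equal(sum(bin$labels), 4)

  # SED (crafts + recumbent) vs MOA pools two behaviours as positives
  sed <- binarize_ovo(lab, c("sedentary_crafts", "recumbent_listening"),
                      "sedentary_screen_time")
  expect_equal(sum(sed$labels), 8)
  expect_length(sed$scores, 12)

  expect_error(binarize_ovo(lab, "sprinting", "sprinting"), "disjoint")
})

test_that("the ROC sweep reproduces hand-enumerated confusion tables", {
  # separable classes: a perfect point exists
  roc <- roc_curve(c(10, 11, 1, 2), c(1, 1, 0, 0))
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))

  # all scores identical: only the trivial corners
  flat <- roc_curve(c(5, 5, 5, 5), c(1, 0, 1, 0))
  expect_setequal(paste(flat$sensitivity, flat$specificity),
                  c("1 0", "0 1"))

  # pos {3, 5}, neg {1, 4}: at t = 4 sensitivity 0.5, specificity 1
  roc2 <- roc_curve(c(3, 5, 1, 4), c(1, 1, 0, 0))
  at4 <- roc2[roc2$threshold == 4, ]
  expect_equal(at4$sensitivity, 0.5)
  expect_equal(at4$specificity, 1)
})

test_that("Youden selection maximises J and breaks ties toward the smallest threshold", {
  sep <- youden_cutoff(roc_curve(c(10, 11, 1, 2), c(1, 1, 0, 0)))
  expect_equal(sep$youden_j, 1)
  expect_equal(sep$cutoff, 2) # report convention "> 2"

  flat <- youden_cutoff(roc_curve(rep(5, 6), c(1, 0, 1, 0, 1, 0)))
  expect_equal(flat$youden_j, 0)

  tie <- youden_cutoff(roc_curve(c(3, 5, 1, 4), c(1, 1, 0, 0)))
  expect_equal(tie$youden_j, 0.5) # attained at t = 1 and t = 4
  expect_equal(tie$cutoff, 1)     # tie-break: smallest threshold
  expect_true(tie$tie)
})

test_that("selected J equals the exhaustive-scan maximum on random problems", {
  set.seed(8)
  for (i in 1:25) {
    n1 <- sample(3:30, 1)
    n0 <- sample(3:30, 1)
    scores <- c(round(rnorm(n1, 1, 2), 1), round(rnorm(n0, 0, 2), 1))
    labels <- c(rep(1, n1), rep(0, n0))
    got <- youden_cutoff(roc_curve(scores, labels))
    expect_equal(got$youden_j, youden_bruteforce(scores, labels))
    expect_equal(got$youden_j, got$sensitivity + got$specificity - 1)
  }
})

test_that("AUC equals brute-force pair counting and the trapezoidal ROC area", {
  expect_equal(auc(c(3, 5, 1, 4), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc(c(10, 11, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(5, 4), c(1, 0, 1, 0)), 0.5)

  set.seed(23)
  for (i in 1:20) {
    n1 <- sample(2:40, 1)
    n0 <- sample(2:40, 1)
    scores <- c(sample(0:15, n1, TRUE), sample(0:15, n0, TRUE)) # many ties
    labels <- c(rep(1, n1), rep(0, n0))
    expect_equal(auc(scores, labels), auc_bruteforce(scores, labels))
  }
})

test_that("AUC and DeLong CI agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- c(rnorm(60, 1), rnorm(80))
  labels <- c(rep(1, 60), rep(0, 80))
  ref <- pROC::roc(labels, scores, direction = "<", quiet = TRUE)
  expect_equal(auc(scores, labels), as.numeric(pROC::auc(ref)))
  ours <- auc_ci(scores, labels)
  theirs <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$low, theirs[1], tolerance = 1e-8)
  expect_equal(ours$high, theirs[3], tolerance = 1e-8)
})

test_that("with equal class sizes the OvR AUC is the mean of pairwise AUCs", {
  set.seed(64)
  n <- 12
  lab <- dplyr::bind_rows(lapply(seq_along(behaviour_levels()), function(i) {
    tibble::tibble(
      child_id = "c01", device = "MW8", position = "wrist",
      behaviour = behaviour_factor(rep(behaviour_levels()[i], n)),
      count = rnorm(n, i * 50, 30)
    )
  }))
  for (nm in c("VPA", "MVPA", "LMVPA")) {
    scheme <- class_scheme(nm)
    bin <- binarize_ovr(lab, scheme)
    composite <- auc(bin$scores, bin$labels)
    pairwise <- sapply(scheme$negative_set, function(q) {
      sub <- lab[as.character(lab$behaviour) %in%
                   c(scheme$positive_set, q), ]
      b2 <- binarize_ovo(sub, scheme$positive_set, q)
      auc(b2$scores, b2$labels)
    })
    expect_equal(composite, mean(pairwise), info = nm)
  }
})

test_that("J vanishes when both classes share a distribution", {
  scores <- rep(c(1, 4, 7, 9), 2)
  labels <- rep(c(1, 0), each = 4) # identical multisets
  expect_equal(youden_cutoff(roc_curve(scores, labels))$youden_j, 0)

  set.seed(77)
  big <- c(rnorm(4000), rnorm(4000))
  expect_lt(youden_cutoff(roc_curve(big, rep(c(1, 0), each = 4000)))$youden_j,
            0.08)
})

test_that("DeLong intervals cover the point AUC and bootstrap is seed-stable", {
  set.seed(9)
  for (i in 1:40) {
    scores <- c(rnorm(15, 0.8), rnorm(20))
    labels <- c(rep(1, 15), rep(0, 20))
    ci <- auc_ci(scores, labels)
    a <- auc(scores, labels)
    expect_lte(ci$low, a)
    expect_gte(ci$high, a)
    expect_gte(ci$low, 0)
    expect_lte(ci$high, 1)
  }
  scores <- c(rnorm(25, 1), rnorm(25))
  labels <- rep(c(1, 0), each = 25)
  b1 <- auc_ci(scores, labels, method = "bootstrap", n_boot = 200, seed = 4)
  b2 <- auc_ci(scores, labels, method = "bootstrap", n_boot = 200, seed = 4)
  expect_identical(b1, b2)
  expect_error(auc_ci(c(1, 0.5), c(1, 0)), "at least 2")
})

test_that("accuracy bands follow the published boundaries", {
  expect_equal(accuracy_band(c(0.95, 0.90, 0.89, 0.85, 0.80, 0.79, 0.70,
                               0.5, 0)),
               c("outstanding", "outstanding", "excellent", "excellent",
                 "excellent", "acceptable", "acceptable", "poor", "poor"))
  expect_error(accuracy_band(1.2), "0, 1")
})

test_that("the closed-form surrogate matches symmetry and hand evaluations", {
  params <- tibble::tibble(
    device = "MW8", position = "wrist",
    behaviour = behaviour_factor(behaviour_levels()),
    mean = c(10, 10, 10, 10, 10, 10), sd = 2
  )
  for (nm in c("VPA", "MVPA", "LMVPA", "MOA")) {
    expect_equal(gaussian_mixture_auc(params, class_scheme(nm)), 0.5)
  }
  params0 <- dplyr::mutate(params, sd = 0)
  expect_equal(gaussian_mixture_auc(params0, class_scheme("VPA")), 0.5)

  # hand evaluation: one pair, means 3 apart, sds 4 and 3 -> Phi(3/5)
  two <- dplyr::mutate(params,
    mean = c(0, 0, 0, 0, 0, 3),
    sd = c(3, 3, 3, 3, 3, 4)
  )
  expect_equal(
    gaussian_mixture_auc(two, class_scheme("VPA")),
    pnorm(3 / 5)
  )
})

test_that("channel calibration returns four coherent results on separable data", {
  co <- generate_cohort(small_config(n_children = 10, seed = 2))
  tab <- calibrate_channel(co, "MW8", "wrist")
  expect_s3_class(tab, "cutoff_table")
  expect_named(tab$results, c("VPA", "MVPA", "LMVPA", "MOA"))
  for (r in tab$results) {
    expect_equal(r$youden_j, r$sensitivity + r$specificity - 1)
    expect_gte(r$auc, r$auc_ci[["low"]])
    expect_lte(r$auc, r$auc_ci[["high"]])
  }
  # mobile classes are well separated on this channel
  for (nm in c("VPA", "MVPA", "LMVPA")) {
    expect_gt(tab$results[[nm]]$auc, 0.9)
  }
  # nested schemes give monotone cut-offs on well-separated data
  expect_true(tab$cuts[["vpa"]] > tab$cuts[["mvpa"]])
  expect_true(tab$cuts[["mvpa"]] > tab$cuts[["lmvpa"]])
  expect_true(tab$cuts[["lmvpa"]] > tab$cuts[["moa"]])
  # the sedentary range is definitional
  expect_equal(unname(tab$sed_range),
               unname(c(tab$cuts[["moa"]], tab$cuts[["lmvpa"]])))
  expect_equal(tab$results$MOA$direction, "<")

  one_beh <- labeled_from(sprinting = 1:10)
  expect_error(calibrate_channel(one_beh, "MW8", "wrist"),
               "missing behaviour")
})

test_that("the MOA cut-off reported on the count scale reproduces its confusion table", {
  lab <- labeled_from(
    sedentary_screen_time = c(1, 2, 3, 50),
    recumbent_listening = c(5, 40, 60),
    sedentary_crafts = c(20, 45, 80),
    play_on_floor = c(90, 120),
    floorball_walk = c(150, 200),
    sprinting = c(300, 400)
  )
  tab <- calibrate_channel(lab, "MW8", "wrist")
  r <- tab$results$MOA
  below <- lab$count < r$cutoff
  is_screen <- lab$behaviour == "sedentary_screen_time"
  expect_equal(r$sensitivity, mean(below[is_screen]))
  expect_equal(r$specificity, mean(!below[!is_screen]))
})
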