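test_that("epoch CSV writing then reading is the identity on series content", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(31)
  series <- list(
    epoch_series("c01", "MW8", "wrist", round(runif(20, 0, 500)),
                 start_time = as.POSIXct("2020-10-05 09:00:00", tz = "UTC")),
    epoch_series("c01", "GT3X", "wrist", round(runif(15, 0, 5000)),
                 start_time = as.POSIXct("2020-10-05 09:00:00", tz = "UTC")),
    epoch_series("c02", "MW8", "hip", round(runif(7, 0, 100)),
                 start_time = as.POSIXct("2020-10-05 13:00:00", tz = "UTC"))
  )
  write_epoch_csv(series, tmp)
  back <- read_epoch_csv(tmp)
  expect_length(back, 3)
  key <- function(s) paste(s$child_id, s$device, s$position)
  back <- back[match(vapply(series, key, ""), vapply(back, key, ""))]
  for (i in seq_along(series)) {
    expect_equal(back[[i]]$counts, series[[i]]$counts)
    expect_equal(back[[i]]$offsets, series[[i]]$offsets)
    expect_equal(as.numeric(back[[i]]$start_time),
                 as.numeric(series[[i]]$start_time))
  }
})

test_that("reading groups rows by (child, device, position) as a brute-force scan would", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::tibble(
    child_id = c("a", "a", "a", "b"),
    device = c("MW8", "GT3X", "MW8", "MW8"),
    position = "wrist",
    timestamp = rep("2020-01-01T09:00:00", 4),
    count = c(1, 2, 3, 4)
  )
  # scramble rows; second MW8 row for child a gets a later timestamp
  df$timestamp[3] <- "2020-01-01T09:00:30"
  readr::write_csv(df[c(4, 2, 3, 1), ], tmp)
  back <- read_epoch_csv(tmp)
  keys <- sort(vapply(back, function(s) paste(s$child_id, s$device), ""))
  expect_equal(keys, sort(c("a MW8", "a GT3X", "b MW8")))
  a_mw8 <- back[[which(vapply(back, function(s)
    s$child_id == "a" && s$device == "MW8", logical(1)))]]
  expect_equal(a_mw8$counts, c(1, 3)) # time-ordered within the series
})

test_that("empty and malformed epoch CSVs are handled as specified", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(list(), tmp)
  expect_equal(read_epoch_csv(tmp), list())

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("child_id,device,timestamp,count\na,MW8,2020-01-01T09:00:00,5",
             bad)
  expect_error(read_epoch_csv(bad), "position")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("child_id,device,position,timestamp,count",
               "a,MW8,wrist,2020-01-01T09:00:00,5",
               "a,MW8,wrist,2020-01-01T09:00:30,-2"), neg)
  expect_error(read_epoch_csv(neg), "row 2")
})

test_that("segment extraction keeps only fully contained epochs", {
  t0 <- as.POSIXct("2020-01-01 09:00:00", tz = "UTC")
  s <- epoch_series("c01", "MW8", "wrist", seq_len(40), start_time = t0)

  expect_equal(
    nrow(extract_segments(s, behaviour_protocol(character(), character(),
                                                t0[0], t0[0]))),
    0
  )

  aligned <- behaviour_protocol("c01", "play_on_floor", t0, t0 + 600)
  lab <- extract_segments(s, aligned)
  expect_equal(nrow(lab), 20) # 600 s / 30 s
  expect_equal(lab$count, as.numeric(1:20))
  expect_true(all(lab$behaviour == "play_on_floor"))

  # interval starting 15 s after an epoch boundary: first and last partial
  # epochs fall out, 19 whole epochs remain
  offset15 <- behaviour_protocol("c01", "sprinting", t0 + 15, t0 + 615)
  expect_equal(nrow(extract_segments(s, offset15)), 19)
  expect_equal(extract_segments(s, offset15)$count, as.numeric(2:20))
})

test_that("an interval outside the series range warns and labels nothing", {
  t0 <- as.POSIXct("2020-01-01 09:00:00", tz = "UTC")
  s <- epoch_series("c01", "MW8", "wrist", 1:10, start_time = t0)
  far <- behaviour_protocol("c01", "sprinting", t0 + 4000, t0 + 4600)
  expect_warning(lab <- extract_segments(s, far), "outside")
  expect_equal(nrow(lab), 0)
})

test_that("extraction never labels more epochs than fit in the interval, and pooling preserves rows", {
  t0 <- as.POSIXct("2020-01-01 09:00:00", tz = "UTC")
  set.seed(17)
  series <- lapply(1:4, function(i) {
    epoch_series(paste0("c", i), "MW8", "wrist", runif(60, 0, 100),
                 start_time = t0)
  })
  per_child <- integer(0)
  for (i in 1:4) {
    a <- runif(1, 0, 900)
    len <- runif(1, 60, 700)
    p <- behaviour_protocol(paste0("c", i), "floorball_walk",
                            t0 + a, t0 + a + len)
    lab_i <- extract_segments(series[[i]], p)
    expect_lte(nrow(lab_i), floor(len / 30))
    per_child[i] <- nrow(lab_i)
  }
  pooled <- extract_segments(series, behaviour_protocol(
    paste0("c", 1:4), "sprinting", rep(t0, 4), rep(t0 + 300, 4)
  ))
  expect_equal(nrow(pooled), 4 * 10)
})

test_that("duration validation applies the 8-10 minute rule per cell", {
  lab <- dplyr::bind_rows(
    labeled_from(sprinting = rep(10, 16)),               # 8.0 min: boundary in
    labeled_from(floorball_walk = rep(10, 21)),          # 10.5 min: flagged
    labeled_from(play_on_floor = rep(10, 15))            # 7.5 min: flagged
  )
  rep_tab <- validate_durations(lab, epoch_seconds = 30)
  get <- function(b) rep_tab[as.character(rep_tab$behaviour) == b, ]
  expect_equal(get("sprinting")$minutes, 8)
  expect_true(get("sprinting")$within_limits)
  expect_equal(get("floorball_walk")$minutes, 10.5)
  expect_false(get("floorball_walk")$within_limits)
  expect_false(get("play_on_floor")$within_limits)

  # mixed fixture matches a brute-force tally
  co <- generate_cohort(small_config(n_children = 3))
  rep2 <- validate_durations(co)
  brute <- table(paste(co$child_id, co$device, co$position, co$behaviour))
  key <- paste(rep2$child_id, rep2$device, rep2$position, rep2$behaviour)
  expect_equal(rep2$n_epochs, as.integer(brute[key]), ignore_attr = TRUE)
  expect_true(all(rep2$within_limits))
})

test_that("protocol validation rejects bad intervals", {
  expect_error(
    behaviour_protocol("a", "sprinting", "2020-01-01 10:00:00",
                       "2020-01-01 09:00:00"),
    "stop must be after start"
  )
  expect_error(
    behaviour_protocol(c("a", "a"), c("sprinting", "play_on_floor"),
                       c("2020-01-01 09:00:00", "2020-01-01 09:05:00"),
                       c("2020-01-01 09:10:00", "2020-01-01 09:15:00")),
    "overlapping"
  )
  expect_error(behaviour_factor("jogging"), "Unknown behaviour")
})
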