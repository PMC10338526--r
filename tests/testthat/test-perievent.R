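# Peri-event alignment, class averages, block trends and pointwise
# comparison.

dff_from <- function(v, fps = 30, condition = NA_character_) {
  tibble::new_tibble(
    tibble::tibble(time_s = (seq_along(v) - 1) / fps, dff = v),
    nrow = length(v), class = "dff_trace", fps = fps,
    condition_label = condition
  )
}

events_at <- function(times, type = "nose_poke_active", rewarded = TRUE) {
  tibble::tibble(time_s = times, event_type = type, rewarded = rewarded)
}

test_that("snippets have (pre+post)*fps frames with the event at index pre*fps", {
  v <- rep(0, 600)
  v[301] <- 1 # unit impulse at frame 300 (0-based), i.e. t = 10 s
  pem <- extract_perievent(dff_from(v), events_at(10))
  expect_equal(attr(pem, "n_frames"), 120)
  expect_equal(lengths(pem$snippet), 120)
  expect_equal(pem$snippet[[1]][61], 1) # 0-based index 60
  expect_true(all(pem$snippet[[1]][-61] == 0))
})

test_that("events whose window touches undefined frames are dropped and counted", {
  v <- c(rep(NA_real_, 90), rep(0, 510)) # 3 s warm-up
  pem <- extract_perievent(dff_from(v), events_at(c(1, 10)))
  expect_equal(nrow(pem), 1)
  expect_equal(attr(pem, "n_dropped"), 1)
  expect_error(
    extract_perievent(dff_from(v), events_at(1)),
    "no alignable events"
  )
})

test_that("class averages are frame-wise means with SEM", {
  v <- rep(0, 900)
  pem <- extract_perievent(dff_from(v), events_at(c(10, 15)))
  pem$snippet <- list(rep(1, 120), rep(3, 120))
  avg <- class_average(pem, "NP R+")
  expect_equal(avg$mean, rep(2, 120))
  expect_equal(avg$sem, rep(1, 120)) # sd = sqrt(2), n = 2
  expect_equal(avg$time_s[61], 0)
  # single event: mean is the snippet, SEM is NaN
  pem1 <- extract_perievent(dff_from(rep(0, 900)), events_at(10))
  pem1$snippet <- list(rep(1, 120))
  avg1 <- class_average(pem1, "NP R+")
  expect_equal(avg1$mean, rep(1, 120))
  expect_true(all(is.nan(avg1$sem)))
  expect_error(class_average(pem, "not a class"), "unknown")
})

test_that("CLT: noisy constant snippets average to the constant", {
  set.seed(1)
  v <- rep(0, 40 * 30)
  pem <- extract_perievent(dff_from(v), events_at(seq(5, 34, length.out = 50)))
  pem$snippet <- lapply(1:50, function(i) 0.1 + rnorm(120, 0, 0.05))
  avg <- class_average(pem, "NP R+")
  expect_true(all(abs(avg$mean - 0.1) < 3 * avg$sem))
})

test_that("decile partition covers all events with the spec'd sizes", {
  sizes <- habitometry:::block_assignment(47, 10)
  expect_equal(as.integer(tabulate(sizes, 10)), c(4, 5, 5, 4, 5, 5, 4, 5, 5, 5))
  expect_equal(sum(tabulate(sizes, 10)), 47)
  # partition is a disjoint cover for a range of n
  for (n in c(10, 11, 23, 100)) {
    b <- habitometry:::block_assignment(n, 10)
    expect_equal(length(b), n)
    expect_true(all(b %in% 1:10))
    expect_true(all(diff(b) >= 0)) # contiguous
  }
})

make_trend_pem <- function(metric_by_event, n_frames = 120, fps = 30) {
  n <- length(metric_by_event)
  v <- rep(0, (n + 10) * 60)
  pem <- extract_perievent(dff_from(v), events_at(seq(5, length.out = n, by = 2)))
  # post-mean minus pre-mean equals the requested metric exactly
  pem$snippet <- lapply(metric_by_event, function(m) c(rep(0, 60), rep(m, 60)))
  pem
}

test_that("block trend slope is exact on a block-index staircase", {
  # 20 events, metric equal to its block index (two events per block)
  pem <- make_trend_pem(rep(1:10, each = 2))
  bt <- suppressWarnings(blockwise_trend(pem, "NP R+")) # perfect-fit lm warning
  expect_equal(bt$slope, 1.0, tolerance = 1e-12)
  expect_equal(bt$blocks$mean_metric, as.numeric(1:10))
  expect_equal(bt$blocks$n_events, rep(2L, 10))
})

test_that("constant metric gives zero slope; too few events error", {
  pem <- make_trend_pem(rep(0.4, 30))
  bt <- suppressWarnings(blockwise_trend(pem, "NP R+"))
  expect_equal(bt$slope, 0, tolerance = 1e-12)
  expect_error(blockwise_trend(make_trend_pem(rep(1, 5)), "NP R+"), "fewer events")
})

test_that("trend slope is shift-invariant and scales linearly", {
  set.seed(2)
  m <- rnorm(40)
  s0 <- blockwise_trend(make_trend_pem(m), "NP R+")$slope
  s_shift <- blockwise_trend(make_trend_pem(m + 5), "NP R+")$slope
  s_scale <- blockwise_trend(make_trend_pem(3 * m), "NP R+")$slope
  expect_equal(s_shift, s0, tolerance = 1e-9)
  expect_equal(s_scale, 3 * s0, tolerance = 1e-9)
})

test_that("pointwise comparison flags the constructed effect region only", {
  set.seed(1)
  v <- rep(0, 80 * 30)
  times <- seq(5, length.out = 30, by = 2)
  pem_a <- extract_perievent(dff_from(v), events_at(times))
  pem_b <- extract_perievent(dff_from(v), events_at(times))
  base <- function() rnorm(120, 0, 0.01)
  pem_a$snippet <- lapply(1:30, function(i) base())
  pem_b$snippet <- lapply(1:30, function(i) {
    s <- base()
    s[61:120] <- s[61:120] + 0.1 # 10 SD offset on the post half
    s
  })
  ranges <- pointwise_group_compare(pem_a, pem_b)
  expect_gt(nrow(ranges), 0)
  flagged <- unlist(Map(seq, ranges$start_frame, ranges$end_frame))
  expect_true(all(60:119 %in% flagged))
  expect_false(any(flagged < 55))
  # identical groups: nothing flagged
  expect_equal(nrow(pointwise_group_compare(pem_a, pem_a)), 0)
  # undersized group errors
  pem_one <- extract_perievent(dff_from(v), events_at(5))
  expect_error(pointwise_group_compare(pem_one, pem_b), "at least 2")
})
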