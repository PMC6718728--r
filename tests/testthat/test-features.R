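test_that("digit-status filtering maps flexing to 1, extending to 0, stall holds", {
  time <- (0:3) / 10
  mk <- function(d1) {
    st <- tibble::tibble(time = time)
    for (d in 1:6) st[[paste0("d", d)]] <- if (d == 1) d1 else rep("OPEN", 4)
    st
  }
  f <- filter_digit_status(mk(c("CLOSING", "CLOSED", "STALLED", "OPENING")))
  expect_identical(f$s1, c(1L, 1L, 1L, 0L))
  # leading stall maps to 0
  f2 <- filter_digit_status(mk(c("STALLED", "STALLED", "CLOSING", "STALLED")))
  expect_identical(f2$s1, c(0L, 0L, 1L, 1L))
  # all-open trace is all zero
  f3 <- filter_digit_status(mk(rep("OPEN", 4)))
  expect_true(all(as.matrix(f3[paste0("s", 1:4)]) == 0L))
  # six digits always collapse to four channels
  expect_named(f, c("time", paste0("s", 1:4)))
})

test_that("filtered channels follow their representative digits", {
  time <- (0:1) / 10
  st <- tibble::tibble(
    time = time,
    d1 = c("OPEN", "CLOSING"), d2 = c("OPEN", "OPEN"),
    d3 = c("CLOSING", "CLOSING"), d4 = c("OPEN", "OPEN"),
    d5 = c("OPEN", "OPEN"), d6 = c("OPEN", "CLOSED")
  )
  f <- filter_digit_status(st)
  expect_identical(f$s1, c(0L, 1L)) # thumb flexion = d1
  expect_identical(f$s2, c(0L, 0L)) # index = d2
  expect_identical(f$s3, c(1L, 1L)) # coupled group represented by d3
  expect_identical(f$s4, c(0L, 1L)) # thumb abduction = d6
})

test_that("threshold-crossing counts match a sign-change scan", {
  # constants and single steps
  expect_identical(count_threshold_crossings(cbind(rep(0.05, 50)), 0.3), 0L)
  expect_identical(count_threshold_crossings(cbind(c(0.1, 0.9)), 0.3), 1L)
  # sinusoid around the threshold: three full periods give six crossings
  t <- seq(0, 3, by = 0.01)
  x <- 0.3 + 0.2 * sin(2 * pi * t)
  expect_identical(count_threshold_crossings(cbind(x), 0.3), 6L)
  # samples exactly at the threshold count as below
  expect_identical(count_threshold_crossings(cbind(c(0.3, 0.3, 0.3)), 0.3), 0L)
  expect_identical(count_threshold_crossings(cbind(c(0.2, 0.3, 0.4, 0.3)), 0.3), 2L)
  # brute-force oracle on random windows
  withr::with_seed(42, {
    for (rep in 1:20) {
      x <- runif(100)
      s <- x > 0.3
      oracle <- sum(s[-1] != s[-100])
      expect_identical(count_threshold_crossings(cbind(x), 0.3), oracle)
    }
  })
  expect_error(count_threshold_crossings(cbind(numeric(0)), 0.3), "empty")
})

test_that("status-change counts equal runs minus one", {
  expect_identical(count_status_changes(cbind(rep(1, 30))), 0L)
  expect_identical(count_status_changes(cbind(c(0, 0, 1, 1, 0))), 2L)
  withr::with_seed(7, {
    for (rep in 1:20) {
      v <- sample(0:1, 300, replace = TRUE)
      oracle <- length(rle(v)$lengths) - 1L
      expect_identical(count_status_changes(cbind(v)), oracle)
    }
  })
  expect_error(count_status_changes(cbind(integer(0))), "empty")
})

test_that("window tiling drops trailing partials and halves the step on overlap", {
  expect_identical(nrow(make_windows(0, 30, 3, "none")), 10L)
  expect_identical(nrow(make_windows(0, 10, 1, "half")), 19L)
  expect_identical(nrow(make_windows(0, 0.4, 0.5, "none")), 0L)
  w <- make_windows(2, 8, 1.5, "none")
  expect_equal(w$start, c(2, 3.5, 5, 6.5))
  expect_equal(w$end - w$start, rep(1.5, 4))
  # exact-tiling spans: half overlap doubles the density minus one
  withr::with_seed(1, {
    for (rep in 1:10) {
      len <- sample(c(0.5, 1, 3), 1)
      n <- sample(3:12, 1)
      t0 <- runif(1, 0, 100)
      none <- make_windows(t0, t0 + n * len, len, "none")
      half <- make_windows(t0, t0 + n * len, len, "half")
      expect_identical(nrow(half), 2L * nrow(none) - 1L)
    }
  })
})

test_that("window labels use the half-open failure convention", {
  expect_identical(label_window(0, 3, 1.5), 1L)
  expect_identical(label_window(0, 3, numeric(0)), 0L)
  expect_identical(label_window(0, 3, 3), 0L)
  expect_identical(label_window(3, 6, 3), 1L)
  expect_identical(label_window(0, 3, 0), 1L)
})

test_that("extract_dataset enumerates tasks x windows with correct dimensions", {
  s <- toy_session(n_tasks = 20, rate = 50, span = 600) # 30 s tasks
  ds <- extract_dataset(s, 3, "none", "tc")
  expect_identical(nrow(ds), 200L)
  expect_named(ds, c("task", "window_start", "window_end", paste0("tc", 1:4), "label"))
  expect_true(all(as.matrix(ds[paste0("tc", 1:4)]) == 0L))
  expect_true(all(ds$label == 0L))
  ds8 <- extract_dataset(s, 3, "none", "tcsc")
  expect_identical(
    names(ds8),
    c("task", "window_start", "window_end", paste0("tc", 1:4), paste0("sc", 1:4), "label")
  )
})

test_that("tcsc is the exact concatenation of tc and sc on every window", {
  s <- generate_session(small_sim(seed = 21))
  tc <- extract_dataset(s, 1, "half", "tc")
  sc <- extract_dataset(s, 1, "half", "sc")
  tcsc <- extract_dataset(s, 1, "half", "tcsc")
  expect_identical(tcsc[paste0("tc", 1:4)], tc[paste0("tc", 1:4)])
  expect_identical(tcsc[paste0("sc", 1:4)], sc[paste0("sc", 1:4)])
  # labels are invariant to the feature type
  expect_identical(tc$label, sc$label)
  expect_identical(tc$label, tcsc$label)
  expect_identical(tc$window_start, sc$window_start)
})

test_that("failure windows are labeled 1 across the generated session", {
  s <- generate_session(small_sim(seed = 31))
  expect_gt(nrow(s$failures), 0)
  ds <- extract_dataset(s, 3, "none", "sc")
  lab_oracle <- vapply(seq_len(nrow(ds)), function(i) {
    label_window(ds$window_start[i], ds$window_end[i], s$failures$time)
  }, integer(1))
  expect_identical(ds$label, lab_oracle)
  expect_gt(sum(ds$label), 0)
})
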