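test_that("tapping counts down events inside the 10 s window", {
  expect_equal(score_tapping(tap_session(numeric())), 0L)
  expect_equal(score_tapping(tap_session(seq(0, 9000, length.out = 7))), 7L)
  # 5 pairs inside + 2 at or after 10 s are not counted
  s <- tap_session(c(100, 2000, 4000, 6000, 8000, 10000, 11000))
  expect_equal(score_tapping(s), 5L)
  # window edge: a down at exactly t = 10 s is outside
  expect_equal(score_tapping(tap_session(c(0, 9999))), 2L)
  wrong <- cm_session("open_close", c(0, 50), c(0, 0), c("down", "up"), c(1, 1), c(1, 1))
  expect_error(score_tapping(wrong), "tapping")
})

test_that("isolated tapping requires the spot and resting contacts", {
  spot <- c(10, 8)
  rest <- function(t_up = 11000) {
    list(
      t = c(rep(0, 4), rep(t_up, 4)), pid = c(1:4, 1:4),
      ph = c(rep("down", 4), rep("up", 4)),
      x = rep(c(6, 8, 12, 14), 2), y = rep(c(4, 3, 3, 4), 2)
    )
  }
  mk <- function(t_downs, x = spot[1], y = spot[2], t_up_rest = 11000) {
    tap_session(t_downs,
      x_cm = x, y_cm = y, exercise_id = "iso_tap_index",
      calibration = spot, extra = rest(t_up_rest)
    )
  }
  # taps inside the spot with 4 sustained resting contacts all count
  expect_equal(score_isolated_tapping(mk(seq(100, 9000, length.out = 6))), 6L)
  # taps 2 cm off a 1.25 cm spot never count
  expect_equal(score_isolated_tapping(mk(seq(100, 9000, length.out = 6), x = spot[1] + 2)), 0L)
  # resting hand lifts mid-trial: only taps before the lift count
  expect_equal(score_isolated_tapping(mk(c(1000, 2000, 6000, 7000), t_up_rest = 4000)), 2L)
  # a tap at the exact instant of the lift still counts (contact inclusive)
  expect_equal(score_isolated_tapping(mk(c(1000, 4000, 6000), t_up_rest = 4000)), 2L)
  # missing calibration is an error
  s <- tap_session(1000, exercise_id = "iso_tap_index", extra = rest())
  expect_error(score_isolated_tapping(s), "calibration")
})

test_that("pincer extrema are taken over exactly-two-contact instants", {
  # two static contacts 5 cm apart
  s <- cm_session("pincer_index",
    t_ms = c(0, 0, 400, 400), pointer_id = c(0, 1, 0, 1),
    phase = c("down", "down", "up", "up"),
    x_cm = c(5, 10, 5, 10), y_cm = c(8, 8, 8, 8)
  )
  expect_equal(score_pincer(s), c(pincer_max_cm = 5, pincer_min_cm = 5))

  # one contact fixed, the other moving 2 -> 13 cm radially
  d <- seq(2, 13, by = 0.5)
  s <- cm_session("pincer_index",
    t_ms = c(0, 0, seq(50, by = 50, length.out = length(d)), 50 * length(d) + 50, 50 * length(d) + 50),
    pointer_id = c(0, 1, rep(1, length(d)), 0, 1),
    phase = c("down", "down", rep("move", length(d)), "up", "up"),
    x_cm = c(5, 5 + d[1], 5 + d, 5, 5 + d[length(d)]),
    y_cm = rep(8, length(d) + 4)
  )
  expect_equal(score_pincer(s), c(pincer_max_cm = 13, pincer_min_cm = 2))

  # a transient third contact excludes those frames from the extrema
  s3 <- cm_session("pincer_index",
    t_ms = c(0, 0, 100, 150, 200, 300, 400, 400),
    pointer_id = c(0, 1, 2, 1, 2, 1, 0, 1),
    phase = c("down", "down", "down", "move", "up", "move", "up", "up"),
    x_cm = c(5, 10, 20, 25, 20, 9, 5, 9), # at t=150 the pair is 20 cm apart but 3 contacts
    y_cm = rep(8, 8)
  )
  # frames considered: t=0 (5), t=300 (4), t=400 (4); t=100..200 have 3 contacts
  # (the up at 200 is still in contact at 200, closed interval)
  expect_equal(score_pincer(s3), c(pincer_max_cm = 5, pincer_min_cm = 4))

  # a single contact throughout is unscorable, not zero
  s1 <- cm_session("pincer_index",
    t_ms = c(0, 100), pointer_id = c(0, 0),
    phase = c("down", "up"), x_cm = c(5, 5), y_cm = c(8, 8)
  )
  expect_error(score_pincer(s1), "unscorable")
})

test_that("hand area extrema come from >=3-contact convex hulls", {
  # 5 static contacts: unit-square corners + centre -> area 1 throughout
  s <- cm_session("open_close",
    t_ms = c(rep(0, 5), rep(500, 5)), pointer_id = rep(0:4, 2),
    phase = c(rep("down", 5), rep("up", 5)),
    x_cm = rep(c(4, 5, 5, 4, 4.5), 2), y_cm = rep(c(4, 4, 5, 5, 4.5), 2)
  )
  expect_equal(score_hand_area(s), c(area_max_cm2 = 1, area_min_cm2 = 1))

  # radial contraction by factor 0.5 -> area_min = 0.25 * area_max
  s <- open_close_session(seq(4, 2, length.out = 21))
  a <- score_hand_area(s)
  expect_equal(unname(a["area_min_cm2"] / a["area_max_cm2"]), 0.25, tolerance = 1e-12)

  # scripted open-close cycle: extrema match a frame-by-frame oracle built
  # from scratch with the gift-wrapping hull
  rpath <- 3 + 1.5 * sin(seq(0, 2 * pi, length.out = 40))
  s <- open_close_session(rpath)
  ev <- s$events
  xc <- ev$x_px / s$device$px_per_cm_x
  yc <- ev$y_px / s$device$px_per_cm_y
  areas <- vapply(unique(ev$t_ms), function(t) {
    idx <- vapply(unique(ev$pointer_id), function(pid) {
      rows <- which(ev$pointer_id == pid & ev$t_ms <= t)
      rows[length(rows)]
    }, 0L)
    jarvis_hull_area(cbind(xc[idx], yc[idx]))
  }, 0)
  got <- score_hand_area(s)
  expect_equal(unname(got["area_max_cm2"]), max(areas), tolerance = 1e-9)
  expect_equal(unname(got["area_min_cm2"]), min(areas), tolerance = 1e-9)

  # never >= 3 concurrent contacts -> unscorable
  s2 <- cm_session("open_close",
    t_ms = c(0, 0, 300, 300), pointer_id = c(0, 1, 0, 1),
    phase = c("down", "down", "up", "up"),
    x_cm = c(4, 6, 4, 6), y_cm = c(4, 4, 4, 4)
  )
  expect_error(score_hand_area(s2), "unscorable")
})

test_that("drawing dissimilarity is zero on identity and n*d for parallel offsets", {
  n <- 200L
  tpl <- template_figure("S")
  expect_equal(grapho_dissimilarity(tpl, tpl, n), 0)

  # straight-segment template, trace offset perpendicularly by d -> n * d
  seg <- rbind(c(0, 0), c(10, 0))
  for (d in c(0.1, 0.5, 2)) {
    off <- cbind(seg[, 1], seg[, 2] + d)
    expect_equal(grapho_dissimilarity(off, seg, n), n * d, tolerance = 1e-9)
  }

  # symmetry
  tr <- unclass(tpl) + 0.3
  expect_equal(
    grapho_dissimilarity(tr, tpl, n), grapho_dissimilarity(tpl, tr, n)
  )

  # dissimilarity strictly increases with parallel offset magnitude
  dis <- vapply(seq(0.05, 1, by = 0.05), function(d) {
    grapho_dissimilarity(cbind(seg[, 1], seg[, 2] + d), seg, n)
  }, 0)
  expect_true(all(diff(dis) > 0))

  # rigid-motion invariance of trace+template together
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  d0 <- grapho_dissimilarity(tr, tpl, n)
  expect_equal(
    grapho_dissimilarity(tr %*% R + 2, unclass(tpl) %*% R + 2, n), d0,
    tolerance = 1e-9
  )
})

test_that("graphomotricity scoring uses the traced events", {
  tpl <- template_figure("M")
  tr <- unclass(tpl)
  s <- cm_session("grapho_M",
    t_ms = seq(0, by = 20, length.out = nrow(tr)),
    pointer_id = 0L,
    phase = c("down", rep("move", nrow(tr) - 2), "up"),
    x_cm = tr[, 1] + 2, y_cm = tr[, 2] + 2 # template offset into the screen
  )
  expect_equal(score_graphomotricity(s, template = tr + 2), 0)
  # degenerate trace: all events at one point
  s1 <- cm_session("grapho_M",
    t_ms = c(0, 20, 40), pointer_id = 0L, phase = c("down", "move", "up"),
    x_cm = rep(3, 3), y_cm = rep(3, 3)
  )
  expect_error(score_graphomotricity(s1), "degenerate")
})

test_that("oculo-manual completion is the 32nd distinct acquisition", {
  dev <- test_device()
  layout <- oculo_layout(dev)
  mk <- function(order_idx, t_downs, extra_idx = integer(), extra_t = numeric()) {
    idx <- c(order_idx, extra_idx)
    tt <- c(t_downs, extra_t)
    o <- order(tt)
    idx <- idx[o]; tt <- tt[o]
    cm_session("oculo_finger",
      t_ms = c(rbind(tt, tt + 20)), pointer_id = 0L,
      phase = rep(c("down", "up"), length(tt)),
      x_cm = rep(layout[idx, 1], each = 2), y_cm = rep(layout[idx, 2], each = 2),
      device = dev
    )
  }
  t32 <- seq(300, 12300, length.out = 32)
  expect_equal(score_oculomanual(mk(1:32, t32)), 12.3)
  # repeated touches on an already-acquired target do not advance completion
  s <- mk(1:32, t32, extra_idx = c(1, 1, 2), extra_t = c(1100, 2100, 3100))
  expect_equal(score_oculomanual(s), 12.3)
  # only 31 acquired -> incomplete error reporting the count
  expect_error(score_oculomanual(mk(1:31, t32[1:31])), "31 of 32")
  # acquisitions after the timeout do not count
  cfg <- scoring_config(oculo_timeout_s = 10)
  expect_error(score_oculomanual(mk(1:32, t32), config = cfg), "of 32")
})

test_that("score_session dispatches and attaches session identity", {
  s <- tap_session(seq(0, 9000, length.out = 9))
  rec <- score_session(s)
  expect_s3_class(rec, "outcome_records")
  expect_equal(rec$measure_name, "tap_count")
  expect_equal(rec$units, "n")
  expect_equal(rec$value, 9)
  expect_equal(rec$participant_id, "T01")

  p <- cm_session("pincer_index",
    t_ms = c(0, 0, 400, 400), pointer_id = c(0, 1, 0, 1),
    phase = c("down", "down", "up", "up"),
    x_cm = c(5, 10, 5, 10), y_cm = c(8, 8, 8, 8)
  )
  recp <- score_session(p)
  expect_equal(recp$measure_name, c("pincer_max_cm", "pincer_min_cm"))
  expect_equal(recp$units, c("cm", "cm"))

  # scorer errors propagate with session identity attached
  bad <- cm_session("pincer_index",
    t_ms = c(0, 100), pointer_id = 0L, phase = c("down", "up"),
    x_cm = c(5, 5), y_cm = c(8, 8)
  )
  expect_error(score_session(bad), "T01")

  # batch of mixed sessions: record count = sum of per-exercise measure counts
  batch <- list(
    simulate_stream("tapping", seed = 1),
    simulate_stream("pincer_index", seed = 2),
    simulate_stream("open_close", seed = 3),
    simulate_stream("oculo_finger", seed = 4)
  )
  recs <- do.call(rbind, lapply(batch, score_session))
  expect_equal(nrow(recs), 1 + 2 + 2 + 1)
})

test_that("scorers are pure: identical session and config give identical records", {
  s <- simulate_stream("open_close", seed = 99)
  expect_identical(score_session(s), score_session(s))
})
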