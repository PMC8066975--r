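# Fixture builders: sessions are constructed in cm and converted to pixels
# through the device profile, so fixtures read like the geometry they encode.

test_device <- function() device_profile(2560, 1710, 100, 100) # 25.6 x 17.1 cm panel

cm_session <- function(exercise_id, t_ms, pointer_id, phase, x_cm, y_cm,
                       device = test_device(), calibration = NULL,
                       duration_s = NA_real_, ...) {
  p <- to_px(x_cm, y_cm, device)
  exercise_session(
    participant_id = "T01", exercise_id = exercise_id,
    duration_s = duration_s,
    events = touch_events(t_ms, pointer_id, phase, p$x_px, p$y_px),
    device = device, calibration = calibration, ...
  )
}

# n down/up tap pairs at the given times (ms), fixed position
tap_session <- function(t_downs, x_cm = 10, y_cm = 8, exercise_id = "tapping",
                        device = test_device(), calibration = NULL, extra = NULL) {
  n <- length(t_downs)
  t <- c(rbind(t_downs, t_downs + 40))
  ev <- list(
    t = t, pid = rep(0L, 2 * n), ph = rep(c("down", "up"), n),
    x = rep(x_cm, 2 * n), y = rep(y_cm, 2 * n)
  )
  if (!is.null(extra)) {
    ev <- lapply(
      stats::setNames(names(ev), names(ev)),
      function(k) c(ev[[k]], extra[[k]])
    )
  }
  cm_session(exercise_id, ev$t, ev$pid, ev$ph, ev$x, ev$y,
    device = device, calibration = calibration, duration_s = 10
  )
}

# five pointers held on a circle, radius path rpath (one value per 50 ms step)
open_close_session <- function(rpath, centre = c(12, 8)) {
  ang <- 2 * pi * (0:4) / 5
  nstep <- length(rpath)
  t <- c(rep(0, 5), rep(seq(50, by = 50, length.out = nstep - 1), each = 5),
    rep(50 * nstep, 5)
  )
  pid <- c(0:4, rep(0:4, nstep - 1), 0:4)
  ph <- c(rep("down", 5), rep("move", 5 * (nstep - 1)), rep("up", 5))
  rr <- c(rep(rpath[1], 5), rep(rpath[-1], each = 5), rep(rpath[nstep], 5))
  aa <- rep(ang, nstep + 1)
  cm_session("open_close", t, pid, ph, centre[1] + rr * cos(aa), centre[2] + rr * sin(aa))
}
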