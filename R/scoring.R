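#' Scoring configuration
#'
#' Tunable constants shared by the six scorers.
#'
#' @param tap_window_s Tapping window in seconds (default 10: both tapping
#'   exercises count touches performed in 10 s).
#' @param spot_radius_cm Radius of the calibrated spot for isolated tapping
#'   (default 1.25 cm; roughly a fingertip pad).
#' @param required_resting_contacts Number of weight-bearing pointers that
#'   must be in contact for an isolated tap to count (default 4, the strict
#'   whole-hand reading; configurable because capacitive panels can merge
#'   adjacent fingertips).
#' @param min_area_contacts Minimum concurrent contacts for a hand-area frame
#'   (default 3, the least that spans an area).
#' @param grapho_resample_n Number of arc-length resampling points per curve
#'   in the drawing dissimilarity (default 200).
#' @param target_radius_cm Acquisition radius around a coordination target
#'   (default 1.0 cm).
#' @param oculo_timeout_s Time limit for acquiring all 32 targets
#'   (default 120 s).
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(tap_window_s = 10, spot_radius_cm = 1.25,
                           required_resting_contacts = 4L, min_area_contacts = 3L,
                           grapho_resample_n = 200L, target_radius_cm = 1.0,
                           oculo_timeout_s = 120) {
  vals <- list(
    tap_window_s = tap_window_s, spot_radius_cm = spot_radius_cm,
    required_resting_contacts = as.integer(required_resting_contacts),
    min_area_contacts = as.integer(min_area_contacts),
    grapho_resample_n = as.integer(grapho_resample_n),
    target_radius_cm = target_radius_cm, oculo_timeout_s = oculo_timeout_s
  )
  if (any(unlist(vals) <= 0)) stop("all scoring_config values must be > 0", call. = FALSE)
  structure(vals, class = "scoring_config")
}

#' Built-in template figures
#'
#' Polyline templates in cm for the four drawing figures: a four-stroke "M",
#' a "3" built from two near-semicircular arcs, an "S" curve, and a 2.5-turn
#' Archimedean spiral. All are sized to a tablet-comfortable 8-10 cm and
#' offset into positive coordinates.
#'
#' @param figure One of `"M"`, `"3"`, `"S"`, `"spiral"`.
#' @return A `polyline` (two-column matrix in cm).
#' @export
template_figure <- function(figure = c("M", "3", "S", "spiral")) {
  figure <- match.arg(figure)
  pts <- switch(figure,
    M = cbind(c(0, 0, 2, 4, 4), c(8, 0, 5, 0, 8)),
    `3` = {
      t1 <- seq(-pi / 2, 0.6 * pi, length.out = 40)
      t2 <- seq(-0.6 * pi, pi / 2, length.out = 40)
      upper <- cbind(2 + 2 * cos(t1), 6 - 2 * sin(t1))
      lower <- cbind(2 + 2 * cos(t2), 2 - 2 * sin(t2))
      rbind(upper, lower)
    },
    S = {
      tt <- seq(0, 1, length.out = 80)
      # two stacked half-turns traced top to bottom
      upper <- cbind(2 + 2 * cos(pi / 2 + tt * pi), 6 + 2 * sin(pi / 2 + tt * pi))
      lower <- cbind(2 + 2 * cos(pi / 2 - tt * pi), 2 + 2 * sin(pi / 2 - tt * pi))
      rbind(upper, lower)
    },
    spiral = {
      th <- seq(0, 2.5 * 2 * pi, length.out = 200)
      r <- 0.25 + 4.75 * th / max(th)
      cbind(5 + r * cos(th), 5 + r * sin(th))
    }
  )
  as_polyline(pts)
}

#' Default 4 x 8 target layout for oculo-manual coordination
#'
#' 32 target centres on a 4-row by 8-column grid, evenly spaced inside the
#' usable screen area with a margin.
#'
#' @param device A `device_profile`.
#' @param rows,cols Grid shape (default 4 x 8).
#' @param margin_cm Margin between screen edge and outer target centres.
#' @return A 32 x 2 matrix of centres in cm, row-major from top-left.
#' @export
oculo_layout <- function(device, rows = 4L, cols = 8L, margin_cm = 1.5) {
  w <- device$screen_w_px / device$px_per_cm_x
  h <- device$screen_h_px / device$px_per_cm_y
  xs <- seq(margin_cm, w - margin_cm, length.out = cols)
  ys <- seq(margin_cm, h - margin_cm, length.out = rows)
  as.matrix(expand.grid(x_cm = xs, y_cm = ys))[, 1:2]
}

# Frames of concurrent contact. At each unique event timestamp t: pointers
# whose [down, up] interval contains t (inclusive at both ends) are in
# contact; each pointer's position is its most recent coordinate at or
# before t. Returns a list of frames (t_ms, ids, pos matrix, downs = pointer
# ids that went down at t).
contact_frames <- function(ev) {
  frames <- list()
  if (nrow(ev) == 0L) return(frames)
  pos <- list() # pointer -> c(x, y)
  alive <- character()
  times <- unique(ev$t_ms)
  idx <- split(seq_len(nrow(ev)), match(ev$t_ms, times))
  for (j in seq_along(times)) {
    rows <- idx[[j]]
    ups <- character()
    downs <- character()
    for (i in rows) {
      pid <- as.character(ev$pointer_id[i])
      ph <- ev$phase[i]
      pos[[pid]] <- c(ev$x_cm[i], ev$y_cm[i])
      if (ph == "down") {
        alive <- union(alive, pid)
        downs <- c(downs, pid)
      } else if (ph == "up") {
        ups <- c(ups, pid)
      }
    }
    # ups at t are still in contact at t (closed interval)
    ids <- alive
    frames[[length(frames) + 1L]] <- list(
      t_ms = times[j], ids = ids,
      pos = do.call(rbind, pos[ids]),
      downs = downs
    )
    alive <- setdiff(alive, ups)
  }
  frames
}

check_exercise <- function(session, prefix) {
  if (!startsWith(session$exercise_id, prefix)) {
    stop("session is '", session$exercise_id, "', expected ", prefix, "*", call. = FALSE)
  }
}

#' Score the tapping exercise
#'
#' Counts finger touches: down events with `0 <= t_ms < tap_window_s * 1000`.
#' Touches are counted on the down phase, matching capacitive-hardware
#' semantics.
#'
#' @param session An `exercise_session` with `exercise_id = "tapping"`.
#' @param config A [scoring_config()].
#' @return Integer tap count.
#' @export
score_tapping <- function(session, config = scoring_config()) {
  check_exercise(session, "tapping")
  ev <- session$events
  sum(ev$phase == "down" & ev$t_ms >= 0 & ev$t_ms < config$tap_window_s * 1000)
}

#' Score isolated-finger tapping with weight-bearing digits
#'
#' Counts down events inside the tapping window that (a) land within
#' `spot_radius_cm` of the calibrated spot centre and (b) occur while at
#' least `required_resting_contacts` other pointers are in contact with the
#' screen (a pointer is in contact from its down to its up, inclusive of the
#' tap instant). Taps failing either condition are not counted.
#'
#' @param session An `exercise_session` with an `iso_tap_*` exercise id and a
#'   `calibration` spot centre in cm.
#' @param config A [scoring_config()].
#' @return Integer count of valid taps.
#' @export
score_isolated_tapping <- function(session, config = scoring_config()) {
  check_exercise(session, "iso_tap_")
  if (is.null(session$calibration)) {
    stop("isolated tapping requires a calibration spot centre", call. = FALSE)
  }
  spot <- session$calibration
  ev <- events_cm(session)
  frames <- contact_frames(ev)
  n <- 0L
  for (fr in frames) {
    if (!length(fr$downs) || fr$t_ms < 0 || fr$t_ms >= config$tap_window_s * 1000) next
    for (pid in fr$downs) {
      p <- fr$pos[match(pid, fr$ids), ]
      inside <- sqrt(sum((p - spot)^2)) <= config$spot_radius_cm
      others <- length(setdiff(fr$ids, pid))
      if (inside && others >= config$required_resting_contacts) n <- n + 1L
    }
  }
  n
}

#' Score the pincer grasp exercise
#'
#' Over every instant with exactly two concurrent contacts, the pincer
#' aperture is the Euclidean cm distance between the two pointers' latest
#' positions. Returns the maximum and minimum aperture over such instants;
#' frames with any other number of contacts (e.g. a transient palm touch)
#' are excluded rather than failing the trial. The exercise is untimed;
#' the trial ends at the last event.
#'
#' @param session An `exercise_session` with a `pincer_*` exercise id.
#' @param config A [scoring_config()].
#' @return Named numeric `c(pincer_max_cm, pincer_min_cm)`, `max >= min`.
#' @export
score_pincer <- function(session, config = scoring_config()) {
  check_exercise(session, "pincer_")
  frames <- contact_frames(events_cm(session))
  dists <- unlist(lapply(frames, function(fr) {
    if (length(fr$ids) != 2L) return(NULL)
    sqrt(sum((fr$pos[1, ] - fr$pos[2, ])^2))
  }))
  if (is.null(dists) || !length(dists)) {
    stop("unscorable pincer trial: no instant with exactly two contacts", call. = FALSE)
  }
  c(pincer_max_cm = max(dists), pincer_min_cm = min(dists))
}

#' Score the hand opening and closing exercise
#'
#' Over every instant with at least `min_area_contacts` concurrent contacts,
#' computes the convex hull area of the current contact positions and returns
#' the maximum (hand open) and minimum (hand closed) area.
#'
#' @param session An `exercise_session` with `exercise_id = "open_close"`.
#' @param config A [scoring_config()].
#' @return Named numeric `c(area_max_cm2, area_min_cm2)`, `max >= min >= 0`.
#' @export
score_hand_area <- function(session, config = scoring_config()) {
  check_exercise(session, "open_close")
  frames <- contact_frames(events_cm(session))
  areas <- unlist(lapply(frames, function(fr) {
    if (length(fr$ids) < config$min_area_contacts) return(NULL)
    convex_hull_area(fr$pos)
  }))
  if (is.null(areas) || !length(areas)) {
    stop("unscorable hand-area trial: no instant with >= ",
      config$min_area_contacts, " contacts",
      call. = FALSE
    )
  }
  c(area_max_cm2 = max(areas), area_min_cm2 = min(areas))
}

#' Trace-template dissimilarity
#'
#' Both curves are resampled to `n` points equally spaced by arc length; the
#' dissimilarity is half the sum, over the resampled points of each curve, of
#' the nearest Euclidean distance to the other curve:
#' `0.5 * (sum_i d(a_i, B) + sum_j d(b_j, A))`. Units are cm (a sum over
#' points, not a mean, so values scale with `n`). It is a premetric:
#' non-negative, zero when the curves coincide, symmetric, and invariant
#' under simultaneous rigid motion of both curves.
#'
#' @param trace,template Polylines (or point matrices) in cm.
#' @param n Resampling count per curve (default 200).
#' @return Dissimilarity in cm.
#' @export
grapho_dissimilarity <- function(trace, template, n = 200L) {
  a <- as_polyline(trace)
  b <- as_polyline(template)
  pa <- resample_polyline(a, n)
  pb <- resample_polyline(b, n)
  0.5 * (sum(nearest_distance(pa, b)) + sum(nearest_distance(pb, a)))
}

#' Score a graphomotricity exercise
#'
#' The trace is the time-ordered sequence of all contact positions in cm
#' (drawing is single-stroke; consecutive duplicates are collapsed).
#' Dissimilarity to the template figure is computed with
#' [grapho_dissimilarity()] at `grapho_resample_n` points.
#'
#' @param session An `exercise_session` with a `grapho_*` exercise id.
#' @param template Template polyline in cm; defaults to the built-in
#'   [template_figure()] matching the exercise id.
#' @param config A [scoring_config()].
#' @return Dissimilarity in cm.
#' @export
score_graphomotricity <- function(session, template = NULL, config = scoring_config()) {
  check_exercise(session, "grapho_")
  if (is.null(template)) {
    template <- template_figure(sub("^grapho_", "", session$exercise_id))
  }
  ev <- events_cm(session)
  if (nrow(ev) < 2L) stop("unscorable drawing trial: fewer than 2 trace points", call. = FALSE)
  trace <- as_polyline(cbind(ev$x_cm, ev$y_cm))
  if (nrow(trace) < 2L) {
    stop("unscorable drawing trial: degenerate trace (<2 distinct points)", call. = FALSE)
  }
  grapho_dissimilarity(trace, template, config$grapho_resample_n)
}

#' Score an oculo-manual coordination exercise
#'
#' A target is acquired by the first down event within `target_radius_cm` of
#' its centre (nearest unacquired target wins if several are in range);
#' targets may be touched in any order and repeated touches on an acquired
#' target do not advance completion. The outcome is the time, in seconds, of
#' the down event that acquires the 32nd distinct target.
#'
#' @param session An `exercise_session` with an `oculo_*` exercise id.
#' @param layout Matrix of target centres in cm; defaults to
#'   [oculo_layout()] on the session's device.
#' @param config A [scoring_config()].
#' @return Completion time in seconds. If not all targets are acquired within
#'   `oculo_timeout_s`, an incomplete-trial error reports how many were.
#' @export
score_oculomanual <- function(session, layout = NULL, config = scoring_config()) {
  check_exercise(session, "oculo_")
  if (is.null(layout)) layout <- oculo_layout(session$device)
  ev <- events_cm(session)
  downs <- ev[ev$phase == "down" & ev$t_ms <= config$oculo_timeout_s * 1000, , drop = FALSE]
  acquired <- rep(FALSE, nrow(layout))
  t_done <- NA_real_
  for (i in seq_len(nrow(downs))) {
    d <- sqrt((layout[, 1] - downs$x_cm[i])^2 + (layout[, 2] - downs$y_cm[i])^2)
    d[acquired] <- Inf
    j <- which.min(d)
    if (d[j] <= config$target_radius_cm) {
      acquired[j] <- TRUE
      if (all(acquired)) {
        t_done <- downs$t_ms[i]
        break
      }
    }
  }
  if (is.na(t_done)) {
    stop("incomplete coordination trial: ", sum(acquired), " of ",
      nrow(layout), " targets acquired within ", config$oculo_timeout_s, " s",
      call. = FALSE
    )
  }
  t_done / 1000
}

#' Score a session into outcome records
#'
#' Dispatches on the session's exercise id to the matching scorer and wraps
#' the result in a fully populated [outcome_records()] table.
#'
#' @param session An `exercise_session`.
#' @param config A [scoring_config()].
#' @param templates Optional named list of template polylines keyed by figure
#'   (`"M"`, `"3"`, `"S"`, `"spiral"`); defaults to the built-ins.
#' @param layout Optional oculo-manual target layout.
#' @return An [outcome_records()] tibble with one row per measure.
#' @export
score_session <- function(session, config = scoring_config(), templates = NULL,
                          layout = NULL) {
  stopifnot(inherits(session, "exercise_session"))
  ex <- session$exercise_id
  res <- tryCatch(
    {
      if (ex == "tapping") {
        c(tap_count = score_tapping(session, config))
      } else if (startsWith(ex, "iso_tap_")) {
        c(valid_tap_count = score_isolated_tapping(session, config))
      } else if (startsWith(ex, "pincer_")) {
        score_pincer(session, config)
      } else if (ex == "open_close") {
        score_hand_area(session, config)
      } else if (startsWith(ex, "grapho_")) {
        fig <- sub("^grapho_", "", ex)
        tpl <- if (!is.null(templates)) templates[[fig]] else NULL
        c(dissimilarity_cm = score_graphomotricity(session, tpl, config))
      } else if (startsWith(ex, "oculo_")) {
        c(completion_s = score_oculomanual(session, layout, config))
      } else {
        stop("unknown exercise_id: ", ex, call. = FALSE)
      }
    },
    error = function(e) {
      stop("scoring ", ex, " for participant ", session$participant_id,
        " (session ", session$session_idx, "): ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  outcome_records(
    participant_id = session$participant_id, exercise_id = ex,
    measure_name = names(res), value = unname(res),
    session_idx = session$session_idx, rater_id = session$rater_id
  )
}
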