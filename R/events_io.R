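#' Device profile
#'
#' Describes the capacitive panel that captured an event stream: screen size
#' in pixels and pixel density per axis. Density is mandatory because all
#' outcome measures are reported in centimetres; it is never defaulted.
#' Anisotropic densities are supported since real panels differ per axis.
#'
#' @param screen_w_px,screen_h_px Screen size in pixels (positive integers).
#' @param px_per_cm_x,px_per_cm_y Pixels per centimetre along each axis
#'   (positive reals).
#' @return An object of class `device_profile`.
#' @examples
#' device_profile(2160, 1440, 84.4, 84.4)
#' @export
device_profile <- function(screen_w_px, screen_h_px, px_per_cm_x, px_per_cm_y) {
  for (nm in c("screen_w_px", "screen_h_px", "px_per_cm_x", "px_per_cm_y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("device_profile: `", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  structure(
    list(
      screen_w_px = as.numeric(screen_w_px), screen_h_px = as.numeric(screen_h_px),
      px_per_cm_x = as.numeric(px_per_cm_x), px_per_cm_y = as.numeric(px_per_cm_y)
    ),
    class = "device_profile"
  )
}

#' A 12-inch 3:2 tablet profile
#'
#' Convenience profile matching a 12-inch, 2160 x 1440 panel
#' (screen approximately 25.6 x 17.1 cm, about 84.4 px/cm on both axes).
#' Useful for simulation and examples; real captures must supply their own
#' measured profile.
#' @return A `device_profile`.
#' @export
default_device <- function() {
  device_profile(2160, 1440, 2160 / 25.6, 1440 / 17.066)
}

exercise_ids <- function() {
  c(
    "tapping",
    paste0("iso_tap_", c("thumb", "index", "middle", "ring", "little")),
    paste0("pincer_", c("index", "middle", "ring", "little")),
    "open_close",
    paste0("grapho_", c("M", "3", "S", "spiral")),
    paste0("oculo_", c("finger", "pen", "pen_drop"))
  )
}

#' Build a touch-event table
#'
#' Events carry milliseconds since the start signal, a pointer id stable from
#' down to up, a phase (`down`, `move`, `up`) and screen coordinates in pixels
#' (origin top-left, x rightward, y downward).
#'
#' @param t_ms Integer milliseconds since the exercise start signal (>= 0).
#' @param pointer_id Non-negative integer id, stable from down to up.
#' @param phase Character, each one of `"down"`, `"move"`, `"up"`.
#' @param x_px,y_px Screen coordinates in pixels.
#' @return A tibble with one validated, time-sorted row per event.
#' @export
touch_events <- function(t_ms = integer(), pointer_id = integer(),
                         phase = character(), x_px = numeric(), y_px = numeric()) {
  ev <- tibble::tibble(
    t_ms = as.numeric(t_ms), pointer_id = as.integer(pointer_id),
    phase = as.character(phase), x_px = as.numeric(x_px), y_px = as.numeric(y_px)
  )
  if (nrow(ev)) ev <- ev[order(ev$t_ms), , drop = FALSE] # stable sort keeps ties in input order
  ev
}

#' Validate a touch-event stream against the per-pointer phase grammar
#'
#' Per pointer id the phase sequence must be exactly
#' down, zero-or-more move, up; times must be non-decreasing within a
#' pointer's lifetime; coordinates must lie within screen bounds; a pointer id
#' may not be reused while still in contact.
#'
#' @param events Event tibble as from [touch_events()].
#' @param device Optional `device_profile` used for the bounds check.
#' @return `events`, invisibly, if valid; otherwise an error naming the
#'   offending pointer id.
#' @export
validate_events <- function(events, device = NULL) {
  req <- c("t_ms", "pointer_id", "phase", "x_px", "y_px")
  if (!all(req %in% names(events))) {
    stop("event stream must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(events) == 0L) return(invisible(events))
  if (any(!events$phase %in% c("down", "move", "up"))) {
    stop("unknown phase value in event stream", call. = FALSE)
  }
  if (any(events$t_ms < 0)) stop("event times must be >= 0", call. = FALSE)
  if (any(!is.finite(events$x_px)) || any(!is.finite(events$y_px))) {
    stop("event coordinates must be finite", call. = FALSE)
  }
  if (!is.null(device)) {
    if (any(events$x_px < 0 | events$x_px > device$screen_w_px |
              events$y_px < 0 | events$y_px > device$screen_h_px)) {
      stop("event coordinates outside screen bounds", call. = FALSE)
    }
  }
  if (is.unsorted(events$t_ms)) stop("events must be sorted by t_ms", call. = FALSE)
  for (pid in unique(events$pointer_id)) {
    ph <- events$phase[events$pointer_id == pid]
    tt <- events$t_ms[events$pointer_id == pid]
    # grammar: (down move* up)+ ; lifetimes may repeat for a reused id
    state <- "up" # not in contact
    for (i in seq_along(ph)) {
      ok <- switch(ph[i],
        down = state == "up",
        move = state == "down",
        up   = state == "down"
      )
      if (!ok) {
        stop("pointer ", pid, ": phase '", ph[i], "' violates the down/move*/up grammar",
          call. = FALSE
        )
      }
      state <- if (ph[i] == "up") "up" else "down"
    }
    if (state != "up") {
      stop("pointer ", pid, ": stream ends while pointer still in contact", call. = FALSE)
    }
    if (is.unsorted(tt)) {
      stop("pointer ", pid, ": non-monotone timestamps within lifetime", call. = FALSE)
    }
  }
  invisible(events)
}

#' Assemble an exercise session
#'
#' One participant x exercise x attempt, bundling the event stream, the device
#' profile, the timing window and (for isolated tapping) the calibrated spot
#' centre.
#'
#' @param participant_id,rater_id Identifier strings.
#' @param exercise_id One of the known exercise ids (see Details).
#' @param hand `"left"` or `"right"`.
#' @param session_idx Session index (integer >= 1).
#' @param duration_s Timing window in seconds where applicable, else `NA`.
#' @param events Validated event tibble.
#' @param device A `device_profile`.
#' @param calibration Optional numeric `c(x_cm, y_cm)` spot centre for
#'   `iso_tap_*` exercises.
#'
#' @details Exercise ids: `tapping`; `iso_tap_{thumb,index,middle,ring,little}`;
#' `pincer_{index,middle,ring,little}`; `open_close`;
#' `grapho_{M,3,S,spiral}`; `oculo_{finger,pen,pen_drop}`.
#'
#' @return An object of class `exercise_session`.
#' @export
exercise_session <- function(participant_id, exercise_id, hand = "right",
                             session_idx = 1L, rater_id = "A", duration_s = NA_real_,
                             events = touch_events(), device, calibration = NULL) {
  if (!exercise_id %in% exercise_ids()) {
    stop("unknown exercise_id: ", exercise_id, call. = FALSE)
  }
  if (!hand %in% c("left", "right")) stop("hand must be 'left' or 'right'", call. = FALSE)
  if (!inherits(device, "device_profile")) stop("device must be a device_profile", call. = FALSE)
  if (!is.na(duration_s) && duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (!is.null(calibration) &&
        (!is.numeric(calibration) || length(calibration) != 2L || any(!is.finite(calibration)))) {
    stop("calibration must be c(x_cm, y_cm)", call. = FALSE)
  }
  validate_events(events, device)
  structure(
    list(
      participant_id = as.character(participant_id),
      exercise_id = exercise_id, hand = hand,
      session_idx = as.integer(session_idx), rater_id = as.character(rater_id),
      duration_s = as.numeric(duration_s), events = events, device = device,
      calibration = calibration
    ),
    class = "exercise_session"
  )
}

#' @export
print.exercise_session <- function(x, ...) {
  cat(
    "<exercise_session> ", x$exercise_id, " | participant ", x$participant_id,
    " | session ", x$session_idx, " | rater ", x$rater_id,
    " | ", nrow(x$events), " events\n",
    sep = ""
  )
  invisible(x)
}

#' Convert pixel coordinates to centimetres
#'
#' @param x_px,y_px Pixel coordinates (vectors).
#' @param device A `device_profile`.
#' @return A list with numeric vectors `x_cm`, `y_cm`.
#' @export
to_cm <- function(x_px, y_px, device) {
  stopifnot(inherits(device, "device_profile"))
  list(x_cm = x_px / device$px_per_cm_x, y_cm = y_px / device$px_per_cm_y)
}

#' Convert centimetre coordinates to pixels
#'
#' Inverse of [to_cm()].
#' @param x_cm,y_cm Coordinates in centimetres.
#' @param device A `device_profile`.
#' @return A list with numeric vectors `x_px`, `y_px`.
#' @export
to_px <- function(x_cm, y_cm, device) {
  stopifnot(inherits(device, "device_profile"))
  list(x_px = x_cm * device$px_per_cm_x, y_px = y_cm * device$px_per_cm_y)
}

events_cm <- function(session) {
  p <- to_cm(session$events$x_px, session$events$y_px, session$device)
  tibble::tibble(
    t_ms = session$events$t_ms, pointer_id = session$events$pointer_id,
    phase = session$events$phase, x_cm = p$x_cm, y_cm = p$y_cm
  )
}

#' Read an exercise session from a JSONL event log and manifest
#'
#' The event log holds one JSON object per line:
#' `{"t_ms": int, "pointer_id": int, "phase": "down|move|up", "x_px": num,
#' "y_px": num}`. The manifest JSON holds the session metadata
#' (`participant_id`, `exercise_id`, `hand`, `session_idx`, `rater_id`,
#' `duration_s`, optional `calibration`, and a `device` object).
#'
#' @param events_path Path to the JSONL event log.
#' @param manifest_path Path to the manifest JSON.
#' @param device Optional `device_profile` overriding the manifest's.
#' @return A validated [exercise_session()]. Malformed lines raise a parse
#'   error naming the line number; grammar violations raise a validation
#'   error naming the pointer id.
#' @export
read_stream <- function(events_path, manifest_path, device = NULL) {
  if (!file.exists(events_path)) stop("no such event log: ", events_path, call. = FALSE)
  if (!file.exists(manifest_path)) stop("no such manifest: ", manifest_path, call. = FALSE)
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE)
  if (is.null(device)) {
    if (is.null(man$device)) stop("manifest has no device and none supplied", call. = FALSE)
    device <- device_profile(
      man$device$screen_w_px, man$device$screen_h_px,
      man$device$px_per_cm_x, man$device$px_per_cm_y
    )
  }
  lines <- readLines(events_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]), error = function(e) NULL)
    need <- c("t_ms", "pointer_id", "phase", "x_px", "y_px")
    if (is.null(obj) || !all(need %in% names(obj))) {
      stop("parse error in ", events_path, " at line ", i, call. = FALSE)
    }
    rows[[i]] <- obj[need]
  }
  ev <- if (length(rows)) {
    touch_events(
      t_ms = vapply(rows, function(r) as.numeric(r$t_ms), 0),
      pointer_id = vapply(rows, function(r) as.integer(r$pointer_id), 0L),
      phase = vapply(rows, function(r) as.character(r$phase), ""),
      x_px = vapply(rows, function(r) as.numeric(r$x_px), 0),
      y_px = vapply(rows, function(r) as.numeric(r$y_px), 0)
    )
  } else {
    touch_events()
  }
  exercise_session(
    participant_id = man$participant_id, exercise_id = man$exercise_id,
    hand = man$hand %||% "right", session_idx = man$session_idx %||% 1L,
    rater_id = man$rater_id %||% "A", duration_s = man$duration_s %||% NA_real_,
    events = ev, device = device,
    calibration = if (!is.null(man$calibration)) as.numeric(unlist(man$calibration))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an exercise session to a JSONL event log and manifest
#'
#' @param session An [exercise_session()].
#' @param events_path,manifest_path Output paths.
#' @return Invisibly, the two paths. Round-trips losslessly with
#'   [read_stream()].
#' @export
write_stream <- function(session, events_path, manifest_path) {
  stopifnot(inherits(session, "exercise_session"))
  ev <- session$events
  lines <- vapply(seq_len(nrow(ev)), function(i) {
    jsonlite::toJSON(
      list(
        t_ms = ev$t_ms[i], pointer_id = ev$pointer_id[i], phase = ev$phase[i],
        x_px = ev$x_px[i], y_px = ev$y_px[i]
      ),
      auto_unbox = TRUE, digits = NA
    )
  }, "")
  writeLines(lines, events_path)
  man <- list(
    participant_id = session$participant_id, exercise_id = session$exercise_id,
    hand = session$hand, session_idx = session$session_idx,
    rater_id = session$rater_id, duration_s = session$duration_s,
    calibration = session$calibration,
    device = unclass(session$device)
  )
  jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(events_path, manifest_path))
}

measure_units <- function() {
  c(
    tap_count = "n", valid_tap_count = "n",
    pincer_max_cm = "cm", pincer_min_cm = "cm",
    area_max_cm2 = "cm2", area_min_cm2 = "cm2",
    dissimilarity_cm = "cm", completion_s = "s"
  )
}

#' Build an outcome-record table
#'
#' One row per scored measure: participant, exercise, measure name, value,
#' units, session index and rater. Units are checked against the measure name
#' (`tap_count`/`valid_tap_count` in `n`; pincer distances and dissimilarity
#' in `cm`; areas in `cm2`; completion times in `s`).
#'
#' @param participant_id,exercise_id,measure_name,units,rater_id Character
#'   vectors (recycled).
#' @param value Numeric values; counts must be non-negative integers,
#'   distances/areas/times non-negative reals.
#' @param session_idx Integer session indices.
#' @return A tibble of class `outcome_records`.
#' @export
outcome_records <- function(participant_id = character(), exercise_id = character(),
                            measure_name = character(), value = numeric(),
                            units = NULL, session_idx = 1L, rater_id = "A") {
  known <- measure_units()
  if (is.null(units)) units <- unname(known[measure_name])
  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    exercise_id = as.character(exercise_id),
    measure_name = as.character(measure_name),
    value = as.numeric(value), units = as.character(units),
    session_idx = as.integer(session_idx), rater_id = as.character(rater_id)
  )
  bad <- out$measure_name %in% names(known) & out$units != known[out$measure_name]
  if (any(bad)) {
    stop("units do not match measure_name for: ",
      paste(unique(out$measure_name[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(out$units == "n" & (out$value < 0 | out$value != round(out$value)))) {
    stop("count measures must be non-negative integers", call. = FALSE)
  }
  if (any(out$units != "n" & out$value < 0)) {
    stop("distance/area/time measures must be non-negative", call. = FALSE)
  }
  class(out) <- c("outcome_records", class(out))
  out
}

#' Write an outcome table to CSV
#'
#' Tidy long format, one record per row, stable column order
#' (participant_id, exercise_id, measure_name, value, units, session_idx,
#' rater_id), UTF-8, comma separated, `.` decimal.
#'
#' @param records An [outcome_records()] tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_outcomes <- function(records, path) {
  cols <- c(
    "participant_id", "exercise_id", "measure_name", "value", "units",
    "session_idx", "rater_id"
  )
  stopifnot(all(cols %in% names(records)))
  utils::write.csv(as.data.frame(records)[, cols], path, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Read an outcome table written by [write_outcomes()]
#'
#' @param path CSV path.
#' @return An [outcome_records()] tibble.
#' @export
read_outcomes <- function(path) {
  if (!file.exists(path)) stop("no such outcome table: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  outcome_records(
    participant_id = d$participant_id, exercise_id = d$exercise_id,
    measure_name = d$measure_name, value = d$value, units = d$units,
    session_idx = d$session_idx, rater_id = d$rater_id
  )
}

#' Read a template polyline from CSV
#'
#' Template figures are stored as CSV polylines with columns `x_cm`, `y_cm`.
#' @param path CSV path.
#' @return A two-column numeric matrix (x_cm, y_cm).
#' @export
read_template <- function(path) {
  if (!file.exists(path)) stop("no such template: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("x_cm", "y_cm") %in% names(d)))
  as_polyline(cbind(d$x_cm, d$y_cm))
}

#' Write a template polyline to CSV
#'
#' @param poly Two-column matrix of points in cm.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_template <- function(poly, path) {
  utils::write.csv(
    data.frame(x_cm = poly[, 1], y_cm = poly[, 2]), path, row.names = FALSE
  )
  invisible(path)
}
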