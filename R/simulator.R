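#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so that
#' simulation helpers never leak global random state.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  code
}

# normal draw truncated to [lower, upper] by resampling (the outcome model is
# a normal summary truncated at physical bounds)
rnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Impairment profile: expected outcome distributions per severity group
#'
#' Mean and SD of each outcome measure for a severity group, used by the
#' simulator as the target distributions of scored outcomes. The defaults
#' are the published group summaries of an 88-participant stroke cohort
#' (69 mild / 19 moderate by FMA-UE): e.g. tapping 43.97 (14.47) taps per
#' 10 s for mild vs 25.26 (13.51) for moderate.
#'
#' @param label `"mild"` or `"moderate"`.
#' @return A list of class `impairment_profile` with elements `tapping`,
#'   `iso_tap` (per finger), `pincer` (per finger, min/max cm), `area`
#'   (close/open cm^2), `grapho` (per figure, dissimilarity cm), `oculo`
#'   (per condition, completion s); each leaf is `c(mean, sd)`.
#' @export
impairment_profile <- function(label = c("mild", "moderate")) {
  label <- match.arg(label)
  p <- if (label == "mild") {
    list(
      tapping = c(43.97, 14.47),
      iso_tap = list(
        thumb = c(34.44, 11.46), index = c(37.65, 12.43), middle = c(34.34, 11.24),
        ring = c(28.18, 9.10), little = c(28.86, 9.92)
      ),
      pincer = list(
        index = list(min = c(1.32, 0.70), max = c(13.05, 2.04)),
        middle = list(min = c(1.25, 0.74), max = c(17.94, 2.28)),
        ring = list(min = c(1.17, 0.85), max = c(15.81, 2.35)),
        little = list(min = c(1.39, 0.92), max = c(15.59, 2.87))
      ),
      area = list(close = c(2.48, 0.73), open = c(95.47, 23.84)),
      grapho = list(
        M = c(58.25, 34.76), `3` = c(34.19, 21.41),
        S = c(33.82, 16.62), spiral = c(129.30, 77.22)
      ),
      oculo = list(
        finger = c(28.37, 12.60), pen = c(29.79, 11.91), pen_drop = c(80.52, 32.34)
      )
    )
  } else {
    list(
      tapping = c(25.26, 13.51),
      iso_tap = list(
        thumb = c(17.71, 11.08), index = c(18.31, 11.21), middle = c(17.50, 9.29),
        ring = c(12.00, 9.01), little = c(13.50, 8.50)
      ),
      pincer = list(
        index = list(min = c(1.73, 1.20), max = c(10.31, 2.29)),
        middle = list(min = c(1.59, 0.71), max = c(12.39, 2.48)),
        ring = list(min = c(2.12, 1.43), max = c(12.13, 2.49)),
        little = list(min = c(2.128, 0.953), max = c(12.69, 4.24))
      ),
      area = list(close = c(2.47, 0.54), open = c(67.88, 25.60)),
      grapho = list(
        M = c(82.57, 37.71), `3` = c(52.09, 23.39),
        S = c(40.01, 9.92), spiral = c(145.26, 64.58)
      ),
      oculo = list(
        finger = c(35.87, 10.58), pen = c(39.45, 11.18), pen_drop = c(163.07, 87.81)
      )
    )
  }
  structure(c(list(label = label), p), class = "impairment_profile")
}

# per-template calibration cache: translation offset magnitude -> scored
# dissimilarity, inverted to realise a drawn target value
.grapho_cache <- new.env(parent = emptyenv())

grapho_offset_for <- function(figure, d_target, n = 200L) {
  key <- paste0(figure, ":", n)
  cal <- .grapho_cache[[key]]
  if (is.null(cal)) {
    tpl <- template_figure(figure)
    v <- c(1, 1) / sqrt(2)
    a_grid <- c(0, exp(seq(log(0.002), log(3), length.out = 14)))
    g <- vapply(a_grid, function(a) {
      tr <- unclass(tpl) + matrix(a * v, nrow(tpl), 2, byrow = TRUE)
      grapho_dissimilarity(tr, tpl, n)
    }, 0)
    cal <- list(a = a_grid, g = g)
    .grapho_cache[[key]] <- cal
  }
  if (d_target <= cal$g[1]) return(0)
  if (d_target >= cal$g[length(cal$g)]) {
    # extrapolate with the final (near-linear) slope
    m <- length(cal$g)
    slope <- (cal$a[m] - cal$a[m - 1]) / (cal$g[m] - cal$g[m - 1])
    return(cal$a[m] + slope * (d_target - cal$g[m]))
  }
  stats::approx(cal$g, cal$a, xout = d_target, ties = "ordered")$y
}

#' Simulate a touch-event stream for one exercise
#'
#' Generates an event stream obeying the down/move*/up grammar whose scored
#' outcome follows the profile's distribution for that exercise: tapping
#' streams are sequences of down/up pairs; pincer streams are two-contact
#' radial trajectories attaining drawn extrema; open-close streams are
#' five-contact radial cycles between drawn open/closed areas; drawing
#' streams are template traversals offset to a drawn dissimilarity;
#' coordination streams visit all 32 targets with the drawn completion time.
#' Deterministic given `seed`. The drawn target outcome(s) are attached as
#' `attr(session, "target")`.
#'
#' @param exercise_id One of the known exercise ids.
#' @param profile An [impairment_profile()].
#' @param device A `device_profile`.
#' @param seed Integer seed.
#' @param participant_id,session_idx,rater_id Session identity fields.
#' @return An [exercise_session()] (validated).
#' @export
simulate_stream <- function(exercise_id, profile = impairment_profile("mild"),
                            device = default_device(), seed = 1L,
                            participant_id = "sim", session_idx = 1L, rater_id = "A") {
  stopifnot(inherits(profile, "impairment_profile"))
  if (!exercise_id %in% exercise_ids()) {
    stop("unknown exercise_id: ", exercise_id, call. = FALSE)
  }
  with_seed(seed, {
    w_cm <- device$screen_w_px / device$px_per_cm_x
    h_cm <- device$screen_h_px / device$px_per_cm_y
    centre <- c(w_cm / 2, h_cm / 2)
    mk <- function(t, pid, ph, x_cm, y_cm) {
      p <- to_px(x_cm, y_cm, device)
      touch_events(round(t), pid, ph, p$x_px, p$y_px)
    }
    target <- NULL
    ev <- NULL
    calibration <- NULL
    duration_s <- NA_real_

    if (exercise_id == "tapping") {
      duration_s <- 10
      count <- round(rnorm_trunc(1, profile$tapping[1], profile$tapping[2]))
      target <- c(tap_count = count)
      if (count > 0) {
        t_down <- seq(0, 9900, length.out = count)
        ev <- mk(
          t = c(rbind(t_down, t_down + 40)),
          pid = 0L,
          ph = rep(c("down", "up"), count),
          x_cm = centre[1], y_cm = centre[2]
        )
      } else {
        ev <- touch_events()
      }
    } else if (startsWith(exercise_id, "iso_tap_")) {
      duration_s <- 10
      finger <- sub("^iso_tap_", "", exercise_id)
      ms <- profile$iso_tap[[finger]]
      count <- round(rnorm_trunc(1, ms[1], ms[2]))
      target <- c(valid_tap_count = count)
      calibration <- centre
      # four weight-bearing pointers held down for the whole window
      ang <- seq(0.3, 2.2, length.out = 4)
      rest_x <- centre[1] + 5 * cos(ang)
      rest_y <- centre[2] + 3.5 * sin(ang)
      rest_down <- mk(rep(0, 4), 1:4, "down", rest_x, rest_y)
      rest_up <- mk(rep(10800, 4), 1:4, "up", rest_x, rest_y)
      taps <- if (count > 0) {
        t_down <- seq(5, 9900, length.out = count)
        mk(
          t = c(rbind(t_down, t_down + 40)), pid = 0L,
          ph = rep(c("down", "up"), count),
          x_cm = centre[1], y_cm = centre[2]
        )
      } else {
        touch_events()
      }
      ev <- touch_events(
        t_ms = c(rest_down$t_ms, taps$t_ms, rest_up$t_ms),
        pointer_id = c(rest_down$pointer_id, taps$pointer_id, rest_up$pointer_id),
        phase = c(rest_down$phase, taps$phase, rest_up$phase),
        x_px = c(rest_down$x_px, taps$x_px, rest_up$x_px),
        y_px = c(rest_down$y_px, taps$y_px, rest_up$y_px)
      )
    } else if (startsWith(exercise_id, "pincer_")) {
      finger <- sub("^pincer_", "", exercise_id)
      # the panel itself bounds the aperture: thumb sits at a 1.5 cm margin
      dmax_cap <- w_cm - 3
      repeat {
        dmin <- rnorm_trunc(1, profile$pincer[[finger]]$min[1], profile$pincer[[finger]]$min[2])
        dmax <- rnorm_trunc(1, profile$pincer[[finger]]$max[1], profile$pincer[[finger]]$max[2],
          upper = dmax_cap
        )
        if (dmax > dmin) break
      }
      target <- c(pincer_max_cm = dmax, pincer_min_cm = dmin)
      thumb <- c(1.5, centre[2])
      # radial trajectory mid -> max -> min, 50 ms steps
      dpath <- c(
        seq((dmin + dmax) / 2, dmax, length.out = 15),
        seq(dmax, dmin, length.out = 30)[-1]
      )
      tt <- seq(50, by = 50, length.out = length(dpath))
      finger_x <- thumb[1] + dpath
      ev <- touch_events(
        t_ms = c(0, 0, tt, max(tt) + 50, max(tt) + 50),
        pointer_id = c(0L, 1L, rep(1L, length(dpath)), 0L, 1L),
        phase = c("down", "down", rep("move", length(dpath)), "up", "up"),
        x_px = to_px(c(thumb[1], finger_x[1], finger_x, thumb[1], finger_x[length(dpath)]),
          0, device
        )$x_px,
        y_px = to_px(0, rep(centre[2], length(dpath) + 4), device)$y_px
      )
    } else if (exercise_id == "open_close") {
      # largest pentagon of contacts that fits the panel bounds the open area
      r_cap <- min(w_cm, h_cm) / 2 - 0.5
      a_cap <- 2.5 * sin(2 * pi / 5) * r_cap^2
      repeat {
        a_open <- rnorm_trunc(1, profile$area$open[1], profile$area$open[2], upper = a_cap)
        a_close <- rnorm_trunc(1, profile$area$close[1], profile$area$close[2])
        if (a_open > a_close) break
      }
      target <- c(area_max_cm2 = a_open, area_min_cm2 = a_close)
      # regular pentagon of contact points: area = (5/2) r^2 sin(72 deg)
      r_of <- function(area) sqrt(area / (2.5 * sin(2 * pi / 5)))
      ang <- 2 * pi * (0:4) / 5 - pi / 2
      # closed -> open -> closed, one cycle, 50 ms steps
      rpath <- c(
        seq(r_of(a_close), r_of(a_open), length.out = 20),
        seq(r_of(a_open), r_of(a_close), length.out = 20)[-1]
      )
      nstep <- length(rpath)
      t_ms <- c(rep(0, 5), rep(seq(50, by = 50, length.out = nstep - 1), each = 5),
        rep(50 * nstep, 5)
      )
      pid <- c(0:4, rep(0:4, nstep - 1), 0:4)
      ph <- c(rep("down", 5), rep("move", 5 * (nstep - 1)), rep("up", 5))
      rr <- c(rep(rpath[1], 5), rep(rpath[-1], each = 5), rep(rpath[nstep], 5))
      aa <- rep(ang, nstep + 1)
      ev <- mk(t_ms, pid, ph, centre[1] + rr * cos(aa), centre[2] + rr * sin(aa))
    } else if (startsWith(exercise_id, "grapho_")) {
      fig <- sub("^grapho_", "", exercise_id)
      ms <- profile$grapho[[fig]]
      d_target <- rnorm_trunc(1, ms[1], ms[2])
      target <- c(dissimilarity_cm = d_target)
      a <- grapho_offset_for(fig, d_target)
      tpl <- template_figure(fig)
      tr <- unclass(tpl) + matrix(a * c(1, 1) / sqrt(2), nrow(tpl), 2, byrow = TRUE)
      npt <- nrow(tr)
      ev <- mk(
        t = c(0, seq(20, by = 20, length.out = npt - 2), 20 * npt),
        pid = 0L,
        ph = c("down", rep("move", npt - 2), "up"),
        x_cm = tr[, 1], y_cm = tr[, 2]
      )
    } else if (startsWith(exercise_id, "oculo_")) {
      cond <- sub("^oculo_", "", exercise_id)
      ms <- profile$oculo[[cond]]
      total_s <- rnorm_trunc(1, ms[1], ms[2], lower = 2)
      layout <- oculo_layout(device)
      ord <- sample.int(nrow(layout))
      w <- stats::rexp(nrow(layout))
      t_down <- round(cumsum(w) / sum(w) * total_s * 1000)
      t_down[length(t_down)] <- round(total_s * 1000)
      # enforce strictly increasing downs with room for the up in between
      for (i in seq_along(t_down)[-1]) {
        t_down[i] <- max(t_down[i], t_down[i - 1] + 4)
      }
      t_up <- t_down + pmin(25, c(diff(t_down) - 2, 25))
      target <- c(completion_s = t_down[length(t_down)] / 1000)
      ev <- mk(
        t = c(rbind(t_down, t_up)),
        pid = 0L,
        ph = rep(c("down", "up"), nrow(layout)),
        x_cm = rep(layout[ord, 1], each = 2), y_cm = rep(layout[ord, 2], each = 2)
      )
    }

    session <- exercise_session(
      participant_id = participant_id, exercise_id = exercise_id,
      session_idx = session_idx, rater_id = rater_id, duration_s = duration_s,
      events = ev, device = device, calibration = calibration
    )
    attr(session, "target") <- target
    session
  })
}

cohort_measures <- function() {
  c(
    "tapping",
    paste0("iso_tap_", c("thumb", "index", "middle", "ring", "little")),
    paste0("pincer_", rep(c("index", "middle", "ring", "little"), each = 2), c("_min", "_max")),
    "area_close", "area_open",
    paste0("grapho_", c("M", "3", "S", "spiral")),
    paste0("oculo_", c("finger", "pen", "pen_drop"))
  )
}

profile_mean_sd <- function(profile, measure) {
  if (measure == "tapping") {
    profile$tapping
  } else if (startsWith(measure, "iso_tap_")) {
    profile$iso_tap[[sub("^iso_tap_", "", measure)]]
  } else if (startsWith(measure, "pincer_")) {
    parts <- strsplit(sub("^pincer_", "", measure), "_")[[1]]
    profile$pincer[[parts[1]]][[parts[2]]]
  } else if (measure == "area_close") {
    profile$area$close
  } else if (measure == "area_open") {
    profile$area$open
  } else if (startsWith(measure, "grapho_")) {
    profile$grapho[[sub("^grapho_", "", measure)]]
  } else if (startsWith(measure, "oculo_")) {
    profile$oculo[[sub("^oculo_", "", measure)]]
  } else {
    stop("unknown measure: ", measure, call. = FALSE)
  }
}

#' Simulate a cohort outcome table with severity groups
#'
#' Draws per-participant outcomes for every measure from the two group
#' profiles (normal, truncated at physical bounds; counts rounded), FMA-UE
#' scores uniformly within each group's defining range (mild 47-66, moderate
#' 19-46), and clinical columns constructed with configurable correlation to
#' a chosen outcome measure via a Gaussian latent model.
#'
#' @param n_mild,n_moderate Group sizes (default 69 / 19).
#' @param seed Integer seed.
#' @param profiles List with elements `mild`, `moderate`
#'   ([impairment_profile()]s).
#' @param clinical Named list describing clinical columns, each
#'   `list(measure = <outcome column>, rho = <target correlation>)`.
#' @return A list of three tibbles: `outcomes` (wide, participant x
#'   measure), `fma` (participant_id, fma_ue, group), `clinical`.
#' @export
simulate_cohort <- function(n_mild = 69L, n_moderate = 19L, seed = 1L,
                            profiles = list(
                              mild = impairment_profile("mild"),
                              moderate = impairment_profile("moderate")
                            ),
                            clinical = list(
                              bbt = list(measure = "tapping", rho = 0.70),
                              nhpt = list(measure = "tapping", rho = -0.53),
                              fma_hand = list(measure = "tapping", rho = 0.64)
                            )) {
  stopifnot(n_mild >= 1L, n_moderate >= 1L)
  with_seed(seed, {
    n <- n_mild + n_moderate
    grp <- rep(c("mild", "moderate"), c(n_mild, n_moderate))
    ids <- sprintf("P%03d", seq_len(n))
    outcomes <- tibble::tibble(participant_id = ids)
    for (m in cohort_measures()) {
      v <- numeric(n)
      for (g in c("mild", "moderate")) {
        ms <- profile_mean_sd(profiles[[g]], m)
        draw <- rnorm_trunc(sum(grp == g), ms[1], ms[2])
        if (m == "tapping" || startsWith(m, "iso_tap_")) draw <- round(draw)
        v[grp == g] <- draw
      }
      outcomes[[m]] <- v
    }
    fma <- tibble::tibble(
      participant_id = ids,
      fma_ue = ifelse(grp == "mild",
        sample(47:66, n, replace = TRUE),
        sample(19:46, n, replace = TRUE)
      ),
      group = grp
    )
    clin <- tibble::tibble(participant_id = ids)
    for (nm in names(clinical)) {
      spec <- clinical[[nm]]
      z <- as.numeric(scale(outcomes[[spec$measure]]))
      clin[[nm]] <- spec$rho * z + sqrt(1 - spec$rho^2) * stats::rnorm(n)
    }
    list(outcomes = outcomes, fma = fma, clinical = clin)
  })
}

#' Expected scored outcome under a profile's outcome model
#'
#' The simulator draws outcomes from a normal distribution truncated at the
#' measure's physical lower bound (0 for counts, distances, areas and
#' dissimilarities; 2 s for coordination times, the least a 32-target sweep
#' can plausibly take). This returns the closed-form mean of that truncated
#' distribution, `mu + sigma * phi(a) / (1 - Phi(a))` with
#' `a = (lower - mu) / sigma` -- the value a large Monte-Carlo mean of
#' scored outcomes converges to. For mild-range parameters the truncation is
#' slight and this is close to the configured mean.
#'
#' @param profile An [impairment_profile()].
#' @param measure A cohort measure name (e.g. `"tapping"`,
#'   `"pincer_index_max"`, `"grapho_S"`, `"oculo_finger"`).
#' @return The expected scored outcome.
#' @export
expected_outcome <- function(profile, measure) {
  ms <- profile_mean_sd(profile, measure)
  lower <- if (startsWith(measure, "oculo_")) 2 else 0
  if (ms[2] == 0) {
    return(max(ms[1], lower))
  }
  a <- (lower - ms[1]) / ms[2]
  ms[1] + ms[2] * stats::dnorm(a) / (1 - stats::pnorm(a))
}

#' Variance components of the two-way reliability model
#'
#' @param participant,session,error Variances (>= 0, not all zero) of the
#'   participant, session/rater, and residual components.
#' @return A list of class `variance_components` with the theoretical
#'   ICC(2,1) `participant / (participant + session + error)` attached.
#' @export
variance_components <- function(participant, session, error) {
  v <- c(participant = participant, session = session, error = error)
  if (any(v < 0)) stop("variance components must be >= 0", call. = FALSE)
  if (all(v == 0)) stop("variance components must not all be zero", call. = FALSE)
  structure(
    as.list(v),
    theoretical_icc = participant / sum(v),
    class = "variance_components"
  )
}

#' Simulate two-way reliability data
#'
#' Draws `y_ij = mu + p_i + s_j + e_ij` with independent zero-mean normal
#' components of the given variances; the theoretical ICC(2,1) is
#' `sigma2_p / (sigma2_p + sigma2_s + sigma2_e)`.
#'
#' @param n Participants (rows, >= 2).
#' @param k Sessions/raters (columns, >= 2).
#' @param mu Grand mean.
#' @param vc A [variance_components()] object.
#' @param seed Integer seed.
#' @return An `n` x `k` numeric matrix with the theoretical ICC as
#'   `attr(, "theoretical_icc")`.
#' @export
simulate_reliability <- function(n, k, mu = 0, vc = variance_components(9, 0.5, 0.5),
                                 seed = 1L) {
  stopifnot(n >= 2L, k >= 2L, inherits(vc, "variance_components"))
  with_seed(seed, {
    p <- stats::rnorm(n, 0, sqrt(vc$participant))
    s <- stats::rnorm(k, 0, sqrt(vc$session))
    e <- matrix(stats::rnorm(n * k, 0, sqrt(vc$error)), n, k)
    y <- mu + outer(p, s, "+") + e
    attr(y, "theoretical_icc") <- attr(vc, "theoretical_icc")
    y
  })
}
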