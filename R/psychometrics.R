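#' Pearson convergent validity with strength bands
#'
#' Pearson correlation between an instrumented measure and a clinical score,
#' with the conventional strength band assigned from `|r|`: excellent
#' (> 0.8), strong (0.6, 0.8], moderate (0.4, 0.6], weak (0.2, 0.4],
#' very weak (<= 0.2). Bands use the magnitude because validity against
#' inverted scales (time-to-complete tests) is legitimately negative.
#'
#' @param x,y Numeric vectors of paired scores (>= 3 complete pairs).
#' @return A list with `r`, `p` (two-sided), `band`, and `n`.
#' @export
pearson_validity <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("pearson_validity: need >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_validity: undefined correlation (zero variance)", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(
    r = unname(ct$estimate), p = ct$p.value,
    band = validity_band(unname(ct$estimate)), n = length(x)
  )
}

#' Strength band for a correlation magnitude
#'
#' @param r Correlation coefficient(s).
#' @return Character vector of bands; a total, deterministic function of
#'   `|r|` on `[0, 1]`.
#' @export
validity_band <- function(r) {
  as.character(cut(abs(r),
    breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
    labels = c("very weak", "weak", "moderate", "strong", "excellent"),
    right = TRUE
  ))
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measurement intraclass
#' correlation from the two-way ANOVA without replication:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`, where MSR, MSC
#' and MSE are the rows (participants), columns (sessions/raters) and error
#' mean squares. The p-value is the upper tail of the row-effect F test,
#' `F = MSR / MSE` on `(n - 1, (n - 1)(k - 1))` degrees of freedom.
#'
#' @param data Numeric matrix, rows = participants (n >= 2), columns =
#'   sessions or raters (k >= 2), no missing cells.
#' @return A list with `icc`, `p`, `n`, `k`, and the mean squares
#'   (`msr`, `msc`, `mse`).
#' @export
icc_2_1 <- function(data) {
  m <- as.matrix(data)
  if (any(!is.finite(m))) stop("icc_2_1: matrix must be complete and finite", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("icc_2_1: need n >= 2 participants and k >= 2 columns", call. = FALSE)
  grand <- mean(m)
  sst <- sum((m - grand)^2)
  if (sst == 0) stop("icc_2_1: undefined (zero total variance)", call. = FALSE)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  p <- if (mse > 0) {
    stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  } else {
    0 # rows differ with no residual error: row effect certain
  }
  list(icc = icc, p = p, n = n, k = k, msr = msr, msc = msc, mse = mse)
}

#' Standard error of measurement
#'
#' `SEM = SD(scores) * sqrt(1 - ICC)`, with the n-1 denominator SD taken
#' over the pooled scores of the intra-rater session pair. Quantifies the
#' precision of an individual score in the measure's own units.
#'
#' @param scores Numeric vector of all reliability-subsample measurements
#'   (>= 2 values).
#' @param icc Reliability coefficient (<= 1).
#' @return SEM in measure units (>= 0).
#' @export
sem <- function(scores, icc) {
  if (length(scores) < 2L) stop("sem: need >= 2 scores", call. = FALSE)
  if (icc > 1) stop("sem: icc must be <= 1", call. = FALSE)
  stats::sd(scores) * sqrt(1 - icc)
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC95 = 1.96 * sqrt(2) * SEM`: the smallest change in an individual's
#' score exceeding measurement error with 95% confidence over two occasions.
#'
#' @param sem Standard error of measurement (>= 0).
#' @return MDC95 in measure units.
#' @export
mdc95 <- function(sem) {
  if (any(sem < 0)) stop("mdc95: sem must be >= 0", call. = FALSE)
  1.96 * sqrt(2) * sem
}

#' Per-measure reliability report
#'
#' Computes the intra-rater ICC(2,1) (rater A's two sessions), the
#' inter-rater ICC(2,1) (the first session of each rater), SEM from the
#' intra-rater ICC and the pooled SD of the intra-rater session pair, and
#' MDC95, mirroring a reliability-table row.
#'
#' @param scores Numeric matrix with n participants x 3 columns: session 1
#'   (rater A), session 2 (rater A), session 3 (rater B).
#' @param measure_name Label carried into the report.
#' @return A one-row tibble: measure, icc_intra, icc_intra_p, icc_inter,
#'   icc_inter_p, sem, mdc95, n, k.
#' @export
reliability_report <- function(scores, measure_name = "measure") {
  m <- as.matrix(scores)
  if (ncol(m) != 3L) stop("reliability_report: expected 3 columns (A1, A2, B1)", call. = FALSE)
  intra <- icc_2_1(m[, 1:2])
  inter <- icc_2_1(m[, c(1, 3)])
  s <- sem(c(m[, 1], m[, 2]), intra$icc)
  rep <- tibble::tibble(
    measure = measure_name,
    icc_intra = intra$icc, icc_intra_p = intra$p,
    icc_inter = inter$icc, icc_inter_p = inter$p,
    sem = s, mdc95 = mdc95(s), n = nrow(m), k = 2L
  )
  stopifnot(abs(rep$mdc95 - 1.96 * sqrt(2) * rep$sem) <= 1e-9 * max(1, rep$mdc95))
  rep
}

#' Remove z-score outliers from a participant x measure table
#'
#' Per measure, cells with `|value - mean| / SD > 3` are flagged and set to
#' `NA`; participants flagged in more than two measures are dropped entirely.
#' Zero-SD measures are skipped with a warning.
#'
#' @param table Data frame with a `participant_id` column and one numeric
#'   column per measure (>= 3 participants).
#' @param z_cut Z-score threshold (default 3, two-sided).
#' @param max_flags Participants flagged in more than this many measures are
#'   removed (default 2).
#' @return A list: `table` (filtered), `log` (tibble of cell-level flags),
#'   `removed` (participant ids dropped).
#' @export
remove_outliers <- function(table, z_cut = 3, max_flags = 2L) {
  stopifnot("participant_id" %in% names(table))
  measures <- setdiff(names(table), "participant_id")
  if (nrow(table) < 3L) stop("remove_outliers: need >= 3 participants", call. = FALSE)
  out <- table
  log <- tibble::tibble(
    participant_id = character(), measure = character(),
    value = numeric(), z = numeric()
  )
  for (mcol in measures) {
    v <- out[[mcol]]
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("remove_outliers: zero-SD measure '", mcol, "' skipped", call. = FALSE)
      next
    }
    z <- abs(v - mean(v, na.rm = TRUE)) / s
    hit <- which(!is.na(z) & z > z_cut)
    for (i in hit) {
      log <- rbind(log, tibble::tibble(
        participant_id = as.character(out$participant_id[i]), measure = mcol,
        value = v[i], z = z[i]
      ))
    }
    out[[mcol]][hit] <- NA_real_
  }
  flags <- table(log$participant_id)
  removed <- names(flags)[flags > max_flags]
  out <- out[!as.character(out$participant_id) %in% removed, , drop = FALSE]
  list(table = out, log = log, removed = removed)
}

#' Classify motor impairment severity from the FMA-UE score
#'
#' Fugl-Meyer Assessment for Upper Extremity (0-66; higher = less impaired):
#' 19-46 is moderate, >= 47 is mild. Scores below 19 (severe impairment) are
#' outside the instrument's validated range here and raise an error, as do
#' scores outside 0-66.
#'
#' @param fma_ue Numeric score(s) on 0-66.
#' @return Character vector, `"mild"` or `"moderate"`.
#' @export
classify_severity <- function(fma_ue) {
  if (any(!is.finite(fma_ue)) || any(fma_ue < 0 | fma_ue > 66)) {
    stop("classify_severity: FMA-UE scores must lie in [0, 66]", call. = FALSE)
  }
  if (any(fma_ue < 19)) {
    stop("classify_severity: scores below 19 (severe impairment) are out of scope",
      call. = FALSE
    )
  }
  ifelse(fma_ue >= 47, "mild", "moderate")
}

#' Compare severity groups with Student's t-test
#'
#' Two-sided, equal-variance Student's t by default (`df = n1 + n2 - 2`);
#' Welch's correction available behind a flag.
#'
#' @param mild,moderate Numeric score vectors (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @param welch Use Welch's unequal-variance t instead (default `FALSE`).
#' @return A list with `t`, `df`, `p`, `significant`,
#'   and the group means.
#' @export
compare_groups <- function(mild, moderate, alpha = 0.05, welch = FALSE) {
  mild <- mild[is.finite(mild)]; moderate <- moderate[is.finite(moderate)]
  if (length(mild) < 2L || length(moderate) < 2L) {
    stop("compare_groups: need >= 2 values per group", call. = FALSE)
  }
  tt <- stats::t.test(mild, moderate, var.equal = !welch, alternative = "two.sided")
  list(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    significant = tt$p.value < alpha,
    mean_mild = mean(mild), mean_moderate = mean(moderate)
  )
}

#' All-pairs convergent-validity matrix
#'
#' Pearson validity of every instrumented measure against every clinical
#' score over participants shared by both tables. Pairs with fewer than 3
#' complete shared observations, or with zero variance, are marked
#' unavailable rather than erroring. Pairs with `|r| > 0.4` (moderate or
#' stronger) carry a highlight flag.
#'
#' @param outcomes Wide data frame: `participant_id` plus one column per
#'   instrumented measure.
#' @param clinical Wide data frame: `participant_id` plus one column per
#'   clinical score.
#' @return A tibble with columns measure, clinical, r, p, band, n,
#'   highlight, available.
#' @export
validity_matrix <- function(outcomes, clinical) {
  stopifnot("participant_id" %in% names(outcomes), "participant_id" %in% names(clinical))
  merged <- merge(outcomes, clinical, by = "participant_id", suffixes = c("", ".clin"))
  ms <- setdiff(names(outcomes), "participant_id")
  cs <- setdiff(names(clinical), "participant_id")
  cs_m <- ifelse(cs %in% ms, paste0(cs, ".clin"), cs)
  res <- vector("list", length(ms) * length(cs))
  i <- 0L
  for (m in ms) {
    for (j in seq_along(cs)) {
      i <- i + 1L
      x <- merged[[m]]; y <- merged[[cs_m[j]]]
      pv <- tryCatch(pearson_validity(x, y), error = function(e) NULL)
      res[[i]] <- if (is.null(pv)) {
        tibble::tibble(
          measure = m, clinical = cs[j], r = NA_real_, p = NA_real_,
          band = NA_character_, n = sum(stats::complete.cases(x, y)),
          highlight = FALSE, available = FALSE
        )
      } else {
        tibble::tibble(
          measure = m, clinical = cs[j], r = pv$r, p = pv$p, band = pv$band,
          n = pv$n, highlight = abs(pv$r) > 0.4, available = TRUE
        )
      }
    }
  }
  do.call(rbind, res)
}
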