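#' Between-subject coefficient of variation
#'
#' `100 * SD / mean` with the sample (n-1) standard deviation. When a
#' two-column matrix or data.frame of sessions is supplied, sessions are
#' averaged per subject first, so the statistic targets the variation
#' between individuals.
#'
#' @param values numeric vector of per-subject values, or a matrix /
#'   data.frame with one row per subject and one column per session.
#' @return CoV in percent.
#' @export
between_subject_cov <- function(values) {
  if (is.matrix(values) || is.data.frame(values)) {
    values <- rowMeans(as.matrix(values))
  }
  values <- as.numeric(values)
  if (length(values) < 2L) stop("at least 2 subjects are required")
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive for a relative CoV")
  100 * stats::sd(values) / m
}

#' Paired test-retest input
#'
#' @param exam1,exam2 matched per-subject values from the two sessions.
#' @param subject optional subject ids.
#' @return object of class `repeatability_input`.
#' @export
repeatability_input <- function(exam1, exam2, subject = seq_along(exam1)) {
  if (length(exam1) != length(exam2)) stop("exams must be matched by subject")
  structure(list(exam1 = as.numeric(exam1), exam2 = as.numeric(exam2),
                 subject = subject),
            class = "repeatability_input")
}

#' Within-subject coefficient of variation
#'
#' Session-to-session variability relative to the mean:
#' `100 * (SD(exam2 - exam1) / sqrt(2)) / grand mean`, with the sample
#' (n-1) SD of the paired differences and the grand mean of all
#' observations from both sessions. Symmetric in the exam order. An
#' alternative denominator convention (mean of per-subject pair means,
#' identical for complete pairs) is available via `denominator`.
#'
#' @param input a [repeatability_input()] (or `exam1` vector).
#' @param exam2 second-exam values when `input` is a plain vector.
#' @param denominator `"grand_mean"` (default) or `"pair_means"`.
#' @return CoV in percent.
#' @export
within_subject_cov <- function(input, exam2 = NULL,
                               denominator = c("grand_mean", "pair_means")) {
  denominator <- match.arg(denominator)
  if (!inherits(input, "repeatability_input")) {
    input <- repeatability_input(input, exam2)
  }
  n <- length(input$exam1)
  if (n < 2L) stop("at least 2 matched pairs are required")
  d <- input$exam2 - input$exam1
  gm <- switch(denominator,
               grand_mean = mean(c(input$exam1, input$exam2)),
               pair_means = mean((input$exam1 + input$exam2) / 2))
  if (!is.finite(gm) || gm <= 0) {
    stop("grand mean must be positive for a relative CoV")
  }
  100 * (stats::sd(d) / sqrt(2)) / gm
}

#' Repeatability coefficient
#'
#' The smallest change that is unlikely (95%) to be measurement noise:
#' exactly `1.96 * sqrt(2)` times the within-subject CoV.
#'
#' @param ws_cov_pct within-subject CoV in percent (>= 0).
#' @return repeatability coefficient in percent.
#' @export
repeatability_coefficient <- function(ws_cov_pct) {
  if (any(ws_cov_pct < 0)) stop("within-subject CoV must be >= 0")
  1.96 * sqrt(2) * ws_cov_pct
}

#' Bland-Altman agreement statistics
#'
#' @param input a [repeatability_input()] (or `exam1` vector).
#' @param exam2 second-exam values when `input` is a plain vector.
#' @return list with `bias` (mean difference exam2 - exam1), `lower_loa`,
#'   `upper_loa` (bias -/+ 1.96 SD of the differences), `sd_diff` and a
#'   data.frame `points` (mean, difference) for plotting.
#' @export
bland_altman <- function(input, exam2 = NULL) {
  if (!inherits(input, "repeatability_input")) {
    input <- repeatability_input(input, exam2)
  }
  if (length(input$exam1) < 2L) stop("at least 2 pairs are required")
  d <- input$exam2 - input$exam1
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, lower_loa = bias - 1.96 * s,
       upper_loa = bias + 1.96 * s, sd_diff = s,
       points = data.frame(mean = (input$exam1 + input$exam2) / 2,
                           difference = d))
}

#' Quadratic fit of metabolite dynamics
#'
#' Ordinary least-squares second-degree polynomial in time on the pooled
#' individual data points.
#'
#' @param time_min time in minutes.
#' @param values observed values.
#' @return named coefficients `c(intercept, linear, quadratic)`.
#' @export
dynamics_fit <- function(time_min, values) {
  stopifnot(length(time_min) == length(values))
  if (length(unique(time_min)) < 3L) {
    stop("at least 3 distinct time points are required for a quadratic fit")
  }
  fit <- stats::lm(values ~ time_min + I(time_min^2))
  stats::setNames(as.numeric(stats::coef(fit)),
                  c("intercept", "linear", "quadratic"))
}

#' Repeatability table from a long regional study table
#'
#' Computes, for every metabolite x timepoint x region cell with two
#' sessions, the within-subject CoV, the repeatability coefficient and the
#' between-subject CoV (sessions averaged per subject first). Cells whose
#' values are missing for a subject drop that subject; `n` reports the
#' pairs used. Baseline cells with zero mean (no tracer yet) are skipped.
#'
#' @param regional data.frame with columns `subject`, `session`,
#'   `timepoint_min`, `region`, `metabolite`, `value`.
#' @param min_pairs minimum complete pairs required per cell.
#' @return data.frame of class `repeatability_table` with columns
#'   `metabolite`, `timepoint`, `region`, `within_subject_cov_pct`,
#'   `repeatability_coefficient_pct`, `between_subject_cov_pct`, `n`.
#' @export
repeatability_table <- function(regional, min_pairs = 2L) {
  needed <- c("subject", "session", "timepoint_min", "region", "metabolite",
              "value")
  stopifnot(all(needed %in% names(regional)))
  cells <- unique(regional[, c("metabolite", "timepoint_min", "region")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    sub <- regional[regional$metabolite == cc$metabolite &
                      regional$timepoint_min == cc$timepoint_min &
                      regional$region == cc$region, ]
    wide <- stats::reshape(sub[, c("subject", "session", "value")],
                           idvar = "subject", timevar = "session",
                           direction = "wide")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    complete <- stats::complete.cases(mat)
    mat <- mat[complete, , drop = FALSE]
    if (nrow(mat) < min_pairs || ncol(mat) < 2L) return(NULL)
    if (!all(is.finite(mat)) || mean(mat) <= 0) return(NULL)
    ws <- within_subject_cov(repeatability_input(mat[, 1], mat[, 2]))
    data.frame(metabolite = cc$metabolite, timepoint = cc$timepoint_min,
               region = cc$region,
               within_subject_cov_pct = ws,
               repeatability_coefficient_pct = repeatability_coefficient(ws),
               between_subject_cov_pct = between_subject_cov(mat),
               n = nrow(mat), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(metabolite = character(), timepoint = numeric(),
                      region = character(),
                      within_subject_cov_pct = numeric(),
                      repeatability_coefficient_pct = numeric(),
                      between_subject_cov_pct = numeric(),
                      n = integer(), stringsAsFactors = FALSE)
  }
  class(out) <- c("repeatability_table", "data.frame")
  out
}
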