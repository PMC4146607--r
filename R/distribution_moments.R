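# Descriptive statistics of the prey-mass distributions, overall and by
# environment. Moments are computed on the log10 scale (the scale of all
# analyses); ranges and spans are reported in raw kg. "Mode" of a
# continuous mass variable is implemented as the modal log10-decade bin
# (..., [0.0001, 0.001), [0.001, 0.01), ...).

#' Adjusted Fisher-Pearson sample skewness (G1)
#'
#' `G1 = g1 * sqrt(n(n-1)) / (n-2)` with `g1 = m3 / m2^(3/2)`.
#'
#' @param x numeric vector (n >= 3 and non-constant, else `NA`).
#' @return numeric scalar.
#' @export
skewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Sample excess kurtosis (G2, bias-adjusted; normal = 0)
#'
#' `G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3))` with `g2 = m4/m2^2 - 3`.
#' The raw (non-excess) value `m4/m2^2` is available via `raw = TRUE`.
#'
#' @param x numeric vector (n >= 4 and non-constant, else `NA`).
#' @param raw if `TRUE`, return the unadjusted fourth standardized moment.
#' @return numeric scalar.
#' @export
kurtosis <- function(x, raw = FALSE) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (n < 4 || m2 == 0) return(NA_real_)
  b2 <- mean((x - m)^4) / m2^2
  if (raw) return(b2)
  ((n + 1) * (b2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3))
}

.group_rows <- function(table, group) {
  group <- match.arg(group, c("all", "terrestrial", "aquatic"))
  if (group == "all") rep(TRUE, nrow(table)) else table$environment == group
}

#' Modal log10-decade bin of a positive mass sample
#'
#' Bins values by `floor(log10(x))` and returns the decade interval(s) with
#' the highest count; ties are reported explicitly (several rows,
#' `tie = TRUE`). The full per-decade histogram is attached as attribute
#' `counts` so coarser multi-decade groupings can be formed.
#'
#' @param x positive numeric vector (kg).
#' @return data.frame with columns `lower`, `upper` (kg), `count` and
#'   attributes `counts` (full histogram) and `tie`.
#' @export
modal_bin_values <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (!length(x)) stop("no positive finite values")
  idx <- floor(log10(x))
  rng <- seq(min(idx), max(idx))
  counts <- vapply(rng, function(i) sum(idx == i), numeric(1))
  hist <- data.frame(lower = 10^rng, upper = 10^(rng + 1), count = counts)
  modal <- hist[hist$count == max(hist$count), , drop = FALSE]
  row.names(modal) <- NULL
  attr(modal, "counts") <- hist
  attr(modal, "tie") <- nrow(modal) > 1
  modal
}

#' Modal decade bin of a prey-mass response
#'
#' @param table a `trait_table`.
#' @param group `"all"`, `"terrestrial"` or `"aquatic"`.
#' @param response `"min"`, `"max"` or `"range"` (range on the raw kg scale,
#'   `prey_max - prey_min`, excluding zero ranges).
#' @return see [modal_bin_values()].
#' @export
modal_bin <- function(table, group = "all", response = "min") {
  rows <- .group_rows(table, group)
  modal_bin_values(.raw_response(table, response)[rows])
}

.raw_response <- function(table, response) {
  switch(.response_col(response),
         log_prey_min = table$prey_min,
         log_prey_max = table$prey_max,
         log_prey_range = table$prey_max - table$prey_min)
}

#' Descriptive moments of a prey-mass distribution
#'
#' Mean, median, min, max and SD are computed on the log10(kg) scale;
#' `range_kg` is the raw-kg spread of the response within the group;
#' skewness is the adjusted Fisher-Pearson G1 and kurtosis the excess G2
#' (both `NA` when n < 3 resp. n < 4, reported with a message). The modal
#' decade bin is included.
#'
#' @inheritParams modal_bin
#' @return object of class `moments_summary` (also a one-row data.frame):
#'   group, response, n, mean, median, min, max, sd, range_kg, skewness,
#'   kurtosis_excess, kurtosis_raw, modal_bin_lower, modal_bin_upper.
#' @export
moments <- function(table, group = "all", response = "min") {
  stopifnot(inherits(table, "trait_table"))
  rows <- .group_rows(table, group)
  if (!any(rows)) stop("group '", group, "' is empty")
  lv <- table[[.response_col(response)]][rows]
  lv <- lv[is.finite(lv)]
  raw <- .raw_response(table, response)[rows]
  raw <- raw[is.finite(raw) & raw > 0]
  n <- length(lv)
  if (n < 3) message("n < 3: skewness/kurtosis undefined, reported as NA")
  mb <- modal_bin_values(raw)
  out <- data.frame(
    group = group, response = response, n = n,
    mean = mean(lv), median = median(lv), min = min(lv), max = max(lv),
    sd = if (n >= 2) sd(lv) else NA_real_,
    range_kg = max(raw) - min(raw),
    skewness = skewness(lv),
    kurtosis_excess = kurtosis(lv),
    kurtosis_raw = kurtosis(lv, raw = TRUE),
    modal_bin_lower = mb$lower[1], modal_bin_upper = mb$upper[1])
  class(out) <- c("moments_summary", "data.frame")
  out
}

#' Total prey-mass span of a group
#'
#' `max(prey_max) - min(prey_min)` within the group, in kg: the full extent
#' of prey sizes exploited by the group's species.
#'
#' @param table a `trait_table`.
#' @param group `"all"`, `"terrestrial"` or `"aquatic"`.
#' @return numeric scalar (kg).
#' @export
prey_span <- function(table, group = "all") {
  rows <- .group_rows(table, group)
  if (!any(rows)) stop("group '", group, "' is empty")
  max(table$prey_max[rows]) - min(table$prey_min[rows])
}

#' Moments for all groups and responses as one table
#'
#' @param table a `trait_table`.
#' @param groups subset of `c("all", "terrestrial", "aquatic")`.
#' @param responses subset of `c("min", "max", "range")`.
#' @return long data.frame, one row per group x response.
#' @export
moments_table <- function(table, groups = c("all", "terrestrial", "aquatic"),
                          responses = c("min", "max", "range")) {
  out <- do.call(rbind, lapply(groups, function(g)
    do.call(rbind, lapply(responses, function(r)
      as.data.frame(moments(table, g, r))))))
  row.names(out) <- NULL
  out
}
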