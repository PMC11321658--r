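#' Physiological-age bin schemes
#'
#' The default scheme enumerates the published spans: 0-1 years monthly,
#' 1-2 years every two months, 2-4 years every three months, 4-10 years
#' yearly, 10-22 years every two years, 22-40 years every three years,
#' 40-70 years every five years, and 70-102 years every eight years.
#' Straightforward enumeration of those spans yields 54 left-closed
#' right-open intervals; no fixed bin count is asserted, and custom break
#' vectors are accepted. When training ages are supplied, adjacent
#' underfilled bins are merged until every bin holds at least
#' `min_count` samples.
#'
#' @param ages optional training ages; required for underfill merging and
#'   validated against the scheme's range.
#' @param scheme `"default"` for the enumerated spans, or a numeric
#'   vector of increasing breakpoints.
#' @param min_count minimum samples per bin when `ages` are supplied
#'   (default 100).
#' @return object of class `age_bins`: data.frame with `label`, `lower`,
#'   `upper`, `midpoint` (and `n` when ages were supplied).
#' @export
build_age_bins <- function(ages = NULL, scheme = "default",
                           min_count = 100) {
  if (identical(scheme, "default")) {
    spans <- rbind(c(0, 1, 1 / 12), c(1, 2, 1 / 6), c(2, 4, 1 / 4),
                   c(4, 10, 1), c(10, 22, 2), c(22, 40, 3),
                   c(40, 70, 5), c(70, 102, 8))
    breaks <- unique(unlist(apply(spans, 1, function(s)
      seq(s[1], s[2], by = s[3]), simplify = FALSE)))
  } else {
    breaks <- as.numeric(scheme)
  }
  breaks <- sort(unique(breaks))
  if (length(breaks) < 2) stop("need at least 2 breakpoints")
  lower <- breaks[-length(breaks)]
  upper <- breaks[-1]
  if (!is.null(ages)) {
    if (any(ages < breaks[1] | ages > breaks[length(breaks)]))
      stop("age(s) outside the scheme's range ", breaks[1], "-",
           breaks[length(breaks)], ": ",
           paste(utils::head(ages[ages < breaks[1] |
                                    ages > breaks[length(breaks)]], 3),
                 collapse = ", "))
    counts <- bin_counts(ages, lower, upper)
    while (length(lower) > 1 && any(counts < min_count)) {
      i <- which.min(counts)
      j <- if (i == 1) 2
      else if (i == length(counts)) i - 1
      else if (counts[i - 1] <= counts[i + 1]) i - 1 else i + 1
      lo <- min(i, j)
      hi <- max(i, j)
      lower <- lower[-hi]
      upper <- upper[-lo]
      counts <- bin_counts(ages, lower, upper)
    }
  }
  df <- data.frame(label = sprintf("[%.4g,%.4g)", lower, upper),
                   lower = lower, upper = upper,
                   midpoint = (lower + upper) / 2)
  if (!is.null(ages)) df$n <- bin_counts(ages, lower, upper)
  structure(df, class = c("age_bins", "data.frame"))
}

bin_counts <- function(ages, lower, upper) {
  idx <- assign_age_bin_impl(ages, lower, upper)
  tabulate(idx, nbins = length(lower))
}

assign_age_bin_impl <- function(ages, lower, upper) {
  breaks <- c(lower, upper[length(upper)])
  idx <- findInterval(ages, breaks, rightmost.closed = TRUE)
  idx[ages < lower[1] | ages > upper[length(upper)]] <- NA
  idx
}

#' Assign ages to bins
#'
#' Left-closed, right-open intervals; the last interval also includes its
#' upper bound.
#'
#' @param ages numeric ages.
#' @param bins an `age_bins` scheme.
#' @return integer bin indices (NA outside the scheme).
#' @export
assign_age_bin <- function(ages, bins) {
  stopifnot(inherits(bins, "age_bins"))
  assign_age_bin_impl(ages, bins$lower, bins$upper)
}

#' @export
print.age_bins <- function(x, ...) {
  cat("Age bin scheme:", nrow(x), "bins covering", x$lower[1], "-",
      x$upper[nrow(x)], "years\n")
  invisible(x)
}
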