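#' Assemble per-video wave results into a study table
#'
#' One row per analyzed video, keyed by subject and video identifiers, with
#' the induced intraocular pressure (IOPi) as metadata.
#'
#' @param results data.frame with at least \code{subject}, \code{video},
#'   \code{iop} columns plus the per-video quantities (s1, s2, D1..D5, ...).
#' @return The validated data.frame (class \code{study_table} prepended).
#' @export
study_table <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("subject", "video", "iop") %in% names(results)))
  if (anyDuplicated(results[, c("subject", "video")]))
    stop("(subject, video) keys must be unique")
  if (any(results$iop <= 0)) stop("IOPi must be positive")
  class(results) <- c("study_table", class(results))
  results
}

# quantile rule fixed package-wide: linear interpolation between order
# statistics (stats::quantile type 7), since reported IQRs are artifacts
iqr7 <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7, na.rm = TRUE)
  q[2] - q[1]
}

#' Per-subject PWV summaries
#'
#' Median and interquartile range of the signed down-trend (S1) and
#' up-trend (S2) pulse wave velocities for each subject, with a pooled row
#' (mean and IQR across all videos) appended. Quantiles use linear
#' interpolation between order statistics.
#'
#' @param table A [study_table()] (needs columns \code{subject}, \code{s1},
#'   \code{s2}).
#' @return data.frame with columns \code{subject}, \code{n},
#'   \code{median_s1}, \code{iqr_s1}, \code{median_s2}, \code{iqr_s2}; the
#'   final row (\code{subject = "ALL"}) holds the pooled mean and IQR.
#' @export
summarize_by_subject <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1,
            all(c("subject", "s1", "s2") %in% names(table)))
  subj <- sort(unique(table$subject))
  rows <- lapply(subj, function(s) {
    d <- table[table$subject == s, ]
    data.frame(subject = as.character(s), n = nrow(d),
               median_s1 = stats::median(d$s1, na.rm = TRUE),
               iqr_s1 = iqr7(d$s1),
               median_s2 = stats::median(d$s2, na.rm = TRUE),
               iqr_s2 = iqr7(d$s2))
  })
  pooled <- data.frame(subject = "ALL", n = nrow(table),
                       median_s1 = mean(table$s1, na.rm = TRUE),
                       iqr_s1 = iqr7(table$s1),
                       median_s2 = mean(table$s2, na.rm = TRUE),
                       iqr_s2 = iqr7(table$s2))
  out <- rbind(do.call(rbind, rows), pooled)
  rownames(out) <- NULL
  out
}

#' Numerical summary of the turning-point distance metrics
#'
#' Minimum, maximum, mean, standard deviation, median and IQR of each
#' distance metric across the rows of a (typically pressure-matched) study
#' table.
#'
#' @param table A [study_table()] or data.frame.
#' @param cols Columns to summarize (default D1..D4).
#' @return data.frame with one row per metric.
#' @export
summarize_distances <- function(table, cols = c("D1", "D2", "D3", "D4")) {
  stopifnot(is.data.frame(table), nrow(table) >= 1,
            all(cols %in% names(table)))
  out <- do.call(rbind, lapply(cols, function(cn) {
    v <- table[[cn]]
    data.frame(metric = cn,
               min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
               mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
               median = stats::median(v, na.rm = TRUE), iqr = iqr7(v))
  }))
  rownames(out) <- NULL
  out
}

# minimal-cost monotone assignment of n of the sorted values to the sorted
# grid, dynamic programming over (grid slot, value index); ties prefer the
# smaller values (lexicographically smallest selected IOPi vector)
match_to_grid <- function(values, grid) {
  m <- length(values); n <- length(grid)
  D <- matrix(Inf, n + 1, m + 1)
  D[1, ] <- 0
  for (k in seq_len(n)) for (j in k:m) {
    take <- D[k, j] + abs(values[j] - grid[k])
    skip <- if (j > k) D[k + 1, j] else Inf
    D[k + 1, j + 1] <- min(take, skip)
  }
  # reconstruct, preferring "skip" (use an earlier, smaller value) on ties
  sel <- integer(n)
  k <- n; j <- m
  while (k >= 1) {
    skip <- if (j > k) D[k + 1, j] else Inf
    take <- D[k, j] + abs(values[j] - grid[k])
    if (skip <= take) {
      j <- j - 1
    } else {
      sel[k] <- j
      k <- k - 1; j <- j - 1
    }
  }
  list(idx = sel, cost = D[n + 1, m + 1])
}

#' Select pressure-matched videos for each subject
#'
#' Operationalizes "similarly matched" induced pressures: for each subject,
#' the \code{n_per_subject} in-range videos whose IOPi values minimize the
#' total absolute deviation from a common target grid evenly spaced over
#' the pressure range. Subjects without enough in-range videos are flagged
#' and excluded. Ties break toward the lower IOPi values.
#'
#' @param table A [study_table()].
#' @param n_per_subject Number of videos per subject (default 5).
#' @param range Inclusive IOPi range in mm Hg (default c(16, 45)).
#' @return The selected subset (rows of \code{table}), with the excluded
#'   subjects in \code{attr(, "excluded")}.
#' @export
select_matched_pressures <- function(table, n_per_subject = 5,
                                     range = c(16, 45)) {
  stopifnot(is.data.frame(table),
            all(c("subject", "iop") %in% names(table)))
  grid <- seq(range[1], range[2], length.out = n_per_subject)
  keep <- integer(0)
  excluded <- character(0)
  for (s in unique(table$subject)) {
    rows <- which(table$subject == s &
                    table$iop >= range[1] & table$iop <= range[2])
    if (length(rows) < n_per_subject) {
      excluded <- c(excluded, as.character(s))
      next
    }
    ord <- rows[order(table$iop[rows])]
    sel <- match_to_grid(table$iop[ord], grid)
    keep <- c(keep, ord[sel$idx])
  }
  if (length(keep) == 0) stop("no subject has enough in-range videos")
  out <- table[sort(keep), , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Pitman-Morgan test of equality of variances for paired samples
#'
#' Tests whether two paired samples have equal variances via the
#' correlation between the pairwise sums and differences:
#' \code{r = cor(x + y, x - y)}, \code{t = r * sqrt((n - 2) / (1 - r^2))}
#' on \code{n - 2} degrees of freedom, two-sided.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 3).
#' @return An object of class \code{htest}. When either the sums or the
#'   differences have zero variance the test is degenerate: the statistic
#'   is \code{NA}, \code{p.value = 1}, and a \code{degenerate} element is
#'   set.
#' @export
pitman_morgan <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  s <- x + y; d <- x - y
  dname <- paste(deparse(substitute(x)), "and", deparse(substitute(y)))
  if (stats::var(s) == 0 || stats::var(d) == 0) {
    out <- list(statistic = c(t = NA_real_), parameter = c(df = n - 2),
                p.value = 1, method = "Pitman-Morgan test of equality of variances for paired samples",
                data.name = dname, degenerate = TRUE)
    class(out) <- "htest"
    return(out)
  }
  r <- stats::cor(s, d)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  out <- list(statistic = c(t = tstat), parameter = c(df = n - 2),
              p.value = p, estimate = c(`var ratio` = stats::var(x) / stats::var(y)),
              method = "Pitman-Morgan test of equality of variances for paired samples",
              data.name = dname, degenerate = FALSE)
  class(out) <- "htest"
  out
}
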