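#' Per-participant condition-difference matrix
#'
#' Row i is participant i's condition-A trace minus their condition-B trace
#' on the shared time axis.
#'
#' @param traces List of per-participant [condition_mean()] matrices.
#' @param conditions Length-2 character vector `c(A, B)`; the difference is
#'   `A - B`.
#' @return Numeric matrix participants x time with attribute `"time"` and
#'   rownames from the list names.
#' @export
condition_difference <- function(traces, conditions) {
  stopifnot(length(conditions) == 2)
  rows <- lapply(traces, function(tr) {
    if (!all(conditions %in% rownames(tr))) {
      stop("participant missing a condition: ",
           paste(setdiff(conditions, rownames(tr)), collapse = ", "))
    }
    tr[conditions[1], ] - tr[conditions[2], ]
  })
  out <- do.call(rbind, rows)
  if (anyNA(out)) stop("difference matrix must not contain missing values")
  attr(out, "time") <- attr(traces[[1]], "time")
  out
}

#' Pointwise participant-level bootstrap significance mask
#'
#' Each iteration resamples participants (rows) with replacement and stores
#' the across-participant mean trace. At each time point, `prop_above` is
#' the fraction of iteration means strictly above zero, `prop_below` the
#' fraction strictly below (iteration means exactly zero count in neither
#' tail), and the point is significant when either proportion exceeds
#' `criterion`. With the default `criterion = 0.99` this is two one-sided
#' 1% tests (a nominal two-sided level of about 2%); no correction across
#' time points is applied.
#'
#' @param diff Difference matrix (participants x time), no missing values.
#' @param n_iterations Bootstrap iterations (default 1000).
#' @param criterion Exceedance proportion threshold (default 0.99, strict
#'   `>`).
#' @param seed Optional integer seed for reproducibility.
#' @return A `significance_mask`: list with `time`, `prop_above`,
#'   `prop_below`, `significant`, `sign` (+1/-1/0 per point),
#'   `n_iterations`, `criterion`, `seed`.
#' @export
bootstrap_mask <- function(diff, n_iterations = 1000, criterion = 0.99,
                           seed = NULL) {
  diff <- as.matrix(diff)
  n_p <- nrow(diff)
  if (n_p < 2) stop("bootstrap needs at least 2 participants")
  if (anyNA(diff)) stop("difference matrix must not contain missing values")
  if (!is.null(seed)) set.seed(seed)
  nt <- ncol(diff)
  above <- below <- numeric(nt)
  for (it in seq_len(n_iterations)) {
    m <- colMeans(diff[sample.int(n_p, n_p, replace = TRUE), ,
                       drop = FALSE])
    above <- above + (m > 0)
    below <- below + (m < 0)
  }
  prop_above <- above / n_iterations
  prop_below <- below / n_iterations
  significant <- pmax(prop_above, prop_below) > criterion
  sgn <- integer(nt)
  sgn[significant & prop_above >= prop_below] <- 1L
  sgn[significant & prop_below > prop_above] <- -1L
  structure(list(time = attr(diff, "time"), prop_above = prop_above,
                 prop_below = prop_below, significant = significant,
                 sign = sgn, n_iterations = n_iterations,
                 criterion = criterion, seed = seed),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf(
    "<significance_mask> %d time points, %d iterations, criterion > %.3f\n",
    length(x$significant), x$n_iterations, x$criterion))
  cat(sprintf("  significant: %d points (%.1f%%)\n", sum(x$significant),
              100 * mean(x$significant)))
  invisible(x)
}

#' Contiguous significant intervals of a mask
#'
#' Maximal runs of significant samples sharing one sign, filtered by a
#' minimum run length.
#'
#' @param mask A [bootstrap_mask()] result.
#' @param min_length Minimum run length in samples (default 1).
#' @return data.frame with `start_s`, `end_s` (times of the first and last
#'   sample of the run), `sign` (+1/-1) and `n_samples`.
#' @export
significant_intervals <- function(mask, min_length = 1) {
  empty <- data.frame(start_s = numeric(), end_s = numeric(),
                      sign = integer(), n_samples = integer())
  state <- mask$sign  # 0 where not significant
  if (all(state == 0)) return(empty)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0 & r$lengths >= min_length
  if (!any(keep)) return(empty)
  tm <- if (is.null(mask$time)) seq_along(state) else mask$time
  data.frame(start_s = tm[starts[keep]], end_s = tm[ends[keep]],
             sign = r$values[keep], n_samples = r$lengths[keep])
}
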