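#' Normalize a GAP-FRAP recovery trace
#'
#' Prepares a raw fluorescence time series of a photobleached cell for
#' fitting: the time origin is shifted to the post-bleach minimum-intensity
#' sample and intensities are divided by the maximum intensity after
#' bleaching, so the normalized recovery runs from its minimum towards 1.
#'
#' @param time sample times in seconds (strictly increasing), or a data
#'   frame with columns `time_s` and `intensity`.
#' @param intensity fluorescence intensities (arbitrary units, >= 0);
#'   ignored when `time` is a data frame.
#' @param pre_bleach_max maximum fluorescence intensity before bleaching
#'   (optional; used to report the pre-bleach-normalized recovery constant).
#' @return an object of class `gj_frap`: list with `t` (seconds from the
#'   post-bleach minimum), `intensity` (normalized), `pre_bleach_max`,
#'   `post_bleach_max`.
#' @examples
#' t <- seq(0, 114, by = 3.8)
#' tr <- normalize_frap(t, 1 - exp(-t / 20))
#' range(tr$intensity)
#' @export
normalize_frap <- function(time, intensity = NULL, pre_bleach_max = NULL) {
  if (is.data.frame(time)) {
    df <- time
    if (!all(c("time_s", "intensity") %in% names(df))) {
      stop("trace data frame needs columns 'time_s' and 'intensity'",
           call. = FALSE)
    }
    if (is.null(pre_bleach_max) && "pre_bleach_max" %in% names(df)) {
      pre_bleach_max <- df$pre_bleach_max[1]
    }
    intensity <- df$intensity
    time <- df$time_s
  }
  stopifnot(length(time) == length(intensity), all(intensity >= 0))
  if (any(diff(time) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  m <- which.min(intensity)
  t <- time[m:length(time)] - time[m]
  i <- intensity[m:length(intensity)]
  if (length(t) < 4) {
    stop("need at least 4 samples from the post-bleach minimum onwards",
         call. = FALSE)
  }
  post_max <- max(i)
  if (post_max <= min(i)) stop("flat trace: no recovery to normalize",
                               call. = FALSE)
  out <- list(t = t, intensity = i / post_max,
              pre_bleach_max = pre_bleach_max, post_bleach_max = post_max)
  class(out) <- "gj_frap"
  out
}

#' Fit the exponential recovery model to a FRAP trace
#'
#' Fits the normalized recovery to `I(t) = 1 - exp(-t / Rc)` by nonlinear
#' least squares, where the recovery constant `Rc` (seconds) is inversely
#' related to the intercellular transport rate into the photobleached cell.
#' `Rc` is initialized from the time at which the trace first reaches
#' 63.2% recovery. When a pre-bleach maximum intensity is available, the
#' recovery constant divided by it is also reported (`rc_normalized`), as
#' used for population comparisons; the unnormalized constant is always
#' returned.
#'
#' @param trace a `gj_frap` object from [normalize_frap()].
#' @return a list with `rc` (seconds), `rc_normalized` (or `NA`), `rss`
#'   (residual sum of squares) and `fitted` values.
#' @examples
#' t <- seq(0, 114, by = 3.8)
#' fit <- fit_frap(normalize_frap(t, 1 - exp(-t / 20)))
#' fit$rc
#' @export
fit_frap <- function(trace) {
  stopifnot(inherits(trace, "gj_frap"))
  t <- trace$t
  I <- trace$intensity
  target <- 1 - exp(-1)
  above <- which(I >= target)
  rc0 <- if (length(above)) max(t[min(above)], 1e-6) else stats::median(t[t > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ 1 - exp(-t / rc), data = data.frame(t = t, I = I),
                      start = list(rc = rc0),
                      lower = 1e-9,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("recovery fit did not converge (start Rc = ", signif(rc0, 4),
           " s): ", conditionMessage(e), call. = FALSE)
    })
  rc <- unname(stats::coef(fit)[["rc"]])
  res <- I - (1 - exp(-t / rc))
  list(rc = rc,
       rc_normalized = if (is.null(trace$pre_bleach_max)) NA_real_
                       else rc / trace$pre_bleach_max,
       rss = sum(res^2),
       fitted = 1 - exp(-t / rc))
}

#' Read a FRAP trace from CSV
#'
#' Expects columns `time_s` and `intensity`, with an optional
#' `pre_bleach_max` column (constant), and returns the normalized trace.
#'
#' @param path CSV file path.
#' @return a `gj_frap` object.
#' @export
read_frap_csv <- function(path) {
  normalize_frap(utils::read.csv(path))
}
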