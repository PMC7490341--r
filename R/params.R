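#' Parameters of the RDI pipeline
#'
#' Bundles every tunable of the preprocessing and entropy stages. Defaults
#' reproduce the published pipeline: activity below `lambda = 0.005` is
#' zeroed, a 4th-order Butterworth band-pass with normalized cutoffs
#' `1/2000` and `1/300` (fractions of the Nyquist frequency, 0.5 cycles/min
#' at 1-min binning) is applied, and sample entropy uses embedding dimension
#' `m = 2` with tolerance 0.2 times the SD of the analyzed series.
#'
#' @param lambda Activity threshold (activity units); values strictly below
#'   it are set to zero before filtering.
#' @param filter_order Butterworth prototype order (the band-pass has twice
#'   this many poles).
#' @param f_low,f_high Band edges as fractions of the Nyquist frequency.
#' @param m Embedding dimension of the sample entropy.
#' @param r_frac Entropy tolerance as a fraction of the population SD of the
#'   analyzed (post-filter) series.
#' @param window_w Window length in minutes for the moving and
#'   least-active-hour variants.
#' @param filter_scope `"segment"` filters each analyzed segment (day or
#'   night half) independently; `"full_day"` filters the whole 1440-min day
#'   once. 60-min windows (moving / least-active-hour RDI) always use the
#'   day-level filtered series: a 4th-order band-pass with a 2000-sample
#'   low-period cutoff is not meaningful on 60 samples.
#' @param zero_phase Use forward-backward (zero-phase) filtering; `FALSE`
#'   gives a single causal pass.
#' @return An object of class `rdi_params`.
#' @export
#' @examples
#' p <- rdi_params()
#' p$lambda
rdi_params <- function(lambda = 0.005, filter_order = 4L,
                       f_low = 1 / 2000, f_high = 1 / 300,
                       m = 2L, r_frac = 0.2, window_w = 60L,
                       filter_scope = c("segment", "full_day"),
                       zero_phase = TRUE) {
  filter_scope <- match.arg(filter_scope)
  stopifnot(lambda >= 0, filter_order >= 1,
            f_low > 0, f_low < f_high, f_high < 1,
            m >= 1, r_frac > 0, window_w >= m + 2)
  structure(list(lambda = lambda, filter_order = as.integer(filter_order),
                 f_low = f_low, f_high = f_high, m = as.integer(m),
                 r_frac = r_frac, window_w = as.integer(window_w),
                 filter_scope = filter_scope, zero_phase = isTRUE(zero_phase)),
            class = "rdi_params")
}

#' @export
print.rdi_params <- function(x, ...) {
  cat("RDI parameters\n")
  cat(sprintf("  lambda (threshold): %g\n", x$lambda))
  cat(sprintf("  Butterworth order %d, band [%g, %g] x Nyquist, %s\n",
              x$filter_order, x$f_low, x$f_high,
              if (x$zero_phase) "zero-phase" else "causal"))
  cat(sprintf("  sample entropy m = %d, r = %g x SD\n", x$m, x$r_frac))
  cat(sprintf("  window = %d min, filter scope = %s\n",
              x$window_w, x$filter_scope))
  invisible(x)
}

#' Read RDI parameters from a YAML config block
#'
#' Reads the `rdi_params` block of a YAML file; fields not present keep
#' their defaults.
#'
#' @param path Path to a YAML file with an `rdi_params` mapping.
#' @return An `rdi_params` object.
#' @export
read_rdi_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  blk <- if (!is.null(cfg$rdi_params)) cfg$rdi_params else cfg
  args <- blk[intersect(names(blk), names(formals(rdi_params)))]
  do.call(rdi_params, args)
}
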