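# Geweke convergence diagnostic: z-test comparing the mean of an early
# window against a late window, with variances of the window means taken
# from the spectral density at frequency zero (AR-fit estimator) so chain
# autocorrelation is accounted for.

# spectral density at zero via an AR model chosen by AIC
spectrum0_ar <- function(x) {
  v <- var(x)
  if (!is.finite(v) || v == 0) return(0)
  fit <- tryCatch(ar(x, aic = TRUE, order.max = min(length(x) - 1L, 30L)),
                  error = function(e) NULL)
  if (is.null(fit)) return(v)
  if (fit$order == 0L) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence z statistic
#'
#' Compares the mean of the first `first_frac` of a chain with the mean of
#' the last `last_frac`:
#' \deqn{z = (\bar x_A - \bar x_B) / \sqrt{\widehat{var}(\bar x_A) +
#'   \widehat{var}(\bar x_B)}}
#' with each window-mean variance estimated from the window's spectral
#' density at zero. Values of |z| above 1.96 suggest the chain has not
#' converged.
#'
#' @param chain numeric vector of retained draws for one parameter (length
#'   at least 20).
#' @param first_frac,last_frac window fractions in (0, 1); windows must not
#'   overlap (`first_frac + last_frac <= 1`). Defaults 0.1 and 0.5.
#' @return the z statistic, or `NA` (with a warning) when a window has zero
#'   variance.
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5) {
  n <- length(chain)
  if (n < 20L) stop("chain must have at least 20 draws", call. = FALSE)
  if (first_frac <= 0 || last_frac <= 0 || first_frac >= 1 ||
      last_frac >= 1 || first_frac + last_frac > 1)
    stop("window fractions must lie in (0, 1) and not overlap",
         call. = FALSE)
  a <- chain[seq_len(max(2L, floor(first_frac * n)))]
  b <- chain[seq.int(n - max(2L, floor(last_frac * n)) + 1L, n)]
  s_a <- spectrum0_ar(a)
  s_b <- spectrum0_ar(b)
  if (s_a == 0 || s_b == 0) {
    warning("zero-variance window: Geweke statistic undefined",
            call. = FALSE)
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sqrt(s_a / length(a) + s_b / length(b))
}
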