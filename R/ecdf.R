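#' Empirical CDF with an inverse-CDF quantile
#'
#' A thin container over a sorted sample supporting evaluation
#' \eqn{F(x) = } fraction of values \eqn{\le x} and the type-1
#' (inverse-CDF) quantile: the smallest sample value \eqn{v} with
#' \eqn{F(v) \ge q}.  The type-1 convention makes "there is a 95% probability
#' to find a process equal or smaller than the 95th-percentile length"
#' literally true on the sample.
#'
#' @param values numeric sample (lengths in um, or differences).
#' @return An object of class `empirical_cdf`.
#' @export
empirical_cdf <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values))) {
    stop("empirical CDF needs a nonempty finite sample")
  }
  structure(list(sorted_values = sort(values), n = length(values)),
            class = "empirical_cdf")
}

#' @rdname empirical_cdf
#' @param cdf an `empirical_cdf`.
#' @param x numeric vector of evaluation points.
#' @export
cdf_eval <- function(cdf, x) {
  stopifnot(inherits(cdf, "empirical_cdf"))
  findInterval(x, cdf$sorted_values) / cdf$n
}

#' @rdname empirical_cdf
#' @param q probabilities in `[0, 1]`.
#' @export
cdf_quantile <- function(cdf, q) {
  stopifnot(inherits(cdf, "empirical_cdf"), all(q >= 0 & q <= 1))
  # small slack keeps ceiling() exact when q arrives as k/n with float error
  idx <- pmax(1L, ceiling(q * cdf$n - 1e-9))
  cdf$sorted_values[idx]
}

#' @export
print.empirical_cdf <- function(x, ...) {
  cat("<empirical_cdf> n =", x$n,
      " range [", min(x$sorted_values), ",", max(x$sorted_values), "]\n")
  invisible(x)
}
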