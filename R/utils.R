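# Correlations are clipped to |r| <= R_MAX before atanh so Fisher z stays
# finite; Z_MAX = atanh(R_MAX) is the reported ceiling for perfect correlation.
R_MAX <- 1 - 1e-7

#' Fisher r-to-z transform with clipping
#'
#' `atanh` with `|r|` clipped to `1 - 1e-7` so that perfectly correlated
#' time courses map to a large finite ceiling rather than `Inf`.
#'
#' @param r Numeric vector of correlation coefficients.
#' @return Numeric vector of z scores.
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -R_MAX), R_MAX))

#' @rdname fisher_z
#' @export
z_max <- function() atanh(R_MAX)

# columns standardized to mean 0, unit L2 norm; zero-variance columns -> NA
# so that any correlation involving them propagates NA
standardize_cols <- function(x) {
  x <- sweep(x, 2L, colMeans(x), "-")
  nrm <- sqrt(colSums(x^2))
  nrm[nrm == 0] <- NA_real_
  sweep(x, 2L, nrm, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

msg <- function(...) message(sprintf(...))
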