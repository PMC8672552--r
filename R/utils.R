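#' @keywords internal
#' @importFrom stats median quantile rnorm runif rexp rgamma sd var cor
#'   cor.test pnorm pchisq qnorm uniroot rbinom setNames p.adjust
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# Round half away from zero (R's round() is banker's rounding).
roundHalfUp <- function(x) sign(x) * floor(abs(x) + 0.5)

# Population (1/n) central moment of order k.
popMoment <- function(x, k) {
  mean((x - mean(x))^k)
}

stopIfNot3d <- function(a, what) {
  if (!is.array(a) || length(dim(a)) != 3L)
    stop(what, " must be a 3D array", call. = FALSE)
}
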