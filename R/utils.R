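#' @useDynLib kickout, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor dist lm optim optimize rlnorm rnorm rpois
#'   runif sd t.test uniroot var
#' @importFrom utils read.csv write.csv
NULL

# classed error helper so callers can condition on failure modes
ko_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "kickout_error")))
}

ko_check <- function(cond, msg, class = "kickout_invalid_input") {
  if (!isTRUE(cond)) ko_stop(msg, class)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Counter-based sub-seed derivation.  Mixing is a Lehmer step modulo the
# Mersenne prime 2^31 - 1, so derived seeds stay valid 32-bit integers and
# stream k is independent of how many other streams were drawn before it.
derive_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  x <- (s * 48271) %% m
  x <- (x + as.numeric(k) * 69621) %% m
  as.integer((x * 16807) %% m)
}

# lognormal parameterized by mean 1 and coefficient of variation
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}
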