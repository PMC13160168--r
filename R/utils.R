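#' @importFrom rlang abort warn %||%
#' @importFrom stats dchisq runif rnorm optim median setNames integrate
#'   ks.test hclust cutree as.dist rbinom quantile sd
#' @importFrom utils head
NULL

# numerically stable log(sum(exp(x))); -Inf entries are ignored
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# stable pairwise log(exp(a) + exp(b)) for equal-length vectors
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

stopf <- function(fmt, ..., class = NULL) {
  abort(sprintf(fmt, ...), class = c(class, "shiftmatch_error"))
}

warnf <- function(fmt, ...) warn(sprintf(fmt, ...))
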