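# small numeric helpers shared across modules

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

# logit transform of theta against bounds (a, b), and its inverse
bounded_logit <- function(theta, a, b) {
  u <- (theta - a) / (b - a)
  eps <- 1e-12
  u <- pmin(pmax(u, eps), 1 - eps)
  logit(u)
}
bounded_inv_logit <- function(x, a, b) a + (b - a) * inv_logit(x)

# weighted quantiles by linear interpolation of the weighted ECDF
weighted_quantile <- function(x, w, probs) {
  if (length(x) == 1L) return(rep(x, length(probs)))
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  if (all(w == 0)) w <- rep(1, length(w))
  cw <- cumsum(w) - w / 2
  cw <- cw / sum(w)
  stats::approx(cw, x, xout = probs, rule = 2, ties = "ordered")$y
}

# mode of a weighted sample via Gaussian KDE, Silverman ("nrd0") bandwidth
# (bandwidth from the unweighted sample, then weighted density)
weighted_mode <- function(x, w) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, weights = w / sum(w), bw = stats::bw.nrd0(x))
  d$x[which.max(d$y)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
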