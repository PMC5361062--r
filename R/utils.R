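# Numerical helpers shared across modules.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)   # all -Inf
  m + log(sum(exp(x - m)))
}

#' Cosine similarity of two (sparse, named or aligned) numeric vectors
#'
#' Vectors may be named (sparse map word -> weight) or plain aligned numeric
#' vectors. Returns 0 when either vector has zero norm. Round-off is snapped:
#' values within 1e-12 of 1 are returned as exactly 1 so that identical
#' inputs give cosine distance exactly 0.
#'
#' @param a,b Numeric vectors, optionally named.
#' @return Cosine similarity in `[0, 1]` for non-negative inputs.
#' @export
cosine_sim <- function(a, b) {
  if (!is.null(names(a)) || !is.null(names(b))) {
    words <- union(names(a), names(b))
    av <- stats::setNames(numeric(length(words)), words)
    bv <- av
    av[names(a)] <- a
    bv[names(b)] <- b
    a <- av; b <- bv
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  s <- sum(a * b) / (na * nb)
  if (abs(s - 1) < 1e-12) s <- 1
  if (s > 1) s <- 1
  if (s < -1) s <- -1
  s
}

# Percentile bootstrap CI from a vector of resampled statistics.
percentile_ci <- function(x, level = 0.95) {
  alpha <- (1 - level) / 2
  stats::quantile(x, probs = c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
}

#' Area under the ROC curve by the rank statistic
#'
#' Equivalent to the Mann-Whitney U statistic normalized by the number of
#' positive-negative pairs; ties contribute 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical or 0/1 vector, `TRUE`/1 = positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
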