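#' Storey q-values with the smoother pi0 estimate
#'
#' Estimates the null proportion \eqn{\pi_0} by the smoother method: compute
#' \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m (1 - \lambda))} over the
#' grid \eqn{\lambda = 0.05, 0.10, \dots, 0.95}, fit a cubic smoothing spline
#' (3 df) and evaluate it at the largest \eqn{\lambda}, clamping into
#' \eqn{(0, 1]}.  Q-values are then
#' \eqn{q_i = \min_{p_j \ge p_i} \hat\pi_0 m p_j / rank(p_j)}, i.e. the BH
#' step-up values scaled by \eqn{\hat\pi_0}.  With \code{pi0 = 1} forced, the
#' result equals [adjustBH()].
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambda tuning grid for the pi0 smoother.
#' @param pi0 optional: force the null proportion instead of estimating it.
#' @return Numeric vector of q-values, with the estimate attached as
#'   attribute \code{"pi0"}.
#' @export
storeyQvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                          pi0 = NULL) {
    if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1))
        stop("'p' must be p-values in [0, 1]")
    m <- length(p)
    if (is.null(pi0)) {
        if (m < 2L) {
            message("fewer than 2 p-values: pi0 fixed at 1")
            pi0 <- 1
        } else {
            pi0l <- vapply(lambda,
                           function(l) mean(p > l) / (1 - l), 0)
            fit <- stats::smooth.spline(lambda, pi0l, df = 3)
            pi0 <- stats::predict(fit, x = max(lambda))$y
            # clamp: pi0 > 1 is impossible; non-positive estimates arise only
            # when nearly all p are tiny, in which case at most 1/m can be null
            pi0 <- min(max(pi0, 1 / m), 1)
        }
    } else {
        if (pi0 <= 0 || pi0 > 1)
            stop("'pi0' must lie in (0, 1]")
    }
    o <- order(p, decreasing = TRUE)
    q <- numeric(m)
    q[o] <- pmin(1, cummin(pi0 * m * p[o] / seq(m, 1)))
    attr(q, "pi0") <- pi0
    q
}
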