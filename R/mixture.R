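#' Session threshold from a two-component mixture of log gaps
#'
#' Inter-event gaps on an online platform are strongly bimodal on the log
#' scale: short within-session gaps (seconds to minutes of consecutive
#' consumption) and long between-session gaps (hours). Following the
#' session-identification approach of fitting a two-component Gaussian
#' mixture to log inter-event times, this function estimates the mixture by
#' EM on `log10(gap seconds)` and returns the session threshold `tau`: the
#' gap at which the two components' posterior responsibilities are equal,
#' searched between the two component means. The equal-responsibility
#' criterion stays well defined when the mixing weights are unequal.
#'
#' EM details: components are initialized from the exact one-dimensional
#' two-means split of the log gaps (deterministic, so refits are identical);
#' convergence is declared when the log-likelihood improves by less than
#' `tol`; a component standard deviation collapsing below `sd_floor` is a
#' degeneracy error.
#'
#' @param gaps_seconds Positive gaps in seconds.
#' @param min_gaps Minimum number of gaps required (default 50).
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param sd_floor Smallest admissible component sd on the log10 scale.
#' @param platform Optional label stored in the fit.
#' @return An object of class `gap_mixture_fit` with component means, sds and
#'   weights (ordered by mean), the threshold on both scales, the
#'   log-likelihood trace summary, and a convergence flag.
#' @examples
#' set.seed(1)
#' gaps <- 10^c(rnorm(300, 1, 0.3), rnorm(300, 3.5, 0.4))
#' fit <- fit_gap_mixture(gaps)
#' glance(fit)
#' @export
fit_gap_mixture <- function(gaps_seconds, min_gaps = 50, tol = 1e-6,
                            max_iter = 500, sd_floor = 1e-3, platform = NULL) {
  gaps_seconds <- gaps_seconds[is.finite(gaps_seconds)]
  if (any(gaps_seconds <= 0)) abort("gaps must be strictly positive seconds")
  n <- length(gaps_seconds)
  if (n < min_gaps) {
    abort(sprintf("too few gaps for a mixture fit: %d < %d", n, min_gaps))
  }
  x <- log10(gaps_seconds)
  if (sd(x) < sd_floor) abort("degenerate gaps: no variance on the log scale")

  init <- two_means_split(x)
  mu <- init$mu
  sigma <- pmax(init$sigma, sd_floor * 2)
  w <- init$w
  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sigma[1])
    d2 <- w[2] * dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    ll <- sum(log(tot))
    r1 <- d1 / tot
    n1 <- sum(r1)
    n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) abort("EM collapse: a component lost all mass")
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    sigma <- sqrt(c(
      sum(r1 * (x - mu[1])^2) / n1,
      sum((1 - r1) * (x - mu[2])^2) / n2
    ))
    if (any(sigma < sd_floor)) abort("EM collapse: degenerate component variance")
    w <- c(n1, n2) / n
    if (is.finite(loglik) && abs(ll - loglik) < tol) {
      converged <- TRUE
      loglik <- ll
      break
    }
    loglik <- ll
  }

  ord <- order(mu)
  mu <- mu[ord]; sigma <- sigma[ord]; w <- w[ord]

  thr <- responsibility_crossing(mu, sigma, w)
  structure(
    list(
      means = mu, sds = sigma, weights = w,
      threshold_log10 = thr, tau_seconds = 10^thr,
      n_gaps = n, loglik = loglik, iterations = iter,
      converged = converged, platform = platform
    ),
    class = "gap_mixture_fit"
  )
}

# exact 1-D two-means split: minimizes within-class sum of squares over all
# sorted split points (O(n) with cumulative sums); deterministic
two_means_split <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1)
  ss_left <- cs2[k] - cs[k]^2 / k
  ss_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  best <- which.min(ss_left + ss_right)
  left <- xs[seq_len(best)]
  right <- xs[(best + 1):n]
  list(
    mu = c(mean(left), mean(right)),
    sigma = c(max(sd(left), 0, na.rm = TRUE), max(sd(right), 0, na.rm = TRUE)),
    w = c(best, n - best) / n
  )
}

# log10-gap value between the component means where posterior
# responsibilities are equal, i.e. w1 N(x; m1, s1) = w2 N(x; m2, s2)
responsibility_crossing <- function(mu, sigma, w) {
  f <- function(x) {
    (log(w[1]) + dnorm(x, mu[1], sigma[1], log = TRUE)) -
      (log(w[2]) + dnorm(x, mu[2], sigma[2], log = TRUE))
  }
  lo <- mu[1]; hi <- mu[2]
  if (!(f(lo) > 0 && f(hi) < 0)) {
    abort("no equal-responsibility crossing between the component means")
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' @export
print.gap_mixture_fit <- function(x, ...) {
  cat("<gap_mixture_fit>", if (!is.null(x$platform)) paste0("platform = ", x$platform), "\n")
  cat(sprintf("  components (log10 s): N(%.3f, %.3f) w=%.3f | N(%.3f, %.3f) w=%.3f\n",
              x$means[1], x$sds[1], x$weights[1], x$means[2], x$sds[2], x$weights[2]))
  cat(sprintf("  tau = %.1f s (%.2f min); n_gaps = %d; converged = %s (%d iter)\n",
              x$tau_seconds, x$tau_seconds / 60, x$n_gaps, x$converged, x$iterations))
  invisible(x)
}

#' @rdname fit_gap_mixture
#' @param x A `gap_mixture_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gap_mixture_fit <- function(x, ...) {
  tibble(
    component = c("in_session", "between_session"),
    mean_log10 = x$means, sd_log10 = x$sds, weight = x$weights
  )
}

#' @rdname fit_gap_mixture
#' @exportS3Method generics::glance
glance.gap_mixture_fit <- function(x, ...) {
  tibble(
    tau_seconds = x$tau_seconds, threshold_log10 = x$threshold_log10,
    n_gaps = x$n_gaps, loglik = x$loglik,
    iterations = x$iterations, converged = x$converged
  )
}

#' @rdname fit_gap_mixture
#' @param object A `gap_mixture_fit` object.
#' @param bins Histogram bin count for the log10-gap axis.
#' @exportS3Method ggplot2::autoplot
autoplot.gap_mixture_fit <- function(object, bins = 60, ...) {
  grid <- seq(object$means[1] - 4 * object$sds[1],
              object$means[2] + 4 * object$sds[2], length.out = 400)
  dens <- tibble(
    x = rep(grid, 2),
    component = rep(c("in_session", "between_session"), each = length(grid)),
    density = c(
      object$weights[1] * dnorm(grid, object$means[1], object$sds[1]),
      object$weights[2] * dnorm(grid, object$means[2], object$sds[2])
    )
  )
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold_log10, linetype = "dashed") +
    ggplot2::labs(
      x = "log10 inter-event gap (s)", y = "weighted density",
      title = sprintf("Session threshold tau = %.1f s", object$tau_seconds)
    )
}
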