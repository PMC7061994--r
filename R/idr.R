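# Irreproducible discovery rate for matched peak-score pairs.
#
# Scores from the two pseudo-replicates are reduced to ranks, mapped to
# pseudo-values through the inverse CDF of the current estimate of the
# mixture marginal, and modelled as a two-component Gaussian mixture: a
# reproducible component with mean (mu, mu), variance sigma2 and correlation
# rho, and an irreproducible standard bivariate normal with zero
# correlation. Parameters (pi, mu, sigma2, rho) are estimated by
# pseudo-likelihood EM, re-deriving the pseudo-values from the updated
# marginal between EM rounds (the semiparametric copula fit). The local
# irreproducibility probability P(irreproducible | z) is converted to the
# expected-fraction IDR by cumulative averaging over pairs sorted by local
# probability.

dbvnorm <- function(x, y, mu, sigma2, rho) {
  det <- sigma2^2 * (1 - rho^2)
  q <- ((x - mu)^2 - 2 * rho * (x - mu) * (y - mu) + (y - mu)^2) /
    (sigma2 * (1 - rho^2))
  exp(-q / 2) / (2 * pi * sqrt(det))
}

# inverse of the mixture marginal CDF  G(z) = pi Phi((z-mu)/s) + (1-pi) Phi(z)
mix_marginal_inv <- function(u, p, mu, sigma2, n_grid = 4000) {
  s <- sqrt(sigma2)
  lo <- min(-6, mu - 6 * s); hi <- max(6, mu + 6 * s)
  grid <- seq(lo, hi, length.out = n_grid)
  cdf <- p * stats::pnorm((grid - mu) / s) + (1 - p) * stats::pnorm(grid)
  stats::approx(cdf, grid, xout = u, rule = 2, ties = "ordered")$y
}

#' Fit the IDR copula mixture to matched score pairs
#'
#' @param score1,score2 numeric scores of matched peaks in the two halves.
#' @param max_iter total EM iteration budget per start.
#' @param tol convergence tolerance on the parameter vector (largest change
#'   of pi/mu/sigma2/rho between marginal re-derivation rounds); the
#'   pseudo-likelihood itself jitters when the marginal is re-derived, so
#'   convergence is declared on the parameters.
#' @param inner_iter EM iterations between marginal re-derivations.
#' @return list with `pi` (reproducible fraction), `mu`, `sigma2`, `rho`,
#'   `local_idr` per pair, `idr` (expected-fraction IDR per pair),
#'   `n_iter`, `converged`, `loglik`.
#' @export
idr_fit <- function(score1, score2, max_iter = 20000, tol = 1e-4,
                    inner_iter = 20) {
  n <- length(score1)
  if (n != length(score2)) stop_("score vectors must have equal length")
  if (n < 20) stop_("need at least 20 matched pairs for a stable IDR fit")
  if (length(unique(score1)) == 1 || length(unique(score2)) == 1) {
    stop_("degenerate ranks: all scores tied in one half")
  }
  u1 <- rank(score1, ties.method = "average") / (n + 1)
  u2 <- rank(score2, ties.method = "average") / (n + 1)

  run_em <- function(p, mu, sigma2, rho) {
    par_old <- c(-1, -1, -1, -1)
    converged <- FALSE; total_it <- 0; ll <- -Inf
    while (total_it < max_iter) {
      z1 <- mix_marginal_inv(u1, p, mu, sigma2)
      z2 <- mix_marginal_inv(u2, p, mu, sigma2)
      for (k in seq_len(inner_iter)) {
        total_it <- total_it + 1
        f1 <- dbvnorm(z1, z2, mu, sigma2, rho)
        f0 <- dnorm(z1) * dnorm(z2)
        dens <- p * f1 + (1 - p) * f0
        dens[dens < 1e-300] <- 1e-300
        g <- p * f1 / dens
        ll <- sum(log(dens))
        sg <- sum(g)
        p <- min(max(sg / n, 1e-4), 1 - 1e-4)
        # the reproducible component sits at or above the noise component
        mu <- max(sum(g * (z1 + z2)) / (2 * sg), 0.01)
        sigma2 <- max(sum(g * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * sg), 1e-3)
        rho <- sum(g * (z1 - mu) * (z2 - mu)) / (sigma2 * sg)
        rho <- min(max(rho, -0.999), 0.999)
        if (total_it >= max_iter) break
      }
      par <- c(p, mu, sigma2, rho)
      if (max(abs(par - par_old)) < tol) { converged <- TRUE; break }
      par_old <- par
    }
    list(pi = p, mu = mu, sigma2 = sigma2, rho = rho, n_iter = total_it,
         converged = converged, loglik = ll)
  }

  # multi-start: flat mixture likelihoods have local optima; keep the best
  # converged solution
  starts <- list(c(0.5, 1, 1, 0.5), c(0.7, 2, 1, 0.8), c(0.95, 0.2, 1, 0.2))
  fits <- lapply(starts, function(s) run_em(s[1], s[2], s[3], s[4]))
  ok <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(ok)) {
    f <- fits[[1]]
    stop_(paste("IDR EM did not converge in %d iterations from any start",
                "(last loglik %.4f, pi %.3f, rho %.3f)"),
          max_iter, f$loglik, f$pi, f$rho)
  }
  fit <- fits[ok][[which.max(vapply(fits[ok], function(f) f$loglik, numeric(1)))]]

  z1 <- mix_marginal_inv(u1, fit$pi, fit$mu, fit$sigma2)
  z2 <- mix_marginal_inv(u2, fit$pi, fit$mu, fit$sigma2)
  f1 <- dbvnorm(z1, z2, fit$mu, fit$sigma2, fit$rho)
  f0 <- dnorm(z1) * dnorm(z2)
  joint <- fit$pi * f1 + (1 - fit$pi) * f0

  # signal guard: with no rank correlation the mixture is unidentifiable and
  # any labelling is arbitrary; compare the fitted copula against the
  # independence copula (likelihood-ratio vs chi-square, 4 free parameters)
  # and declare nothing reproducible when the gain is within noise
  s <- sqrt(fit$sigma2)
  g1 <- fit$pi * dnorm((z1 - fit$mu) / s) / s + (1 - fit$pi) * dnorm(z1)
  g2 <- fit$pi * dnorm((z2 - fit$mu) / s) / s + (1 - fit$pi) * dnorm(z2)
  cop_lr <- 2 * sum(log(pmax(joint, 1e-300)) - log(pmax(g1 * g2, 1e-300)))
  no_signal <- cop_lr < stats::qchisq(0.999, df = 4)

  if (no_signal) {
    local <- rep(1, n)
    idr <- rep(1, n)
  } else {
    local <- (1 - fit$pi) * f0 / joint
    ord <- order(local)
    idr <- numeric(n)
    idr[ord] <- cumsum(local[ord]) / seq_len(n)
  }
  c(fit, list(local_idr = local, idr = idr, copula_lr = cop_lr,
              no_signal = no_signal))
}

#' Filter matched peak pairs by IDR
#'
#' @param pairs data.frame with `score1` and `score2` columns (as produced
#'   by [reproducible_peaks()]).
#' @param threshold IDR cutoff; pairs with IDR strictly below it are kept.
#' @param ... passed to [idr_fit()].
#' @return list with `pairs` (input plus `idr` and `keep` columns) and
#'   `fit` (the mixture fit).
#' @export
idr_filter <- function(pairs, threshold = 0.05, ...) {
  fit <- idr_fit(pairs$score1, pairs$score2, ...)
  pairs$idr <- fit$idr
  pairs$keep <- fit$idr < threshold
  list(pairs = pairs, fit = fit)
}
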