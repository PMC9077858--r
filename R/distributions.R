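# Internal distribution machinery for the cohort generator.
#
# Every continuous variable is represented by a quantile function Q(p) so the
# generator can (a) draw marginally-calibrated values from uniforms, (b) share
# one uniform between the component criteria of an organ-failure flag
# (comonotone coupling, which makes the joint exceedance rate equal to the
# smaller marginal exceedance), and (c) evolve values over days through an
# AR(1) walk on the normal score of the same uniform.

# truncated normal quantile; mu is the *untruncated* location
q_truncnorm <- function(p, mu, sd, lo, hi) {
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(plo + p * (phi - plo), mu, sd)
}

truncnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# solve the untruncated location so that the truncated mean hits `target`
solve_truncnorm_mu <- function(target, sd, lo, hi) {
  stats::uniroot(function(m) truncnorm_mean(m, sd, lo, hi) - target,
                 lower = target - 6 * sd, upper = target + 6 * sd,
                 tol = 1e-9)$root
}

# discrete truncated normal on lo..hi (Glasgow Coma Scale); location solved
# so the pmf mean matches `target`
discnorm_pmf <- function(mu, sd, lo, hi) {
  k <- lo:hi
  p <- stats::dnorm(k, mu, sd)
  p / sum(p)
}

solve_discnorm_mu <- function(target, sd, lo, hi) {
  k <- lo:hi
  f <- function(m) sum(k * discnorm_pmf(m, sd, lo, hi)) - target
  stats::uniroot(f, lower = lo - 4 * sd, upper = hi + 4 * sd, tol = 1e-9)$root
}

lognorm_from_mq <- function(median, q1, q3) {
  list(mu = log(median), sigma = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

lognorm_from_ms <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

# Quantile-range limits for the resolved distributions. The full range
# (0, 1) keeps the parametric tails: occasional extreme laboratory values
# are a feature of real sepsis cohorts and of the consensus-clustering
# behaviour the pipeline is built to reproduce. (Restricting the range,
# e.g. to the 2nd-98th percentiles, preserves all reported medians and
# IQRs and can be used to study tail sensitivity.)
TRIM_LO <- 0
TRIM_HI <- 1
trim_u <- function(u) TRIM_LO + (TRIM_HI - TRIM_LO) * u

trim_resolved <- function(entry) {
  q0 <- entry$q
  cdf0 <- entry$cdf
  entry$q <- function(p) q0(trim_u(p))
  entry$cdf <- function(x) {
    pmin(pmax((cdf0(x) - TRIM_LO) / (TRIM_HI - TRIM_LO), 0), 1)
  }
  grid <- seq(1 / 4096, 1 - 1 / 4096, length.out = 2048)
  entry$mean <- mean(q0(trim_u(grid)))
  entry
}

# Resolve a config spec into per-phenotype quantile functions and moments.
# `separation` scales phenotype locations away from the mixture-weighted
# pooled location on the model (normal / log-normal) scale.
resolve_continuous <- function(spec, weights, separation = 1) {
  ph <- c("A", "B", "C", "D")
  out <- vector("list", 4)
  names(out) <- ph
  if (spec$family == "truncnorm") {
    mu <- vapply(ph, function(k) {
      solve_truncnorm_mu(spec$mean[[k]], spec$sd[[k]], spec$lo, spec$hi)
    }, numeric(1))
    mu <- scale_locations(mu, weights, separation)
    for (k in ph) {
      out[[k]] <- local({
        m <- mu[[k]]; s <- spec$sd[[k]]; lo <- spec$lo; hi <- spec$hi
        plo <- stats::pnorm(lo, m, s); phi <- stats::pnorm(hi, m, s)
        list(q = function(p) q_truncnorm(p, m, s, lo, hi),
             cdf = function(x) {
               pmin(pmax((stats::pnorm(x, m, s) - plo) / (phi - plo), 0), 1)
             },
             mean = truncnorm_mean(m, s, lo, hi))
      })
    }
  } else if (spec$family == "discnorm") {
    mu <- vapply(ph, function(k) {
      solve_discnorm_mu(spec$mean[[k]], spec$sd[[k]], spec$lo, spec$hi)
    }, numeric(1))
    mu <- scale_locations(mu, weights, separation)
    for (k in ph) {
      out[[k]] <- local({
        pmf <- discnorm_pmf(mu[[k]], spec$sd[[k]], spec$lo, spec$hi)
        vals <- spec$lo:spec$hi
        cdf <- cumsum(pmf)
        list(q = function(p) vals[findInterval(p, cdf, left.open = TRUE) + 1],
             cdf = function(x) c(0, cdf)[findInterval(x, vals) + 1],
             mean = sum(vals * pmf))
      })
    }
  } else {
    par <- if (spec$family == "lognorm_mq") {
      lapply(ph, function(k) {
        lognorm_from_mq(spec$median[[k]], spec$q1[[k]], spec$q3[[k]])
      })
    } else {
      lapply(ph, function(k) lognorm_from_ms(spec$mean[[k]], spec$sd[[k]]))
    }
    names(par) <- ph
    mu <- scale_locations(vapply(par, `[[`, numeric(1), "mu"), weights,
                          separation)
    for (k in ph) {
      out[[k]] <- local({
        m <- mu[[k]]; s <- par[[k]]$sigma
        list(q = function(p) stats::qlnorm(p, m, s),
             cdf = function(x) stats::plnorm(x, m, s),
             mean = exp(m + s^2 / 2))
      })
    }
  }
  lapply(out, trim_resolved)
}

scale_locations <- function(loc, weights, separation) {
  pooled <- sum(weights * loc)
  pooled + separation * (loc - pooled)
}

# binary rate scaling on the logit scale, clamped away from 0/1
scale_rates <- function(p, weights, separation) {
  pc <- pmin(pmax(p, 1e-4), 1 - 1e-4)
  lo <- stats::qlogis(pc)
  pooled <- sum(weights * lo)
  out <- stats::plogis(pooled + separation * (lo - pooled))
  # keep exact structural zeros/ones at the calibrated separation
  if (separation == 1) out[p %in% c(0, 1)] <- p[p %in% c(0, 1)]
  out
}

# log-normal quantile function with a fixed shape and a location solved so
# that P(X < threshold) = p_below (used for the labs that only exist to make
# an organ-failure criterion fire at the right rate)
lognorm_threshold_q <- function(threshold, p_below, sigma) {
  p_below <- pmin(pmax(p_below, 1e-4), 1 - 1e-4)
  mu <- log(threshold) - sigma * stats::qnorm(p_below)
  function(p) stats::qlnorm(p, mu, sigma)
}
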