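# Independent reference implementations used as oracles. These are coded
# from the definitions, deliberately not sharing code paths with the
# package: the LOWESS oracle is a naive O(n^2) loop with no delta
# interpolation, and the Fisher oracle enumerates the hypergeometric
# support with log-binomial coefficients.

# Naive robust locally weighted regression, no delta acceleration.
lowess_oracle <- function(y, frac = 0.1, it = 3) {
  n <- length(y)
  x <- as.numeric(seq_len(n))
  q <- min(n, max(2L, ceiling(frac * n)))
  rw <- rep(1, n)
  fit <- numeric(n)
  for (iter in 0:it) {
    for (i in seq_len(n)) {
      d <- abs(x - x[i])
      ord <- order(d, seq_len(n))
      sel <- sort(ord[seq_len(q)])
      h <- max(d[sel])
      w <- if (h > 0) (1 - pmin(d[sel] / h, 1)^3)^3 else rep(1, q)
      w <- w * rw[sel]
      if (sum(w) <= 0) {
        fit[i] <- mean(y[sel])
        next
      }
      cf <- stats::lm.wfit(cbind(1, x[sel]), y[sel], w)$coefficients
      fit[i] <- if (any(is.na(cf))) {
        sum(w * y[sel]) / sum(w)
      } else {
        cf[1] + cf[2] * x[i]
      }
    }
    if (iter == it) break
    res <- y - fit
    s6 <- 6 * stats::median(abs(res))
    if (s6 <= 1e-7 * max(mean(abs(y)), .Machine$double.eps)) break
    rw <- pmax(1 - pmin(abs(res) / s6, 1)^2, 0)^2
  }
  fit
}

# Two-sided Fisher p by explicit enumeration over all tables with the
# observed margins, probabilities from log binomial coefficients.
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ])
  n2 <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(m + n2, k)
  pmf <- exp(logp)
  p_obs <- pmf[match(a, support)]
  sum(pmf[pmf <= p_obs * (1 + 1e-7)])
}

# Closed-form mean of an exponential(mean) conditioned on [lo, hi].
trunc_exp_mean_oracle <- function(mean, lo, hi) {
  lam <- 1 / mean
  d <- hi - lo
  lo + 1 / lam - d * exp(-lam * d) / (1 - exp(-lam * d))
}

# Repeated-measures two-way ANOVA reference via aov() error strata.
rm_anova_oracle <- function(yr, yu) {
  n <- nrow(yr)
  tp <- ncol(yr)
  d <- expand.grid(subject = factor(seq_len(n)),
                   type = factor(c("r", "u")),
                   time = factor(seq_len(tp)))
  d$y <- mapply(function(s, ty, ti) if (ty == "r") yr[s, ti] else yu[s, ti],
                as.integer(d$subject), as.character(d$type),
                as.integer(d$time))
  s <- summary(stats::aov(y ~ type * time + Error(subject / (type * time)),
                          data = d))
  c(
    time = s[["Error: subject:time"]][[1]]["time", "F value"],
    trial_type = s[["Error: subject:type"]][[1]]["type", "F value"],
    interaction = s[["Error: subject:type:time"]][[1]]["type:time", "F value"]
  )
}
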