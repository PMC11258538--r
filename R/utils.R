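#' @keywords internal
"_PACKAGE"

#' @import tibble
#' @importFrom rlang abort warn %||% .data
#' @importFrom stats median pnorm qnorm rbinom rexp rgeom rlnorm rnbinom rnorm
#'   rpois runif sd cor.test t.test dhyper approx complete.cases setNames
#' @importFrom utils head tail
NULL

# -- argument checks ----------------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE,
                         allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    abort(sprintf("`%s` must be supplied.", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).",
      name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_probability <- function(x, name) {
  check_number(x, name, lower = 0, upper = 1)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

# Draw from a normal distribution truncated to [lo, hi] by CDF inversion.
# Inversion keeps the draw count deterministic for a given RNG state.
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (n == 0L) return(numeric(0))
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  if (p_hi <= p_lo) abort("Degenerate truncation interval for normal draw.")
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# Discrete count-distribution spec used for licks-per-bout: a list with a
# `name` and its parameters. All variants are shifted to be >= 1.
draw_counts <- function(n, spec) {
  if (n == 0L) return(integer(0))
  switch(spec$name,
    fixed = rep.int(as.integer(spec$size), n),
    geometric = 1L + rgeom(n, prob = 1 / spec$mean),
    nbinom = 1L + rnbinom(n, size = spec$size, mu = spec$mu),
    poisson = 1L + rpois(n, lambda = spec$lambda),
    abort(sprintf("Unknown count distribution `%s`.", spec$name))
  )
}

validate_count_spec <- function(spec, name) {
  if (!is.list(spec) || is.null(spec$name)) {
    abort(sprintf("`%s` must be a list with a `name` element.", name))
  }
  switch(spec$name,
    fixed = check_number(spec$size, paste0(name, "$size"), lower = 1),
    geometric = check_number(spec$mean, paste0(name, "$mean"), lower = 1,
                             strict_lower = TRUE),
    nbinom = {
      check_number(spec$size, paste0(name, "$size"), lower = 0,
                   strict_lower = TRUE)
      check_number(spec$mu, paste0(name, "$mu"), lower = 0)
    },
    poisson = check_number(spec$lambda, paste0(name, "$lambda"), lower = 0),
    abort(sprintf("Unknown count distribution `%s`.", spec$name))
  )
  invisible(spec)
}

new_config <- function(x, subclass) {
  structure(x, class = c(subclass, "lick_config", "list"))
}

#' @export
print.lick_config <- function(x, ...) {
  cat("<", class(x)[1L], ">\n", sep = "")
  flat <- unlist(x)
  for (nm in names(flat)) cat(" ", nm, "=", format(flat[[nm]]), "\n")
  invisible(x)
}
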