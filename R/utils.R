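# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    assert_scalar_num(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# trapezoid rule on an (x, y) grid
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# simple-regression summaries computed directly, so exact (zero-residual)
# data does not trip the degenerate-fit warnings of summary.lm/confint
ols_line <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- if (n > 2) sum(res^2) / (n - 2) else 0
  ss_tot <- sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(s2 / sxx),
       intercept_se = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
       r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1,
       df = n - 2)
}
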