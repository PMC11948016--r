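#' Sequential irreversible RNA-adsorption model
#'
#' Parameters of the initial-stage adsorption process: `r0` RNA molecules and
#' `L0` liposomes set the target mean load `r0 / L0`; the per-liposome
#' adsorption rate is either `lambda0 * (k + 1)` for a liposome already
#' holding `k` RNAs (`rate_rule = "linear"`, whose time-t load law is exactly
#' geometric) or a constant `lambda0` (`rate_rule = "constant"`, a Poisson
#' negative control).
#'
#' @param r0 initial RNA molecule count (> 0).
#' @param L0 liposome count (> 0).
#' @param lambda0 base adsorption rate per unit time (>= 0).
#' @param rate_rule `"linear"` (rate proportional to k + 1) or `"constant"`.
#' @return Object of class `adsorption_model` with `target_mean = r0 / L0`.
#' @export
adsorption_model <- function(r0, L0, lambda0 = 1,
                             rate_rule = c("linear", "constant")) {
  rate_rule <- match.arg(rate_rule)
  assert_scalar_num(r0, "r0", lower = 0, strict_lower = TRUE)
  assert_scalar_num(L0, "L0", lower = 0, strict_lower = TRUE)
  assert_scalar_num(lambda0, "lambda0", lower = 0)
  structure(list(r0 = r0, L0 = L0, lambda0 = lambda0, rate_rule = rate_rule,
                 target_mean = r0 / L0),
            class = "adsorption_model")
}

#' @export
print.adsorption_model <- function(x, ...) {
  cat(sprintf("Adsorption model: r0 = %g, L0 = %g (target mean %g), lambda0 = %g, rate rule '%s'\n",
              x$r0, x$L0, x$target_mean, x$lambda0, x$rate_rule))
  invisible(x)
}

#' Equilibrium RNA-per-liposome distribution
#'
#' The discrete form is geometric on 0, 1, 2, ...:
#' `P(n) = (1 / (1 + m)) * (m / (1 + m))^n` with mean `m`; the continuum form
#' is the exponential density `(1/m) exp(-n/m)`, its large-mean limit, whose
#' mean-scaled density is `exp(-x)`.
#'
#' @param mean target mean load (>= 0).
#' @param form `"discrete"` or `"continuum"`.
#' @param tail_mass support truncated where the remaining tail mass drops
#'   below this (discrete form).
#' @return Object of class `rna_load_distribution`: `support`, `pmf` (or
#'   `density` function for the continuum form), `mean`, `form`.
#' @export
equilibrium_distribution <- function(mean, form = c("discrete", "continuum"),
                                     tail_mass = 1e-12) {
  form <- match.arg(form)
  assert_scalar_num(mean, "mean", lower = 0)
  if (form == "continuum") {
    if (mean <= 0) stop("continuum form requires mean > 0")
    return(structure(list(form = "continuum", mean = mean,
                          density = function(x) exp(-x / mean) / mean,
                          survival = function(x) exp(-x / mean)),
                     class = "rna_load_distribution"))
  }
  if (mean == 0) {
    return(structure(list(form = "discrete", support = 0L, pmf = 1,
                          mean = 0),
                     class = "rna_load_distribution"))
  }
  q <- mean / (1 + mean)
  kmax <- max(1L, ceiling(log(tail_mass) / log(q)))
  support <- 0:kmax
  pmf <- (1 - q) * q^support
  structure(list(form = "discrete", support = support, pmf = pmf,
                 mean = sum(support * pmf)),
            class = "rna_load_distribution")
}

#' @export
print.rna_load_distribution <- function(x, ...) {
  if (x$form == "continuum")
    cat(sprintf("RNA load distribution (continuum exponential), mean %g\n",
                x$mean))
  else
    cat(sprintf("RNA load distribution (discrete), mean %.6g, support 0..%d\n",
                x$mean, max(x$support)))
  invisible(x)
}

#' Maximum-entropy load distribution for a fixed mean
#'
#' Numerically maximizes Shannon entropy over a truncated non-negative
#' integer support subject to normalization and a fixed mean, by solving the
#' exponential-family dual: the optimizer has the form
#' `p_k = exp(-theta k) / Z(theta)` and `theta` is found by root-finding on
#' the mean constraint. Coincides with the kinetic equilibrium law.
#'
#' @param mean target mean (> 0).
#' @param tail_mass support truncation criterion.
#' @return An `rna_load_distribution`.
#' @export
maxent_distribution <- function(mean, tail_mass = 1e-12) {
  assert_scalar_num(mean, "mean", lower = 0, strict_lower = TRUE)
  q <- mean / (1 + mean)
  kmax <- max(2L, ceiling(log(tail_mass) / log(q)))
  support <- 0:kmax
  mean_of_theta <- function(theta) {
    w <- exp(-theta * support)
    sum(support * w) / sum(w)
  }
  # theta > 0 for mean below the uniform mean kmax/2
  f <- function(theta) mean_of_theta(theta) - mean
  sol <- tryCatch(uniroot(f, lower = 1e-12, upper = 50, tol = 1e-14,
                          extendInt = "downX"),
                  error = function(e)
                    stop("max-entropy solve did not converge: ",
                         conditionMessage(e)))
  w <- exp(-sol$root * support)
  pmf <- w / sum(w)
  structure(list(form = "discrete", support = support, pmf = pmf,
                 mean = sum(support * pmf), theta = sol$root),
            class = "rna_load_distribution")
}

#' Total-variation distance between two discrete load distributions
#'
#' @param p,q `rna_load_distribution`s in discrete form.
#' @return Total-variation distance.
#' @export
tv_distance <- function(p, q) {
  stopifnot(p$form == "discrete", q$form == "discrete")
  kmax <- max(max(p$support), max(q$support))
  pv <- qv <- numeric(kmax + 1)
  pv[p$support + 1] <- p$pmf
  qv[q$support + 1] <- q$pmf
  sum(abs(pv - qv)) / 2
}

#' Exact stochastic simulation of the adsorption birth process
#'
#' Simulates `n_liposomes` independent pure-birth trajectories. Under the
#' linear rule the embedded jump chain allocates each successive RNA to
#' liposome i with probability proportional to `k_i + 1`, simulated exactly
#' by an urn scheme in O(1) per event; waiting times are drawn from the exact
#' exponential law with the total rate `lambda0 * sum(k_i + 1)`. Counts never
#' decrease. Stops either when the empirical mean load reaches the model's
#' target mean, or at a fixed time.
#'
#' @param model an [adsorption_model()].
#' @param n_liposomes number of simulated liposomes.
#' @param stop list: `list(type = "target_mean")` (default; uses
#'   `model$target_mean`) or `list(type = "time", t = t_end)`.
#' @param seed optional RNG seed.
#' @param max_events guard on the total number of adsorption events.
#' @param finite_pool if TRUE, cap total adsorbed RNA at
#'   `r0 * n_liposomes / L0`.
#' @return Object of class `adsorption_sim`: `counts` (per-liposome loads),
#'   `event_times`, `event_liposome`, `t_end`, `model`.
#' @export
simulate_adsorption <- function(model, n_liposomes,
                                stop = list(type = "target_mean"),
                                seed = NULL, max_events = 1e7,
                                finite_pool = FALSE) {
  stopifnot(inherits(model, "adsorption_model"))
  assert_scalar_num(n_liposomes, "n_liposomes", lower = 1)
  set_seed_if(seed)
  n <- as.integer(n_liposomes)
  lam <- model$lambda0
  target_events <- if (identical(stop$type, "target_mean")) {
    if (lam == 0) stop("target mean unreachable with lambda0 = 0")
    ceiling(model$target_mean * n)
  } else Inf
  t_end <- if (identical(stop$type, "time")) stop$t else Inf
  if (!is.finite(target_events) && !is.finite(t_end))
    stop("stop rule must be 'target_mean' or 'time'")
  pool_cap <- if (finite_pool) floor(model$r0 * n / model$L0) else Inf
  counts <- integer(n)
  cap <- min(target_events, max_events, pool_cap)
  alloc <- as.integer(min(cap, max(1024, 4L * n)))
  ev_t <- numeric(alloc)
  ev_l <- integer(alloc)
  if (model$rate_rule == "linear") {
    slots <- integer(n + alloc)
    slots[seq_len(n)] <- seq_len(n)
    nslots <- n
  }
  t <- 0
  m <- 0L
  while (m < cap) {
    total_rate <- if (model$rate_rule == "linear") lam * (n + m) else lam * n
    if (total_rate <= 0) break
    t <- t + rexp(1, total_rate)
    if (t > t_end) break
    m <- m + 1L
    if (m > alloc) {  # grow event storage geometrically
      alloc <- as.integer(min(2L * alloc, max(cap, 2L * alloc)))
      length(ev_t) <- alloc
      length(ev_l) <- alloc
      if (model$rate_rule == "linear") length(slots) <- n + alloc
    }
    if (model$rate_rule == "linear") {
      lip <- slots[sample.int(nslots, 1L)]
      nslots <- nslots + 1L
      slots[nslots] <- lip
    } else {
      lip <- sample.int(n, 1L)
    }
    counts[lip] <- counts[lip] + 1L
    ev_t[m] <- t
    ev_l[m] <- lip
  }
  if (is.finite(target_events) && m < target_events && m >= max_events)
    stop("target mean not reached within max_events")
  structure(list(counts = counts, event_times = ev_t[seq_len(m)],
                 event_liposome = ev_l[seq_len(m)],
                 t_end = if (is.finite(t_end)) t_end else t, model = model),
            class = "adsorption_sim")
}

#' @export
print.adsorption_sim <- function(x, ...) {
  cat(sprintf("Adsorption simulation: %d liposomes, %d events, empirical mean load %.4f\n",
              length(x$counts), length(x$event_times), mean(x$counts)))
  invisible(x)
}

#' Linear fit of mean RNA load versus RNA-to-liposome mass ratio
#'
#' Least-squares line through `(mass_ratio, mean_intensity)` pairs; reports
#' whether the intercept is consistent with zero at the 95% level.
#'
#' @param mass_ratio RNA-to-liposome mass ratios (>= 3 distinct levels).
#' @param mean_intensity measured mean RNA intensity per liposome at each
#'   ratio.
#' @return List with `slope`, `intercept`, `r_squared`,
#'   `intercept_ci` (95%), `intercept_consistent_with_zero`.
#' @export
fit_mean_vs_ratio <- function(mass_ratio, mean_intensity) {
  if (length(unique(mass_ratio)) < 3)
    stop("need at least 3 distinct mass-ratio levels")
  fit <- ols_line(mass_ratio, mean_intensity)
  tq <- qt(0.975, max(fit$df, 1))
  ci <- fit$intercept + c(-1, 1) * tq * fit$intercept_se
  list(slope = fit$slope,
       intercept = fit$intercept,
       r_squared = fit$r_squared,
       intercept_ci = ci,
       intercept_consistent_with_zero = ci[1] <= 0 && ci[2] >= 0)
}
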