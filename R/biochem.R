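# Roadblock-efficiency (E_RB) quantification, complex-stability decay fits,
# and the condition-comparison statistics.

#' Raw roadblock ratio from lane intensities
#'
#' Background-subtracted roadblock band intensity divided by
#' background-subtracted scaffold intensity, floored at zero.
#'
#' @param roadblock,scaffold,background lane intensities (arbitrary units);
#'   vectorized, `background` recycled.
#' @return Numeric ratio(s) >= 0.
#' @export
compute_erb <- function(roadblock, scaffold, background = 0) {
  if (any(roadblock < 0) || any(scaffold < 0) || any(background < 0))
    .stopf("negative intensity")
  den <- scaffold - background
  if (any(den <= 0))
    .stopf("non-positive denominator: scaffold intensity must exceed background")
  pmax(0, (roadblock - background) / den)
}

#' Rescale a salt-titration series to E_RB
#'
#' Each lane's raw roadblock ratio is divided by the ratio of the anchor-salt
#' lane, pinning E_RB = 1 at the anchor (background already maps to 0 through
#' the background subtraction in [compute_erb()]).
#'
#' @param lanes data.frame with columns `salt_mM`, `roadblock`, `scaffold`
#'   and optionally `background` (default 0) and `condition`.
#' @param anchor_salt salt concentration (mM) of the anchor lane; default 50.
#' @return `lanes` with columns `erb_raw` and `erb` added.
#' @export
rescale_titration <- function(lanes, anchor_salt = 50) {
  stopifnot(is.data.frame(lanes))
  need <- c("salt_mM", "roadblock", "scaffold")
  miss <- setdiff(need, names(lanes))
  if (length(miss)) .stopf("lane table lacks column(s): %s",
                           paste(miss, collapse = ", "))
  bg <- lanes$background %||% 0
  lanes$erb_raw <- compute_erb(lanes$roadblock, lanes$scaffold, bg)
  i <- which(lanes$salt_mM == anchor_salt)
  if (!length(i)) .stopf("no lane at the anchor salt (%g mM)", anchor_salt)
  anchor <- lanes$erb_raw[i[1]]
  if (anchor <= 0) .stopf("anchor lane has non-positive raw ratio")
  lanes$erb <- lanes$erb_raw / anchor
  lanes
}

#' Normalize replicate E_RB values to a reference condition
#'
#' Every replicate is divided by the mean of the reference condition, so the
#' reference mean maps to exactly 1. Mean and standard deviation (SD, not
#' SEM) are reported per condition.
#'
#' @param values named list: condition -> numeric vector of replicate E_RB.
#' @param reference_condition name of the reference condition.
#' @return data.frame (condition, mean, sd, n) with attribute
#'   `"normalized_values"` holding the rescaled replicates.
#' @export
normalize_erb <- function(values, reference_condition) {
  stopifnot(is.list(values), !is.null(names(values)))
  if (!reference_condition %in% names(values))
    .stopf("reference condition '%s' absent", reference_condition)
  ref_mean <- mean(values[[reference_condition]])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    .stopf("reference condition mean must be > 0")
  normed <- lapply(values, function(v) v / ref_mean)
  # means/SDs divided after aggregation so the reference mean is exactly 1
  out <- data.frame(
    condition = names(values),
    mean = vapply(values, mean, numeric(1)) / ref_mean,
    sd = vapply(values, sd, numeric(1)) / ref_mean,
    n = vapply(values, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "normalized_values") <- normed
  out
}

#' Fraction of intact complex from a decay timepoint signal
#'
#' Normalizes the summed lane signal between the no-NTP control (100%
#' intact) and the proteinase K control (background), clipping to \[0, 1\];
#' any clipping is reported via a warning and the `"n_clipped"` attribute.
#'
#' @param signal signal at each timepoint (arbitrary units).
#' @param no_ntp_control,pk_control control signals; must satisfy
#'   `no_ntp_control > pk_control`.
#' @return Fractions in \[0, 1\].
#' @export
fraction_intact <- function(signal, no_ntp_control, pk_control) {
  if (any(no_ntp_control <= pk_control))
    .stopf("no-NTP control must exceed proteinase K control")
  f <- (signal - pk_control) / (no_ntp_control - pk_control)
  n_clip <- sum(f < 0 | f > 1)
  if (n_clip) .warnf("%d fraction value(s) clipped to [0, 1]", n_clip)
  f <- pmin(1, pmax(0, f))
  attr(f, "n_clipped") <- n_clip
  f
}

# bi-exponential model and its constrained least-squares fit.
# Variable projection: for fixed rates the amplitudes are a two-column
# non-negative least-squares subproblem, solved exactly in closed form
# (unconstrained 2x2 normal equations; if a coefficient is negative the
# optimum lies on a face, i.e. the better of the two single-column fits);
# rates are optimized by Nelder-Mead on log scale from a grid of starts.
.biexp <- function(t, a1, k1, a2, k2) a1 * exp(-k1 * t) + a2 * exp(-k2 * t)

.nnls2 <- function(x1, x2, y) {
  s11 <- sum(x1 * x1); s22 <- sum(x2 * x2)
  s12 <- sum(x1 * x2); b1 <- sum(x1 * y); b2 <- sum(x2 * y)
  det <- s11 * s22 - s12 * s12
  if (det > 1e-14 * s11 * s22) {
    a <- c(s22 * b1 - s12 * b2, s11 * b2 - s12 * b1) / det
    if (all(a >= 0)) return(a)
  }
  a1 <- max(0, if (s11 > 0) b1 / s11 else 0)
  a2 <- max(0, if (s22 > 0) b2 / s22 else 0)
  r1 <- sum((y - a1 * x1)^2); r2 <- sum((y - a2 * x2)^2)
  if (r1 <= r2) c(a1, 0) else c(0, a2)
}

.biexp_rss <- function(logk, t, y) {
  k <- exp(logk)
  x1 <- exp(-k[1] * t); x2 <- exp(-k[2] * t)
  a <- .nnls2(x1, x2, y)
  sum((y - a[1] * x1 - a[2] * x2)^2)
}

.biexp_solve <- function(t, y) {
  tmax <- max(t[t > 0], 1)
  kgrid <- log(2) / (tmax * c(0.05, 0.2, 1, 5, 20))
  starts <- expand.grid(k1 = kgrid, k2 = kgrid)
  starts <- starts[starts$k1 >= starts$k2, ]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(log(c(starts$k1[i], starts$k2[i])), .biexp_rss, t = t, y = y,
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) .stopf("bi-exponential fit failed from all starts")
  k <- sort(exp(best$par), decreasing = TRUE)  # enforce k1 >= k2
  a <- .nnls2(exp(-k[1] * t), exp(-k[2] * t), y)
  .biexp_canonical(a, k, best$value)
}

# canonical parameter form: a vanished component carries no rate of its own
# and near-identical rates merge into a single component
.biexp_canonical <- function(a, k, rss) {
  if (abs(k[1] - k[2]) < 1e-6 * max(k[1], 1e-12)) {
    a <- c(a[1] + a[2], 0); k[2] <- 0
  }
  if (a[1] <= 1e-12 && a[2] > 0) {
    a <- c(a[2], 0); k <- c(k[2], 0)
  }
  if (a[2] <= 1e-12) { a[2] <- 0; k[2] <- 0 }
  list(a1 = a[1], k1 = k[1], a2 = a[2], k2 = k[2], rss = rss)
}

# time at which the fitted curve reaches half its t = 0 value
.biexp_half_life <- function(a1, k1, a2, k2) {
  f0 <- a1 + a2
  if (f0 <= 0) return(NA_real_)
  target <- f0 / 2
  f <- function(t) .biexp(t, a1, k1, a2, k2) - target
  kslow <- if (k2 > 0) k2 else k1
  if (kslow <= 0) return(Inf)
  upper <- 10 / kslow
  while (f(upper) > 0 && upper < 1e12) upper <- upper * 10
  if (f(upper) > 0) return(Inf)  # curve never decays to half (a plateau)
  uniroot(f, c(0, upper), tol = 1e-10)$root
}

#' Fit a bi-exponential decay and estimate the half-life
#'
#' Fits `a1 exp(-k1 t) + a2 exp(-k2 t)` with `a1, a2 >= 0` and
#' `k1 >= k2 >= 0` by variable-projection least squares (non-negative
#' amplitude subproblem, multi-start rate optimization). The half-life is
#' the time at which the fitted curve reaches half its fitted t = 0 value
#' (solved numerically). The 95% confidence interval comes from a seeded
#' parametric bootstrap: residual-variance Gaussian noise around the fitted
#' curve, refit, percentile interval of the half-life.
#'
#' @param timepoints times, minutes, strictly increasing.
#' @param fractions intact fractions in \[0, 1\], same length.
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return Object of class `decay_fit`: `a1`, `a2`, `k1`, `k2` (min^-1),
#'   `half_life` (min), `ci95` (low, high), `rss`, `fitted` (function of t).
#' @export
fit_biexponential <- function(timepoints, fractions, n_boot = 1000,
                              conf = 0.95, seed = 1) {
  t <- as.numeric(timepoints); y <- as.numeric(fractions)
  stopifnot(length(t) == length(y))
  if (length(t) < 5L) .stopf("need at least 5 timepoints")
  if (any(diff(t) <= 0)) .stopf("timepoints must be strictly increasing")
  if (any(y < -1e-9 | y > 1 + 1e-9)) .stopf("fractions must lie in [0, 1]")

  fit <- .biexp_solve(t, y)
  hl <- .biexp_half_life(fit$a1, fit$k1, fit$a2, fit$k2)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    sigma <- sqrt(fit$rss / max(1, length(t) - 4))
    yhat <- .biexp(t, fit$a1, fit$k1, fit$a2, fit$k2)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    hls <- vapply(seq_len(n_boot), function(b) {
      yb <- yhat + rnorm(length(t), sd = sigma)
      fb <- tryCatch(.biexp_refit(t, yb, fit), error = function(e) NULL)
      if (is.null(fb)) return(NA_real_)
      .biexp_half_life(fb$a1, fb$k1, fb$a2, fb$k2)
    }, numeric(1))
    hls <- hls[is.finite(hls)]
    if (length(hls) >= 10)
      ci <- unname(quantile(hls, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(a1 = fit$a1, a2 = fit$a2, k1 = fit$k1, k2 = fit$k2,
                 half_life = hl, ci95 = ci, rss = fit$rss,
                 fitted = function(tt) .biexp(tt, fit$a1, fit$k1,
                                              fit$a2, fit$k2)),
            class = "decay_fit")
}

# single-start refit from previous parameters (used by the bootstrap)
.biexp_refit <- function(t, y, start) {
  k0 <- pmax(c(start$k1, start$k2), 1e-8)
  fit <- optim(log(k0), .biexp_rss, t = t, y = y, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-10))
  k <- sort(exp(fit$par), decreasing = TRUE)
  a <- .nnls2(exp(-k[1] * t), exp(-k[2] * t), y)
  list(a1 = a[1], k1 = k[1], a2 = a[2], k2 = k[2])
}

# save/restore the global RNG state so seeded internals do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay_fit: a1 %.3f (k1 %.4g /min), a2 %.3f (k2 %.4g /min)\n",
    x$a1, x$k1, x$a2, x$k2))
  cat(sprintf("  half-life %.2f min (95%% CI %.2f-%.2f)\n",
              x$half_life, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Pairwise Welch t-tests with optional Benjamini-Hochberg correction
#'
#' Two-tailed, unpaired t-tests with Welch's correction (Satterthwaite
#' degrees of freedom) for every pair of groups; when `correct = TRUE` the
#' p-values are Benjamini-Hochberg adjusted across the requested pairs.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param correct apply BH adjustment across the pairs?
#' @return data.frame (group1, group2, t, df, p, p_adjusted).
#' @export
compare_conditions <- function(groups, correct = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  if (any(vapply(groups, length, integer(1)) < 2L))
    .stopf("every group needs n >= 2")
  pairs <- utils::combn(names(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    if (var(x) == 0 && var(y) == 0) {
      # t.test errors on doubly-constant data; the Welch statistic is 0/0 ->
      # define t = 0, p = 1 when the means coincide, else +/-Inf, p = 0
      d <- mean(x) - mean(y)
      tt <- list(statistic = if (d == 0) 0 else sign(d) * Inf,
                 parameter = length(x) + length(y) - 2,
                 p.value = if (d == 0) 1 else 0)
    } else {
      tt <- t.test(x, y, var.equal = FALSE)
    }
    c(t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value)
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t = res["t", ], df = res["df", ], p = res["p", ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$p_adjusted <- if (correct) p.adjust(out$p, method = "BH") else out$p
  out
}
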