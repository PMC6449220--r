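# single-accumulator passage-time pdf/cdf (start U(0,A), drift N(v, s)),
# not conditioned on finishing; negative-drift mass never finishes
lba_acc_pdf <- function(t, b, A, v, s) {
  out <- numeric(length(t))
  ok <- t > 0
  tt <- t[ok]
  if (A > 0) {
    z1 <- (b - A - tt * v) / (tt * s)
    z2 <- (b - tt * v) / (tt * s)
    out[ok] <- (-v * pnorm(z1) + s * dnorm(z1) + v * pnorm(z2) - s * dnorm(z2)) / A
  } else {
    out[ok] <- (b / tt^2) * dnorm((b / tt - v) / s) / s
  }
  pmax(out, 0)
}

lba_acc_cdf <- function(t, b, A, v, s) {
  out <- numeric(length(t))
  ok <- t > 0
  tt <- t[ok]
  if (A > 0) {
    z1 <- (b - A - tt * v) / (tt * s)
    z2 <- (b - tt * v) / (tt * s)
    out[ok] <- 1 + ((b - A - tt * v) / A) * pnorm(z1) -
      ((b - tt * v) / A) * pnorm(z2) +
      (tt * s / A) * (dnorm(z1) - dnorm(z2))
  } else {
    out[ok] <- pnorm((v - b / tt) / s)
  }
  pmin(pmax(out, 0), 1)
}

# thresholds per accumulator given the stimulus side; "match" is the
# accumulator for the correct response
lba_thresholds <- function(p, stim) {
  b_r <- p$b - p$start_bias
  b_l <- p$b + p$start_bias
  if (stim == "R") list(match = b_r, mismatch = b_l)
  else list(match = b_l, mismatch = b_r)
}

#' Defective first-passage density of the LBA
#'
#' Density that the named accumulator (the one matching the stimulus, or the
#' mismatching one) reaches its threshold first at response time `t`. Summed
#' over both accumulators and integrated over `t`, the total mass equals one
#' minus the probability that both sampled drifts are negative (in which case
#' neither accumulator ever finishes).
#'
#' @param t Vector of response times (s); zero density at or below `t0`.
#' @param p An [lba_params()] object.
#' @param which `"match"` or `"mismatch"`: which accumulator wins.
#' @param stim Stimulus side (`"R"` or `"L"`), used to resolve the per-response
#'   threshold offset `start_bias`.
#' @return Numeric vector of densities (1/s).
#' @examples
#' p <- lba_params(b = 1, A = 0.5, v_c = 2, v_e = 0.5)
#' lba_defective_density(c(0.3, 0.5, 1), p, "match")
#' @export
lba_defective_density <- function(t, p, which = c("match", "mismatch"),
                                  stim = "R") {
  which <- match.arg(which)
  stim <- match.arg(stim, c("L", "R"))
  validate_lba_params(p)
  td <- t - p$t0
  th <- lba_thresholds(p, stim)
  if (which == "match") {
    lba_acc_pdf(td, th$match, p$A, p$v_c, p$sdrift) *
      (1 - lba_acc_cdf(td, th$mismatch, p$A, p$v_e, p$sdrift))
  } else {
    lba_acc_pdf(td, th$mismatch, p$A, p$v_e, p$sdrift) *
      (1 - lba_acc_cdf(td, th$match, p$A, p$v_c, p$sdrift))
  }
}

#' Probability that neither LBA accumulator finishes
#'
#' Both sampled drifts negative: the race never terminates (trials are
#' resolved by resampling or censoring in [simulate_lba()]).
#'
#' @param p An [lba_params()] object.
#' @return A probability.
#' @export
lba_nonterminating_prob <- function(p) {
  validate_lba_params(p)
  pnorm(-p$v_c / p$sdrift) * pnorm(-p$v_e / p$sdrift)
}

#' Choice probability of the LBA by quadrature
#'
#' Integral of the defective density for the named accumulator.
#'
#' @inheritParams lba_defective_density
#' @return A probability.
#' @export
lba_choice_prob <- function(p, which = c("match", "mismatch"), stim = "R") {
  which <- match.arg(which)
  validate_lba_params(p)
  integrate(lba_defective_density, lower = p$t0, upper = Inf, p = p,
            which = which, stim = stim, rel.tol = 1e-9,
            abs.tol = 1e-12)$value
}

#' Simulate choice-RT trials from the LBA
#'
#' Start points are uniform, drifts normal, accumulation ballistic. Trials on
#' which both sampled drifts are non-positive never terminate; by default they
#' are resampled (and counted), alternatively censored at the deadline.
#'
#' @inheritParams simulate_diffusion
#' @param p An [lba_params()] object.
#' @param negative_drift `"resample"` (default) or `"censor"`.
#' @return A tibble with columns `response`, `rt`, `timed_out`; the number of
#'   resampled trials is attached as attribute `n_resampled`.
#' @examples
#' simulate_lba(lba_params(b = 1, A = 0.5, v_c = 2, v_e = 0.5), "R",
#'              n = 5, seed = 1)
#' @export
simulate_lba <- function(p, stim = "R", n, deadline = 3, seed = NULL,
                         negative_drift = c("resample", "censor")) {
  negative_drift <- match.arg(negative_drift)
  stim <- match.arg(stim, c("L", "R"))
  validate_lba_params(p)
  stopifnot(n >= 1, deadline > p$t0)
  th <- lba_thresholds(p, stim)
  run <- function() {
    n_resampled <- 0L
    d_m <- rnorm(n, p$v_c, p$sdrift)
    d_x <- rnorm(n, p$v_e, p$sdrift)
    if (negative_drift == "resample") {
      repeat {
        bad <- which(d_m <= 0 & d_x <= 0)
        if (!length(bad)) break
        n_resampled <- n_resampled + length(bad)
        d_m[bad] <- rnorm(length(bad), p$v_c, p$sdrift)
        d_x[bad] <- rnorm(length(bad), p$v_e, p$sdrift)
      }
    }
    k_m <- runif(n, 0, p$A)
    k_x <- runif(n, 0, p$A)
    t_m <- ifelse(d_m > 0, (th$match - k_m) / d_m, Inf)
    t_x <- ifelse(d_x > 0, (th$mismatch - k_x) / d_x, Inf)
    match_wins <- t_m < t_x
    rt <- p$t0 + pmin(t_m, t_x)
    resp_match <- if (stim == "R") "R" else "L"
    resp_mis <- if (stim == "R") "L" else "R"
    response <- ifelse(match_wins, resp_match, resp_mis)
    timed_out <- rt > deadline
    response[timed_out] <- NA_character_
    rt[timed_out] <- deadline
    out <- tibble::tibble(response = response, rt = rt, timed_out = timed_out)
    attr(out, "n_resampled") <- n_resampled
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
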