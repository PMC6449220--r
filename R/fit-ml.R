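#' Fitting configuration for the maximum-likelihood estimators
#'
#' @param min_trials Minimum trials required after outlier exclusion.
#' @param n_starts Number of jittered optimizer starts (the first start is
#'   unjittered, at the moment-based initial values).
#' @param jitter_sd SD of the jitter applied to the transformed parameters.
#' @param maxit Iteration cap per Nelder-Mead run.
#' @param min_rt Fast-guess cutoff passed to [exclude_outliers()].
#' @param seed Integer seed making the jittered starts reproducible.
#' @param estimate_bias For the LBA: estimate the `start_bias` threshold
#'   offset (needed to infer response bias).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(min_trials = 20, n_starts = 5, jitter_sd = 0.15,
                       maxit = 2000, min_rt = 0.18, seed = 1,
                       estimate_bias = TRUE) {
  structure(list(min_trials = min_trials, n_starts = n_starts,
                 jitter_sd = jitter_sd, maxit = maxit, min_rt = min_rt,
                 seed = seed, estimate_bias = estimate_bias),
            class = "fit_config")
}

new_rt_fit <- function(model, params, logLik, converged, n_used, n_excluded) {
  structure(list(model = model, params = params, logLik = logLik,
                 converged = converged, n_used = n_used,
                 n_excluded = n_excluded),
            class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("<rt_fit: %s> logLik = %.2f, n = %d (%d excluded), %s\n",
              x$model, x$logLik, x$n_used, x$n_excluded,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  invisible(x)
}

#' @rdname tidy.rt_fit
#' @export
glance.rt_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$logLik, converged = x$converged,
                 n_used = x$n_used, n_excluded = x$n_excluded)
}

#' Tidy a fitted response-time model
#'
#' @param x An `rt_fit` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with columns `term` and `estimate`; `glance()`:
#'   a one-row tibble with fit-level summaries.
#' @export
tidy.rt_fit <- function(x, ...) {
  est <- unlist(x$params[!vapply(x$params, is.null, logical(1))])
  tibble::tibble(term = names(est), estimate = unname(est))
}

run_multistart <- function(nll, start, cfg) {
  starts <- list(start)
  if (cfg$n_starts > 1) {
    jit <- withr::with_seed(cfg$seed, {
      lapply(seq_len(cfg$n_starts - 1), function(i)
        start + rnorm(length(start), 0, cfg$jitter_sd))
    })
    starts <- c(starts, jit)
  }
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      optim(st, nll, method = "Nelder-Mead",
            control = list(maxit = cfg$maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  best
}

#' Maximum-likelihood fit of the simple diffusion model
#'
#' Maximizes the summed log defective first-passage densities over trials.
#' The four parameters `(v, a, zr, ter)` are optimized on transformed scales
#' (log for `a`, logit for `zr`, and `ter` mapped into `(0, min observed
#' RT)`), via Nelder-Mead from jittered EZ-based starting values; the best of
#' the starts is returned. Timed-out and fast-guess trials are excluded
#' first.
#'
#' @param trials A trial table with `stimulus`, `response`, `rt` (and
#'   optionally `timed_out`).
#' @param config A [fit_config()].
#' @param s Diffusion scale convention.
#' @return An `rt_fit` object (see [tidy.rt_fit()]).
#' @export
fit_ml_simple_diffusion <- function(trials, config = fit_config(), s = 1) {
  tr <- exclude_outliers(trials, config$min_rt)
  n_exc <- attr(tr, "n_excluded")
  if (nrow(tr) < config$min_trials)
    stop("fewer than min_trials trials after exclusion", call. = FALSE)
  rt_min <- min(tr$rt)
  # group trials by stimulus x response; upper boundary is response "R"
  groups <- split(tr$rt, interaction(tr$stimulus, tr$response, drop = TRUE))
  nll <- function(th) {
    v <- th[1]; a <- exp(th[2]); zr <- plogis(th[3])
    ter <- plogis(th[4]) * rt_min
    if (a > 50 || a < 1e-3) return(1e10)
    ll <- 0
    for (g in names(groups)) {
      sides <- strsplit(g, ".", fixed = TRUE)[[1]]
      drift <- if (sides[1] == "R") v else -v
      td <- groups[[g]] - ter
      dens <- if (sides[2] == "R")
        wiener_fpt_lower_cpp(td, -drift, a, 1 - zr, s, 1e-7)
      else
        wiener_fpt_lower_cpp(td, drift, a, zr, s, 1e-7)
      ll <- ll + sum(log(pmax(dens, 1e-12)))
    }
    -ll
  }
  m <- tryCatch(compute_ez_moments(tr, min_rt = 0), error = function(e) NULL)
  start <- if (!is.null(m) && is.finite(m$vrt) && m$vrt > 0) {
    ez <- ez_point_estimates(m, s = s)
    ter0 <- min(max(ez$ter, 0.02), 0.95 * rt_min)
    c(ez$v, log(max(ez$a, 0.1)), 0, qlogis(ter0 / rt_min))
  } else c(1, 0, 0, 0)
  best <- run_multistart(nll, start, config)
  if (is.null(best))
    return(new_rt_fit("simple_diffusion",
                      diffusion_params(v = NA_real_, a = 1, zr = 0.5, ter = 0),
                      NA_real_, FALSE, nrow(tr), n_exc))
  th <- best$par
  p <- diffusion_params(v = th[1], a = exp(th[2]), zr = plogis(th[3]),
                        ter = plogis(th[4]) * rt_min, s = s)
  new_rt_fit("simple_diffusion", p, -best$value, best$convergence == 0,
             nrow(tr), n_exc)
}

#' Maximum-likelihood fit of the LBA
#'
#' Same protocol as [fit_ml_simple_diffusion()], using the LBA defective
#' densities. The drift SD is fixed at 1 within each condition as the
#' standard scaling (identifiability) constraint. The likelihood is
#' normalized by the probability that at least one accumulator finishes,
#' matching data generated under trial resampling.
#'
#' @param trials A trial table with `stimulus`, `response`, `rt`.
#' @param config A [fit_config()]; `estimate_bias` controls whether the
#'   threshold offset `start_bias` is estimated or fixed at 0.
#' @param sdrift Fixed between-trial drift SD.
#' @return An `rt_fit` object.
#' @export
fit_ml_lba <- function(trials, config = fit_config(), sdrift = 1) {
  tr <- exclude_outliers(trials, config$min_rt)
  n_exc <- attr(tr, "n_excluded")
  if (nrow(tr) < config$min_trials)
    stop("fewer than min_trials trials after exclusion", call. = FALSE)
  rt_min <- min(tr$rt)
  est_bias <- isTRUE(config$estimate_bias)
  groups <- split(tr$rt, interaction(tr$stimulus, tr$response, drop = TRUE))
  nll <- function(th) {
    A <- exp(th[1]); gap <- exp(th[2])
    v_c <- th[3]; v_e <- th[4]
    t0 <- plogis(th[5]) * rt_min
    bias <- if (est_bias) th[6] else 0
    b <- A + gap
    if (b - abs(bias) <= A) return(1e10)
    p <- list(b = b, A = A, v_c = v_c, v_e = v_e, sdrift = sdrift, t0 = t0,
              start_bias = bias)
    norm <- 1 - pnorm(-v_c / sdrift) * pnorm(-v_e / sdrift)
    ll <- 0
    for (g in names(groups)) {
      sides <- strsplit(g, ".", fixed = TRUE)[[1]]
      th_side <- lba_thresholds(p, sides[1])
      td <- groups[[g]] - t0
      dens <- if (sides[2] == sides[1])
        lba_acc_pdf(td, th_side$match, A, v_c, sdrift) *
          (1 - lba_acc_cdf(td, th_side$mismatch, A, v_e, sdrift))
      else
        lba_acc_pdf(td, th_side$mismatch, A, v_e, sdrift) *
          (1 - lba_acc_cdf(td, th_side$match, A, v_c, sdrift))
      ll <- ll + sum(log(pmax(dens / norm, 1e-12)))
    }
    -ll
  }
  # moment-flavored starting values
  acc <- mean(tr$response == tr$stimulus)
  mrt <- mean(tr$rt)
  t00 <- min(0.6 * rt_min, 0.2)
  b0 <- max((mrt - t00) * 2, 0.3)
  start <- c(log(b0 / 2), log(b0 / 2), 2 * acc + 0.5, 2 * (1 - acc),
             qlogis(t00 / rt_min))
  if (est_bias) start <- c(start, 0)
  best <- run_multistart(nll, start, config)
  if (is.null(best))
    return(new_rt_fit("lba", lba_params(b = 1, A = 0, v_c = NA_real_,
                                        v_e = 0, sdrift = sdrift, t0 = 0),
                      NA_real_, FALSE, nrow(tr), n_exc))
  th <- best$par
  p <- lba_params(b = exp(th[1]) + exp(th[2]), A = exp(th[1]), v_c = th[3],
                  v_e = th[4], sdrift = sdrift,
                  t0 = plogis(th[5]) * rt_min,
                  start_bias = if (est_bias) th[6] else 0)
  new_rt_fit("lba", p, -best$value, best$convergence == 0, nrow(tr), n_exc)
}

#' Fit every participant of a condition with one estimator
#'
#' Applies EZ, EZ2 or a maximum-likelihood fit per participant and collects
#' the estimates in one row per participant, the delimited-text-friendly
#' layout consumed by the inference step.
#'
#' @param trials A trial table with a `participant` column.
#' @param method `"ez2"`, `"ez"`, `"ml_diffusion"` or `"ml_lba"`.
#' @param config A [fit_config()].
#' @param s Diffusion scale convention (diffusion-based methods).
#' @return A tibble with one row per participant: parameter columns (the
#'   component-mapped names depend on the method), `logLik` (ML methods),
#'   `converged`, `n_used`, `n_excluded`.
#' @export
fit_participants <- function(trials, method = c("ez2", "ez", "ml_diffusion",
                                                "ml_lba"),
                             config = fit_config(), s = 1) {
  method <- match.arg(method)
  trials |>
    dplyr::group_by(participant = .data$participant) |>
    dplyr::group_modify(function(d, key) {
      switch(method,
        ez = {
          m <- compute_ez_moments(d, min_rt = config$min_rt)
          est <- ez_point_estimates(m, s = s)
          dplyr::mutate(est, converged = TRUE, n_used = m$n,
                        n_excluded = m$n_excluded)
        },
        ez2 = {
          m <- compute_ez_moments(d, min_rt = config$min_rt)
          est <- ez2_point_estimates(m, s = s)
          dplyr::mutate(est[c("v", "a", "zr", "ter", "converged")],
                        n_used = m$n, n_excluded = m$n_excluded)
        },
        ml_diffusion = {
          f <- fit_ml_simple_diffusion(d, config = config, s = s)
          tibble::tibble(v = f$params$v, a = f$params$a, zr = f$params$zr,
                         ter = f$params$ter, logLik = f$logLik,
                         converged = f$converged, n_used = f$n_used,
                         n_excluded = f$n_excluded)
        },
        ml_lba = {
          f <- fit_ml_lba(d, config = config)
          tibble::tibble(v_c = f$params$v_c, v_e = f$params$v_e,
                         b = f$params$b, A = f$params$A,
                         start_bias = f$params$start_bias, t0 = f$params$t0,
                         logLik = f$logLik, converged = f$converged,
                         n_used = f$n_used, n_excluded = f$n_excluded)
        })
    }) |>
    dplyr::ungroup()
}
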