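#' Outlier exclusion applied before any fitting
#'
#' A single documented default used by every estimator: censored (timed-out)
#' trials and implausibly fast responses (`rt < min_rt`) are dropped.
#'
#' @param trials A trial table with `rt` and (optionally) `timed_out`.
#' @param min_rt Fast-guess cutoff in seconds.
#' @return The filtered table, with the number of excluded trials attached as
#'   attribute `n_excluded`.
#' @export
exclude_outliers <- function(trials, min_rt = 0.18) {
  keep <- trials$rt >= min_rt
  if ("timed_out" %in% names(trials)) keep <- keep & !trials$timed_out
  keep <- keep & !is.na(trials$response)
  out <- trials[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

edge_correct <- function(p, n) {
  stopifnot(n >= 1)
  if (p >= 1) return(1 - 1 / (2 * n))
  if (p <= 0) return(1 / (2 * n))
  p
}

#' Moments entering the EZ and EZ2 estimators
#'
#' Proportion correct plus the mean and variance of correct-response RTs,
#' with the proportion edge-corrected away from 0, 1/2 and 1 where the EZ
#' inversion is undefined (by 1/(2n); at exactly 1/2 the nudge is toward
#' correctness when correct responses are at least as fast as errors, and
#' away otherwise). Per-stimulus-side moments (proportion correct plus mean
#' and variance of all RTs on that side) are attached for EZ2.
#'
#' @param trials A trial table with `stimulus`, `response`, `rt` (and
#'   optionally `timed_out`).
#' @param min_rt Fast-guess cutoff passed to [exclude_outliers()].
#' @return An object of class `ez_moments`: a list with `n`, `pc`, `mrt`,
#'   `vrt`, a `by_side` tibble (`stimulus`, `n`, `pc`, `mrt_all`, `vrt_all`)
#'   and `n_excluded`.
#' @examples
#' tr <- simulate_diffusion(diffusion_params(v = 1, a = 2), "R", 500, seed = 1)
#' compute_ez_moments(dplyr::mutate(tr, stimulus = "R"))
#' @export
compute_ez_moments <- function(trials, min_rt = 0.18) {
  tr <- exclude_outliers(trials, min_rt)
  n <- nrow(tr)
  if (n < 1) stop("no scoreable trials after outlier exclusion", call. = FALSE)
  correct <- tr$response == tr$stimulus
  if (!any(correct)) stop("no correct trials after outlier exclusion",
                          call. = FALSE)
  pc_raw <- mean(correct)
  pc <- edge_correct(pc_raw, n)
  if (abs(pc - 0.5) < 1e-12) {
    dir <- if (!any(!correct) ||
               mean(tr$rt[correct]) <= mean(tr$rt[!correct])) 1 else -1
    pc <- 0.5 + dir / (2 * n)
  }
  rts_c <- tr$rt[correct]
  by_side <- tr |>
    dplyr::group_by(stimulus = .data$stimulus) |>
    dplyr::summarise(
      n = dplyr::n(),
      pc = edge_correct(mean(.data$response == .data$stimulus[1]), dplyr::n()),
      mrt_all = mean(.data$rt),
      vrt_all = var(.data$rt),
      .groups = "drop")
  structure(list(n = n, pc = pc, mrt = mean(rts_c),
                 vrt = if (length(rts_c) > 1) var(rts_c) else NA_real_,
                 by_side = by_side,
                 n_excluded = attr(tr, "n_excluded")),
            class = "ez_moments")
}

#' Forward EZ moments of an unbiased simple diffusion process
#'
#' Closed-form proportion correct, mean and variance of decision times at the
#' correct boundary for the unbiased (`zr = 0.5`) simple diffusion model.
#' `mrt` includes the non-decision time.
#'
#' @param v,a,ter,s Diffusion parameters (see [diffusion_params()]).
#' @return A list with `pc`, `mrt`, `vrt`.
#' @examples
#' ez_forward_moments(v = 1, a = 2, ter = 0.3)
#' @export
ez_forward_moments <- function(v, a, ter = 0, s = 1) {
  stopifnot(v != 0, a > 0, s > 0)
  y <- exp(-a * v / s^2)
  pc <- 1 / (1 + y)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  vdt <- (a * s^2 / (2 * v^3)) * (2 * (-a * v / s^2) * y - y^2 + 1) / (y + 1)^2
  list(pc = pc, mrt = mdt + ter, vrt = vdt)
}

#' EZ closed-form diffusion estimates
#'
#' Inverts the forward map of the unbiased simple diffusion model: proportion
#' correct fixes `v * a`, the variance of correct RTs then identifies `v`,
#' and the mean RT minus the implied mean decision time gives `ter`. The
#' inversion is an exact round trip with [ez_forward_moments()].
#'
#' @param m An `ez_moments` object (or any list with `pc`, `mrt`, `vrt`).
#' @param s Scale convention for the diffusion coefficient.
#' @return A tibble with columns `v`, `a`, `ter`.
#' @examples
#' fm <- ez_forward_moments(v = 1, a = 2, ter = 0.3)
#' ez_point_estimates(fm)
#' @export
ez_point_estimates <- function(m, s = 1) {
  pc <- m$pc
  if (!is.finite(m$vrt) || m$vrt <= 0)
    stop("EZ requires a positive RT variance", call. = FALSE)
  if (pc <= 0 || pc >= 1 || pc == 0.5)
    stop("proportion correct must be edge-corrected into (0,1) \\ {0.5}",
         call. = FALSE)
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / m$vrt
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- exp(-a * v / s^2)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  tibble::tibble(v = v, a = a, ter = m$mrt - mdt)
}

# predicted per-stimulus-side moments (pc, mean and var of all RTs) for a
# biased simple diffusion process; used by the EZ2 moment solver. Lean path:
# no parameter objects, plain numeric output c(pc, mean, var) per side.
ez2_predicted_moments <- function(v, a, zr, ter, s = 1, n_nodes = 160) {
  gl <- gauss_legendre01(n_nodes)
  one <- function(drift, correct_boundary) {
    lam <- (drift / s)^2 / 2 + pi^2 * s^2 / (2 * a^2)
    umax <- sqrt(max(1, 30 / lam))
    u <- gl$x * umax
    wq <- gl$w * umax * 2 * u
    tt <- u^2
    fl <- wiener_fpt_lower_cpp(tt, drift, a, zr, s, 1e-9)
    fu <- wiener_fpt_lower_cpp(tt, -drift, a, 1 - zr, s, 1e-9)
    pu <- sum(wq * fu); pl <- sum(wq * fl)
    m1 <- sum(wq * tt * (fu + fl))
    m2 <- sum(wq * tt^2 * (fu + fl))
    tot <- pu + pl
    m_mix <- m1 / tot
    s2 <- m2 / tot - m_mix^2
    pc <- if (correct_boundary == "upper") pu / tot else pl / tot
    c(pc = pc, m = m_mix + ter, v = s2)
  }
  list(R = one(v, "upper"), L = one(-v, "lower"))
}

#' EZ2 moment-based diffusion estimates with a starting point
#'
#' Numerically inverts the per-stimulus-side moment map of the biased simple
#' diffusion model. The observed statistics are, for each stimulus side, the
#' proportion correct and the mean and variance of all RTs on that side; the
#' predicted statistics are computed from the first-passage density by
#' quadrature, and the parameters `(v, a, zr, ter)` minimize the sum of
#' squared residuals (variances compared on the SD scale). When the data are
#' side-symmetric the solution reduces to the EZ estimates with `zr = 0.5`.
#'
#' @param m An `ez_moments` object carrying the `by_side` table with both
#'   response sides observed.
#' @param s Scale convention for the diffusion coefficient.
#' @return A tibble with columns `v`, `a`, `zr`, `ter`, `converged`,
#'   `objective`.
#' @export
ez2_point_estimates <- function(m, s = 1) {
  bs <- m$by_side
  if (!all(c("L", "R") %in% bs$stimulus))
    stop("EZ2 needs trials on both stimulus sides", call. = FALSE)
  obs <- unlist(lapply(c("R", "L"), function(sd) {
    r <- bs[bs$stimulus == sd, ]
    c(r$pc, r$mrt_all, sqrt(r$vrt_all))
  }))
  resid <- function(th) {
    v <- th[1]; a <- exp(th[2]); zr <- plogis(th[3]); ter <- exp(th[4])
    pr <- ez2_predicted_moments(v, a, zr, ter, s = s)
    pred <- c(pr$R[["pc"]], pr$R[["m"]], sqrt(max(pr$R[["v"]], 0)),
              pr$L[["pc"]], pr$L[["m"]], sqrt(max(pr$L[["v"]], 0)))
    sum((pred - obs)^2)
  }
  start <- tryCatch({
    ez <- ez_point_estimates(m, s = s)
    c(ez$v, log(max(ez$a, 0.1)), 0, log(max(ez$ter, 0.05)))
  }, error = function(e) c(1, log(1), 0, log(0.2)))
  fit <- optim(start, resid, method = "Nelder-Mead",
               control = list(maxit = 600, reltol = 1e-10))
  fit <- optim(fit$par, resid, method = "BFGS",
               control = list(maxit = 200, reltol = 1e-14))
  th <- fit$par
  tibble::tibble(v = th[1], a = exp(th[2]), zr = plogis(th[3]),
                 ter = exp(th[4]),
                 converged = fit$convergence == 0 || fit$value < 1e-10,
                 objective = fit$value)
}
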