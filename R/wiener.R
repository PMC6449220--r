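#' First-passage-time density of the simple diffusion model
#'
#' Defective density of the decision process reaching the named boundary at
#' response time `t` (i.e. decision time `t - ter`). Integrated over `t`, the
#' density at a boundary equals the probability of responding at that boundary,
#' and the two boundaries together account for all probability mass.
#'
#' The density is evaluated by an infinite-series representation with a
#' small-time/large-time switching rule; the truncation is chosen so that the
#' absolute error of the standardized density is at most `eps`.
#'
#' @param t Vector of response times (s). Values at or below `ter` have zero
#'   density.
#' @param p A [diffusion_params()] object describing the simple model
#'   (`sv = szr = st = 0`).
#' @param boundary `"upper"` or `"lower"`.
#' @param eps Absolute truncation error bound for the standardized density.
#' @return Numeric vector of densities (1/s).
#' @examples
#' p <- diffusion_params(v = 1, a = 2)
#' wiener_fpt_density(c(0.2, 0.5, 1), p, "upper")
#' @export
wiener_fpt_density <- function(t, p, boundary = c("upper", "lower"),
                               eps = 1e-7) {
  boundary <- match.arg(boundary)
  validate_diffusion_params(p)
  if (p$sv > 0 || p$szr > 0 || p$st > 0)
    stop("wiener_fpt_density() is defined for the simple model; ",
         "set sv = szr = st = 0", call. = FALSE)
  stopifnot(is.numeric(t))
  td <- t - p$ter
  if (boundary == "lower") {
    wiener_fpt_lower_cpp(td, p$v, p$a, p$zr, p$s, eps)
  } else {
    wiener_fpt_lower_cpp(td, -p$v, p$a, 1 - p$zr, p$s, eps)
  }
}

#' Boundary-hit probability of the simple diffusion model
#'
#' Closed-form probability that the process is absorbed at the given boundary.
#'
#' @inheritParams wiener_fpt_density
#' @return A probability.
#' @examples
#' wiener_hit_prob(diffusion_params(v = 1, a = 2), "upper")
#' @export
wiener_hit_prob <- function(p, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  validate_diffusion_params(p)
  k <- 2 * p$v / p$s^2
  pu <- if (abs(k * p$a) < 1e-10) p$zr else expm1(-k * p$zr * p$a) / expm1(-k * p$a)
  if (boundary == "upper") pu else 1 - pu
}

# cached Gauss-Legendre nodes/weights on [0, 1]
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  # Golub-Welsch: eigen-decomposition of the Jacobi matrix for Legendre weights
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values                      # nodes on [-1, 1]
  w <- 2 * e$vectors[1, ]^2
  o <- order(x)
  res <- list(x = (x[o] + 1) / 2, w = w[o] / 2)
  .gl_cache[[key]] <- res
  res
}

#' Defective decision-time moments of the simple diffusion model
#'
#' Choice probabilities and the conditional mean and variance of the decision
#' time at each boundary, computed by Gauss-Legendre quadrature over the
#' first-passage density (with a square-root time substitution to resolve the
#' early peak). Non-decision time is not included.
#'
#' @inheritParams wiener_fpt_density
#' @param n_nodes Number of quadrature nodes.
#' @return A tibble with one row per boundary and columns `boundary`, `prob`,
#'   `mean_dt`, `var_dt`.
#' @examples
#' wiener_moments(diffusion_params(v = 1, a = 2))
#' @export
wiener_moments <- function(p, n_nodes = 192) {
  validate_diffusion_params(p)
  gl <- gauss_legendre01(n_nodes)
  # slowest decay rate of the density: first series eigenvalue + drift term
  lam <- (p$v / p$s)^2 / 2 + pi^2 * p$s^2 / (2 * p$a^2)
  tmax <- max(1, 30 / lam)
  # substitute t = u^2 to concentrate nodes near zero
  umax <- sqrt(tmax)
  u <- gl$x * umax
  wq <- gl$w * umax * 2 * u          # dt = 2 u du
  tt <- u^2
  one_side <- function(bnd) {
    f <- if (bnd == "lower") wiener_fpt_lower_cpp(tt, p$v, p$a, p$zr, p$s, 1e-9)
         else wiener_fpt_lower_cpp(tt, -p$v, p$a, 1 - p$zr, p$s, 1e-9)
    m0 <- sum(wq * f)
    m1 <- sum(wq * tt * f)
    m2 <- sum(wq * tt^2 * f)
    mean_dt <- m1 / m0
    tibble::tibble(boundary = bnd, prob = m0, mean_dt = mean_dt,
                   var_dt = m2 / m0 - mean_dt^2)
  }
  dplyr::bind_rows(one_side("upper"), one_side("lower"))
}

#' Simulate choice-RT trials from the diffusion model
#'
#' Euler-Maruyama integration of the diffusion process with a Brownian-bridge
#' boundary-crossing correction within each step, which removes the dominant
#' discretization bias of the plain scheme. Trial-level parameters are drawn
#' from the full model's variability distributions (normal for drift, uniform
#' for start and non-decision ranges). Trials still unabsorbed at `deadline`
#' are censored and flagged `timed_out`.
#'
#' The upper boundary maps to response `"R"`, the lower to `"L"`. For stimulus
#' `"L"` the drift sign is flipped so that `v` is always the drift toward the
#' correct response.
#'
#' @param p A [diffusion_params()] object.
#' @param stim Stimulus side, `"L"` or `"R"`.
#' @param n Number of trials.
#' @param deadline Response deadline in seconds (must exceed `ter`).
#' @param seed Optional integer seed; when supplied the call is reproducible
#'   and leaves the global RNG state untouched.
#' @param dt Euler step size in seconds.
#' @return A tibble with columns `response` (`"L"`/`"R"`, `NA` when censored),
#'   `rt` (s) and `timed_out`.
#' @examples
#' simulate_diffusion(diffusion_params(v = 2, a = 1), "R", n = 5, seed = 1)
#' @export
simulate_diffusion <- function(p, stim = "R", n, deadline = 3, seed = NULL,
                               dt = 5e-4) {
  validate_diffusion_params(p)
  stim <- match.arg(stim, c("L", "R"))
  stopifnot(n >= 1, deadline > p$ter, dt > 0)
  run <- function() sim_diffusion_cpp(n, if (stim == "R") p$v else -p$v,
                                      p$a, p$zr, p$ter, p$s, p$sv, p$szr,
                                      p$st, dt, deadline)
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(
    response = dplyr::case_when(is.na(res$upper) ~ NA_character_,
                                res$upper == 1L ~ "R", TRUE ~ "L"),
    rt = res$rt,
    timed_out = res$timed_out
  )
}
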