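#' Diffusion-model parameters for one condition
#'
#' Bundles the parameters of the drift-diffusion model: drift rate `v`
#' (evidence/s), boundary separation `a` (evidence units), relative starting
#' point `zr` (fraction of `a`), non-decision time `ter` (s), within-trial
#' diffusion coefficient `s`, and the trial-to-trial variabilities of the full
#' model: `sv` (SD of drift), `szr` (range of relative start), `st` (range of
#' non-decision time, s). With `sv = szr = st = 0` the object describes the
#' simple diffusion model exactly.
#'
#' The default scale convention is `s = 1`. The `s = 0.1` convention common in
#' parts of the literature is an equivalent reparameterization; see
#' [diffusion_rescale()].
#'
#' @param v Drift rate. Positive values drive the process toward the upper
#'   boundary.
#' @param a Boundary separation, `> 0`.
#' @param zr Relative starting point in `(0, 1)`; `0.5` is unbiased.
#' @param ter Non-decision time in seconds, `>= 0`.
#' @param s Within-trial diffusion coefficient, `> 0`.
#' @param sv,szr,st Trial-to-trial variabilities (all `>= 0`). `szr` must
#'   satisfy `szr < 2 * min(zr, 1 - zr)` and `st <= 2 * ter` so that the
#'   trial-level draws stay in the valid region.
#' @return An object of class `diffusion_params` (a named list).
#' @examples
#' diffusion_params(v = 1, a = 2)
#' @export
diffusion_params <- function(v, a, zr = 0.5, ter = 0.3, s = 1,
                             sv = 0, szr = 0, st = 0) {
  p <- structure(list(v = v, a = a, zr = zr, ter = ter, s = s,
                      sv = sv, szr = szr, st = st),
                 class = "diffusion_params")
  validate_diffusion_params(p)
  p
}

validate_diffusion_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("v", "a", "zr", "ter", "s", "sv", "szr", "st")) {
    if (!num1(p[[f]])) stop("diffusion parameter '", f, "' must be a finite number",
                            call. = FALSE)
  }
  if (p$a <= 0) stop("boundary separation 'a' must be > 0", call. = FALSE)
  if (p$zr <= 0 || p$zr >= 1) stop("relative starting point 'zr' must lie in (0, 1)",
                                   call. = FALSE)
  if (p$ter < 0) stop("non-decision time 'ter' must be >= 0", call. = FALSE)
  if (p$s <= 0) stop("diffusion coefficient 's' must be > 0", call. = FALSE)
  if (p$sv < 0 || p$szr < 0 || p$st < 0)
    stop("trial-to-trial variabilities must be >= 0", call. = FALSE)
  if (p$szr >= 2 * min(p$zr, 1 - p$zr))
    stop("'szr' must be < 2 * min(zr, 1 - zr)", call. = FALSE)
  if (p$st > 2 * p$ter) stop("'st' must be <= 2 * ter", call. = FALSE)
  invisible(p)
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat("<diffusion_params>",
      sprintf("v = %.4g, a = %.4g, zr = %.4g, ter = %.4g, s = %.4g", x$v, x$a,
              x$zr, x$ter, x$s), sep = "\n")
  if (x$sv > 0 || x$szr > 0 || x$st > 0)
    cat(sprintf("sv = %.4g, szr = %.4g, st = %.4g  (full model)\n",
                x$sv, x$szr, x$st))
  invisible(x)
}

#' Convert diffusion parameters between scale conventions
#'
#' The diffusion coefficient `s` is not identifiable from data: multiplying
#' `v`, `a` and `s` (and `sv`) by the same constant leaves the predicted
#' choice-RT distributions unchanged. This converter re-expresses a parameter
#' set on a different scale, e.g. between the `s = 1` convention used here and
#' the `s = 0.1` convention.
#'
#' @param p A [diffusion_params()] object.
#' @param s_new Target diffusion coefficient.
#' @return A `diffusion_params` object with identical behavior and `s = s_new`.
#' @examples
#' diffusion_rescale(diffusion_params(v = 1, a = 2), s_new = 0.1)
#' @export
diffusion_rescale <- function(p, s_new) {
  validate_diffusion_params(p)
  stopifnot(is.numeric(s_new), length(s_new) == 1, s_new > 0)
  k <- s_new / p$s
  diffusion_params(v = p$v * k, a = p$a * k, zr = p$zr, ter = p$ter,
                   s = s_new, sv = p$sv * k, szr = p$szr, st = p$st)
}

#' Linear ballistic accumulator parameters for one condition
#'
#' Two independent accumulators race ballistically to a threshold. Start
#' points are uniform on `[0, A]`, drift rates are drawn once per trial from
#' normals with SD `sdrift`, and the observed RT is the winning passage time
#' plus non-decision time `t0`.
#'
#' @param b Response threshold, `>= A`.
#' @param A Upper bound of the uniform start-point distribution, `>= 0`.
#' @param v_c Mean drift of the accumulator matching the stimulus.
#' @param v_e Mean drift of the mismatching accumulator.
#' @param sdrift Between-trial drift SD shared by both accumulators, `> 0`.
#' @param t0 Non-decision time in seconds, `>= 0`.
#' @param start_bias Additive threshold offset implementing response bias: the
#'   accumulator for response "R" races to `b - start_bias` and the one for
#'   "L" to `b + start_bias`, so positive values favor "R". With
#'   `start_bias = 0` the two response sides are exchangeable under stimulus
#'   relabeling.
#' @return An object of class `lba_params`.
#' @examples
#' lba_params(b = 1, A = 0.5, v_c = 2, v_e = 0.5)
#' @export
lba_params <- function(b, A, v_c, v_e, sdrift = 1, t0 = 0.2, start_bias = 0) {
  p <- structure(list(b = b, A = A, v_c = v_c, v_e = v_e, sdrift = sdrift,
                      t0 = t0, start_bias = start_bias),
                 class = "lba_params")
  validate_lba_params(p)
  p
}

validate_lba_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("b", "A", "v_c", "v_e", "sdrift", "t0", "start_bias")) {
    if (!num1(p[[f]])) stop("LBA parameter '", f, "' must be a finite number",
                            call. = FALSE)
  }
  if (p$A < 0) stop("start-point range 'A' must be >= 0", call. = FALSE)
  if (p$b < p$A) stop("threshold 'b' must be >= 'A'", call. = FALSE)
  if (p$sdrift <= 0) stop("'sdrift' must be > 0", call. = FALSE)
  if (p$t0 < 0) stop("'t0' must be >= 0", call. = FALSE)
  if (p$b - abs(p$start_bias) < p$A)
    stop("'start_bias' too large: effective threshold falls below 'A'",
         call. = FALSE)
  invisible(p)
}

#' @export
print.lba_params <- function(x, ...) {
  cat("<lba_params>",
      sprintf("b = %.4g, A = %.4g, v_c = %.4g, v_e = %.4g", x$b, x$A, x$v_c, x$v_e),
      sprintf("sdrift = %.4g, t0 = %.4g, start_bias = %.4g", x$sdrift, x$t0,
              x$start_bias), sep = "\n")
  invisible(x)
}
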