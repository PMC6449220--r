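#' Default manipulation effect sizes of the synthetic experiment
#'
#' Effect sizes on the `s = 1` scale: drift rate 1.0 on hard and 2.0 on easy
#' trials, boundary separation 1.0 under speed and 2.0 under accuracy
#' emphasis, and a starting-point shift of 0.05 toward the favored response in
#' biased blocks (base rate 2/3 for the favored stimulus). These produce
#' block-level accuracies and response-time quantiles in the ranges observed
#' in the behavioral study the generator emulates.
#'
#' @return A named list with elements `v_hard`, `v_easy`, `a_speed`,
#'   `a_accuracy`, `zr_bias_shift`.
#' @export
default_effect_sizes <- function() {
  list(v_hard = 1, v_easy = 2, a_speed = 1, a_accuracy = 2,
       zr_bias_shift = 0.05)
}

#' Draw a heterogeneous participant population
#'
#' Per-participant base diffusion parameters are log-normal perturbations of
#' the group-level base for the positive parameters (`v`, `a`, `ter`) and a
#' logit-normal perturbation for the relative starting point `zr`. Spreads
#' are coefficients of variation (log-normal sdlog chosen so the CV matches)
#' and, for `zr`, the SD on the logit scale.
#'
#' @param n_participants Number of participants.
#' @param base Group-level [diffusion_params()].
#' @param spread Named numeric vector of spreads for `v`, `a`, `ter`
#'   (coefficients of variation) and `zr` (logit-scale SD). Zero spread makes
#'   every participant identical to `base`.
#' @param seed Optional integer seed.
#' @return A tibble with columns `participant`, `v`, `a`, `zr`, `ter` plus the
#'   base `s`, `sv`, `szr`, `st`.
#' @examples
#' participant_population(3, diffusion_params(v = 1, a = 1), seed = 1)
#' @export
participant_population <- function(n_participants,
                                   base = diffusion_params(v = 1, a = 1),
                                   spread = c(v = 0.15, a = 0.15, ter = 0.1,
                                              zr = 0.1),
                                   seed = NULL) {
  stopifnot(n_participants >= 1)
  validate_diffusion_params(base)
  spread <- spread[c("v", "a", "ter", "zr")]
  if (anyNA(spread) || any(spread < 0))
    stop("'spread' must supply non-negative v, a, ter and zr entries",
         call. = FALSE)
  draw <- function() {
    logn <- function(m, cv) {
      if (cv == 0) return(rep(m, n_participants))
      sdlog <- sqrt(log(1 + cv^2))
      # mean of the log-normal equals the base value
      exp(rnorm(n_participants, log(m) - sdlog^2 / 2, sdlog))
    }
    zr <- if (spread["zr"] == 0) rep(base$zr, n_participants)
          else plogis(rnorm(n_participants, qlogis(base$zr), spread["zr"]))
    tibble::tibble(
      participant = seq_len(n_participants),
      v = logn(base$v, spread["v"]),
      a = logn(base$a, spread["a"]),
      zr = zr,
      ter = logn(base$ter, spread["ter"]),
      s = base$s, sv = base$sv, szr = base$szr, st = base$st
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Map a design cell onto condition-specific diffusion parameters
#'
#' Selective influence by construction: easy trials raise the drift rate,
#' accuracy emphasis raises the boundary separation, and a bias manipulation
#' shifts the starting point toward the favored response (the stimulus base
#' rate of 2/3 for the favored side is applied when trials are generated).
#' All other fields are untouched; the cell (hard, speed, none) is the
#' reference cell and returns `base` unchanged when the default effect sizes
#' have `v_hard` and `a_speed` equal to the base values.
#'
#' @param base [diffusion_params()] for one participant.
#' @param cell A list or one-row data frame with `difficulty`, `emphasis`,
#'   `bias` (`"left"`, `"none"`, `"right"`).
#' @param effect_sizes See [default_effect_sizes()]. Drift and boundary
#'   effects act multiplicatively relative to their reference levels, so they
#'   respect participant heterogeneity in `base`.
#' @return A [diffusion_params()] object for that cell.
#' @examples
#' base <- diffusion_params(v = 1, a = 1)
#' map_cell_to_params(base, list(difficulty = "easy", emphasis = "speed",
#'                               bias = "none"))
#' @export
map_cell_to_params <- function(base, cell, effect_sizes = default_effect_sizes()) {
  validate_diffusion_params(base)
  difficulty <- match.arg(cell$difficulty, c("easy", "hard"))
  emphasis <- match.arg(cell$emphasis, c("speed", "accuracy"))
  bias <- match.arg(cell$bias, c("left", "none", "right"))
  e <- effect_sizes
  v <- base$v * if (difficulty == "easy") e$v_easy / e$v_hard else 1
  a <- base$a * if (emphasis == "accuracy") e$a_accuracy / e$a_speed else 1
  zr <- base$zr + switch(bias, none = 0, right = e$zr_bias_shift,
                         left = -e$zr_bias_shift)
  diffusion_params(v = v, a = a, zr = zr, ter = base$ter, s = base$s,
                   sv = base$sv, szr = base$szr, st = base$st)
}
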