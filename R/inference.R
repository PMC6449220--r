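#' Configuration for drawing component inferences
#'
#' @param alpha Two-sided test level for the estimate-based procedure.
#' @param component_map Named character vector mapping the four components to
#'   parameter columns of a fit table. Defaults to the diffusion mapping;
#'   [lba_component_map()] gives the LBA analogue. Components mapped to `NA`
#'   are never inferred (returned as `"0"`).
#' @param accuracy_cutoff Heuristic: accuracy difference beyond which the
#'   conditions are taken to differ in ease (the 5% rule).
#' @param rt_q_cutoff Heuristic: cutoff (s) on RT-quantile differences (0.9
#'   quantile for caution, 0.1 quantile for non-decision time).
#' @param criterion_cutoff Heuristic: cutoff on the signal-detection
#'   criterion difference for a bias inference.
#' @return A list of class `inference_config`.
#' @export
inference_config <- function(alpha = 0.05,
                             component_map = c(ease = "v", caution = "a",
                                               biasR = "zr", ndt = "ter"),
                             accuracy_cutoff = 0.05, rt_q_cutoff = 0.05,
                             criterion_cutoff = 0.1) {
  stopifnot(alpha > 0, alpha < 1, accuracy_cutoff >= 0, rt_q_cutoff >= 0,
            criterion_cutoff >= 0)
  stopifnot(all(c("ease", "caution", "biasR", "ndt") %in%
                  names(component_map)))
  structure(list(alpha = alpha, component_map = component_map,
                 accuracy_cutoff = accuracy_cutoff,
                 rt_q_cutoff = rt_q_cutoff,
                 criterion_cutoff = criterion_cutoff),
            class = "inference_config")
}

#' Component-to-parameter mapping for LBA fits
#'
#' Ease maps to the matching drift, caution to the threshold, rightward bias
#' to the threshold offset and non-decision time to `t0`.
#'
#' @return A named character vector usable as `component_map`.
#' @export
lba_component_map <- function() {
  c(ease = "v_c", caution = "b", biasR = "start_bias", ndt = "t0")
}

#' Estimate-based inference of the manipulated components
#'
#' For each component, the mapped parameter estimates are compared across
#' conditions with a paired two-sided t-test over participants. When the test
#' is significant at `alpha`, the condition with the higher mean is labeled;
#' otherwise the component is `"0"`. No multiple-testing correction is
#' applied across the four components, mirroring the modal practice of
#' testing each parameter separately.
#'
#' @param fits_A,fits_B Per-participant fit tables (see
#'   [fit_participants()]) for the two conditions, sharing participants.
#' @param cfg An [inference_config()].
#' @return A one-row tibble with columns `ease`, `caution`, `biasR`, `ndt`,
#'   each `"A"`, `"0"` or `"B"`.
#' @export
infer_pattern_estimate_based <- function(fits_A, fits_B,
                                         cfg = inference_config()) {
  shared <- intersect(fits_A$participant, fits_B$participant)
  if (length(shared) < 3)
    stop("estimate-based inference needs at least 3 paired participants",
         call. = FALSE)
  a <- fits_A[match(shared, fits_A$participant), ]
  b <- fits_B[match(shared, fits_B$participant), ]
  one <- function(par) {
    if (is.na(par) || !par %in% names(a) || !par %in% names(b)) return("0")
    xa <- a[[par]]; xb <- b[[par]]
    ok <- is.finite(xa) & is.finite(xb)
    if (sum(ok) < 3) return("0")
    d <- xa[ok] - xb[ok]
    if (all(abs(d) < 1e-14)) return("0")
    tt <- t.test(d)
    if (tt$p.value >= cfg$alpha) "0" else if (mean(d) > 0) "A" else "B"
  }
  tibble::tibble(ease = one(cfg$component_map[["ease"]]),
                 caution = one(cfg$component_map[["caution"]]),
                 biasR = one(cfg$component_map[["biasR"]]),
                 ndt = one(cfg$component_map[["ndt"]]))
}

#' Signal-detection criterion
#'
#' `C = (z(H) + z(FA)) / 2` with `z` the standard-normal quantile function,
#' `H` the probability of responding "L" to a leftward stimulus and `FA` the
#' probability of responding "L" to a rightward stimulus. Positive values
#' indicate a bias toward responding "left".
#'
#' @param H,FA Hit and false-alarm rates (edge-corrected into (0, 1)).
#' @return The criterion value(s).
#' @examples
#' sdt_criterion(0.8413, 0.5)
#' @export
sdt_criterion <- function(H, FA) {
  if (any(H <= 0 | H >= 1 | FA <= 0 | FA >= 1))
    stop("H and FA must be edge-corrected into (0, 1)", call. = FALSE)
  0.5 * (qnorm(H) + qnorm(FA))
}

#' Edge-corrected hit/false-alarm rates for the "L" response
#'
#' @param trials A trial table with `stimulus` and `response`.
#' @return A list with `H`, `FA` and the criterion `C`.
#' @export
sdt_rates <- function(trials) {
  ok <- !is.na(trials$response)
  l_stim <- trials$stimulus[ok] == "L"
  nH <- sum(l_stim); nF <- sum(!l_stim)
  if (nH == 0 || nF == 0)
    stop("both stimulus sides are needed to compute SDT rates", call. = FALSE)
  H <- edge_correct(mean(trials$response[ok][l_stim] == "L"), nH)
  FA <- edge_correct(mean(trials$response[ok][!l_stim] == "L"), nF)
  list(H = H, FA = FA, C = sdt_criterion(H, FA))
}

participant_summaries <- function(trials, min_rt = 0.18) {
  trials |>
    dplyr::group_by(participant = .data$participant) |>
    dplyr::group_modify(function(d, key) {
      d <- exclude_outliers(d, min_rt)
      sdt <- sdt_rates(d)
      correct <- d$response == d$stimulus
      q10_by_resp <- vapply(c("L", "R"), function(r) {
        rts <- d$rt[d$response == r]
        if (length(rts) < 5) NA_real_ else unname(quantile(rts, 0.1))
      }, numeric(1))
      tibble::tibble(accuracy = mean(correct),
                     q90 = unname(quantile(d$rt, 0.9)),
                     q10_L = q10_by_resp[["L"]], q10_R = q10_by_resp[["R"]],
                     criterion = sdt$C)
    }) |>
    dplyr::ungroup()
}

#' Heuristic inference of the manipulated components
#'
#' Model-free rules on summary statistics, in the spirit of the published
#' 5%-accuracy rule: the conditions differ in ease when accuracy differs by
#' more than `accuracy_cutoff`; in caution when the slower condition (0.9 RT
#' quantile beyond `rt_q_cutoff`) is also the more accurate; in rightward
#' bias when the signal-detection criterion differs by more than
#' `criterion_cutoff` (the lower-criterion condition is the more
#' rightward-biased); and in non-decision time when the 0.1 RT quantile
#' shifts by more than `rt_q_cutoff` in the same direction for both response
#' classes. Statistics are computed per participant and averaged.
#'
#' @param trials_A,trials_B Trial tables for the two conditions.
#' @param cfg An [inference_config()].
#' @param min_rt Fast-guess cutoff.
#' @return A one-row tibble with `ease`, `caution`, `biasR`, `ndt`.
#' @export
infer_pattern_heuristic <- function(trials_A, trials_B,
                                    cfg = inference_config(),
                                    min_rt = 0.18) {
  stopifnot(nrow(trials_A) > 0, nrow(trials_B) > 0)
  sa <- participant_summaries(trials_A, min_rt)
  sb <- participant_summaries(trials_B, min_rt)
  d_acc <- mean(sa$accuracy) - mean(sb$accuracy)
  d_q90 <- mean(sa$q90) - mean(sb$q90)
  d_crit <- mean(sa$criterion) - mean(sb$criterion)
  d_q10_L <- mean(sa$q10_L, na.rm = TRUE) - mean(sb$q10_L, na.rm = TRUE)
  d_q10_R <- mean(sa$q10_R, na.rm = TRUE) - mean(sb$q10_R, na.rm = TRUE)
  ease <- if (abs(d_acc) > cfg$accuracy_cutoff) {
    if (d_acc > 0) "A" else "B"
  } else "0"
  caution <- if (abs(d_q90) > cfg$rt_q_cutoff && sign(d_q90) == sign(d_acc) &&
                 d_acc != 0) {
    if (d_q90 > 0) "A" else "B"
  } else "0"
  biasR <- if (abs(d_crit) > cfg$criterion_cutoff) {
    if (d_crit < 0) "A" else "B"   # lower criterion = more rightward bias
  } else "0"
  ndt <- if (!is.na(d_q10_L) && !is.na(d_q10_R) &&
             sign(d_q10_L) == sign(d_q10_R) &&
             min(abs(d_q10_L), abs(d_q10_R)) > cfg$rt_q_cutoff) {
    if (d_q10_L > 0) "A" else "B"
  } else "0"
  tibble::tibble(ease = ease, caution = caution, biasR = biasR, ndt = ndt)
}

#' Infer manipulation patterns for all pseudo-experiments
#'
#' Runs one inference procedure over every data set of a
#' `pseudo_experiments` object and returns the submission-style inference
#' table (rows = data sets, columns = components, entries in `A`/`0`/`B`).
#'
#' @param pe A [construct_pseudo_experiments()] result.
#' @param method `"ez2"`, `"ez"`, `"ml_diffusion"`, `"ml_lba"` (estimate-based
#'   inference on the corresponding fits) or `"heuristic"`.
#' @param cfg An [inference_config()]; for `"ml_lba"` the component map
#'   defaults to [lba_component_map()].
#' @param config A [fit_config()] for the model-based methods.
#' @return A tibble with columns `dataset`, `ease`, `caution`, `biasR`,
#'   `ndt`.
#' @export
infer_experiments <- function(pe, method = c("ez2", "ez", "ml_diffusion",
                                             "ml_lba", "heuristic"),
                              cfg = NULL, config = fit_config()) {
  method <- match.arg(method)
  stopifnot(inherits(pe, "pseudo_experiments"))
  if (is.null(cfg)) {
    cfg <- if (method == "ml_lba")
      inference_config(component_map = lba_component_map())
    else inference_config()
  }
  rows <- purrr::map2(pe$dataset, pe$data, function(id, dat) {
    A <- dat[dat$condition == "A", ]
    B <- dat[dat$condition == "B", ]
    pat <- if (method == "heuristic") {
      infer_pattern_heuristic(A, B, cfg, min_rt = config$min_rt)
    } else {
      fa <- fit_participants(A, method = method, config = config)
      fb <- fit_participants(B, method = method, config = config)
      infer_pattern_estimate_based(fa, fb, cfg)
    }
    dplyr::mutate(pat, dataset = id, .before = 1)
  })
  dplyr::bind_rows(rows)
}
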