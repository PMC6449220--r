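#' Run the full blinded-validation pipeline on synthetic data
#'
#' Convenience driver chaining the whole study: draw a participant
#' population, simulate the factorial session, relabel left/right, construct
#' the pseudo-experiments, run one or more inference procedures, and score
#' every inference table under the requested keys.
#'
#' @param seed Integer seed for the whole run.
#' @param n_participants Number of simulated participants.
#' @param n_per Trials per participant per condition in the constructed data
#'   sets.
#' @param methods Inference procedures (see [infer_experiments()]).
#' @param keys Scoring keys (see [scoring_key()]).
#' @param datasets Which pseudo-experiments to construct.
#' @param base,spread Population settings (see [participant_population()]).
#' @param effect_sizes See [default_effect_sizes()].
#' @param dt Euler step size for the generator.
#' @param config A [fit_config()] for model-based methods.
#' @return A list of class `validation_study` with elements `pe` (the
#'   pseudo-experiments), `inferences` (named list of inference tables),
#'   `scores` (tibble: method, key, outcome counts and proportions) and
#'   `agreement` (if two or more methods ran).
#' @export
run_validation_study <- function(seed = 1, n_participants = 20, n_per = 312,
                                 methods = c("ez2", "heuristic"),
                                 keys = c("planned", "alt1", "alt2", "no_ndt"),
                                 datasets = 1:14,
                                 base = diffusion_params(v = 1, a = 1),
                                 spread = c(v = 0.15, a = 0.15, ter = 0.1,
                                            zr = 0.1),
                                 effect_sizes = default_effect_sizes(),
                                 dt = 5e-4, config = fit_config()) {
  pop <- participant_population(n_participants, base = base, spread = spread,
                                seed = substream_seed(seed, 0, 1))
  session <- simulate_factorial_session(pop, effect_sizes = effect_sizes,
                                        seed = substream_seed(seed, 0, 2),
                                        dt = dt)
  session <- relabel_trials(session)
  pe <- construct_pseudo_experiments(session, n_per = n_per,
                                     seed = substream_seed(seed, 0, 3),
                                     datasets = datasets)
  inferences <- purrr::map(setNames(methods, methods), function(m)
    infer_experiments(pe, method = m, config = config))
  truth <- truth_patterns(pe)
  scores <- purrr::map(methods, function(m) {
    purrr::map(keys, function(k) {
      ss <- summarize_scores(inferences[[m]], build_truth(truth, k))
      dplyr::mutate(tibble::as_tibble(ss), method = m,
                    key = scoring_key(k)$name,
                    n_slots = attr(ss, "n_slots"), .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  out <- list(pe = pe, inferences = inferences, scores = scores,
              agreement = if (length(methods) >= 2)
                agreement_matrix(inferences) else NULL)
  class(out) <- "validation_study"
  out
}

#' @export
print.validation_study <- function(x, ...) {
  cat(sprintf("<validation_study> %d data sets, methods: %s\n",
              nrow(x$pe), paste(names(x$inferences), collapse = ", ")))
  wide <- x$scores |>
    dplyr::select("method", "key", "outcome", "proportion") |>
    dplyr::mutate(proportion = round_half_up(.data$proportion, 2)) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "proportion")
  print(wide)
  invisible(x)
}

#' Replicated end-to-end recovery study
#'
#' Repeats the whole pipeline (population, session, relabeling,
#' construction, fitting, inference) across seeded replicates and returns
#' the slot-level results, the raw material for detection and false-alarm
#' rates of an inference procedure under known manipulations.
#'
#' @param n_reps Number of replicates.
#' @param seed Base seed; replicate `r` runs with a substream seed derived
#'   from it.
#' @param datasets Which pseudo-experiments to construct per replicate.
#' @param method Inference procedure (see [infer_experiments()]).
#' @param ... Passed to [run_validation_study()].
#' @return A tibble with columns `replicate`, `dataset`, `component`,
#'   `truth`, `inferred`, `outcome`.
#' @export
recovery_study <- function(n_reps = 50, seed = 1, datasets = 1:4,
                           method = "ez2", ...) {
  purrr::map(seq_len(n_reps), function(r) {
    st <- run_validation_study(seed = substream_seed(seed, r, 0),
                               methods = method, keys = "planned",
                               datasets = datasets, ...)
    truth <- patterns_long(truth_patterns(st$pe))
    inf <- patterns_long(st$inferences[[method]], "inferred")
    out <- dplyr::inner_join(truth, inf, by = c("dataset", "component"))
    out$outcome <- classify_slot(out$truth, out$inferred)
    dplyr::mutate(out, replicate = r, .before = 1)
  }) |> dplyr::bind_rows()
}
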