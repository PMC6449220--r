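#' Simulate the full factorial session for a participant sample
#'
#' Generates trial-level data for every participant and block of the
#' schedule. Within each block, half the trials are easy and half hard,
#' randomly intermixed; the stimulus side is drawn with base rate 1/2 in
#' no-bias blocks and 2/3 for the favored side in biased blocks. Choice and
#' RT come from the diffusion model via [simulate_diffusion()], with the
#' participant's base parameters mapped through [map_cell_to_params()].
#' Responses slower than the deadline are censored and flagged.
#'
#' Reproducibility is hierarchical: from the session seed a deterministic
#' substream seed is derived per participant-by-block cell, so the same seed
#' reproduces the same table regardless of participant subset order.
#'
#' @param participants A participant table from [participant_population()].
#' @param schedule A block schedule, by default [block_schedule()].
#' @param effect_sizes See [default_effect_sizes()].
#' @param seed Integer session seed.
#' @param deadline Response deadline (s).
#' @param dt Euler step size passed to the simulator.
#' @return A tibble with columns `participant`, `block`, `trial`, `emphasis`,
#'   `bias`, `difficulty`, `stimulus`, `response`, `rt`, `timed_out`,
#'   `correct`.
#' @examples
#' pop <- participant_population(2, seed = 1)
#' sess <- simulate_factorial_session(pop, schedule = block_schedule()[1:2, ],
#'                                    seed = 1)
#' @export
simulate_factorial_session <- function(participants,
                                       schedule = block_schedule(),
                                       effect_sizes = default_effect_sizes(),
                                       seed = 1, deadline = 3, dt = 5e-4) {
  stopifnot(is.data.frame(participants), nrow(participants) >= 1,
            is.data.frame(schedule))
  combos <- tidyr::expand_grid(pp = seq_len(nrow(participants)),
                               bb = seq_len(nrow(schedule)))
  rows <- purrr::pmap(combos, function(pp, bb) {
    prow <- participants[pp, ]
    brow <- schedule[bb, ]
    sub_seed <- substream_seed(seed, prow$participant, brow$block)
    withr::with_seed(sub_seed, {
      n <- brow$n_trials
      difficulty <- sample(rep(c("easy", "hard"), length.out = n))
      p_right <- switch(brow$bias, none = 0.5, right = 2 / 3, left = 1 / 3)
      stimulus <- ifelse(runif(n) < p_right, "R", "L")
      base <- diffusion_params(v = prow$v, a = prow$a, zr = prow$zr,
                               ter = prow$ter, s = prow$s, sv = prow$sv,
                               szr = prow$szr, st = prow$st)
      out <- tibble::tibble(
        participant = prow$participant, block = brow$block, trial = seq_len(n),
        emphasis = brow$emphasis, bias = brow$bias,
        difficulty = difficulty, stimulus = stimulus,
        response = NA_character_, rt = NA_real_, timed_out = NA
      )
      for (dd in c("easy", "hard")) {
        for (ss in c("L", "R")) {
          idx <- which(difficulty == dd & stimulus == ss)
          if (!length(idx)) next
          cp <- map_cell_to_params(base, list(difficulty = dd,
                                              emphasis = brow$emphasis,
                                              bias = brow$bias), effect_sizes)
          sim <- simulate_diffusion(cp, stim = ss, n = length(idx),
                                    deadline = deadline, dt = dt)
          out$response[idx] <- sim$response
          out$rt[idx] <- sim$rt
          out$timed_out[idx] <- sim$timed_out
        }
      }
      out
    })
  })
  out <- dplyr::bind_rows(rows)
  out$correct <- !is.na(out$response) & out$response == out$stimulus
  out
}

# deterministic substream seed per participant x block, kept inside 32-bit range
substream_seed <- function(seed, participant, block) {
  as.integer((as.numeric(seed) * 7919 + participant * 104729 + block * 1009) %%
               2147483629)
}

#' Relabel left/right so the favored option reads "R"
#'
#' In biased blocks, stimulus and response labels are swapped where needed so
#' that the side favored by the base-rate manipulation is always labeled
#' `"R"` (the `bias` column then reads `"right"` everywhere a bias was
#' applied). In no-bias blocks, the labels of both stimulus and response are
#' flipped for the even-indexed half of the trials, so that any intrinsic
#' left/right asymmetry averages out. RT and correctness are invariant under
#' both operations.
#'
#' @param trials A trial table carrying `bias` and `trial` provenance columns
#'   (as produced by [simulate_factorial_session()]).
#' @return The relabeled trial table.
#' @export
relabel_trials <- function(trials) {
  needed <- c("bias", "trial", "stimulus", "response")
  missing <- setdiff(needed, names(trials))
  if (length(missing))
    stop("relabel_trials() needs provenance columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  flip_lab <- function(x) dplyr::case_when(x == "L" ~ "R", x == "R" ~ "L",
                                           TRUE ~ x)
  flip <- (trials$bias == "left") |
    (trials$bias == "none" & trials$trial %% 2 == 0)
  out <- trials
  out$stimulus[flip] <- flip_lab(trials$stimulus[flip])
  out$response[flip] <- flip_lab(trials$response[flip])
  out$bias[out$bias == "left"] <- "right"
  if ("correct" %in% names(out))
    out$correct <- !is.na(out$response) & out$response == out$stimulus
  out
}
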