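#' Construct the 14 two-condition pseudo-experiments
#'
#' Assembles blinded two-condition data sets from a relabeled factorial trial
#' table, one per row of [pseudo_experiment_design()]. Trials for each
#' condition are drawn at random (pooled freely across qualifying blocks)
#' from the source cell, per participant. The null experiment (data set 1)
#' splits the hard/speed/no-bias pool into two disjoint halves. Participant
#' ids are shuffled independently per data set (but consistently across the
#' two conditions, preserving the pairing), and the A/B labels of a random
#' half of the data sets are flipped; the stored truth pattern and source
#' cells are swapped along with the labels, so they always describe the
#' emitted conditions.
#'
#' @param trials A trial table that has been passed through
#'   [relabel_trials()].
#' @param n_per Trials per participant per condition (default 312, the yield
#'   of four qualifying blocks with 78 same-difficulty trials each).
#' @param seed Integer seed governing sampling, shuffling and flipping.
#' @param datasets Which data sets to construct (default all 14).
#' @return A tibble of class `pseudo_experiments` with the truth columns
#'   `ease`, `caution`, `biasR`, `ndt`, bookkeeping columns `flipped`,
#'   `cell_A`, `cell_B`, and a `data` list-column of per-trial tibbles with
#'   columns `participant`, `condition`, `stimulus`, `response`, `rt`,
#'   `timed_out`, `correct`.
#' @export
construct_pseudo_experiments <- function(trials, n_per = 312, seed = 1,
                                         datasets = 1:14) {
  stopifnot(is.data.frame(trials), all(datasets %in% 1:14))
  if (!all(trials$bias %in% c("none", "right")))
    stop("trials must be relabeled first (see relabel_trials())", call. = FALSE)
  trials$bias_type <- ifelse(trials$bias == "none", "none", "biased")
  design <- dplyr::filter(pseudo_experiment_design(), .data$dataset %in% datasets)
  flipped_ids <- withr::with_seed(substream_seed(seed, 0, 15),
                                  sample(datasets, floor(length(datasets) / 2)))
  pool_for <- function(dd, ee, bb) {
    dplyr::filter(trials, .data$difficulty == dd, .data$emphasis == ee,
                  .data$bias_type == bb)
  }
  take <- c("participant", "stimulus", "response", "rt", "timed_out", "correct")
  rows <- purrr::pmap(design, function(dataset, ease, caution, biasR, ndt,
                                       diff_A, emph_A, bias_A,
                                       diff_B, emph_B, bias_B) {
    sub_seed <- substream_seed(seed, 0, dataset)
    cellname <- function(d, e, b) paste(d, e, b, sep = ".")
    withr::with_seed(sub_seed, {
      if (dataset == 1L) {
        pool <- pool_for(diff_A, emph_A, bias_A)
        halves <- pool |>
          dplyr::group_by(.data$participant) |>
          dplyr::slice_sample(prop = 1) |>
          dplyr::mutate(condition = ifelse(
            dplyr::row_number() <= min(floor(dplyr::n() / 2), n_per), "A",
            ifelse(dplyr::row_number() > dplyr::n() -
                     min(floor(dplyr::n() / 2), n_per), "B", NA))) |>
          dplyr::ungroup() |>
          dplyr::filter(!is.na(.data$condition))
        dat <- halves[c(take, "condition")]
      } else {
        sample_cell <- function(d, e, b, cond) {
          pool <- pool_for(d, e, b)
          counts <- dplyr::count(pool, .data$participant)
          short <- counts$participant[counts$n < n_per]
          if (length(short) || nrow(counts) == 0)
            stop("insufficient trials in cell '", cellname(d, e, b),
                 "' for condition ", cond, call. = FALSE)
          pool |>
            dplyr::group_by(.data$participant) |>
            dplyr::slice_sample(n = n_per) |>
            dplyr::ungroup() |>
            dplyr::mutate(condition = cond) |>
            dplyr::select(dplyr::all_of(c(take, "condition")))
        }
        dat <- dplyr::bind_rows(sample_cell(diff_A, emph_A, bias_A, "A"),
                                sample_cell(diff_B, emph_B, bias_B, "B"))
      }
      # shuffle participant ids (same mapping in both conditions)
      ids <- sort(unique(dat$participant))
      new_ids <- sample(seq_along(ids))
      dat$participant <- new_ids[match(dat$participant, ids)]
      dat <- dplyr::arrange(dat, .data$condition, .data$participant)
      flip <- dataset %in% flipped_ids
      if (flip) dat$condition <- ifelse(dat$condition == "A", "B", "A")
      truth <- c(ease = ease, caution = caution, biasR = biasR, ndt = ndt)
      cells <- c(A = cellname(diff_A, emph_A, bias_A),
                 B = cellname(diff_B, emph_B, bias_B))
      if (flip) {
        truth <- swap_pattern(truth)
        cells <- cells[c("B", "A")]
      }
      tibble::tibble(dataset = dataset, ease = truth[["ease"]],
                     caution = truth[["caution"]], biasR = truth[["biasR"]],
                     ndt = truth[["ndt"]], flipped = flip,
                     cell_A = cells[[1]], cell_B = cells[[2]],
                     data = list(dat))
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("pseudo_experiments", class(out))
  out
}

#' Extract the truth patterns of constructed pseudo-experiments
#'
#' @param pe A `pseudo_experiments` object.
#' @return A tibble with columns `dataset`, `ease`, `caution`, `biasR`, `ndt`.
#' @export
truth_patterns <- function(pe) {
  stopifnot(inherits(pe, "pseudo_experiments"))
  tibble::as_tibble(pe[c("dataset", "ease", "caution", "biasR", "ndt")])
}

#' Write pseudo-experiments as delimited text
#'
#' One CSV per data set (columns: dataset, participant, condition, stimulus,
#' response, rt, correct) plus a separate `truth.csv` holding the hidden
#' manipulation patterns, kept apart to preserve blinding.
#'
#' @param pe A `pseudo_experiments` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pseudo_experiments <- function(pe, dir) {
  stopifnot(inherits(pe, "pseudo_experiments"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map2_chr(pe$dataset, pe$data, function(id, dat) {
    path <- file.path(dir, sprintf("dataset_%02d.csv", id))
    out <- dplyr::mutate(dat, dataset = id, .before = 1)
    utils::write.csv(out[c("dataset", "participant", "condition", "stimulus",
                           "response", "rt", "correct")],
                     path, row.names = FALSE)
    path
  })
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(pe[c("dataset", "ease", "caution", "biasR", "ndt",
                        "flipped", "cell_A", "cell_B")],
                   truth_path, row.names = FALSE)
  invisible(c(paths, truth_path))
}
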