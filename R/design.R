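#' Block schedule of the factorial session
#'
#' The 18 main blocks of 156 trials: speed vs. accuracy emphasis and the
#' stimulus base-rate bias (favored side left, right, or none) alternate
#' across blocks; difficulty is manipulated within blocks. From block 2
#' through 17 every emphasis-by-bias cell occurs four times; blocks 1 and 18
#' add two extra speed/no-bias blocks so that the null pseudo-experiment can
#' be built from two disjoint halves of that cell.
#'
#' @return A tibble with columns `block`, `emphasis` (`"speed"`/`"accuracy"`),
#'   `bias` (`"left"`/`"none"`/`"right"`) and `n_trials` (156).
#' @examples
#' block_schedule()
#' @export
block_schedule <- function() {
  emphasis <- c("speed", "accuracy", "speed", "speed", "accuracy", "accuracy",
                "speed", "speed", "accuracy", "accuracy", "speed", "speed",
                "accuracy", "accuracy", "speed", "speed", "accuracy", "speed")
  bias <- c("none", "none", "none", "left", "left", "none", "none", "right",
            "right", "none", "none", "left", "left", "none", "none", "right",
            "right", "none")
  tibble::tibble(block = 1:18, emphasis = emphasis, bias = bias,
                 n_trials = 156L)
}

#' The factorial design cells
#'
#' @return A tibble of the 2 x 2 x 3 = 12 cells: `difficulty`
#'   (`"easy"`/`"hard"`), `emphasis`, `bias`.
#' @export
design_cells <- function() {
  tidyr::expand_grid(difficulty = c("easy", "hard"),
                     emphasis = c("speed", "accuracy"),
                     bias = c("left", "none", "right"))
}

pattern_levels <- c("A", "0", "B")

# swap condition labels in a pattern vector
swap_pattern <- function(x) {
  out <- x
  out[x == "A"] <- "B"
  out[x == "B"] <- "A"
  out
}

# canonical representative of {p, swap(p)}: prefer more B entries; on a tie,
# prefer B on the later component
canonical_pattern <- function(p) {
  q <- swap_pattern(p)
  nb_p <- sum(p == "B"); nb_q <- sum(q == "B")
  if (nb_p != nb_q) return(if (nb_p > nb_q) p else q)
  for (i in rev(seq_along(p))) {
    if (p[i] != q[i] && p[i] != "0")
      return(if (p[i] == "B") p else q)
  }
  p
}

#' Design of the 14 two-condition pseudo-experiments
#'
#' For each pseudo-experiment: the truth pattern (which condition was
#' manipulated to have the higher value on ease, caution and rightward bias;
#' non-decision time is never manipulated) and the source cells of the
#' factorial design from which each condition is drawn. Cells are stated
#' after relabeling, when the favored side of every biased block reads
#' "right", so bias is simply `"none"` or `"biased"`. Where several cell
#' pairs could realize a pattern, the pair with no bias and the most errors
#' (hard over easy, speed over accuracy) is used, because most RT models need
#' error responses to constrain their parameters.
#'
#' @return A tibble with columns `dataset`, `ease`, `caution`, `biasR`, `ndt`
#'   (each in `"A"`, `"0"`, `"B"`) and the source cells `diff_A`, `emph_A`,
#'   `bias_A`, `diff_B`, `emph_B`, `bias_B`.
#' @examples
#' pseudo_experiment_design()
#' @export
pseudo_experiment_design <- function() {
  d <- tibble::tribble(
    ~dataset, ~ease, ~caution, ~biasR, ~cell_A,              ~cell_B,
    1L,  "0", "0", "0", "hard.speed.none",    "hard.speed.none",
    2L,  "B", "0", "0", "hard.speed.none",    "easy.speed.none",
    3L,  "0", "B", "0", "hard.speed.none",    "hard.accuracy.none",
    4L,  "0", "0", "B", "hard.speed.none",    "hard.speed.biased",
    5L,  "B", "B", "0", "hard.speed.none",    "easy.accuracy.none",
    6L,  "B", "0", "B", "hard.speed.none",    "easy.speed.biased",
    7L,  "0", "B", "B", "hard.speed.none",    "hard.accuracy.biased",
    8L,  "A", "B", "0", "easy.speed.none",    "hard.accuracy.none",
    9L,  "A", "0", "B", "easy.speed.none",    "hard.speed.biased",
    10L, "0", "A", "B", "hard.accuracy.none", "hard.speed.biased",
    11L, "A", "B", "B", "easy.speed.none",    "hard.accuracy.biased",
    12L, "B", "A", "B", "hard.accuracy.none", "easy.speed.biased",
    13L, "B", "B", "A", "hard.speed.biased",  "easy.accuracy.none",
    14L, "B", "B", "B", "hard.speed.none",    "easy.accuracy.biased"
  )
  split_cell <- function(x, suffix) {
    parts <- strsplit(x, ".", fixed = TRUE)
    out <- tibble::tibble(purrr::map_chr(parts, 1), purrr::map_chr(parts, 2),
                          purrr::map_chr(parts, 3))
    names(out) <- paste0(c("diff_", "emph_", "bias_"), suffix)
    out
  }
  dplyr::bind_cols(
    d[c("dataset", "ease", "caution", "biasR")],
    ndt = "0",
    split_cell(d$cell_A, "A"),
    split_cell(d$cell_B, "B")
  )
}

#' Enumerate the canonical truth patterns
#'
#' All assignments of `{A, 0, B}` to the three manipulable components (ease,
#' caution, rightward bias), reduced to equivalence classes under the global
#' swap of condition labels A and B: `(3^3 + 1) / 2 = 14` classes. Each class
#' is represented by its canonical labeling and ordered as in
#' [pseudo_experiment_design()]. Non-decision time is `"0"` throughout, as it
#' is never manipulated.
#'
#' @return A tibble with columns `dataset`, `ease`, `caution`, `biasR`, `ndt`.
#' @examples
#' enumerate_patterns()
#' @export
enumerate_patterns <- function() {
  grid <- tidyr::expand_grid(ease = pattern_levels, caution = pattern_levels,
                             biasR = pattern_levels)
  canon <- purrr::pmap(grid, function(ease, caution, biasR) {
    canonical_pattern(c(ease, caution, biasR))
  })
  canon <- unique(canon)
  classes <- tibble::tibble(
    ease = purrr::map_chr(canon, 1),
    caution = purrr::map_chr(canon, 2),
    biasR = purrr::map_chr(canon, 3),
    ndt = "0"
  )
  design <- pseudo_experiment_design()[
    c("dataset", "ease", "caution", "biasR", "ndt")]
  out <- dplyr::inner_join(design, classes,
                           by = c("ease", "caution", "biasR", "ndt"))
  if (nrow(out) != nrow(classes) || nrow(out) != nrow(design))
    stop("enumerated pattern classes do not match the canonical design",
         call. = FALSE)  # nocov
  dplyr::arrange(out, .data$dataset)
}
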