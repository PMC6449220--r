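#' Plot a score summary
#'
#' Bar chart of the outcome proportions (correct, miss, false alarm, flip)
#' for one method under one scoring key.
#'
#' @param object A `score_summary` from [summarize_scores()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_summary <- function(object, ...) {
  cols <- c(correct = "#2e7d32", miss = "#1565c0", false_alarm = "#ef6c00",
            flip = "#212121")
  df <- tibble::as_tibble(object)
  df$outcome <- factor(df$outcome, levels = names(cols))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$proportion,
                                   fill = .data$outcome)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = cols) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion of inferences") +
    ggplot2::theme_minimal()
}

#' Plot a method-agreement matrix
#'
#' Tile map of the pairwise proportion of shared inferences.
#'
#' @param object An `agreement_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tibble::as_tibble(as.table(m), .name_repair = ~ c("m1", "m2", "agreement"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m1, y = .data$m2,
                                   fill = .data$agreement)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$agreement)), color = "white") +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "grey30",
                                 high = "#2e7d32") +
    ggplot2::labs(x = NULL, y = NULL, fill = "shared") +
    ggplot2::theme_minimal()
}

#' Compare a defective density with simulated trials
#'
#' Overlays the model's defective first-passage density on a histogram of
#' simulated response times for the same boundary or accumulator, a visual
#' version of the simulation/density cross-checks in the test suite.
#'
#' @param p A [diffusion_params()] or [lba_params()] object.
#' @param n Number of simulated trials.
#' @param boundary For the diffusion: `"upper"` or `"lower"`; for the LBA:
#'   `"match"` or `"mismatch"`.
#' @param seed Seed for the simulation.
#' @return A ggplot object.
#' @export
plot_density_check <- function(p, n = 5000, boundary = "upper", seed = 1) {
  if (inherits(p, "diffusion_params")) {
    sim <- simulate_diffusion(p, "R", n = n, seed = seed)
    keep <- sim$response == (if (boundary == "upper") "R" else "L") &
      !sim$timed_out
    f <- function(t) wiener_fpt_density(t, p, boundary = boundary)
  } else {
    sim <- simulate_lba(p, "R", n = n, seed = seed)
    keep <- sim$response == (if (boundary == "match") "R" else "L") &
      !sim$timed_out
    f <- function(t) lba_defective_density(t, p, which = boundary)
  }
  rts <- sim$rt[keep & !is.na(keep)]
  grid <- tibble::tibble(t = seq(min(rts), max(rts), length.out = 400))
  grid$density <- f(grid$t) / (length(rts) / n)
  ggplot2::ggplot(tibble::tibble(rt = rts), ggplot2::aes(x = .data$rt)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey80", color = "grey60") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$t, y = .data$density),
                       color = "#b71c1c", linewidth = 0.8) +
    ggplot2::labs(x = "response time (s)",
                  y = "conditional density (1/s)") +
    ggplot2::theme_minimal()
}
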