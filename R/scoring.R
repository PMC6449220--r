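#' Scoring keys for inference tables
#'
#' Four ways of defining the "correct" inference: `planned` assumes strict
#' selective influence (the truth patterns as manipulated); `alt1_caution_ease`
#' assumes emphasis manipulations affect both caution and ease, so the ease
#' truth is set equal to the caution truth wherever caution was manipulated —
#' data sets whose manipulated ease and caution point in opposite directions
#' cannot be rescored coherently and are excluded (data sets 8, 11 and 12
#' for the canonical patterns); `alt2_caution_ndt` assumes emphasis
#' manipulations affect both caution and non-decision time, coupling the ndt
#' truth to the caution truth; `planned_no_ndt` is the planned key with the
#' non-decision-time column removed.
#'
#' @param name One of `"planned"`, `"alt1_caution_ease"`,
#'   `"alt2_caution_ndt"`, `"planned_no_ndt"` (aliases `"alt1"`, `"alt2"`,
#'   `"no_ndt"`).
#' @return A list of class `scoring_key`.
#' @export
scoring_key <- function(name = c("planned", "alt1_caution_ease",
                                 "alt2_caution_ndt", "planned_no_ndt",
                                 "alt1", "alt2", "no_ndt")) {
  name <- match.arg(name)
  name <- switch(name, alt1 = "alt1_caution_ease", alt2 = "alt2_caution_ndt",
                 no_ndt = "planned_no_ndt", name)
  structure(list(name = name), class = "scoring_key")
}

components <- c("ease", "caution", "biasR", "ndt")

patterns_long <- function(patterns, value_name = "truth") {
  out <- tidyr::pivot_longer(
    patterns[c("dataset", components)],
    cols = dplyr::all_of(components),
    names_to = "component", values_to = value_name)
  out$component <- factor(out$component, levels = components)
  out
}

#' Build the truth table for a scoring key
#'
#' Applies the key's component coupling and exclusions to a set of
#' manipulation patterns. Exclusions under the caution-and-ease key are
#' computed generically: a data set is dropped when its manipulated ease and
#' caution truths are non-zero and opposite.
#'
#' @param patterns A pattern table (columns `dataset`, `ease`, `caution`,
#'   `biasR`, `ndt`), e.g. [enumerate_patterns()] or [truth_patterns()].
#' @param key A [scoring_key()] or key name.
#' @return A long tibble with columns `dataset`, `component`, `truth`.
#' @examples
#' build_truth(enumerate_patterns(), "alt1")
#' @export
build_truth <- function(patterns, key = "planned") {
  if (!inherits(key, "scoring_key")) key <- scoring_key(key)
  p <- tibble::as_tibble(patterns[c("dataset", components)])
  manipulated <- p$caution != "0"
  if (key$name == "alt1_caution_ease") {
    conflicted <- manipulated & p$ease != "0" & p$ease != p$caution
    p <- p[!conflicted, ]
    manipulated <- p$caution != "0"
    p$ease[manipulated] <- p$caution[manipulated]
  } else if (key$name == "alt2_caution_ndt") {
    p$ndt[manipulated] <- p$caution[manipulated]
  }
  out <- patterns_long(p)
  if (key$name == "planned_no_ndt") out <- out[out$component != "ndt", ]
  out
}

#' Classify one inference slot against the truth
#'
#' Vectorized over slots: equal labels are `correct`; a manipulated effect
#' inferred as absent is a `miss`; an absent effect inferred as present is a
#' `false_alarm`; opposite non-zero labels are a `flip`. The four outcomes
#' partition all 9 truth-by-inference combinations.
#'
#' @param truth,inferred Vectors with entries in `"A"`, `"0"`, `"B"`.
#' @return A factor with levels `correct`, `miss`, `false_alarm`, `flip`.
#' @examples
#' classify_slot(c("B", "B", "0", "A"), c("B", "0", "A", "B"))
#' @export
classify_slot <- function(truth, inferred) {
  stopifnot(all(truth %in% c("A", "0", "B")),
            all(inferred %in% c("A", "0", "B")))
  out <- dplyr::case_when(
    truth == inferred ~ "correct",
    truth != "0" & inferred == "0" ~ "miss",
    truth == "0" & inferred != "0" ~ "false_alarm",
    TRUE ~ "flip"
  )
  factor(out, levels = c("correct", "miss", "false_alarm", "flip"))
}

#' Round half away from zero (display rounding)
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Score an inference table against a truth table
#'
#' Joins the inference table onto the truth table of a scoring key,
#' classifies every slot and tallies the outcomes. Proportions are stored at
#' full precision; printing rounds to two decimals (half up) for
#' tabular display.
#'
#' @param inferences An inference table (columns `dataset`, `ease`,
#'   `caution`, `biasR`, `ndt`).
#' @param truth A long truth table from [build_truth()].
#' @return A tibble of class `score_summary` with columns `outcome`, `count`,
#'   `proportion`, and attribute `n_slots`.
#' @examples
#' truth <- build_truth(enumerate_patterns(), "planned")
#' perfect <- enumerate_patterns()
#' summarize_scores(perfect, truth)
#' @export
summarize_scores <- function(inferences, truth) {
  inf_long <- patterns_long(inferences, "inferred")
  slots <- dplyr::inner_join(truth, inf_long, by = c("dataset", "component"))
  if (nrow(slots) != nrow(truth))
    stop("inference table does not cover every truth slot", call. = FALSE)
  slots$outcome <- classify_slot(slots$truth, slots$inferred)
  counts <- table(slots$outcome)
  out <- tibble::tibble(outcome = names(counts),
                        count = as.integer(counts),
                        proportion = as.integer(counts) / nrow(slots))
  attr(out, "n_slots") <- nrow(slots)
  class(out) <- c("score_summary", class(out))
  out
}

#' @export
print.score_summary <- function(x, ...) {
  cat(sprintf("<score_summary> %d slots\n", attr(x, "n_slots")))
  disp <- dplyr::mutate(tibble::as_tibble(x),
                        proportion = round_half_up(.data$proportion, 2))
  print(disp)
  invisible(x)
}

#' Pairwise agreement between inference tables
#'
#' Proportion of identical `{A, 0, B}` entries over the shared slots for
#' every pair of methods.
#'
#' @param tables A named list of inference tables covering the same slots.
#' @return A symmetric matrix of class `agreement_matrix` with unit diagonal.
#' @export
agreement_matrix <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2, !is.null(names(tables)))
  longs <- purrr::map(tables, patterns_long, value_name = "inferred")
  ref <- longs[[1]][c("dataset", "component")]
  for (l in longs[-1]) {
    if (!identical(l[c("dataset", "component")], ref))
      stop("all inference tables must cover the same slots", call. = FALSE)
  }
  k <- length(tables)
  m <- matrix(1, k, k, dimnames = list(names(tables), names(tables)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      agree <- mean(longs[[i]]$inferred == longs[[j]]$inferred)
      m[i, j] <- m[j, i] <- agree
    }
  }
  class(m) <- c("agreement_matrix", class(m))
  m
}
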