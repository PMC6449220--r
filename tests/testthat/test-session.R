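# a small shared session keeps these tests fast; generated once per run
session_cache <- new.env()
small_session <- function() {
  if (is.null(session_cache$sess)) {
    pop <- participant_population(2, seed = 42)
    session_cache$sess <- simulate_factorial_session(pop, seed = 7)
  }
  session_cache$sess
}

test_that("session has the factorial trial structure", {
  sess <- small_session()
  expect_equal(nrow(sess), 2 * 18 * 156)
  counts <- dplyr::count(sess, participant, block)
  expect_true(all(counts$n == 156))
  # 50/50 easy-hard within every block
  mix <- dplyr::count(sess, participant, block, difficulty)
  expect_true(all(mix$n == 78))
  expect_true(all(sess$rt > 0 & sess$rt <= 3))
})

test_that("stimulus base rates follow the bias manipulation", {
  sess <- small_session()
  byb <- sess |>
    dplyr::group_by(bias) |>
    dplyr::summarise(pL = mean(stimulus == "L"), n = dplyr::n())
  for (b in c("left", "none", "right")) {
    target <- switch(b, none = 0.5, left = 2 / 3, right = 1 / 3)
    row <- byb[byb$bias == b, ]
    se <- sqrt(target * (1 - target) / row$n)
    expect_lt(abs(row$pL - target), 3 * se)
  }
})

test_that("accuracy emphasis produces slower and more accurate behavior", {
  sess <- small_session()
  byemph <- sess |>
    dplyr::group_by(emphasis) |>
    dplyr::summarise(acc = mean(correct), med = median(rt),
                     q10 = quantile(rt, 0.1), q90 = quantile(rt, 0.9))
  ac <- byemph[byemph$emphasis == "accuracy", ]
  sp <- byemph[byemph$emphasis == "speed", ]
  expect_gt(ac$acc, sp$acc)
  expect_gt(ac$med, sp$med)
  expect_gt(ac$q10, sp$q10)
  expect_gt(ac$q90, sp$q90)
  # easy trials are answered more accurately than hard ones
  bydiff <- sess |>
    dplyr::group_by(difficulty) |>
    dplyr::summarise(acc = mean(correct))
  expect_gt(bydiff$acc[bydiff$difficulty == "easy"],
            bydiff$acc[bydiff$difficulty == "hard"])
})

test_that("session generation is seed-reproducible", {
  pop <- participant_population(1, seed = 3)
  sched <- block_schedule()[1:2, ]
  s1 <- simulate_factorial_session(pop, schedule = sched, seed = 11)
  s2 <- simulate_factorial_session(pop, schedule = sched, seed = 11)
  expect_identical(s1, s2)
})

test_that("relabeling makes the favored option read R and preserves
           accuracy and RT", {
  sess <- small_session()
  rel <- relabel_trials(sess)
  expect_true(all(rel$bias %in% c("none", "right")))
  # originally left-biased blocks now have majority R stimuli
  left_blocks <- unique(sess$block[sess$bias == "left"])
  sub <- rel[rel$block %in% left_blocks, ]
  expect_gt(mean(sub$stimulus == "R"), 0.6)
  expect_identical(rel$rt, sess$rt)
  expect_equal(mean(rel$correct), mean(sess$correct))
  per_block <- function(d) d |>
    dplyr::group_by(block) |>
    dplyr::summarise(acc = mean(correct))
  expect_equal(per_block(rel), per_block(sess))
})

test_that("relabeling is an involution on no-bias blocks", {
  sess <- small_session()
  nb <- sess[sess$bias == "none", ]
  twice <- relabel_trials(relabel_trials(nb))
  expect_identical(twice$stimulus, nb$stimulus)
  expect_identical(twice$response, nb$response)
})

test_that("relabeling requires provenance columns", {
  expect_error(relabel_trials(tibble::tibble(stimulus = "L", response = "L")),
               "provenance")
})

test_that("participant heterogeneity has the configured spread", {
  # large-n check of the coefficient of variation of boundary separation
  pop <- participant_population(2000, spread = c(v = 0.15, a = 0.2,
                                                 ter = 0.1, zr = 0.1),
                                seed = 9)
  cv_a <- stats::sd(pop$a) / mean(pop$a)
  # sampling SE of a log-normal CV at n = 2000 is roughly cv/sqrt(2n)
  expect_lt(abs(cv_a - 0.2), 3 * 0.2 / sqrt(2 * 2000) * 1.5)
  expect_equal(mean(pop$a), 1, tolerance = 0.03)
  # zero spread collapses onto the base
  pop0 <- participant_population(5, spread = c(v = 0, a = 0, ter = 0, zr = 0),
                                 seed = 1)
  expect_true(all(pop0$v == 1 & pop0$a == 1 & pop0$zr == 0.5 &
                    pop0$ter == 0.3))
  expect_identical(participant_population(5, seed = 2),
                   participant_population(5, seed = 2))
})

test_that("cell mapping implements selective influence by construction", {
  base <- diffusion_params(v = 1, a = 1, zr = 0.5, ter = 0.3)
  ref <- map_cell_to_params(base, list(difficulty = "hard",
                                       emphasis = "speed", bias = "none"))
  expect_equal(unclass(ref), unclass(base))
  easy <- map_cell_to_params(base, list(difficulty = "easy",
                                        emphasis = "speed", bias = "none"))
  expect_equal(easy$v, 2)
  expect_equal(easy[c("a", "zr", "ter")], base[c("a", "zr", "ter")])
  acc <- map_cell_to_params(base, list(difficulty = "hard",
                                       emphasis = "accuracy", bias = "none"))
  expect_equal(acc$a, 2)
  expect_equal(acc[c("v", "zr", "ter")], base[c("v", "zr", "ter")])
  left <- map_cell_to_params(base, list(difficulty = "hard",
                                        emphasis = "speed", bias = "left"))
  expect_equal(left$zr, 0.45)
})
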