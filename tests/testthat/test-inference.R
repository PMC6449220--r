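# oracle per-participant "fits": true parameters plus small independent noise
oracle_fits <- function(n = 20, v = 1, a = 1, zr = 0.5, ter = 0.3,
                        noise = 1e-3, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    participant = seq_len(n),
    v = v + rnorm(n, 0, noise), a = a + rnorm(n, 0, noise),
    zr = zr + rnorm(n, 0, noise), ter = ter + rnorm(n, 0, noise)))
}

test_that("estimate-based inference labels the manipulated component only", {
  fa <- oracle_fits(seed = 1)
  fb <- oracle_fits(a = 2, seed = 2)
  pat <- infer_pattern_estimate_based(fa, fb)
  expect_equal(unlist(pat, use.names = FALSE), c("0", "B", "0", "0"))
  # identical fits give the all-zero pattern
  expect_equal(unlist(infer_pattern_estimate_based(fa, fa), use.names = FALSE),
               rep("0", 4))
  # antisymmetry under condition swap
  swapped <- infer_pattern_estimate_based(fb, fa)
  expect_equal(unlist(swapped, use.names = FALSE), c("0", "A", "0", "0"))
  expect_error(infer_pattern_estimate_based(fa[1:2, ], fb[1:2, ]), "paired")
})

test_that("estimate-based inference skips components without a mapped
           parameter", {
  fa <- oracle_fits(seed = 3)[, c("participant", "v", "a", "ter")]
  fb <- oracle_fits(v = 2, seed = 4)[, c("participant", "v", "a", "ter")]
  pat <- infer_pattern_estimate_based(fa, fb)
  expect_equal(pat$biasR, "0")
  expect_equal(pat$ease, "B")
})

test_that("false-alarm rate of the paired test is calibrated at alpha", {
  # null case: both conditions share the same population parameters; the
  # per-component rejection rate must sit inside binomial bounds of alpha
  n_rep <- 200
  hits <- purrr::map(1:n_rep, function(r) {
    fa <- oracle_fits(noise = 0.05, seed = 2 * r)
    fb <- oracle_fits(noise = 0.05, seed = 2 * r + 1)
    unlist(infer_pattern_estimate_based(fa, fb), use.names = FALSE) != "0"
  })
  k <- sum(do.call(rbind, hits))   # pooled over the four components
  n_tot <- 4 * n_rep
  expect_gte(k, qbinom(0.025, n_tot, 0.05))
  expect_lte(k, qbinom(0.975, n_tot, 0.05))
})

test_that("sdt criterion follows the normal-quantile definition", {
  expect_equal(sdt_criterion(0.5, 0.5), 0)
  expect_equal(sdt_criterion(0.8413447, 0.5), 0.5, tolerance = 1e-4)
  expect_error(sdt_criterion(1, 0.5), "edge-corrected")
  # leftward response bias gives positive criterion
  tr <- tibble::tibble(stimulus = rep(c("L", "R"), each = 100),
                       response = c(rep("L", 95), rep("R", 5),
                                    rep("L", 40), rep("R", 60)))
  expect_gt(sdt_rates(tr)$C, 0)
})

test_that("heuristic rules fire on the constructed contrasts", {
  base <- function(acc, rt_shift = 0, n = 400, seed = 1) {
    withr::with_seed(seed, tibble::tibble(
      participant = rep(1:4, each = n / 4),
      stimulus = sample(c("L", "R"), n, TRUE),
      rt = 0.5 + rt_shift + rexp(n, 8),
      timed_out = FALSE) |>
        dplyr::mutate(response = ifelse(runif(n) < acc, stimulus,
                                        ifelse(stimulus == "L", "R", "L"))))
  }
  # pure accuracy difference, equal RTs: ease only (the 5% rule)
  pat <- infer_pattern_heuristic(base(0.90, seed = 1), base(0.80, seed = 2))
  expect_equal(pat$ease, "A")
  expect_equal(pat$caution, "0")
  # identical conditions: all-zero
  x <- base(0.85, seed = 3)
  expect_equal(unlist(infer_pattern_heuristic(x, x), use.names = FALSE),
               rep("0", 4))
  # slower AND more accurate: caution
  pat2 <- infer_pattern_heuristic(base(0.9, rt_shift = 0.15, seed = 4),
                                  base(0.8, seed = 5))
  expect_equal(pat2$caution, "A")
  # common shift of the fast tail in both response classes: ndt
  pat3 <- infer_pattern_heuristic(base(0.85, rt_shift = 0.1, seed = 6),
                                  base(0.85, seed = 7))
  expect_equal(pat3$ndt, "A")
  # antisymmetry
  pat4 <- infer_pattern_heuristic(base(0.80, seed = 2), base(0.90, seed = 1))
  expect_equal(pat4$ease, "B")
})

test_that("heuristic detects a caution manipulation in simulated data", {
  # a doubled in condition B, everything else equal: expect caution = B in
  # the vast majority of seeded replicates
  hit <- vapply(1:10, function(r) {
    pa <- diffusion_params(v = 1, a = 1, ter = 0.3)
    pb <- diffusion_params(v = 1, a = 2, ter = 0.3)
    mk <- function(p, seed) {
      purrr::map(1:6, function(i) {
        dplyr::mutate(sim_trials_diffusion(p, 78, seed = seed + i),
                      participant = i)
      }) |> dplyr::bind_rows()
    }
    pat <- infer_pattern_heuristic(mk(pa, 5000 + 100 * r),
                                   mk(pb, 7000 + 100 * r))
    pat$caution == "B"
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("bias shows up as a criterion difference in the right direction", {
  # rightward starting-point bias lowers the criterion
  pa <- diffusion_params(v = 1, a = 1, zr = 0.5, ter = 0.3)
  pb <- diffusion_params(v = 1, a = 1, zr = 0.6, ter = 0.3)
  ca <- sdt_rates(sim_trials_diffusion(pa, 2000, seed = 41))$C
  cb <- sdt_rates(sim_trials_diffusion(pb, 2000, seed = 42))$C
  expect_gt(ca, cb)
  # and a leftward bias (zr < .5) raises it above the unbiased value
  pl <- diffusion_params(v = 1, a = 1, zr = 0.4, ter = 0.3)
  cl <- sdt_rates(sim_trials_diffusion(pl, 2000, seed = 43))$C
  expect_gt(cl, ca)
})
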