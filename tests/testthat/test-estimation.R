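test_that("ez moments follow hand arithmetic and the edge-correction rules", {
  toy <- tibble::tibble(stimulus = "R", response = "R",
                        rt = c(0.4, 0.5, 0.6), timed_out = FALSE)
  m <- compute_ez_moments(toy)
  expect_equal(m$pc, 1 - 1 / (2 * 3))
  expect_equal(m$mrt, 0.5)
  expect_equal(m$vrt, 0.01)
  # perfect accuracy at n = 100 corrects to 0.995
  big <- tibble::tibble(stimulus = "R", response = "R",
                        rt = runif(100, 0.3, 1), timed_out = FALSE)
  expect_equal(compute_ez_moments(big)$pc, 1 - 1 / 200)
  # trial order is irrelevant
  p <- diffusion_params(v = 1, a = 1.5, ter = 0.3)
  tr <- sim_trials_diffusion(p, 300, seed = 5)
  m1 <- compute_ez_moments(tr)
  m2 <- compute_ez_moments(tr[sample(nrow(tr)), ])
  expect_equal(m1[c("pc", "mrt", "vrt")], m2[c("pc", "mrt", "vrt")])
  expect_equal(dplyr::arrange(m1$by_side, stimulus),
               dplyr::arrange(m2$by_side, stimulus))
})

test_that("outlier rule drops fast guesses and censored trials", {
  tr <- tibble::tibble(stimulus = "R", response = c("R", "R", "L", "R"),
                       rt = c(0.1, 0.5, 0.6, 3), timed_out = c(FALSE, FALSE,
                                                               FALSE, TRUE))
  kept <- exclude_outliers(tr)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "n_excluded"), 2)
})

test_that("ez closed-form inversion is an exact round trip with the
           forward equations", {
  for (pars in list(c(1, 2, 0.3), c(2, 1, 0.3), c(0.8, 1.7, 0.45))) {
    fm <- ez_forward_moments(v = pars[1], a = pars[2], ter = pars[3])
    est <- ez_point_estimates(fm)
    expect_equal(c(est$v, est$a, est$ter), pars, tolerance = 1e-8)
  }
  # and the forward equations agree with quadrature over the density
  p <- diffusion_params(v = 1.3, a = 1.4, ter = 0)
  fm <- ez_forward_moments(v = 1.3, a = 1.4)
  pu <- integrate_density(wiener_fpt_density, 0, Inf, p = p,
                          boundary = "upper")
  m1 <- integrate_density(function(t) t * wiener_fpt_density(t, p, "upper"),
                          0, Inf)
  m2 <- integrate_density(function(t) t^2 * wiener_fpt_density(t, p, "upper"),
                          0, Inf)
  expect_equal(fm$pc, pu, tolerance = 1e-7)
  expect_equal(fm$mrt, m1 / pu, tolerance = 1e-7)
  expect_equal(fm$vrt, m2 / pu - (m1 / pu)^2, tolerance = 1e-7)
})

test_that("ez estimates recover simulated parameters at large n", {
  p <- diffusion_params(v = 1.5, a = 1.5, ter = 0.3)
  tr <- sim_trials_diffusion(p, 5e4, seed = 31)
  est <- ez_point_estimates(compute_ez_moments(tr, min_rt = 0))
  # Monte-Carlo error at n = 1e5 is small; allow a generous multiple
  expect_equal(est$v, 1.5, tolerance = 0.03)
  expect_equal(est$a, 1.5, tolerance = 0.03)
  expect_equal(est$ter, 0.3, tolerance = 0.01)
})

test_that("ez2 reduces to symmetry and inverts biased forward moments", {
  sym <- ez2_point_estimates(ez2_oracle_moments(1.5, 1.5, 0.5, 0.3))
  expect_lt(abs(sym$zr - 0.5), 1e-6)
  for (pars in list(c(1, 2, 0.55, 0.3), c(1.2, 1.5, 0.6, 0.25))) {
    est <- ez2_point_estimates(ez2_oracle_moments(pars[1], pars[2], pars[3],
                                                  pars[4]))
    expect_true(est$converged)
    expect_equal(c(est$v, est$a, est$zr, est$ter), pars, tolerance = 1e-4)
  }
  expect_error(ez2_point_estimates(
    structure(list(by_side = tibble::tibble(stimulus = "R")),
              class = "ez_moments")), "both")
})

test_that("ez2 recovers a biased starting point from simulated data", {
  p <- diffusion_params(v = 1.2, a = 1.5, zr = 0.6, ter = 0.3)
  tr <- sim_trials_diffusion(p, 2e4, seed = 13)
  est <- ez2_point_estimates(compute_ez_moments(tr, min_rt = 0))
  expect_equal(est$zr, 0.6, tolerance = 0.02)
  expect_equal(est$v, 1.2, tolerance = 0.1)
  expect_equal(est$a, 1.5, tolerance = 0.05)
})

test_that("ml diffusion fit recovers parameters and prefers the truth", {
  p <- diffusion_params(v = 1.5, a = 1.5, zr = 0.55, ter = 0.3)
  errs <- purrr::map(1:8, function(r) {
    tr <- sim_trials_diffusion(p, 500, seed = 100 + 7 * r)
    f <- fit_ml_simple_diffusion(tr, config = fit_config(n_starts = 2))
    abs(c(f$params$v, f$params$a, f$params$ter) - c(1.5, 1.5, 0.3)) /
      c(1.5, 1.5, 0.3)
  })
  med <- apply(do.call(rbind, errs), 2, median)
  expect_true(all(med < 0.10))
  # likelihood at the truth beats a v-doubled alternative on fresh data;
  # stimulus-R trials only, so the drift sign is fixed
  tr <- sim_trials_diffusion(p, 2000, seed = 900)
  trR <- tr[tr$stimulus == "R" & !tr$timed_out, ]
  llR <- function(q) sum(log(pmax(ifelse(
    trR$response == "R",
    wiener_fpt_density(trR$rt, q, "upper"),
    wiener_fpt_density(trR$rt, q, "lower")), 1e-12)))
  expect_gt(llR(p), llR(diffusion_params(v = 3, a = 1.5, zr = 0.55,
                                         ter = 0.3)))
})

test_that("ml estimators are consistent: error shrinks with sample size", {
  p <- diffusion_params(v = 1.2, a = 1.4, zr = 0.5, ter = 0.3)
  med_err <- vapply(c(250, 1000, 4000), function(n) {
    errs <- vapply(1:10, function(r) {
      tr <- sim_trials_diffusion(p, ceiling(n / 2), seed = 2000 + 13 * r + n)
      f <- fit_ml_simple_diffusion(tr, config = fit_config(n_starts = 1))
      mean(abs(c(f$params$v / 1.2, f$params$a / 1.4, f$params$ter / 0.3) - 1))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(med_err[1] > med_err[2])
  expect_true(med_err[2] > med_err[3])
})

test_that("ml lba fit recovers parameters with the scaling constraint", {
  # truth with a start-point range large relative to threshold, where all
  # five parameters (including the weakly identified A) are recoverable
  truth <- c(1.5, 1.0, 2.5, 1.0, 0.25)
  p <- lba_params(b = truth[1], A = truth[2], v_c = truth[3],
                  v_e = truth[4], sdrift = 1, t0 = truth[5])
  cfg <- fit_config(n_starts = 5, jitter_sd = 0.3, estimate_bias = FALSE)
  errs <- purrr::map(1:10, function(r) {
    tr <- sim_trials_lba(p, 500, seed = 40 + 13 * r)
    f <- fit_ml_lba(tr, config = cfg)
    abs(c(f$params$b, f$params$A, f$params$v_c, f$params$v_e, f$params$t0) -
          truth) / truth
  })
  med <- apply(do.call(rbind, errs), 2, median)
  expect_true(all(med < 0.15))
  # likelihood at the truth beats drift-swapped parameters
  tr <- sim_trials_lba(p, 1000, seed = 77)
  nllish <- function(q) {
    d <- exclude_outliers(tr)
    dens <- ifelse(d$response == d$stimulus,
                   lba_defective_density(d$rt, q, "match", stim = "R"),
                   lba_defective_density(d$rt, q, "mismatch", stim = "R"))
    sum(log(pmax(dens, 1e-12)))
  }
  swapped <- lba_params(b = truth[1], A = truth[2], v_c = truth[4],
                        v_e = truth[3], sdrift = 1, t0 = truth[5])
  expect_gt(nllish(p), nllish(swapped))
})

test_that("fits are deterministic and invariant to trial order and
           relabeling", {
  p <- diffusion_params(v = 1.3, a = 1.3, ter = 0.3)
  tr <- sim_trials_diffusion(p, 250, seed = 55)
  tr$participant <- 1L
  f1 <- fit_participants(tr, "ez2")
  f2 <- fit_participants(tr[sample(nrow(tr)), ], "ez2")
  expect_equal(f1, f2)
  f3 <- fit_participants(tr, "ml_diffusion",
                         config = fit_config(n_starts = 2))
  f4 <- fit_participants(tr, "ml_diffusion",
                         config = fit_config(n_starts = 2))
  expect_identical(f3, f4)
  # relabeling flips stimulus and response together: for an unbiased
  # process the EZ moments are unchanged
  tr_even <- dplyr::mutate(tr, bias = "none", trial = dplyr::row_number())
  rel <- relabel_trials(tr_even)
  m1 <- compute_ez_moments(tr_even)
  m2 <- compute_ez_moments(rel)
  expect_equal(m1$pc, m2$pc)
  expect_equal(m1$mrt, m2$mrt)
  expect_equal(m1$vrt, m2$vrt)
})
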