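# Shared helpers: simulation-vs-density comparisons and small trial-table
# builders. Everything is generated in code at test time.

# KS distance between simulated RTs (censored at the deadline) and the
# deadline-truncated model CDF for the same boundary/accumulator
ks_distance <- function(rts, cdf_fun, total_mass) {
  rts <- sort(rts)
  u <- seq(0.005, 0.995, by = 0.005)
  qs <- stats::quantile(rts, u, type = 8)
  th <- vapply(qs, function(q) cdf_fun(q) / total_mass, numeric(1))
  max(abs(th - u))
}

integrate_density <- function(f, lower, upper, ...) {
  stats::integrate(f, lower, upper, ..., rel.tol = 1e-10,
                   subdivisions = 500L)$value
}

# two-sided trial table from the diffusion model: n_R/n_L trials per stimulus
sim_trials_diffusion <- function(p, n_R, n_L = n_R, seed = 1, deadline = 3,
                                 dt = 5e-4) {
  dplyr::bind_rows(
    dplyr::mutate(simulate_diffusion(p, "R", n_R, deadline = deadline,
                                     seed = seed, dt = dt), stimulus = "R"),
    dplyr::mutate(simulate_diffusion(p, "L", n_L, deadline = deadline,
                                     seed = seed + 17, dt = dt),
                  stimulus = "L"))
}

sim_trials_lba <- function(p, n_R, n_L = n_R, seed = 1, deadline = 3) {
  dplyr::bind_rows(
    dplyr::mutate(simulate_lba(p, "R", n_R, deadline = deadline, seed = seed),
                  stimulus = "R"),
    dplyr::mutate(simulate_lba(p, "L", n_L, deadline = deadline,
                               seed = seed + 17), stimulus = "L"))
}

# forward EZ2 moments wrapped as an ez_moments object (population oracle)
ez2_oracle_moments <- function(v, a, zr, ter, s = 1) {
  pm <- rtvalidity:::ez2_predicted_moments(v, a, zr, ter, s = s)
  structure(list(
    pc = NA_real_, mrt = NA_real_, vrt = NA_real_,
    by_side = tibble::tibble(
      stimulus = c("L", "R"), n = 1e6,
      pc = c(pm$L[["pc"]], pm$R[["pc"]]),
      mrt_all = c(pm$L[["m"]], pm$R[["m"]]),
      vrt_all = c(pm$L[["v"]], pm$R[["v"]]))),
    class = "ez_moments")
}
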