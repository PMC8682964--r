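test_that("compiled and reference right-hand sides agree along a
          trajectory", {
  p <- iom_parameters()
  trC <- simulate_iom(p, t_span = 0.1, init = iom_initial_state(),
                      out_dt = 500, engine = "compiled",
                      rtol = 1e-10, atol = 1e-12)
  trR <- simulate_iom(p, t_span = 0.1, init = iom_initial_state(),
                      out_dt = 500, engine = "R",
                      rtol = 1e-10, atol = 1e-12)
  for (sn in iom_state_names())
    expect_equal(trC[[sn]], trR[[sn]], tolerance = 1e-5)
})

test_that("finite differences of a short trajectory match the assembled rhs", {
  p <- iom_parameters()
  tr <- simulate_iom(p, t_span = 0.2, init = iom_initial_state(),
                     out_dt = 5, rtol = 1e-10, atol = 1e-12)
  ## central-difference oracle at interior points, on the slow variables
  i <- seq(10, nrow(tr) - 10, by = 40)
  dt_ms <- 10
  for (k in i[1:8]) {
    st <- unlist(tr[k, iom_state_names()])
    d <- iom_rhs_r(0, st, p)[[1]]
    for (sn in c("adpc", "f6p", "nadhm", "psim")) {
      fd <- (tr[[sn]][k + 1] - tr[[sn]][k - 1]) / dt_ms
      expect_equal(fd, unname(d[sn]), tolerance = 2e-2,
                   label = sprintf("d%s/dt at row %d", sn, k))
    }
  }
})

test_that("simulation is deterministic and equilibration is reproducible", {
  p <- iom_parameters()
  s1 <- equilibrate_iom(p, t_equil = 2)
  s2 <- equilibrate_iom(p, t_equil = 2)
  expect_identical(s1, s2)
  tr1 <- sim_short(p, t_span = 3)
  tr2 <- sim_short(p, t_span = 3)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
})

test_that("conserved totals hold to 1e-6 relative tolerance along runs", {
  tr <- sim_short(iom_parameters(), t_span = 10)
  p <- attr(tr, "params")
  expect_true(all(abs((tr$nadhm + tr$nadm) / p$nadtot - 1) < 1e-6))
  expect_true(all(abs((tr$adpm + tr$atpm) / p$amtot - 1) < 1e-6))
  expect_true(all(abs((tr$adpc + tr$atpc) / p$actot - 1) < 1e-6))
})

test_that("with all transport zeroed total calcium is conserved", {
  p <- iom_parameters(alpha = 0, kpmca = 0, khydca = 0,
                      p21 = 0, p22 = 0, p23 = 0)
  ## only ER exchange remains: cytosol + volume-weighted ER is invariant
  tr <- simulate_iom(p, t_span = 2, init = iom_initial_state(),
                     out_dt = 500, rtol = 1e-10, atol = 1e-12)
  tot <- tr$cac / p$fca + tr$caer / (p$fer * p$sigmaer)
  expect_lt(diff(range(tot)) / tot[1], 1e-6)
})

test_that("trajectories round-trip through the CSV + JSON interface", {
  tr <- sim_short(iom_parameters(vpdh = 0.4), t_span = 2)
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_trajectory(path)
  expect_equal(back$v, tr$v, tolerance = 1e-9)
  expect_equal(back$fbp, tr$fbp, tolerance = 1e-9)
  expect_equal(attr(back, "params")$vpdh, 0.4)
  header <- readLines(path, n = 1)
  expect_match(header, "t_min")
  expect_match(header, "Ca_c_uM")
  expect_match(header, "psi_m_mV")
  unlink(c(path, paste0(path, ".json")))
})

test_that("state invariants hold at every sample of a bursting run", {
  tr <- sim_short(iom_parameters(), t_span = 10)
  p <- attr(tr, "params")
  expect_true(all(tr$n >= 0 & tr$n <= 1))
  expect_true(all(tr$cac > 0 & tr$caer > 0 & tr$cam > 0))
  expect_true(all(tr$fbp >= 0 & tr$f6p >= 0))
  expect_true(all(tr$nadhm >= 0 & tr$nadhm <= p$nadtot))
  expect_true(all(tr$oinf > 0 & tr$oinf <= 1))
  expect_true(all(is.finite(tr$v)))
})

test_that("invalid configuration and state are rejected", {
  expect_error(iom_parameters(gca = -5), "> 0")
  expect_error(iom_parameters(nonsense = 1), "unknown parameter")
  expect_error(simulate_iom(iom_parameters(), t_span = -1), "t_span")
  expect_error(simulate_iom(iom_parameters(), t_span = 1,
                            init = c(v = -60)), "iom_state_names")
})
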