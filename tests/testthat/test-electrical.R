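test_that("K(ATP) open fraction has the analytic limits and monotonicities", {
  ## zero nucleotides: numerator 0.08 over denominator 1
  expect_equal(katp_open_fraction(0, 0), 0.08)
  ## bounded in (0, 1] over a wide nucleotide grid
  grid <- expand.grid(atp = c(0, 10, 100, 1000, 2400),
                      adp = c(0, 10, 100, 1000, 2400))
  o <- katp_open_fraction(grid$atp, grid$adp)
  expect_true(all(o > 0 & o <= 1))
  ## strictly decreasing in ATP at fixed ADP
  atp <- seq(10, 2000, by = 10)
  expect_true(all(diff(katp_open_fraction(atp, 500)) < 0))
  ## raising the ATP dissociation constant (diazoxide) opens channels,
  ## for every nucleotide combination on the grid
  o1 <- katp_open_fraction(grid$atp, grid$adp, ktt = 1)
  o2 <- katp_open_fraction(grid$atp, grid$adp, ktt = 2)
  pos <- grid$atp > 0
  expect_true(all(o2[pos] > o1[pos]))
  ## the channel-regulating species are fixed fractions of the totals
  nuc <- katp_nucleotides(2000, 1000)
  expect_equal(nuc$mgadp, 165)
  expect_equal(nuc$adp3, 135)
  expect_equal(nuc$atp4, 100)
  expect_error(katp_open_fraction(-1, 0), "must be >= 0")
  expect_error(katp_open_fraction(10, 10, ktt = 0), "must be > 0")
})

test_that("each membrane current reverses at its reversal potential", {
  p <- iom_parameters()
  cur <- membrane_currents(p$vca, 0.3, 0.2, 1500, 800, p)
  expect_equal(cur$ica, 0)
  cur <- membrane_currents(p$vk, 0.3, 0.2, 1500, 800, p)
  expect_equal(cur$ik, 0)
  expect_equal(cur$ikca, 0)
  expect_equal(cur$ikatp, 0)
  ## sign flips across the reversal potential
  below <- membrane_currents(p$vk - 5, 0.3, 0.2, 1500, 800, p)
  above <- membrane_currents(p$vk + 5, 0.3, 0.2, 1500, 800, p)
  for (nm in c("ik", "ikca", "ikatp")) {
    expect_lt(below[[nm]], 0)
    expect_gt(above[[nm]], 0)
  }
  ## K(Ca) activation vanishes with Ca and scales linearly in conductance
  expect_equal(membrane_currents(-50, 0.3, 1e-9, 1500, 800, p)$ikca, 0,
               tolerance = 1e-6)
  p600 <- iom_parameters(gkca = 600)
  expect_equal(membrane_currents(-50, 0.3, 0.2, 1500, 800, p600)$ikca,
               4 * membrane_currents(-50, 0.3, 0.2, 1500, 800,
                                     iom_parameters(gkca = 150))$ikca)
})

test_that("membrane rhs is the current balance and n relaxes to n_inf", {
  p <- iom_parameters()
  cur <- membrane_currents(-55, 0.2, 0.15, 1500, 800, p)
  mem <- membrane_rhs(-55, 0.2, cur, p)
  ## oracle: recompute dV/dt independently from the current set
  expect_equal(mem$dv,
               -(cur$ica + cur$ik + cur$ikca + cur$ikatp) / p$cm)
  zero <- list(ica = 0, ik = 0, ikca = 0, ikatp = 0)
  expect_equal(membrane_rhs(-55, 0.2, zero, p)$dv, 0)
  ## at n = n_inf(V) the gate is stationary
  expect_equal(membrane_rhs(-40, n_inf(-40, p), cur, p)$dn, 0)
  expect_error(membrane_rhs(-55, 0.2, cur, iom_parameters(cm = 5300) |>
                              (\(x) { x$cm <- -1; x })()),
               "cm")
})

test_that("closed calcium compartments conserve and ER relaxes to cytosol", {
  p <- iom_parameters(alpha = 0, kpmca = 0, kserca = 0, pleak = 0)
  d <- calcium_compartment_rhs(0.2, 150, -500, 0, 0, p)
  expect_equal(d$dcac, 0)
  expect_equal(d$dcaer, 0)
  ## with only the leak active the ER monotonically approaches Ca_c
  ## (oracle: integrate the reduced two-variable system)
  p2 <- iom_parameters(alpha = 0, kpmca = 0, kserca = 0, pleak = 2e-4)
  f <- function(t, y, parms) {
    d <- calcium_compartment_rhs(y[1], y[2], 0, 0, 0, p2)
    list(c(d$dcac, d$dcaer))
  }
  out <- deSolve::ode(c(0.2, 150), seq(0, 5e5, 1000), f, NULL)
  expect_true(all(diff(out[, 3]) < 0))
  expect_lt(out[nrow(out), 3] - out[nrow(out), 2], 150)
})
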