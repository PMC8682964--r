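test_that("glucokinase flux is a saturating, monotone function of glucose", {
  p <- iom_parameters()
  expect_equal(gk_flux(0, p), 0)
  g <- seq(0, 30, by = 0.5)
  j <- gk_flux(g, p)
  expect_true(all(diff(j) > 0))
  expect_true(all(j < p$vgk))
  expect_gt(gk_flux(11, p), gk_flux(5, p))
  expect_error(gk_flux(-1, p), ">= 0")
})

test_that("PFK rate has the allosteric regulation signs", {
  p <- iom_parameters()
  expect_equal(pfk_flux(0, 1, 1500, amp = 300, params = p), 0)
  ## product activation: increasing in FBP over a positive grid
  fbp <- seq(0.01, 5, length.out = 60)
  j <- pfk_flux(200, fbp, 1500, amp = 300, params = p)
  expect_true(all(diff(j) > 0))
  ## ATP is an allosteric inhibitor
  atp <- seq(200, 2400, length.out = 60)
  j <- vapply(atp, function(a) pfk_flux(200, 1, a, amp = 300, params = p),
              numeric(1))
  expect_true(all(diff(j) < 0))
  ## AMP activates
  amp <- seq(1, 2000, length.out = 60)
  j <- vapply(amp, function(a) pfk_flux(200, 1, 1500, amp = a, params = p),
              numeric(1))
  expect_true(all(diff(j) > 0))
  ## increasing in substrate from zero
  f6p <- seq(0, 800, length.out = 60)
  j <- pfk_flux(f6p, 1, 1500, amp = 300, params = p)
  expect_true(all(diff(j) > 0))
  ## adenylate-kinase closure: amp = adp^2/atp
  expect_equal(pfk_flux(200, 1, 1600, adp = 800, params = p),
               pfk_flux(200, 1, 1600, amp = 800^2 / 1600, params = p))
  expect_error(pfk_flux(200, 1, 0, adp = 800, params = p), "atp > 0")
})

test_that("GPDH flux has the printed limit cases", {
  expect_equal(gpdh_flux(0.5, 0, kgpdh = 3), 0)
  ## half-saturation: Ca_m^2 = K_GPDH gives FBP/2
  expect_equal(gpdh_flux(sqrt(3), 10, kgpdh = 3), 5)
  ## saturation in Ca_m approaches FBP
  expect_equal(gpdh_flux(1e5, 10, kgpdh = 3), 10, tolerance = 1e-8)
  ## linear in FBP
  expect_equal(gpdh_flux(0.3, 8, kgpdh = 3), 4 * gpdh_flux(0.3, 2, kgpdh = 3))
  expect_error(gpdh_flux(0.3, 1, kgpdh = 0), "> 0")
})

test_that("glycolytic derivatives are the stated flux balances", {
  p <- iom_parameters()
  d <- glycolysis_rhs(jgk = 0.006, jpfk = 0.006, jgpdh = 0.012, p)
  expect_equal(d$df6p, 0)
  expect_equal(d$dfbp, 0)
  d <- glycolysis_rhs(jgk = 0.01, jpfk = 0.004, jgpdh = 0.002, p)
  expect_equal(d$df6p, p$kappa * 0.006)
  expect_equal(d$dfbp, 0.004 - 0.001)
})

test_that("without FBP product activation the glycolytic subsystem admits no
          limit cycle", {
  ## neutralize product activation: FBP/ATP interaction neutral and the
  ## fully-activated state no faster than the rest
  p <- iom_parameters(lampfk = 1, f23 = 1, f42 = 1)
  gly <- function(t, y, parms) {
    jpfk <- pfk_flux(max(y[1], 0), max(y[2], 0), 1500, amp = 300, params = p)
    d <- glycolysis_rhs(gk_flux(11, p), jpfk,
                        gpdh_flux(0.25, max(y[2], 0), p$kgpdh), p)
    list(c(d$df6p, d$dfbp))
  }
  for (y0 in list(c(50, 0.05), c(300, 2), c(1000, 20))) {
    out <- deSolve::ode(y0, seq(0, 2.4e6, 12000), gly, NULL,
                        rtol = 1e-8, atol = 1e-10)
    tail_fbp <- out[out[, 1] > 1.8e6, 3]
    expect_lt(diff(range(tail_fbp)), 0.02 * max(mean(tail_fbp), 0.01))
  }
})
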