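test_that("PDH flux follows the printed form", {
  expect_equal(pdh_flux(500, 500, 0, vpdh = 2), 0)
  ## zero NADH: ratio term vanishes, rate = vpdh * jgpdh / K
  expect_equal(pdh_flux(0, 500, 0.01, vpdh = 2, knadhpdh = 0.05),
               2 * 0.01 / 0.05)
  ## linear in vpdh
  expect_equal(pdh_flux(300, 700, 0.01, vpdh = 4, knadhpdh = 0.05),
               2 * pdh_flux(300, 700, 0.01, vpdh = 2, knadhpdh = 0.05))
  ## strictly decreasing in the redox ratio
  nadh <- seq(10, 900, by = 10)
  j <- pdh_flux(nadh, 1000 - nadh, 0.01)
  expect_true(all(diff(j) < 0))
  expect_error(pdh_flux(10, 0, 0.01), "> 0")
})

test_that("uniporter flux is linear with the stated zero crossing", {
  expect_equal(uniporter_flux(0, 160), 0)
  p21 <- 0.013; p22 <- 1.65
  ## zero at psi_m = p22/p21 for any Ca
  expect_equal(uniporter_flux(0.7, p22 / p21, p21, p22), 0)
  ## linear in Ca_c
  expect_equal(uniporter_flux(0.4, 160, p21, p22),
               2 * uniporter_flux(0.2, 160, p21, p22))
  ## raising p21 from 0.013 to 0.03 increases influx above the reversal
  expect_gt(uniporter_flux(0.2, 160, 0.03, p22),
            uniporter_flux(0.2, 160, 0.013, p22))
})

test_that("assembled mitochondrial fluxes have the stated dependences", {
  p <- iom_parameters()
  mf0 <- mito_fluxes(0, 8000, 0.2, 155, 0.15, 0.01, 800, p)
  expect_equal(mf0$jo, 0)          # no substrate, no respiration
  expect_equal(mf0$jhres, 0)
  mf <- mito_fluxes(400, 8000, 0.2, 155, 0.15, 0.01, 800, p)
  expect_equal(mf$jhres, p$kres * mf$jo)
  expect_equal(mf$jhatp, 3 * mf$jf1f0)
  ## ATP synthase: no ADP, no synthesis; increasing in psi_m
  expect_equal(mito_fluxes(400, 0, 0.2, 155, 0.15, 0.01, 800, p)$jf1f0, 0)
  psis <- seq(120, 180, by = 2)
  jf <- vapply(psis, function(ps)
    mito_fluxes(400, 8000, 0.2, ps, 0.15, 0.01, 800, p)$jf1f0, numeric(1))
  expect_true(all(diff(jf) > 0))
  ## NaCa: increasing in Ca_m, decreasing in Ca_c
  j1 <- mito_fluxes(400, 8000, 0.1, 155, 0.15, 0.01, 800, p)$jnaca
  j2 <- mito_fluxes(400, 8000, 0.3, 155, 0.15, 0.01, 800, p)$jnaca
  expect_gt(j2, j1)
  j3 <- mito_fluxes(400, 8000, 0.2, 155, 0.3, 0.01, 800, p)$jnaca
  j4 <- mito_fluxes(400, 8000, 0.2, 155, 0.1, 0.01, 800, p)$jnaca
  expect_lt(j3, j4)
})

test_that("mitochondrial derivatives implement the charge and mass balances", {
  p <- iom_parameters()
  zero <- as.list(setNames(rep(0, 9), c("jpdh", "jo", "jhres", "jf1f0",
                                        "jhatp", "jant", "jhleak", "juni",
                                        "jnaca")))
  d <- mito_rhs(zero, p)
  expect_true(all(unlist(d) == 0))
  f <- list(jpdh = 0.02, jo = 0.01, jhres = 1.7, jf1f0 = 0.012,
            jhatp = 0.036, jant = 0.011, jhleak = 1.5, juni = 0.03,
            jnaca = 0.02)
  d <- mito_rhs(f, p)
  expect_equal(d$dnadhm, p$gamma * (0.02 - 0.01))
  expect_equal(d$dadpm, p$gamma * (0.011 - 0.012))
  expect_equal(d$dcam, p$fm * (0.03 - 0.02))
  ## the uniporter carries two charges
  expect_equal(d$dpsim,
               (1.7 - 0.036 - 0.011 - 1.5 - 0.02 - 2 * 0.03) / p$cmito)
})

test_that("hydrolysis rises with clamped Ca and lowers steady-state ATP", {
  p <- iom_parameters()
  expect_equal(hydrolysis_flux(0.3, 0, p), 0)
  ## isolated nucleotide balance: dADPc/dt = 0 defines ATP*(Ca); oracle by
  ## root finding on the one-variable balance at fixed J_ANT
  atp_star <- function(cac) {
    f <- function(adpc) nucleotide_rhs(adpc, cac, jant = 0.008, p)
    p$actot - stats::uniroot(f, c(1, p$actot - 1))$root
  }
  expect_gt(atp_star(0.05), atp_star(0.4))
})
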