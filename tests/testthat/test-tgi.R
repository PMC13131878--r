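p_table1 <- tgi_params(lambda0 = 0.0063, lambda1 = 5.93, kill = 2.4e-5,
                       tv0 = 100)

test_that("growth rate has the exponential and linear limits", {
  p <- p_table1
  # far below the switch volume the correction term is (tv lambda0/lambda1)^20
  tv_small <- 0.01 * p$lambda1 / p$lambda0
  expect_equal(tgi_growth_rate(tv_small, 0, p), p$lambda0 * tv_small,
               tolerance = 1e-12)
  # exactly at the switch: bracket = (1 + 1)^(1/20)
  tv_sw <- p$lambda1 / p$lambda0
  expect_equal(tgi_growth_rate(tv_sw, 0, p),
               p$lambda0 * tv_sw / 2^(1 / 20), tolerance = 1e-12)
  # switch volume ~941 mm3 for the default truth; far above it the rate
  # plateaus at lambda1 = 5.93 mm3/h
  expect_equal(tv_sw, 941.27, tolerance = 1e-4)
  expect_equal(tgi_growth_rate(20000, 0, p), 5.93, tolerance = 1e-3)
  expect_error(tgi_growth_rate(-5, 0, p), "positive")
})

test_that("natural growth laws have their documented forms and limits", {
  p <- p_table1
  expect_equal(natural_growth_rate(100, p = p, model = "exponential"), 0.63)
  # Koch: ~2 lambda0 tv at small volumes, plateau lambda1 at large
  expect_equal(natural_growth_rate(1e-4, p = p, model = "koch"),
               2 * p$lambda0 * 1e-4, tolerance = 1e-6)
  expect_equal(natural_growth_rate(1e9, p = p, model = "koch"),
               p$lambda1, tolerance = 1e-5)
  # simeoni with no drug equals the full model at kill = 0
  p0 <- tgi_params(p$lambda0, p$lambda1, kill = 0, tv0 = 100)
  for (tv in c(1, 500, 941, 5000))
    expect_equal(natural_growth_rate(tv, p = p0, model = "simeoni"),
                 tgi_growth_rate(tv, 0, p0))
  # quadratic growth law integrates to TV0 (1 + lambda0 t)^2
  pq <- tgi_params(lambda0 = 0.002, lambda1 = 1, tv0 = 50)
  tr <- simulate_tumor(pq, pk_params(), regimen_preset("vehicle"),
                       seq(0, 480, 24), model = "quadratic")
  expect_equal(tr$tv_mm3, 50 * (1 + 0.002 * tr$time_h)^2, tolerance = 1e-6)
  expect_error(natural_growth_rate(100, p = p, model = "gompertz"), "unknown")
})

test_that("trajectories reproduce the no-drug closed forms", {
  pk <- pk_params()
  veh <- regimen_preset("vehicle")
  # exponential phase
  pe <- tgi_params(0.0063, 5.93, tv0 = 10)
  tr <- simulate_tumor(pe, pk, veh, seq(0, 480, 24))
  expect_equal(tr$tv_mm3, 10 * exp(0.0063 * tr$time_h), tolerance = 5e-3)
  # linear phase
  pl <- tgi_params(0.0063, 5.93, tv0 = 5000)
  tr <- simulate_tumor(pl, pk, veh, seq(0, 480, 24))
  expect_equal(tr$tv_mm3, 5000 + 5.93 * tr$time_h, tolerance = 5e-3)
})

test_that("forward solver agrees with quadrature and lsoda references", {
  pk <- pk_params()
  veh <- regimen_preset("vehicle")
  p <- tgi_params(0.0063, 5.93, tv0 = 300)  # crosses the switch region
  tr <- simulate_tumor(p, pk, veh, seq(0, 720, 24))
  # independent separable-ODE check: time to reach TV(t) by quadrature
  for (i in c(10, 20, 31)) {
    t_quad <- time_to_volume_quadrature(300, tr$tv_mm3[i], 0.0063, 5.93)
    expect_equal(t_quad, tr$time_h[i], tolerance = 1e-3)
  }
  skip_if_not_installed("deSolve")
  pd <- tgi_params(0.0063, 5.93, kill = 2.4e-5, tv0 = 100)
  reg <- regimen_preset("2.85 BIWx6")
  a <- simulate_tumor(pd, pk, reg, seq(0, 2400, 24))
  b <- simulate_tumor(pd, pk, reg, seq(0, 2400, 24), engine = "lsoda")
  expect_equal(a$tv_mm3, b$tv_mm3, tolerance = 1e-3)
})

test_that("volumes stay positive and decrease under dominant kill", {
  pk <- pk_params()
  reg <- regimen_preset("0.9 Q1dx5")  # daily dosing: exposure never troughs out
  p <- tgi_params(0.0063, 5.93, kill = 5e-4, tv0 = 200)  # kill >> growth
  tr <- simulate_tumor(p, pk, reg, seq(0, 96, 6))
  expect_true(all(tr$tv_mm3 > 0))
  expect_true(all(diff(tr$tv_mm3) < 0))
})

test_that("tumor volume is monotone in kill rate and dose", {
  pk <- pk_params()
  reg <- regimen_preset("0.9 Q1dx5")
  times <- seq(0, 720, 24)
  kills <- c(0, 1e-5, 2.4e-5, 1e-4)
  prev <- NULL
  for (k in kills) {
    tr <- simulate_tumor(tgi_params(0.0063, 5.93, kill = k, tv0 = 150),
                         pk, reg, times)$tv_mm3
    if (!is.null(prev)) expect_true(all(tr <= prev + 1e-9))
    prev <- tr
  }
  doses <- c("0.3 Q1dx5", "0.6 Q1dx5", "0.9 Q1dx5")
  prev <- NULL
  for (d in doses) {
    tr <- simulate_tumor(tgi_params(0.0063, 5.93, kill = 2.4e-5, tv0 = 150),
                         pk, regimen_preset(d), times)$tv_mm3
    if (!is.null(prev)) expect_true(all(tr <= prev + 1e-9))
    prev <- tr
  }
})

test_that("threshold crossing follows the detection rule", {
  tr <- tibble::tibble(time_h = c(0, 24, 48, 72), tv_mm3 = c(100, 800, 1600, 2500))
  expect_equal(time_to_threshold(tr, 1500), 48)
  expect_equal(time_to_threshold(tr, 3000), NA_real_)
  expect_error(time_to_threshold(tr[0, ], 1500), "empty")
  # continuous rule: pure exponential from 100 crosses 1500 at ln(15)/lambda0
  pk <- pk_params()
  pe <- tgi_params(0.0063, 1e6, tv0 = 100)  # switch far away: pure exponential
  grid <- seq(0, 720, 24)
  tre <- simulate_tumor(pe, pk, regimen_preset("vehicle"), grid)
  t_true <- log(15) / 0.0063
  expect_equal(time_to_threshold(tre, 1500, rule = "continuous"), t_true,
               tolerance = 1e-3)
  # discrete rule returns the next scheduled measurement after the crossing
  expect_equal(time_to_threshold(tre, 1500), grid[which(grid >= t_true)[1]])
})
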