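# Point and clamped-sodium models: right-hand sides, stoichiometry,
# rest states, integration contract.

test_that("without NCX the nominal rest point is an exact fixed point", {
  p0 <- ncx_params(Jbar = 0)
  na <- 25
  st <- c(d_hp$Ca_rest, h_inf(d_hp$Ca_rest, na, p0))
  expect_equal(rhs_clamped(st, na, d_env, p0, d_hp), c(0, 0))
  st3 <- c(d_hp$Ca_rest, d_hp$Na_rest,
           h_inf(d_hp$Ca_rest, d_hp$Na_rest, p0))
  expect_equal(rhs_point(st3, c(0, 0), d_env, p0, d_hp), c(0, 0, 0))
  r <- find_rest_state(model_variant("point_full"), d_env, p0, d_hp)
  expect_equal(unname(r), st3, tolerance = 1e-9)
})

test_that("states on the calcium nullcline have zero calcium rate", {
  na <- 45
  ca <- 10^seq(-3.7, -2.8, length.out = 25)
  h_on <- (ca - d_hp$Ca_rest) /
    (d_hp$tau_Ca * d_p$Jbar * n_inf(ca, d_p) *
       j_delta_e(ca, na, d_env, d_p))
  keep <- h_on >= 0 & h_on <= 1
  expect_gt(sum(keep), 5)
  for (i in which(keep)) {
    d <- rhs_clamped(c(ca[i], h_on[i]), na, d_env, d_p, d_hp)
    expect_lt(abs(d[1]), 1e-10)
  }
})

test_that("point-model right-hand side equals the sum of its flux terms", {
  st <- draw_states(100, seed = 31)
  for (i in seq_len(20)) {
    y <- c(st$Ca[i], st$Na[i], st$h[i])
    stim <- c(2e-4, 0.5)
    got <- rhs_point(y, stim, d_env, d_p, d_hp)
    J <- d_p$Jbar * n_inf(y[1], d_p) * y[3] *
      oracle_jde(y[1], y[2], d_env, d_p)
    want <- c(J + stim[1] + (d_hp$Ca_rest - y[1]) / d_hp$tau_Ca,
              stim[2] - 3 * J + (d_hp$Na_rest - y[2]) / d_hp$tau_Na,
              (h_inf(y[1], y[2], d_p) - y[3]) / tau_h(y[1], d_p))
    expect_rel_equal(got, want, 1e-12)
  }
})

test_that("sodium carries exactly -3 times the NCX calcium flux", {
  st <- draw_states(200, seed = 37)
  for (i in seq_len(nrow(st))) {
    y <- c(st$Ca[i], st$Na[i], st$h[i])
    d <- rhs_point(y, c(0, 0), d_env, d_p, d_hp)
    ncx_ca <- d[1] - (d_hp$Ca_rest - y[1]) / d_hp$tau_Ca
    ncx_na <- d[2] - (d_hp$Na_rest - y[2]) / d_hp$tau_Na
    expect_lt(abs(ncx_na + 3 * ncx_ca), 1e-12)
  }
})

test_that("with NCX disabled both ions relax at their homeostatic rates", {
  p0 <- ncx_params(Jbar = 0)
  init <- c(Ca = 5 * d_hp$Ca_rest, Na = 2 * d_hp$Na_rest, h = 0.5)
  s <- integrate_model(model_variant("point_full"), empty_protocol(),
                       c(0, 12), d_env, p0, d_hp, init = init,
                       dt_out = 0.25)
  fit_rate <- function(dev) {
    keep <- s$t <= 8
    -coef(lm(log(dev[keep]) ~ s$t[keep]))[2]
  }
  expect_lt(abs(fit_rate(s$Ca - d_hp$Ca_rest) - 1 / d_hp$tau_Ca),
            0.01 / d_hp$tau_Ca)
  expect_lt(abs(fit_rate(s$Na - d_hp$Na_rest) - 1 / d_hp$tau_Na),
            0.01 / d_hp$tau_Na)
})

test_that("allosteric-off control matches the full model's flux at rest", {
  s <- allostery_off_scale(d_p, d_hp)
  jde <- j_delta_e(d_hp$Ca_rest, d_hp$Na_rest, d_env, d_p)
  full <- j_ncx(d_hp$Ca_rest, d_hp$Na_rest,
                h_inf(d_hp$Ca_rest, d_hp$Na_rest, d_p), d_env, d_p)
  expect_equal(s * d_p$Jbar * jde, full, tolerance = 1e-14)
  # and the variant's rhs uses exactly that scaled flux
  y <- c(2e-4, 30, 0.42)
  d <- rhs_no_allostery(y, c(0, 0), d_env, d_p, d_hp, scale = s)
  J <- s * d_p$Jbar * j_delta_e(y[1], y[2], d_env, d_p)
  expect_equal(d[1], J + (d_hp$Ca_rest - y[1]) / d_hp$tau_Ca,
               tolerance = 1e-14)
  expect_equal(d[3], 0)
})

test_that("unstimulated runs from rest stay at rest", {
  p0 <- ncx_params(Jbar = 0)
  s0 <- integrate_model(model_variant("point_full"), empty_protocol(),
                        c(0, 50), d_env, p0, d_hp)
  expect_lt(max(abs(s0$Ca - s0$Ca[1])), 1e-10)
  expect_lt(max(abs(s0$Na - s0$Na[1])), 1e-7)
  s1 <- integrate_model(model_variant("point_full"), empty_protocol(),
                        c(0, 50), d_env, d_p, d_hp)
  expect_lt(max(abs(s1$Ca - s1$Ca[1])) / s1$Ca[1], 1e-6)
})

test_that("clamped-ion gate relaxation in the integrator matches closed form", {
  # with the exchanger disabled and calcium started at rest, the clamped-Na
  # model reduces to the linear gate ODE with constant coefficients
  p0 <- ncx_params(Jbar = 0)
  na <- 20
  s <- integrate_model(model_variant("clamped_na"), empty_protocol(),
                       c(0, 40), d_env, p0, d_hp,
                       init = c(d_hp$Ca_rest, 0.9), Na_i = na,
                       dt_out = 0.5)
  hs <- h_inf(d_hp$Ca_rest, na, p0)
  th <- tau_h(d_hp$Ca_rest, p0)
  closed <- hs + (0.9 - hs) * exp(-s$t / th)
  expect_lt(max(abs(s$h - closed)), 1e-7)
  expect_lt(max(abs(s$Ca - d_hp$Ca_rest)), 1e-12)
})

test_that("halving solver tolerances barely moves the endpoint", {
  pr <- preset_fig2a()
  run <- function(rtol, atol)
    integrate_model(model_variant("point_full"), pr$joint, c(0, 120),
                    d_env, d_p, d_hp, dt_out = 1,
                    rtol = rtol, atol = atol)
  a <- run(1e-8, 1e-12)
  b <- run(5e-9, 5e-13)
  end_a <- unlist(a[nrow(a), c("Ca", "Na", "h")])
  end_b <- unlist(b[nrow(b), c("Ca", "Na", "h")])
  expect_lt(max(abs(end_a - end_b) / abs(end_b)), 1e-6)
})

test_that("trajectories on the shipped protocols stay positive and finite", {
  pr <- preset_fig2a()
  s <- integrate_model(model_variant("point_full"), pr$joint,
                       c(0, pr$t_end), d_env, d_p, d_hp, dt_out = 1)
  expect_true(all(is.finite(unlist(s[c("Ca", "Na", "h")]))))
  expect_true(all(s$Ca > 0 & s$Na > 0))
  expect_true(all(s$h >= -1e-9 & s$h <= 1 + 1e-9))
})

test_that("a calcium pulse at resting sodium is attenuated by forward-mode NCX", {
  pl <- stim_protocol(data.frame(species = "Ca", start = 20, duration = 5,
                                 amplitude = 2e-4))
  s <- integrate_model(model_variant("point_full"), pl, c(0, 80),
                       d_env, d_p, d_hp, dt_out = 0.25)
  win <- s$t >= 20 & s$t <= 60
  ncx_integral <- sum(s$J_ncx[win] * c(diff(s$t[win]), 0))
  expect_lt(ncx_integral, 0)   # net extrusion: transient reduced vs NCX-free
})
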