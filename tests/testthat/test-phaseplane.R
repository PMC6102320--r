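# Nullclines, equilibria, basins, and the sodium/potential bistability map
# of the clamped-sodium model.

test_that("h-nullcline is h = h_inf pointwise and flattens as Na -> 0", {
  ca <- 10^seq(-5, -2, length.out = 60)
  hn0 <- h_nullcline(ca, 0, d_p)
  expect_true(all(hn0$h == 1))
  hn1 <- h_nullcline(ca, 20, d_p)
  expect_equal(hn1$h, h_inf(ca, 20, d_p))
  for (i in seq(1, 60, by = 10))
    expect_equal(dh_dt(hn1$h[i], ca[i], 20, d_p), 0)
  hn2 <- h_nullcline(ca, 45, d_p)
  expect_true(all(hn2$h <= hn1$h))    # branch shifts down with Na
})

test_that("Ca-nullcline splits at the reversal point and self-validates", {
  na <- 20
  ca <- 10^seq(-5, -2, length.out = 300)
  cn <- ca_nullcline(ca, na, d_env, d_p, d_hp)
  disc <- attr(cn, "discontinuity")
  # closed-form reversal calcium, recomputed independently
  vfrt <- -0.08 * 96485.33212 / (8.314462618 * 310)
  expect_rel_equal(disc, 2 * (na / 140)^3 * exp(vfrt), 1e-10)
  expect_length(cn, 2)
  for (br in cn) {
    expect_true(all(br$Ca < disc) || all(br$Ca > disc))
    keep <- br$physical
    dCa <- d_p$Jbar * n_inf(br$Ca[keep], d_p) * br$h[keep] *
      j_delta_e(br$Ca[keep], na, d_env, d_p) +
      (d_hp$Ca_rest - br$Ca[keep]) / d_hp$tau_Ca
    if (any(keep)) expect_lt(max(abs(dCa)), 1e-8)
  }
  # h -> 0 as Ca -> Ca_rest on the nullcline
  i <- which.min(abs(ca - d_hp$Ca_rest))
  all_pts <- do.call(rbind, cn)
  expect_lt(abs(all_pts$h[which.min(abs(all_pts$Ca - d_hp$Ca_rest))]), 0.05)
})

test_that("exchanger-free system has the single nominal equilibrium", {
  p0 <- ncx_params(Jbar = 0)
  eq <- find_equilibria(30, d_env, p0, d_hp)
  expect_equal(nrow(eq), 1)
  expect_equal(eq$Ca, d_hp$Ca_rest)
  expect_equal(eq$h, h_inf(d_hp$Ca_rest, 30, p0))
  expect_equal(eq$stability, "stable")
})

test_that("sodium loading creates three equilibria: two stable, one saddle", {
  eq <- find_equilibria(45, d_env, d_p, d_hp)
  expect_equal(nrow(eq), 3)
  expect_equal(sum(eq$stability == "stable"), 2)
  expect_equal(sum(eq$stability == "saddle"), 1)
  # residuals vanish at every reported equilibrium
  for (i in seq_len(3)) {
    r <- rhs_clamped(c(eq$Ca[i], eq$h[i]), 45, d_env, d_p, d_hp)
    expect_lt(max(abs(r)), 1e-10)
  }
  # saddle sits between the stable states in calcium
  ord <- order(eq$Ca)
  expect_equal(eq$stability[ord], c("stable", "saddle", "stable"))
  # resting sodium remains monostable
  eq_low <- find_equilibria(17, d_env, d_p, d_hp)
  expect_equal(nrow(eq_low), 1)
  expect_equal(eq_low$stability, "stable")
})

test_that("equilibrium finder agrees with a fine-grid sign-change oracle", {
  set.seed(101)
  for (k in 1:20) {
    na <- runif(1, 10, 90)
    env <- cell_env(V_mV = runif(1, -95, -55))
    p <- ncx_params(Jbar = 10^runif(1, -2.2, -1.3))
    eq <- find_equilibria(na, env, p, d_hp)
    # oracle: dense scan of the nullcline difference, no refinement
    ca <- exp(seq(log(1e-6), log(0.05), length.out = 2000))
    disc <- reversal_ca(na, env)
    hca <- (ca - d_hp$Ca_rest) /
      (d_hp$tau_Ca * p$Jbar * n_inf(ca, p) * j_delta_e(ca, na, env, p))
    g <- hca - h_inf(ca, na, p)
    side <- ca > disc
    cross <- which(sign(g[-1]) * sign(g[-2000]) < 0 &
                     side[-1] == side[-2000] &
                     pmin(hca[-1], hca[-2000]) <= 1 &
                     pmax(hca[-1], hca[-2000]) >= 0)
    expect_equal(nrow(eq), length(cross))
    if (nrow(eq)) {
      eq <- eq[order(eq$Ca), , drop = FALSE]
      for (i in seq_len(nrow(eq)))
        expect_true(eq$Ca[i] >= ca[cross[i]] - 1e-6 &
                      eq$Ca[i] <= ca[cross[i] + 1] + 1e-6)
    }
  }
})

test_that("basin map labels stable states and brackets the saddle", {
  eq <- find_equilibria(45, d_env, d_p, d_hp)
  stable <- eq[eq$stability == "stable", ]
  bm <- basin_map(eq, 45, d_env, d_p, d_hp,
                  ca_lim = c(5e-5, 5e-3), n_ca = 14, n_h = 14,
                  horizon = 400)
  # cells seeded exactly at the stable equilibria resolve to themselves
  for (i in seq_len(2)) {
    bmi <- basin_map(eq, 45, d_env, d_p, d_hp,
                     ca_lim = c(stable$Ca[i], stable$Ca[i] * 1.0001),
                     h_lim = c(stable$h[i], stable$h[i]),
                     n_ca = 2, n_h = 2, horizon = 50)
    expect_true(all(bmi$basin == i))
  }
  # both basins are represented and most cells resolve
  expect_true(all(c(1, 2) %in% bm$basin))
  expect_lt(attr(bm, "unresolved") / nrow(bm), 0.2)
  # the saddle lies within one grid cell of the basin boundary
  saddle <- eq[eq$stability == "saddle", ]
  lab <- matrix(bm$basin, 14, 14)   # Ca varies along rows
  ca_grid <- sort(unique(bm$Ca0)); h_grid <- sort(unique(bm$h0))
  boundary <- NULL
  for (i in 1:13) for (j in 1:14) {
    a <- lab[i, j]; b <- lab[i + 1, j]
    if (!is.na(a) && !is.na(b) && a != b)
      boundary <- rbind(boundary,
                        c(sqrt(ca_grid[i] * ca_grid[i + 1]), h_grid[j]))
  }
  expect_gt(nrow(boundary), 0)
  d_log <- abs(log(boundary[, 1]) - log(saddle$Ca))
  cell_log <- diff(log(ca_grid))[1]
  expect_lt(min(d_log), 1.5 * cell_log)
  # monostable input is rejected
  eq1 <- find_equilibria(17, d_env, d_p, d_hp)
  expect_error(basin_map(eq1, 17, d_env, d_p, d_hp),
               "two stable")
})

test_that("bistability needs sufficient exchanger strength and grows with it", {
  Vr <- c(-90, -78); Nar <- c(35, 90)
  weak <- bifurcation_scan(Vr, Nar, n_V = 5, n_Na = 7,
                           p = ncx_params(Jbar = 1e-4), hp = d_hp)
  expect_true(all(!weak$bistable))
  expect_true(all(weak$n_eq == 1))
  mid <- bifurcation_scan(Vr, Nar, n_V = 5, n_Na = 7,
                          p = ncx_params(Jbar = 0.015), hp = d_hp)
  strong <- bifurcation_scan(Vr, Nar, n_V = 5, n_Na = 7,
                             p = ncx_params(Jbar = 0.02), hp = d_hp)
  expect_gt(sum(strong$bistable), 0)
  # set inclusion: every cell bistable at the weaker Jbar stays bistable
  expect_true(all(!mid$bistable | strong$bistable))
  expect_gte(sum(strong$bistable), sum(mid$bistable))
})

test_that("sodium compensates for polarization along the bistability boundary", {
  map <- bifurcation_scan(c(-92, -77), c(30, 95), n_V = 6, n_Na = 12,
                          p = d_p, hp = d_hp)
  # minimal bistable Na per potential, over rows where bistability occurs
  vs <- sort(unique(map$V_mV))
  min_na <- sapply(vs, function(v) {
    b <- map$Na_i[map$V_mV == v & map$bistable]
    if (length(b)) min(b) else NA_real_
  })
  found <- !is.na(min_na)
  expect_gt(sum(found), 2)
  # more depolarized potential (larger V) -> bistability at lower sodium
  expect_true(all(diff(min_na[found]) <= 0))
})
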