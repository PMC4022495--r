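published_design <- function() itc_design()   # 18 x 2 uL of 1.25 mM into 0.280 mL of 0.05 mM

test_that("zero enthalpy and zero offset give identically zero heats", {
  iso <- simulate_isotherm(published_design(), one_site_params(dh = 0))
  expect_true(all(abs(iso$heats_ucal) < 1e-12))
})

test_that("the stoichiometric (tight-binding) limit behaves like a step", {
  des <- published_design()
  iso <- simulate_isotherm(des, one_site_params(n = 1, k_d = 1e-15,
                                                dh = -10))
  q <- iso$heats_ucal
  # pre-equivalence heats are flat (each injection's ligand binds completely)
  pre <- q[1:4]
  expect_lt(stats::sd(pre) / abs(mean(pre)), 0.005)
  # post-saturation heats vanish
  expect_lt(max(abs(q[15:18])), 1e-6 * abs(q[1]))
  # total heat ~ dH x min(total ligand, site capacity); the displacement
  # bookkeeping dilutes the cell contents, so agreement is to a few percent
  delivered <- 1.25e-3 * sum(des$injection_volumes_ul) * 1e-6     # mol
  capacity <- 1 * 0.05e-3 * des$cell_volume_ml * 1e-3             # n M0 V0
  expect_equal(sum(q), -10 * min(delivered, capacity) * 1e9,
               tolerance = 0.03)
})

test_that("the final molar ratio matches the delivered-moles arithmetic", {
  iso <- simulate_isotherm(published_design(), one_site_params())
  # 18 x 2 uL x 1.25 mM = 45 nmol ligand; 0.280 mL x 0.05 mM = 14 nmol
  expect_equal(utils::tail(iso$molar_ratio, 1), 45 / 14, tolerance = 1e-9)
})

test_that("exponential and linear dilution conventions differ below 1%", {
  p <- one_site_params(n = 1, k_d = 1.3e-9, dh = -10)
  qe <- simulate_isotherm(published_design(), p, dilution = "exponential")$heats_ucal
  ql <- simulate_isotherm(published_design(), p, dilution = "linear")$heats_ucal
  expect_lt(max(abs(qe - ql)) / max(abs(qe)), 0.01)
})

test_that("noise is reproducible per seed and absent at sd zero", {
  p <- one_site_params()
  a <- simulate_isotherm(published_design(), p, noise_sd = 0.3, seed = 42)
  b <- simulate_isotherm(published_design(), p, noise_sd = 0.3, seed = 42)
  c0 <- simulate_isotherm(published_design(), p, noise_sd = 0.3, seed = 43)
  expect_identical(a$heats_ucal, b$heats_ucal)
  expect_false(identical(a$heats_ucal, c0$heats_ucal))
})

test_that("cumulative heat accounts for final plus expelled bound material", {
  des <- published_design()
  p <- one_site_params(n = 1.2, k_d = 5e-8, dh = -8, q_offset = 0.05)
  iso <- simulate_isotherm(des, p)
  conc <- swapbp:::itc_concentrations(des)
  theta <- swapbp:::one_site_theta(conc$X_t, conc$M_t, p$n, 1 / p$k_d)
  B <- p$n * conc$M_t * theta * conc$v0          # bound moles in the cell
  f <- exp(-des$injection_volumes_ul * 1e-6 / conc$v0)
  expelled <- sum(c(0, utils::head(B, -1)) * (1 - f))
  expected <- p$dh * (utils::tail(B, 1) + expelled) * 1e9 +
    length(iso$heats_ucal) * p$q_offset
  expect_equal(sum(iso$heats_ucal), expected,
               tolerance = 1e-9)
})

test_that("a noiseless isotherm is refit to machine-level accuracy", {
  des <- published_design()
  truth <- one_site_params(n = 1.0, k_d = 1.3e-9, dh = -10, q_offset = 0)
  iso <- simulate_isotherm(des, truth)
  fit <- fit_one_site(iso, des)
  expect_true(fit$converged)
  expect_equal(fit$params$n, 1, tolerance = 1e-6)
  expect_lt(abs(fit$params$k_d - 1.3e-9) / 1.3e-9, 1e-6)
  expect_equal(fit$params$dh, -10, tolerance = 1e-6)
  expect_lt(abs(fit$params$q_offset), 1e-6)
})

test_that("Monte-Carlo recovery at 2% noise keeps the median K_d within 2x", {
  des <- published_design()
  truth <- one_site_params(n = 1.0, k_d = 1.3e-9, dh = -10)
  base <- simulate_isotherm(des, truth)
  qmax <- max(abs(base$heats_ucal))
  kds <- ns <- numeric(100)
  for (s in 1:100) {
    iso <- simulate_isotherm(des, truth, noise_sd = 0.02 * qmax, seed = s)
    f <- fit_one_site(iso, des)
    kds[s] <- if (is.null(f$params)) NA else f$params$k_d
    ns[s] <- if (is.null(f$params)) NA else f$params$n
  }
  med <- stats::median(kds, na.rm = TRUE)
  expect_gt(med, 1.3e-9 / 2)
  expect_lt(med, 1.3e-9 * 2)
  expect_lt(abs(stats::median(ns, na.rm = TRUE) - 1), 0.05)
  # at this c-value the K_d spread is wide: central 80% spans >= half a decade
  qs <- stats::quantile(kds, c(0.1, 0.9), na.rm = TRUE)
  expect_gt(log10(qs[2] / qs[1]), 0.5)
})

test_that("the fit is scale-consistent in the enthalpy", {
  des <- published_design()
  iso <- simulate_isotherm(des, one_site_params(n = 1, k_d = 1e-8, dh = -6,
                                                q_offset = 0.2))
  f1 <- fit_one_site(iso, des)
  f2 <- fit_one_site(2 * iso$heats_ucal, des)
  expect_equal(f2$params$dh, 2 * f1$params$dh, tolerance = 1e-6)
  expect_equal(f2$params$q_offset, 2 * f1$params$q_offset, tolerance = 1e-6)
})

test_that("flat (no-binding) isotherms are flagged, not fit as tight binders", {
  des <- published_design()
  flat0 <- fit_one_site(rep(0, 18), des)
  expect_true(flat0$no_binding)
  noisy_flat <- simulate_isotherm(des, one_site_params(dh = 0),
                                  noise_sd = 0.05, seed = 9)
  ff <- fit_one_site(noisy_flat, des)
  expect_true(ff$no_binding)
})

test_that("isotherm TSV round trip preserves heats", {
  iso <- simulate_isotherm(published_design(), one_site_params(), noise_sd = 0.1,
                           seed = 5)
  f <- tempfile(fileext = ".tsv")
  write_isotherm_tsv(iso, f)
  expect_equal(read_isotherm_heats(f), iso$heats_ucal, tolerance = 1e-9)
  unlink(f)
})
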