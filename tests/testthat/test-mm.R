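mm_data <- function(kcat = 0.4, KM = 23e-3, n = 60, noise = 0, seed = NULL,
                    E0 = 1e-6) {
  if (!is.null(seed)) set.seed(seed)
  fl <- fluidic_config(substrate_stock = 0.4, enzyme_initial = E0)
  ac <- assign_concentrations(0:(n - 1), fl)
  v0 <- kcat * ac$E * ac$S / (KM + ac$S)
  if (noise > 0) v0 <- v0 * (1 + rnorm(n, 0, noise))
  data.frame(S = ac$S, E = ac$E, v0 = v0)
}

test_that("exact model data reproduce the generating parameters to 1e-6", {
  d <- mm_data(kcat = 0.4, KM = 23.0e-3)
  f <- fit_mm(d)
  expect_true(f$converged)
  expect_equal(f$kcat, 0.4, tolerance = 1e-6)
  expect_equal(f$KM, 23.0e-3, tolerance = 1e-6)
  expect_equal(f$kcat_over_KM, f$kcat / f$KM, tolerance = 1e-12)
})

test_that("recovery is insensitive to starting values within 10x of truth", {
  d <- mm_data(kcat = 0.4, KM = 23.0e-3)
  for (fac in c(0.1, 0.5, 2, 10)) {
    f <- fit_mm(d, start = list(kcat = 0.4 * fac, KM = 23e-3 / fac))
    expect_true(f$converged)
    expect_equal(f$kcat, 0.4, tolerance = 1e-6)
    expect_equal(f$KM, 23e-3, tolerance = 1e-6)
  }
})

test_that("all-zero rates do not converge and are reported as such", {
  d <- mm_data()
  d$v0 <- 0
  f <- fit_mm(d)
  expect_false(f$converged)
  expect_true(is.na(f$kcat))
})

test_that("fit is scale-equivariant in the enzyme concentration", {
  d <- mm_data(kcat = 2, KM = 5e-3, noise = 0.02, seed = 3)
  f1 <- fit_mm(d)
  d2 <- d
  d2$E <- d$E * 10
  f2 <- fit_mm(d2)
  expect_equal(f2$kcat, f1$kcat / 10, tolerance = 1e-8)
  expect_equal(f2$KM, f1$KM, tolerance = 1e-8)
})

test_that("standard errors cover the truth in >= 95% of seeded replicates", {
  # 200 Monte-Carlo replicates at 5% rate noise; the 3-sigma joint ellipse
  # (Mahalanobis distance <= 3 under the Jacobian covariance) should cover
  # the generating parameters in at least 95% of fits
  set.seed(2024)
  truth <- c(kcat = 0.4, KM = 23e-3)
  hits <- logical(200)
  for (i in 1:200) {
    d <- mm_data(kcat = truth[1], KM = truth[2], noise = 0.05)
    f <- fit_mm(d)
    if (!f$converged) { hits[i] <- FALSE; next }
    V <- matrix(c(f$se_kcat^2, f$cov_kcat_KM, f$cov_kcat_KM, f$se_KM^2), 2)
    delta <- c(f$kcat - truth[1], f$KM - truth[2])
    d2 <- drop(t(delta) %*% solve(V) %*% delta)
    hits[i] <- d2 <= 9
  }
  expect_gte(mean(hits), 0.95)
})

test_that("optional rate-law variants recover their generating parameters", {
  fl <- fluidic_config(substrate_stock = 0.4, enzyme_initial = 1e-6)
  ac <- assign_concentrations(0:59, fl)
  # substrate inhibition
  v_si <- 0.5 * ac$E * ac$S / (10e-3 + ac$S + ac$S^2 / 30e-3)
  f_si <- fit_mm(data.frame(S = ac$S, E = ac$E, v0 = v_si),
                 model = "substrate_inhibition")
  expect_true(f_si$converged)
  expect_equal(f_si$kcat, 0.5, tolerance = 1e-4)
  expect_equal(f_si$KM, 10e-3, tolerance = 1e-4)
  expect_equal(f_si$extra$Ki, 30e-3, tolerance = 1e-4)
  # Hill cooperativity
  v_h <- 0.5 * ac$E * ac$S^2 / ((15e-3)^2 + ac$S^2)
  f_h <- fit_mm(data.frame(S = ac$S, E = ac$E, v0 = v_h), model = "hill")
  expect_true(f_h$converged)
  expect_equal(f_h$extra$n, 2, tolerance = 1e-4)
  expect_equal(f_h$KM, 15e-3, tolerance = 1e-4)
})

test_that("specificity constants match the published worked examples", {
  expect_equal(signif(specificity_constant(0.4, 21.9e-3), 2), 18)
  expect_equal(signif(specificity_constant(0.48, 23.5e-3), 2), 20)
  expect_equal(specificity_constant(0, 1e-3), 0)
  expect_error(specificity_constant(1, 0), "KM")
})

test_that("replicate aggregation is the textbook mean/sd/rsd", {
  f <- function(kcat) structure(list(kcat = kcat, KM = 0.02, converged = TRUE),
                                class = "mm_fit")
  s <- aggregate_fits(list(f(0.38), f(0.40), f(0.42)))
  expect_equal(s$mean_kcat, 0.40)
  expect_equal(s$sd_kcat, 0.02)
  expect_equal(s$rsd_kcat, 0.05)
  expect_equal(s$n_fits, 3)
  s2 <- aggregate_fits(list(f(0.4), f(0.4)))
  expect_equal(s2$sd_kcat, 0)
  # fewer than 2 converged: sd marked undefined
  s3 <- aggregate_fits(list(f(0.4)))
  expect_true(is.na(s3$sd_kcat))
  # grouping
  s4 <- aggregate_fits(list(f(1), f(2), f(10)), group = c("a", "a", "b"))
  expect_equal(nrow(s4), 2)
  expect_equal(s4$mean_kcat, c(1.5, 10))
})

test_that("dynamic range is order-invariant and unity for one substrate", {
  x <- c(1.7e6, 13, 1.6e4, 0.31, 17.4, 0.17)
  r1 <- dynamic_range_report(x)
  r2 <- dynamic_range_report(rev(x))
  expect_equal(r1$fold, r2$fold)
  expect_equal(r1$fold, 1.7e6 / 0.17)
  expect_equal(dynamic_range_report(5)$fold, 1)
  expect_equal(dynamic_range_report(5)$log10_fold, 0)
})
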