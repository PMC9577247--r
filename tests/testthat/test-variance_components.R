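test_that("EMS solves the one-way toy exactly (hand arithmetic)", {
  fit <- ems_components(oneway_toy(), oneway_model(), "y")
  # MSB = 24, MSW = 1, n = 3 -> between (24 - 1)/3 = 23/3, residual 1
  expect_equal(unname(fit$estimates["group"]), 23 / 3, tolerance = 1e-12)
  expect_equal(unname(fit$estimates["Residual"]), 1, tolerance = 1e-12)
  expect_equal(fit$std_dev^2, fit$estimates, tolerance = 1e-9)
})

test_that("zero within-cell variation gives residual exactly 0", {
  spec <- generative_spec(mid_design(), 20,
                          c(Variety = 5, Nanopaper = 2, Residual = 0),
                          seed = 4)
  tab <- simulate_observations(spec)
  fit <- ems_components(tab, bn_model("nested"), "tensile_index")
  expect_identical(unname(fit$estimates["Residual"]), 0)
})

test_that("negative raw solutions are truncated and flagged", {
  v <- c(A = -0.5, Residual = 2)
  t1 <- truncate_negative(v)
  expect_equal(unname(t1), c(0, 2), ignore_attr = TRUE)
  expect_equal(attr(t1, "truncated"), "A")
  v2 <- c(A = 1, Residual = 2)
  expect_equal(unname(truncate_negative(v2)), c(1, 2), ignore_attr = TRUE)
  v3 <- c(A = -1, B = -2, Residual = 2)
  expect_equal(unname(truncate_negative(v3)), c(0, 0, 2), ignore_attr = TRUE)

  # a small true component often solves negative; raw is kept, estimate is 0
  spec <- generative_spec(mid_design(), 0,
                          c(Variety = 0, Residual = 10), seed = 8)
  fit <- ems_components(simulate_observations(spec), bn_model("nested"),
                        "tensile_index")
  expect_true(all(fit$estimates >= 0))
  if (any(fit$raw < 0)) {
    expect_setequal(fit$truncated_terms, names(fit$raw)[fit$raw < 0])
  }
})

test_that("EMS rejects unbalanced layouts, pointing to REML", {
  spec <- generative_spec(mid_design(), 10, c(Residual = 1), seed = 5)
  tab <- observation_table(as.data.frame(simulate_observations(spec))[-1, ])
  expect_error(ems_components(tab, bn_model("nested"), "tensile_index"),
               "reml_components")
})

test_that("REML matches EMS on the balanced one-way toy", {
  ems <- ems_components(oneway_toy(), oneway_model(), "y")
  reml <- reml_components(oneway_toy(), oneway_model(), "y",
                          tol = 1e-12, max_iter = 10000)
  expect_true(reml$converged)
  expect_equal(reml$estimates, ems$estimates, tolerance = 1e-4)
})

test_that("EMS and REML agree on balanced data with interior solutions", {
  spec <- generative_spec(
    mid_design(), 100,
    c(Variety = 40, "Section:Variety" = 30, Energy = 60, Nanopaper = 10,
      Residual = 20),
    seed = 6
  )
  tab <- simulate_observations(spec)
  ems <- ems_components(tab, bn_model("nested"), "tensile_index")
  expect_true(all(ems$raw > 0))  # interior solution for this fixture
  reml <- reml_components(tab, bn_model("nested"), "tensile_index",
                          tol = 1e-10, max_iter = 50000)
  expect_equal(reml$estimates / ems$estimates,
               rep(1, length(ems$estimates)), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("REML restricted likelihood ascends monotonically", {
  fits <- list(
    reml_components(oneway_toy(), oneway_model(), "y", max_iter = 200),
    reml_components(
      simulate_observations(generative_spec(
        mid_design(), 10, c(Variety = 4, Energy = 2, Residual = 1),
        seed = 7)),
      bn_model("nested"), "tensile_index", max_iter = 200
    )
  )
  for (fit in fits) {
    expect_monotone_loglik(fit)
  }
})

test_that("REML handles degenerate and unbalanced inputs", {
  const <- data.frame(group = rep(c("A", "B"), 3), value = 5, metric = "y")
  fit <- reml_components(const, oneway_model(), "y")
  expect_true(all(fit$estimates == 0))
  expect_true(fit$converged)

  spec <- generative_spec(mid_design(), 10,
                          c(Variety = 4, Residual = 1), seed = 9)
  tab <- observation_table(as.data.frame(simulate_observations(spec))[-1, ])
  fit2 <- reml_components(tab, bn_model("nested"), "tensile_index",
                          tol = 1e-6, max_iter = 10000)
  expect_true(fit2$converged)
  expect_true(all(fit2$estimates >= 0))

  expect_error(reml_components(const[1, ], oneway_model(), "y"),
               "at least 2")
})

test_that("EM-REML agrees with an independent mixed-model fit", {
  spec <- generative_spec(
    mid_design(), 100,
    c(Variety = 40, "Section:Variety" = 30, Energy = 60, Nanopaper = 10,
      Residual = 20),
    seed = 6
  )
  tab <- as.data.frame(simulate_observations(spec))
  tab$sheet <- interaction(tab$variety, tab$section, tab$energy,
                           tab$nanopaper, drop = TRUE)
  fm <- lme4::lmer(
    value ~ (1 | variety) + (1 | variety:section) + (1 | energy) +
      (1 | sheet),
    data = tab, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")
  )
  vc <- as.data.frame(lme4::VarCorr(fm))
  oracle <- stats::setNames(vc$vcov, vc$grp)
  fit <- reml_components(tab, bn_model("nested"), "tensile_index",
                         tol = 1e-10, max_iter = 50000)
  expect_equal(unname(fit$estimates["Variety"]),
               unname(oracle["variety"]), tolerance = 1e-3)
  expect_equal(unname(fit$estimates["Section:Variety"]),
               unname(oracle["variety:section"]), tolerance = 1e-3)
  expect_equal(unname(fit$estimates["Energy"]),
               unname(oracle["energy"]), tolerance = 1e-3)
  expect_equal(unname(fit$estimates["Nanopaper"]),
               unname(oracle["sheet"]), tolerance = 1e-3)
  expect_equal(unname(fit$estimates["Residual"]),
               unname(oracle["Residual"]), tolerance = 1e-3)
})

test_that("estimates are scale-equivariant and permutation-invariant", {
  spec <- generative_spec(mid_design(), 10,
                          c(Variety = 4, "Section:Variety" = 3, Energy = 2,
                            Nanopaper = 1, Residual = 1),
                          seed = 10)
  tab <- simulate_observations(spec)
  base_fit <- ems_components(tab, bn_model("nested"), "tensile_index")

  scaled <- as.data.frame(tab)
  scaled$value <- scaled$value * 3
  fit_scaled <- ems_components(observation_table(scaled),
                               bn_model("nested"), "tensile_index")
  expect_equal(fit_scaled$estimates, 9 * base_fit$estimates,
               tolerance = 1e-9)

  shuffled <- as.data.frame(tab)[sample(nrow(tab)), ]
  fit_shuffled <- ems_components(observation_table(shuffled),
                                 bn_model("nested"), "tensile_index")
  expect_equal(fit_shuffled$estimates, base_fit$estimates, tolerance = 1e-11)

  reml_a <- reml_components(tab, bn_model("nested"), "tensile_index",
                            tol = 1e-8, max_iter = 500)
  reml_b <- reml_components(observation_table(shuffled), bn_model("nested"),
                            "tensile_index", tol = 1e-8, max_iter = 500)
  expect_equal(reml_a$estimates, reml_b$estimates, tolerance = 1e-9)
})

test_that("EMS is unbiased over replicates of the mid-size design", {
  truth <- c(Variety = 40, "Section:Variety" = 30, Energy = 60,
             Nanopaper = 10, Residual = 20)
  model <- bn_model("nested")
  template <- simulate_observations(
    generative_spec(mid_design(), 0, truth, seed = 0))
  prep <- ems_prepare(template, model, "tensile_index")
  reps <- vapply(0:199, function(s) {
    tab <- simulate_observations(generative_spec(mid_design(), 0, truth,
                                                 seed = s))
    ems_refit(prep, tab)$raw[names(truth)]
  }, numeric(5))
  m <- rowMeans(reps)
  mc_se <- apply(reps, 1L, sd) / sqrt(ncol(reps))
  expect_true(all(abs(m - truth) < 3 * mc_se + 1e-9))
})

test_that("confounded terms are rejected with a clear message", {
  # nested strips carry one observation each: no residual stratum left
  full <- model_spec(list(
    "Variety" = "variety",
    "Section:Variety" = c("variety", "section"),
    "Energy" = "energy",
    "Nanopaper" = c("variety", "section", "energy", "nanopaper"),
    "Strip:Nanopaper" = c("variety", "section", "energy", "nanopaper",
                          "strip")
  ))
  spec <- generative_spec(small_design(), 10, c(Residual = 1), seed = 1)
  tab <- simulate_observations(spec)
  expect_error(ems_components(tab, full, "tensile_index"),
               "residual|degrees of freedom")
  expect_error(reml_components(tab, full, "tensile_index"),
               "confounded")
})
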