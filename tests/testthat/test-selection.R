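sel_mm <- function(x, ids = NULL, mets = NULL) {
  x <- as.matrix(x)
  rownames(x) <- ids %||% paste0("s", seq_len(nrow(x)))
  colnames(x) <- mets %||% paste0("m", seq_len(ncol(x)))
  metric_matrix(x)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("quality scores are min-max rescaled weighted means", {
  m <- sel_mm(rbind(c(0, 4), c(10, 8)))
  q <- quality_definition("Q", c("m1", "m2"))
  s <- quality_score(m, q)
  expect_equal(unname(s), c(0, 1))

  # single constituent: monotone transform preserves sample ranking
  m2 <- sel_mm(cbind(c(3, 1, 7, 5), c(1, 1, 2, 2)))
  s2 <- quality_score(m2, quality_definition("Q1", "m1"))
  expect_equal(order(s2), order(unclass(m2)[, "m1"]))
  expect_equal(range(s2), c(0, 1))

  # direction -1 flips the rescaled constituent
  s_up <- quality_score(m2, quality_definition("Q", "m1"))
  s_dn <- quality_score(m2, quality_definition("Q", "m1", directions = -1))
  expect_equal(s_dn, 1 - s_up)

  expect_error(quality_score(m2, quality_definition("Q", "absent")),
               "absent")
  const <- sel_mm(cbind(c(1, 2, 3), c(5, 5, 5)))
  expect_error(quality_score(const, quality_definition("Q", "m2")),
               "m2.*constant|constant.*m2")
})

test_that("quality scores are invariant to affine positive rescaling", {
  m <- sel_mm(matrix(rnorm(40), 10, 4))
  q <- quality_definition("Q", c("m1", "m3"), weights = c(2, 1),
                          directions = c(1, -1))
  s1 <- quality_score(m, q)
  x <- unclass(m)
  x[, "m1"] <- 7 * x[, "m1"] + 100
  s2 <- quality_score(metric_matrix(x), q)
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_true(all(s1 >= 0 & s1 <= 1))
})

test_that("selection gradients are OLS slopes with optional trait scaling", {
  set.seed(1)
  trait <- rnorm(30, 10, 3)
  z <- (trait - mean(trait)) / sd(trait)
  g <- selection_gradient(trait, 2 * z)
  expect_equal(g$beta, 2, tolerance = 1e-12)
  expect_equal(g$n, 30L)
  expect_equal(g$r_squared, 1, tolerance = 1e-12)

  g0 <- selection_gradient(trait, rep(0.5, 30))
  expect_equal(g0$beta, 0)

  g3 <- selection_gradient(c(0, 1, 2), c(1, 3, 5), standardize_trait = FALSE)
  expect_equal(g3$beta, 2, tolerance = 1e-12)

  # affine positive rescaling of the trait leaves standardized beta alone
  fitness <- 0.3 * z + rnorm(30, sd = 0.1)
  b1 <- selection_gradient(trait, fitness)$beta
  b2 <- selection_gradient(5 * trait - 2, fitness)$beta
  expect_equal(b1, b2, tolerance = 1e-12)

  expect_error(selection_gradient(c(1, 2), c(1, 2)), "at least 3")
  expect_error(selection_gradient(rep(1, 5), rnorm(5)), "zero spread")
})

test_that("G matrix is the (co)variance of metrics", {
  set.seed(7)
  x <- matrix(rnorm(5000 * 3), 5000, 3)
  m <- sel_mm(cbind(x, dup = x[, 1]),
              mets = c("m1", "m2", "m3", "dup"))
  G <- g_matrix(m)
  expect_equal(unname(diag(unclass(G))), rep(1, 4))
  expect_equal(unname(G["m1", "dup"]), 1, tolerance = 1e-12)
  expect_true(all(abs(G["m1", c("m2", "m3")]) < 0.05))
  expect_true(all(abs(G["m2", "m3"]) < 0.05))

  Graw <- g_matrix(m, standardized = FALSE)
  expect_equal(unname(diag(unclass(Graw))),
               unname(apply(unclass(m), 2, var)), tolerance = 1e-12)
  expect_error(g_matrix(sel_mm(matrix(1:3, 1))), "at least 2")
})

test_that("predicted response is G beta, aligned by label", {
  G2 <- structure(matrix(c(2, 1, 1, 3), 2,
                         dimnames = list(c("a", "b"), c("a", "b"))),
                  class = c("g_matrix", "matrix", "array"))
  expect_equal(predicted_response(G2, c(a = 1, b = -1)),
               c(a = 1, b = -2))
  expect_equal(predicted_response(G2, c(b = -1, a = 1)),
               c(a = 1, b = -2))  # alignment by label, not position
  expect_equal(predicted_response(G2, c(a = 0, b = 0)), c(a = 0, b = 0))

  id <- structure(diag(2), dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(predicted_response(id, c(a = 0.4, b = -0.2)),
               c(a = 0.4, b = -0.2))

  expect_error(predicted_response(G2, c(a = 1, c = 2)), "b.*c|c.*b")
})

test_that("G beta matches the brute-force expansion and diagonal limit", {
  set.seed(42)
  for (rep in 1:5) {
    mets <- paste0("t", 1:6)
    m <- sel_mm(matrix(rnorm(50 * 6), 50, 6), mets = mets)
    G <- g_matrix(m, standardized = FALSE)
    beta <- setNames(rnorm(6), mets)
    got <- predicted_response(G, beta)
    brute <- vapply(mets, function(n) {
      acc <- 0
      for (k in mets) acc <- acc + unclass(G)[n, k] * beta[[k]]
      acc
    }, numeric(1))
    expect_equal(got, brute, tolerance = 1e-10)
  }
  # diagonal G: response decouples to V_n * beta_n
  Gd <- structure(diag(c(2, 5, 0.5)),
                  dimnames = rep(list(c("a", "b", "c")), 2))
  beta <- c(a = 1, b = -2, c = 4)
  expect_equal(predicted_response(Gd, beta),
               c(a = 2, b = -10, c = 2))
})

test_that("cross-definition table orders by mean and measures spread", {
  g <- data.frame(
    metric = rep(c("mA", "mB"), 2),
    definition = rep(c("Q1", "Q5"), each = 2),
    beta = c(1, 1, 1, -1)
  )
  tab <- cross_quality_table(g)
  expect_equal(tab$metric, c("mB", "mA"))  # means 0 < 1, ascending
  expect_equal(tab$mean_beta, c(0, 1))
  expect_equal(tab$range_beta, c(2, 0))

  same <- g; same$beta <- c(0.5, -0.3, 0.5, -0.3)
  expect_equal(cross_quality_table(same)$range_beta, c(0, 0))

  bad <- g; bad$metric[4] <- "mC"
  expect_error(cross_quality_table(bad), "metric set")
  expect_error(cross_quality_table(g[g$definition == "Q1", ]),
               "two quality definitions")
})

test_that("a metric driving both definitions has the smaller spread", {
  # A drives both quality constituents; B drives only the first.
  set.seed(5)
  n <- 200
  A <- rnorm(n); B <- rnorm(n)
  qa <- A + B + rnorm(n, sd = 0.1)   # constituent of definition 1
  qb <- A - B + rnorm(n, sd = 0.1)   # constituent of definition 2
  m <- sel_mm(cbind(A, B, qa, qb), mets = c("A", "B", "qa", "qb"))
  defs <- list(quality_definition("D1", "qa"), quality_definition("D2", "qb"))
  grads <- selection_gradients(m, defs, traits = c("A", "B"))
  tab <- cross_quality_table(grads)
  expect_lt(tab$range_beta[tab$metric == "A"],
            tab$range_beta[tab$metric == "B"])
})

test_that("full selection pipeline runs on the default population", {
  m <- simulate_metric_matrix(default_metric_cov_spec(seed = 3))
  defs <- default_quality_definitions()
  grads <- selection_gradients(m, defs)
  expect_setequal(unique(grads$definition), c("Q1", "Q5"))
  expect_equal(nrow(grads), 2 * 10)  # ten morphology traits per definition
  G <- g_matrix(m, traits = unique(grads$metric))
  dz <- predicted_response(G, grads[grads$definition == "Q1", ])
  expect_equal(length(dz), 10L)
  expect_true(all(is.finite(dz)))
  tab <- cross_quality_table(grads)
  expect_equal(tab$mean_beta, sort(tab$mean_beta))
})
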