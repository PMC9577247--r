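# Shared fixtures, built in code.

# Small balanced design: 2 varieties x 2 sections x 2 energies,
# 2 duplicates x 3 strips = 48 strip observations.
small_design <- function() {
  design_spec(
    varieties = c("V1", "V2"),
    sections_by_variety = c("Leaf", "Stem"),
    energy_levels = c("Low", "High"),
    n_duplicates = 2L,
    n_strips = 3L
  )
}

# Mid-size balanced design with 3 varieties so every stratum has a few
# degrees of freedom: 3 x 2 x 2 x 2 x 3 = 72 observations.
mid_design <- function() {
  design_spec(
    varieties = c("V1", "V2", "V3"),
    sections_by_variety = c("Leaf", "Stem"),
    energy_levels = c("Low", "High"),
    n_duplicates = 2L,
    n_strips = 3L
  )
}

# Reference variance partition for the nanopaper tensile index
# (per-term variances; energy term labelled HPH as in the source report).
reference_components <- function() {
  path <- system.file("extdata", "tensile_index_varcomp.csv",
                      package = "nanoherit")
  df <- read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$variance, df$term)
}

# Two-group toy with hand-computable mean squares:
# groups A = {1,2,3}, B = {5,6,7} -> MSB = 24, MSW = 1,
# between-group variance (24 - 1)/3 = 23/3, residual 1.
oneway_toy <- function() {
  data.frame(
    group = rep(c("A", "B"), each = 3L),
    value = c(1, 2, 3, 5, 6, 7),
    metric = "y",
    stringsAsFactors = FALSE
  )
}

oneway_model <- function() model_spec(list(group = "group"))

# A 6-row wide CSV with all five factor columns and one metric.
toy_csv <- function(path) {
  df <- data.frame(
    variety = rep("V1", 6), section = rep(c("Leaf", "Stem"), each = 3),
    energy = "Low", nanopaper = rep(c("1", "2"), 3),
    strip = as.character(rep(1:3, 2)), tensile_index = c(10, 12, 11, 9, 8, 10)
  )
  write.csv(df, path, row.names = FALSE)
  path
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Monotone REML ascent up to floating-point noise in evaluating the
# restricted log-likelihood (relative to its magnitude).
expect_monotone_loglik <- function(fit) {
  tr <- fit$loglik_trace
  slack <- 1e-9 * (1 + abs(tr[-1]))
  testthat::expect_true(all(diff(tr) > -slack))
}
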