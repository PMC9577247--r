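# Canonical random-term names for the biomass-to-nanopaper model.
# "Energy" is the homogenisation (HPH) energy level.
bn_terms <- c("Variety", "Section:Variety", "Energy", "Nanopaper",
              "Strip:Nanopaper")

# Evaluate an expression with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards: generators take explicit seeds and leave
# no hidden global state behind.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generative specification for synthetic observation tables
#'
#' True parameters of the additive random-effects model used to simulate
#' strip-level observations: value = grand mean + variety effect +
#' section-within-variety effect + energy effect + nanopaper effect +
#' strip effect + residual, every effect Gaussian with mean zero and the
#' stated variance.
#'
#' @param design a [design_spec()].
#' @param grand_mean overall mean of the simulated metric.
#' @param components named non-negative variances for any subset of
#'   `"Variety"`, `"Section:Variety"`, `"Energy"`, `"Nanopaper"`,
#'   `"Strip:Nanopaper"`, plus `"Residual"`. Omitted terms default to 0.
#' @param seed integer seed; the same spec always simulates the same table.
#' @param metric name of the simulated metric column.
#' @return An object of class `generative_spec`.
#' @export
generative_spec <- function(design, grand_mean, components, seed,
                            metric = "tensile_index") {
  known <- c(bn_terms, "Residual")
  if (is.null(names(components)) || !all(names(components) %in% known)) {
    stop("components must be named among: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  if (any(components < 0)) {
    stop("negative variance component: ",
         paste(names(components)[components < 0], collapse = ", "),
         call. = FALSE)
  }
  full <- stats::setNames(numeric(length(known)), known)
  full[names(components)] <- components
  structure(
    list(design = design, grand_mean = grand_mean, components = full,
         seed = as.integer(seed), metric = metric),
    class = "generative_spec"
  )
}

# Strip-level design frame in canonical (sorted) row order.
design_frame <- function(design) {
  cells <- design_cells(design)
  idx <- rep(seq_len(nrow(cells)),
             each = design$n_duplicates * design$n_strips)
  data.frame(
    variety = cells$variety[idx],
    section = cells$section[idx],
    energy = cells$energy[idx],
    nanopaper = as.character(rep(rep(seq_len(design$n_duplicates),
                                     each = design$n_strips),
                                 nrow(cells))),
    strip = as.character(rep(seq_len(design$n_strips),
                             design$n_duplicates * nrow(cells))),
    stringsAsFactors = FALSE
  )
}

# Grouping factor for one canonical term. Under the nested coding the
# nanopaper duplicate is a distinct sheet per sample and strips are distinct
# per sheet; under the literal coding duplicate labels 1-2 and strip labels
# 1-8 are shared factor levels across all samples (the model formula as the
# study's software coded it).
term_factor <- function(term, df, coding = c("nested", "literal")) {
  coding <- match.arg(coding)
  switch(term,
    "Variety" = factor(df$variety),
    "Section:Variety" = interaction(df$variety, df$section,
                                    drop = TRUE, sep = ":"),
    "Energy" = factor(df$energy),
    "Nanopaper" = if (coding == "nested") {
      interaction(df$variety, df$section, df$energy, df$nanopaper,
                  drop = TRUE, sep = ":")
    } else {
      factor(df$nanopaper)
    },
    "Strip:Nanopaper" = if (coding == "nested") {
      interaction(df$variety, df$section, df$energy, df$nanopaper, df$strip,
                  drop = TRUE, sep = ":")
    } else {
      interaction(df$nanopaper, df$strip, drop = TRUE, sep = ":")
    },
    stop("unknown model term: ", term, call. = FALSE)
  )
}

#' Simulate a fully balanced observation table
#'
#' Draws one independent Gaussian effect per level of each random term and
#' sums them with the grand mean and residual noise. Always yields a fully
#' balanced table ([validate_balance()] is true by construction).
#'
#' @param spec a [generative_spec()].
#' @param coding `"nested"` (each duplicate sheet and strip is its own unit)
#'   or `"literal"` (duplicate and strip labels shared across samples; this
#'   is the coding under which a `"Strip:Nanopaper"` component is estimable
#'   separately from the residual).
#' @return An [observation_table()] with
#'   `|varieties| * |sections| * |energies| * n_duplicates * n_strips` rows.
#' @export
simulate_observations <- function(spec, coding = c("nested", "literal")) {
  coding <- match.arg(coding)
  df <- design_frame(spec$design)
  comp <- spec$components
  y <- with_seed(spec$seed, {
    out <- rep(spec$grand_mean, nrow(df))
    for (term in bn_terms) {
      if (comp[[term]] > 0) {
        f <- term_factor(term, df, coding)
        eff <- stats::rnorm(nlevels(f), 0, sqrt(comp[[term]]))
        out <- out + eff[as.integer(f)]
      }
    }
    if (comp[["Residual"]] > 0) {
      out <- out + stats::rnorm(nrow(df), 0, sqrt(comp[["Residual"]]))
    }
    out
  })
  df$metric <- spec$metric
  df$value <- y
  observation_table(df, design = spec$design)
}

#' Draw i.i.d. Gaussian effects
#'
#' Auxiliary generator used to check the effect distribution of the
#' simulator directly (e.g. that a variance-4 term's draws have sample
#' variance 4).
#'
#' @param n number of draws.
#' @param variance effect variance (>= 0).
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_effects <- function(n, variance, seed) {
  if (variance < 0) stop("negative variance", call. = FALSE)
  with_seed(seed, stats::rnorm(n, 0, sqrt(variance)))
}

#' Covariance specification for synthetic metric matrices
#'
#' @param metric_names metric labels.
#' @param means mean per metric.
#' @param covariance symmetric positive-semidefinite covariance matrix
#'   (symmetry checked to 1e-10; eigenvalues >= -1e-8 * max eigenvalue).
#' @param n_samples number of samples to draw.
#' @param seed integer seed.
#' @param sample_ids optional sample labels (default `"s001"`, ...).
#' @return An object of class `metric_cov_spec`.
#' @export
metric_cov_spec <- function(metric_names, means, covariance, n_samples, seed,
                            sample_ids = NULL) {
  k <- length(metric_names)
  covariance <- as.matrix(covariance)
  if (length(means) != k || !all(dim(covariance) == k)) {
    stop("means/covariance dimensions do not match metric_names",
         call. = FALSE)
  }
  if (max(abs(covariance - t(covariance))) > 1e-10) {
    stop("covariance matrix is not symmetric (tolerance 1e-10)",
         call. = FALSE)
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(abs(ev), 1)
  if (min(ev) < -tol) {
    stop(sprintf(
      "covariance is not positive semidefinite: eigenvalue %.6g", min(ev)),
      call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%03d", seq_len(n_samples))
  }
  if (length(sample_ids) != n_samples || anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique and of length n_samples", call. = FALSE)
  }
  structure(
    list(metric_names = metric_names, means = as.numeric(means),
         covariance = covariance, n_samples = as.integer(n_samples),
         seed = as.integer(seed), sample_ids = as.character(sample_ids)),
    class = "metric_cov_spec"
  )
}

#' Simulate a multivariate-normal metric matrix
#'
#' Rows are i.i.d. draws from N(means, covariance), via the symmetric
#' eigendecomposition of the covariance (tiny negative eigenvalues within
#' tolerance are clamped to zero), reproducible under the spec's seed.
#'
#' @param spec a [metric_cov_spec()].
#' @return A [metric_matrix()] of size `n_samples` x `length(metric_names)`.
#' @export
simulate_metric_matrix <- function(spec) {
  k <- length(spec$metric_names)
  eg <- eigen(spec$covariance, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  L <- eg$vectors %*% diag(sqrt(lam), k)
  z <- with_seed(spec$seed,
                 matrix(stats::rnorm(spec$n_samples * k), spec$n_samples, k))
  values <- sweep(z %*% t(L), 2L, spec$means, `+`)
  dimnames(values) <- list(spec$sample_ids, spec$metric_names)
  metric_matrix(values)
}

#' Metric matrix with planted correlation blocks
#'
#' Builds a block-diagonal correlation matrix (unit variances, correlation
#' `within_r` inside each block, zero across blocks) and simulates from it.
#' The planted partition is attached as attribute `"blocks"`, so cluster
#' recovery can be scored against the truth.
#'
#' @param n_samples number of samples.
#' @param blocks named list partitioning the metric names into blocks
#'   (disjoint, non-empty).
#' @param within_r within-block correlation in `[0, 1)`.
#' @param seed integer seed.
#' @return A [metric_matrix()] with a `blocks` attribute (named integer
#'   vector: metric -> block index).
#' @export
planted_block_metrics <- function(n_samples, blocks, within_r, seed) {
  mets <- unlist(blocks, use.names = FALSE)
  if (anyDuplicated(mets)) {
    stop("blocks overlap: ", paste(mets[duplicated(mets)], collapse = ", "),
         call. = FALSE)
  }
  if (within_r < 0 || within_r >= 1) {
    stop("within_r must be in [0, 1)", call. = FALSE)
  }
  k <- length(mets)
  sigma <- diag(k)
  dimnames(sigma) <- list(mets, mets)
  for (b in blocks) {
    sigma[b, b] <- within_r
    sigma[cbind(b, b)] <- 1
  }
  spec <- metric_cov_spec(mets, rep(0, k), sigma, n_samples, seed)
  m <- simulate_metric_matrix(spec)
  membership <- rep(seq_along(blocks), lengths(blocks))
  names(membership) <- mets
  attr(m, "blocks") <- membership
  m
}
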