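#' Factor "heritability" shares
#'
#' Expresses each variance component (including the residual) as a share of
#' the total variance — the per-factor "heritability" of the material trait.
#' Shares are exact fractions summing to one; percent values are a display
#' convenience.
#'
#' @param components a [variance_components()] or named non-negative vector
#'   including `"Residual"`.
#' @return A data.frame of class `heritability_table` with columns `term`,
#'   `variance`, `std_dev`, `share` (fraction) and `share_pct`; attribute
#'   `total_variance` holds the denominator.
#' @export
factor_shares <- function(components) {
  est <- if (inherits(components, "variance_components")) {
    components$estimates
  } else {
    stats::setNames(as.numeric(components), names(components))
  }
  if (is.null(names(est))) stop("components must be named", call. = FALSE)
  if (any(est < 0)) stop("components must be non-negative", call. = FALSE)
  total <- sum(est)
  if (total <= 0) {
    stop("all components are zero; shares are undefined", call. = FALSE)
  }
  out <- data.frame(
    term = names(est),
    variance = unname(est),
    std_dev = sqrt(unname(est)),
    share = unname(est) / total,
    stringsAsFactors = FALSE
  )
  out$share_pct <- 100 * out$share
  attr(out, "total_variance") <- total
  class(out) <- c("heritability_table", "data.frame")
  out
}

#' @export
print.heritability_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$variance <- round(df$variance, 2)
  df$std_dev <- round(df$std_dev, 2)
  df$share_pct <- round(df$share_pct, 1)
  df$share <- NULL
  print(df, row.names = FALSE)
  cat("total variance:", round(attr(x, "total_variance"), 2), "\n")
  invisible(x)
}

#' Genetic heritability of a metric
#'
#' Proportion of total variance attributed to the biomass ("genetic")
#' factors — by default the variety and section-within-variety terms —
#' over the total variance across all terms including the residual.
#'
#' @param components a [variance_components()] or named non-negative vector
#'   including `"Residual"`.
#' @param genetic_terms term names counted as genetic.
#' @return A single value in `[0, 1]`.
#' @export
genetic_heritability <- function(components,
                                 genetic_terms = c("Variety",
                                                   "Section:Variety")) {
  shares <- factor_shares(components)
  unknown <- setdiff(genetic_terms, shares$term)
  if (length(unknown) > 0L) {
    stop("unknown genetic term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(shares$share[shares$term %in% genetic_terms])
}

#' Rank metrics by genetic heritability
#'
#' @param per_metric named numeric: metric -> heritability in `[0, 1]`.
#' @return data.frame (`metric`, `genetic_h2`, `rank`) sorted by descending
#'   heritability, ties broken lexicographically by metric name.
#' @export
heritability_ranking <- function(per_metric) {
  if (length(per_metric) == 0L || is.null(names(per_metric))) {
    stop("per_metric must be a non-empty named vector", call. = FALSE)
  }
  ord <- order(-per_metric, names(per_metric), method = "radix")
  data.frame(
    metric = names(per_metric)[ord],
    genetic_h2 = unname(per_metric)[ord],
    rank = seq_along(per_metric),
    stringsAsFactors = FALSE
  )
}

#' Parametric bootstrap intervals for factor shares
#'
#' Simulates `n_boot` replicate experiments from fitted components, refits
#' each by expected mean squares on the (fixed, balanced) design, and
#' returns percentile intervals for every factor share.
#'
#' @param spec a [generative_spec()] whose components are the fitted values.
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed integer seed.
#' @param coding design coding passed to the simulator and the model
#'   (see [bn_model()]).
#' @param level confidence level (default 0.95; percentile 2.5/97.5).
#' @return data.frame with `term`, `share`, `lower`, `upper` (fractions).
#' @export
bootstrap_share_ci <- function(spec, n_boot, seed,
                               coding = c("nested", "literal"),
                               level = 0.95) {
  coding <- match.arg(coding)
  if (n_boot < 2L) stop("n_boot must be at least 2", call. = FALSE)
  model <- bn_model(coding)
  template <- simulate_observations(spec, coding = coding)
  prep <- ems_prepare(template, model, spec$metric)
  point <- factor_shares(ems_refit(prep, template))
  terms <- c(names(model$terms), "Residual")
  draws <- with_seed(seed, {
    mu <- spec$grand_mean
    comp <- spec$components
    df <- design_frame(spec$design)
    # put rows in the exact canonical order ems_prepare used
    df <- df[do.call(order, df[unique(unlist(model$terms))]), , drop = FALSE]
    Zi <- lapply(bn_terms, function(tm) term_factor(tm, df, coding))
    names(Zi) <- bn_terms
    vapply(seq_len(n_boot), function(b) {
      y <- rep(mu, nrow(df))
      for (tm in bn_terms) {
        if (comp[[tm]] > 0) {
          f <- Zi[[tm]]
          y <- y + stats::rnorm(nlevels(f), 0, sqrt(comp[[tm]]))[
            as.integer(f)]
        }
      }
      y <- y + stats::rnorm(nrow(df), 0, sqrt(comp[["Residual"]]))
      fit <- ems_refit(prep, y)
      fit$estimates[terms] / sum(fit$estimates)
    }, numeric(length(terms)))
  })
  alpha <- (1 - level) / 2
  # inverse-ECDF (type 1) percentiles: with two replicates the interval is
  # exactly their min/max
  out <- data.frame(
    term = terms,
    share = point$share[match(terms, point$term)],
    lower = apply(draws, 1L, stats::quantile, probs = alpha, names = FALSE,
                  type = 1),
    upper = apply(draws, 1L, stats::quantile, probs = 1 - alpha,
                  names = FALSE, type = 1),
    stringsAsFactors = FALSE
  )
  attr(out, "draws") <- draws
  out
}

#' Per-metric heritability for every metric of a table
#'
#' Convenience wrapper: fits the model to each metric column and returns the
#' genetic heritability ranking.
#'
#' @param table an [observation_table()].
#' @param model a [model_spec()].
#' @param genetic_terms see [genetic_heritability()].
#' @param method `"EMS"` (balanced layouts) or `"REML"`.
#' @param ... passed to [reml_components()].
#' @return A [heritability_ranking()] data.frame over the table's metrics.
#' @export
heritability_by_metric <- function(table, model = bn_model(),
                                   genetic_terms = c("Variety",
                                                     "Section:Variety"),
                                   method = c("EMS", "REML"), ...) {
  method <- match.arg(method)
  mets <- metrics_of(table)
  h2 <- vapply(mets, function(m) {
    fit <- if (method == "EMS") ems_components(table, model, m)
           else reml_components(table, model, m, ...)
    genetic_heritability(fit, genetic_terms)
  }, numeric(1))
  heritability_ranking(h2)
}
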