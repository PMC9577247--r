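#' Material quality definition
#'
#' A named, weighted, direction-signed combination of characterisation
#' metrics. Each constituent is min-max rescaled to `[0, 1]` per sample
#' population (direction -1 reverses the scale: lower raw values are
#' better), then combined as a weighted mean — so the score is bounded in
#' `[0, 1]`, tunable, and invariant to affine positive rescaling of any
#' constituent. Weights are normalised to sum to one.
#'
#' @param name definition label (e.g. `"Q1"`, `"Q5"`).
#' @param metrics constituent metric names.
#' @param weights non-negative weights (default equal); normalised to sum 1.
#' @param directions +1 (higher is better, default) or -1 per constituent.
#' @return An object of class `quality_definition`.
#' @export
quality_definition <- function(name, metrics, weights = NULL,
                               directions = NULL) {
  if (length(metrics) == 0L || anyDuplicated(metrics)) {
    stop("constituent metrics must be non-empty and unique", call. = FALSE)
  }
  k <- length(metrics)
  if (is.null(weights)) weights <- rep(1, k)
  if (is.null(directions)) directions <- rep(1, k)
  if (length(weights) != k || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative, matching the metrics, not all zero",
         call. = FALSE)
  }
  if (length(directions) != k || !all(directions %in% c(-1, 1))) {
    stop("directions must be +1 or -1 per constituent", call. = FALSE)
  }
  structure(
    list(
      name = name,
      constituents = data.frame(
        metric = as.character(metrics),
        weight = weights / sum(weights),
        direction = as.numeric(directions),
        stringsAsFactors = FALSE
      )
    ),
    class = "quality_definition"
  )
}

#' @export
print.quality_definition <- function(x, ...) {
  cat("Quality definition", x$name, "\n")
  print(x$constituents, row.names = FALSE)
  invisible(x)
}

#' Per-sample quality scores (fitness proxy)
#'
#' Applies a [quality_definition()] to a metric matrix: each constituent is
#' min-max rescaled over the sample population (direction -1 maps x to
#' 1 - x after rescaling) and the weighted mean taken. Scores lie in
#' `[0, 1]` and act as the fitness proxy for selection-gradient analysis.
#'
#' @param m a [metric_matrix()].
#' @param definition a [quality_definition()].
#' @return Named numeric vector of scores per sample.
#' @export
quality_score <- function(m, definition) {
  x <- unclass(as.matrix(m))
  if (nrow(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  cons <- definition$constituents
  missing_m <- setdiff(cons$metric, colnames(x))
  if (length(missing_m) > 0L) {
    stop("constituent metric(s) absent: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  scaled <- vapply(seq_len(nrow(cons)), function(i) {
    v <- x[, cons$metric[i]]
    rng <- range(v)
    if (rng[1] == rng[2]) {
      stop("constituent metric '", cons$metric[i],
           "' is constant; its min-max rescaling is undefined",
           call. = FALSE)
    }
    s <- (v - rng[1]) / (rng[2] - rng[1])
    if (cons$direction[i] < 0) 1 - s else s
  }, numeric(nrow(x)))
  drop(scaled %*% cons$weight)
}

#' Selection gradient of one trait
#'
#' Ordinary least-squares slope of the fitness (quality) score on the trait.
#' With `standardize_trait = TRUE` (default) the trait is z-standardized
#' first, so gradients of incommensurable metrics share one axis and the
#' value is invariant to affine positive rescaling of the trait.
#'
#' @param trait numeric trait values per sample.
#' @param fitness quality scores per sample (same length).
#' @param standardize_trait z-standardize the trait before regressing.
#' @return A list of class `sel_gradient`: `beta`, `n`, `r_squared`.
#' @export
selection_gradient <- function(trait, fitness, standardize_trait = TRUE) {
  if (length(trait) != length(fitness)) {
    stop("trait and fitness lengths differ", call. = FALSE)
  }
  ok <- is.finite(trait) & is.finite(fitness)
  trait <- trait[ok]; fitness <- fitness[ok]
  n <- length(trait)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(trait) == 0) {
    stop("trait has zero spread; the gradient is undefined", call. = FALSE)
  }
  if (standardize_trait) {
    trait <- (trait - mean(trait)) / stats::sd(trait)
  }
  beta <- stats::cov(trait, fitness) / stats::var(trait)
  vf <- stats::var(fitness)
  r2 <- if (vf == 0) 0 else stats::cor(trait, fitness)^2
  structure(list(beta = beta, n = n, r_squared = r2),
            class = "sel_gradient")
}

#' Selection gradients for every metric under one or more quality definitions
#'
#' @param m a [metric_matrix()] whose columns are the traits.
#' @param definitions a [quality_definition()] or list of them.
#' @param traits which metric columns to regress (default: all columns that
#'   are not constituents of any definition).
#' @param standardize_trait see [selection_gradient()].
#' @return data.frame with `metric`, `definition`, `beta`, `n`, `r_squared`.
#' @export
selection_gradients <- function(m, definitions, traits = NULL,
                                standardize_trait = TRUE) {
  if (inherits(definitions, "quality_definition")) {
    definitions <- list(definitions)
  }
  if (is.null(traits)) {
    used <- unique(unlist(lapply(definitions,
                                 function(d) d$constituents$metric)))
    traits <- setdiff(colnames(m), used)
  }
  missing_t <- setdiff(traits, colnames(m))
  if (length(missing_t) > 0L) {
    stop("trait metric(s) absent: ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  out <- do.call(rbind, lapply(definitions, function(d) {
    fitness <- quality_score(m, d)
    do.call(rbind, lapply(traits, function(tr) {
      g <- selection_gradient(unclass(m)[, tr], fitness, standardize_trait)
      data.frame(metric = tr, definition = d$name, beta = g$beta, n = g$n,
                 r_squared = g$r_squared, stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Phenotypic variance-covariance (G) matrix
#'
#' Sample covariance (denominator n-1) of the metric columns. With
#' `standardized = TRUE` (default) the metrics are z-standardized first, so
#' G is the correlation matrix — the unit-coherent companion of
#' standardized-trait selection gradients.
#'
#' @param m a [metric_matrix()].
#' @param standardized use standardized metrics (correlation matrix).
#' @param traits metric columns to include (default all).
#' @return Symmetric matrix of class `g_matrix`.
#' @export
g_matrix <- function(m, standardized = TRUE, traits = NULL) {
  x <- unclass(as.matrix(m))
  if (!is.null(traits)) x <- x[, traits, drop = FALSE]
  if (nrow(x) < 2L) {
    stop("need at least 2 samples to estimate covariances", call. = FALSE)
  }
  G <- if (standardized) stats::cor(x) else stats::cov(x)
  G <- (G + t(G)) / 2
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("G matrix is not positive semidefinite", call. = FALSE)
  }
  structure(G, class = c("g_matrix", "matrix", "array"))
}

#' Predicted response to selection (breeder's equation)
#'
#' Multiplies the trait variance-covariance matrix by the selection-gradient
#' vector: the predicted shift in every trait mean under one round of
#' selection on the quality score, accounting for trait covariances.
#'
#' @param G a [g_matrix()] (labelled square symmetric matrix).
#' @param beta named numeric vector of gradients, or the data.frame from
#'   [selection_gradients()] filtered to one definition.
#' @return Named numeric vector of predicted responses, aligned to `G`'s
#'   labels.
#' @export
predicted_response <- function(G, beta) {
  if (is.data.frame(beta)) {
    if (length(unique(beta$definition)) > 1L) {
      stop("beta mixes several quality definitions; filter to one",
           call. = FALSE)
    }
    beta <- stats::setNames(beta$beta, beta$metric)
  }
  labels <- rownames(G)
  if (is.null(labels) || is.null(names(beta))) {
    stop("G and beta must carry metric labels", call. = FALSE)
  }
  unmatched <- c(setdiff(labels, names(beta)), setdiff(names(beta), labels))
  if (length(unmatched) > 0L) {
    stop("metric labels do not match between G and beta: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  drop(unclass(G) %*% beta[labels])
}

#' Compare selection gradients across quality definitions
#'
#' One row per trait metric: the per-definition gradients, their mean and
#' their range (max - min), ordered ascending by the mean — metrics at the
#' extremes drive quality consistently, metrics with a wide range respond
#' differently depending on how quality is defined.
#'
#' @param gradients data.frame from [selection_gradients()] over at least
#'   two definitions sharing one metric set.
#' @return data.frame: `metric`, one `beta_<definition>` column per
#'   definition, `mean_beta`, `range_beta`, sorted by `mean_beta`.
#' @export
cross_quality_table <- function(gradients) {
  defs <- unique(gradients$definition)
  if (length(defs) < 2L) {
    stop("need gradients for at least two quality definitions",
         call. = FALSE)
  }
  sets <- lapply(defs, function(d) {
    sort(gradients$metric[gradients$definition == d])
  })
  if (!all(vapply(sets, identical, logical(1), sets[[1L]]))) {
    stop("definitions do not share one metric set", call. = FALSE)
  }
  mets <- sets[[1L]]
  B <- vapply(defs, function(d) {
    g <- gradients[gradients$definition == d, ]
    g$beta[match(mets, g$metric)]
  }, numeric(length(mets)))
  B <- matrix(B, nrow = length(mets),
              dimnames = list(mets, paste0("beta_", defs)))
  out <- data.frame(metric = mets, B,
                    mean_beta = rowMeans(B),
                    range_beta = apply(B, 1L, function(r) diff(range(r))),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(out$mean_beta, out$metric, method = "radix"), ]
  rownames(out) <- NULL
  out
}
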