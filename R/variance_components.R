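#' Random-effects model specification
#'
#' An ordered list of random terms, each defined by the factor columns whose
#' interaction forms its grouping factor; the residual is implied. Terms must
#' be listed coarse-to-fine along nesting chains (e.g. `Variety` before
#' `Section:Variety`) so that analysis-of-variance strata are attributed
#' correctly.
#'
#' @param terms named list: term label -> character vector of factor column
#'   names; the grouping factor is the (dropped) interaction of the columns.
#' @return An object of class `model_spec`.
#' @seealso [bn_model()] for the biomass-to-nanopaper default.
#' @export
model_spec <- function(terms) {
  if (length(terms) == 0L || is.null(names(terms)) ||
      anyDuplicated(names(terms)) || any(!nzchar(names(terms)))) {
    stop("terms must be a non-empty, uniquely named list", call. = FALSE)
  }
  if ("Residual" %in% names(terms)) {
    stop("the residual is implied; do not list it as a term", call. = FALSE)
  }
  structure(list(terms = lapply(terms, as.character)), class = "model_spec")
}

#' Biomass-to-nanopaper model structure
#'
#' The default random-terms structure for the sorghum study design. Under the
#' `"nested"` coding (default) each nanopaper duplicate is a distinct sheet
#' within its variety x section x energy sample, and strip-to-strip variation
#' is the residual stratum. Under the `"literal"` coding duplicate labels and
#' strip labels are factor levels shared across samples — the structure of
#' the model formula `(1|variety) + (1|variety:section) + (1|energy) +
#' (1|nanopaper/strip)` as written — which makes a separate
#' `Strip:Nanopaper` component estimable.
#'
#' @param coding `"nested"` or `"literal"`.
#' @return A [model_spec()].
#' @export
bn_model <- function(coding = c("nested", "literal")) {
  coding <- match.arg(coding)
  if (coding == "nested") {
    model_spec(list(
      "Variety" = "variety",
      "Section:Variety" = c("variety", "section"),
      "Energy" = "energy",
      "Nanopaper" = c("variety", "section", "energy", "nanopaper")
    ))
  } else {
    model_spec(list(
      "Variety" = "variety",
      "Section:Variety" = c("variety", "section"),
      "Energy" = "energy",
      "Nanopaper" = "nanopaper",
      "Strip:Nanopaper" = c("nanopaper", "strip")
    ))
  }
}

#' Variance component estimates
#'
#' Container for named variance estimates (one per random term plus
#' `"Residual"`). Also usable directly to wrap published component values
#' for downstream heritability arithmetic.
#'
#' @param estimates named non-negative variances including `"Residual"`.
#' @param method estimation method label (`"EMS"`, `"REML"`, `"manual"`).
#' @param raw optional untruncated estimates (may be negative for EMS).
#' @param converged,n_iterations iteration metadata.
#' @param truncated_terms terms whose negative raw estimate was set to zero.
#' @param loglik_trace restricted log-likelihood per iteration (REML only).
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(estimates, method = "manual", raw = NULL,
                                converged = TRUE, n_iterations = 0L,
                                truncated_terms = character(),
                                loglik_trace = NULL) {
  if (is.null(names(estimates)) || !"Residual" %in% names(estimates)) {
    stop("estimates must be named and include 'Residual'", call. = FALSE)
  }
  estimates <- stats::setNames(as.numeric(estimates), names(estimates))
  if (any(estimates < 0)) {
    stop("variance estimates must be non-negative (see truncate_negative)",
         call. = FALSE)
  }
  structure(
    list(
      estimates = estimates,
      std_dev = sqrt(estimates),
      method = method,
      raw = if (is.null(raw)) estimates else raw,
      converged = converged,
      n_iterations = as.integer(n_iterations),
      truncated_terms = truncated_terms,
      loglik_trace = loglik_trace
    ),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (", x$method, ")\n", sep = "")
  print(data.frame(Variance = round(x$estimates, 4),
                   Std.Dev = round(x$std_dev, 4)))
  if (length(x$truncated_terms) > 0L) {
    cat("truncated to zero:", paste(x$truncated_terms, collapse = ", "), "\n")
  }
  if (x$method == "REML") {
    cat("converged:", x$converged, "after", x$n_iterations, "iterations\n")
  }
  invisible(x)
}

#' Truncate negative variance estimates to zero
#'
#' @param components a [variance_components()] object, or a plain named
#'   numeric vector.
#' @return The same type with negative entries set to 0; truncated terms are
#'   recorded (in `$truncated_terms`, or attribute `"truncated"` for a
#'   vector).
#' @export
truncate_negative <- function(components) {
  if (inherits(components, "variance_components")) {
    raw <- components$raw
    flagged <- names(raw)[raw < 0]
    variance_components(
      pmax(raw, 0), method = components$method, raw = raw,
      converged = components$converged,
      n_iterations = components$n_iterations,
      truncated_terms = union(components$truncated_terms, flagged),
      loglik_trace = components$loglik_trace
    )
  } else {
    flagged <- names(components)[components < 0]
    structure(pmax(components, 0), truncated = flagged)
  }
}

# ---- internal machinery -----------------------------------------------

# Filter one metric, sort rows canonically, return factor frame + response.
metric_slice <- function(table, model, metric = NULL) {
  df <- as.data.frame(table)
  if (!is.null(metric) && "metric" %in% names(df)) {
    df <- df[df$metric == metric, , drop = FALSE]
    if (nrow(df) == 0L) stop("metric not found: ", metric, call. = FALSE)
  }
  cols <- unique(unlist(model$terms))
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("model terms reference absent column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[!is.na(df$value), , drop = FALSE]
  if (nrow(df) == 0L) stop("no observed values", call. = FALSE)
  df <- df[do.call(order, df[cols]), , drop = FALSE]
  list(factors = df[cols], y = df$value, n = nrow(df))
}

model_factors <- function(model, factor_frame) {
  lapply(model$terms, function(cols) {
    interaction(factor_frame[cols], drop = TRUE, sep = ":", lex.order = TRUE)
  })
}

#' Prepare the expected-mean-squares system for a design
#'
#' Builds, once per design, the sequential analysis-of-variance strata
#' (orthonormal increment bases) and the expected-mean-squares coefficient
#' matrix, so repeated fits on the same layout (bootstrap, Monte-Carlo) are
#' cheap. Requires a balanced layout: every cell of the full crossing of the
#' model's grouping factors must have the same count.
#'
#' @param table an [observation_table()] (or data.frame with the model's
#'   factor columns and a `value` column).
#' @param model a [model_spec()].
#' @param metric metric to fit (required when the table holds several).
#' @return An object of class `ems_design` for [ems_refit()].
#' @export
ems_prepare <- function(table, model, metric = NULL) {
  sl <- metric_slice(table, model, metric)
  n <- sl$n
  facs <- model_factors(model, sl$factors)
  # balance check on the full crossing
  cross <- interaction(sl$factors, drop = TRUE)
  counts <- tabulate(cross)
  full_cells <- prod(vapply(sl$factors, function(x) length(unique(x)), 1L))
  if (length(counts) < full_cells || length(unique(counts)) != 1L) {
    stop("layout is not balanced for this metric; use reml_components()",
         call. = FALSE)
  }
  basis <- matrix(1 / sqrt(n), n, 1L)
  strata <- list()
  Zs <- list()
  for (nm in names(facs)) {
    f <- facs[[nm]]
    Z <- matrix(0, n, nlevels(f))
    Z[cbind(seq_len(n), as.integer(f))] <- 1
    Zs[[nm]] <- Z
    R <- Z - basis %*% crossprod(basis, Z)
    sv <- svd(R)
    keep <- sv$d > 1e-8 * max(sv$d, 1)
    df <- sum(keep)
    if (df == 0L) {
      stop("term '", nm, "' adds no degrees of freedom ",
           "(confounded with earlier terms)", call. = FALSE)
    }
    U <- sv$u[, keep, drop = FALSE]
    strata[[nm]] <- list(U = U, df = df)
    basis <- cbind(basis, U)
  }
  df_e <- n - ncol(basis)
  if (df_e <= 0L) {
    stop("singular residual stratum: no degrees of freedom left for the ",
         "residual (drop the finest term)", call. = FALSE)
  }
  k <- length(strata)
  terms <- names(facs)
  C <- matrix(0, k + 1L, k + 1L,
              dimnames = list(c(terms, "Residual"), c(terms, "Residual")))
  for (i in seq_len(k)) {
    Ui <- strata[[i]]$U
    for (t in seq_len(k)) {
      C[i, t] <- sum(crossprod(Ui, Zs[[t]])^2) / strata[[i]]$df
    }
    C[i, k + 1L] <- 1
  }
  # residual-stratum coefficients by complement (exactly 0 for balanced
  # layouts since every Z lies in the fitted span; kept for numerical audit)
  for (t in seq_len(k)) {
    tot <- sum(Zs[[t]]^2)
    fitted_norm <- sum(crossprod(basis, Zs[[t]])^2)
    C[k + 1L, t] <- max(tot - fitted_norm, 0) / df_e
  }
  C[k + 1L, k + 1L] <- 1
  structure(
    list(model = model, metric = metric, strata = strata, C = C,
         df = c(vapply(strata, `[[`, 1L, "df"), Residual = df_e), n = n,
         key = do.call(paste, c(sl$factors, sep = "\r"))),
    class = "ems_design"
  )
}

#' Refit the expected-mean-squares system to a response
#'
#' Fast path over a prepared [ems_prepare()] design: computes the ANOVA mean
#' squares of `y` and solves the expected-mean-squares linear system. `y`
#' must follow the design's canonical row order — pass an observation table
#' to have rows matched by key.
#'
#' @param prep an `ems_design`.
#' @param y numeric response in canonical order, or an [observation_table()]
#'   with the same layout.
#' @param metric metric name when `y` is a table.
#' @return A [variance_components()] (negatives truncated, raw retained).
#' @export
ems_refit <- function(prep, y, metric = NULL) {
  if (is.data.frame(y)) {
    sl <- metric_slice(y, prep$model, metric %||% prep$metric)
    if (!identical(do.call(paste, c(sl$factors, sep = "\r")), prep$key)) {
      stop("table layout does not match the prepared design", call. = FALSE)
    }
    y <- sl$y
  }
  if (length(y) != prep$n) {
    stop("response length does not match the prepared design", call. = FALSE)
  }
  k <- length(prep$strata)
  ms <- numeric(k + 1L)
  ss_model <- 0
  for (i in seq_len(k)) {
    ssi <- sum(crossprod(prep$strata[[i]]$U, y)^2)
    ms[i] <- ssi / prep$strata[[i]]$df
    ss_model <- ss_model + ssi
  }
  ss_tot <- sum(y^2) - sum(y)^2 / prep$n
  ms[k + 1L] <- max(ss_tot - ss_model, 0) / prep$df[["Residual"]]
  raw <- solve(prep$C, ms)
  names(raw) <- rownames(prep$C)
  # snap solver noise to exact zero (relative to the mean-square scale)
  raw[abs(raw) < 1e-12 * max(abs(ms), .Machine$double.xmin)] <- 0
  truncated <- names(raw)[raw < 0]
  variance_components(pmax(raw, 0), method = "EMS", raw = raw,
                      truncated_terms = truncated)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected-mean-squares variance component estimation
#'
#' Method-of-moments estimator for balanced layouts: equates each sequential
#' ANOVA mean square to its expectation (a known linear combination of the
#' component variances) and solves the resulting linear system,
#' stratum-by-stratum coefficients being computed exactly from the design's
#' indicator matrices. Negative solutions are truncated to zero and flagged;
#' the untruncated solutions are kept in `$raw`.
#'
#' @param table an [observation_table()] (or compatible data.frame).
#' @param model a [model_spec()]; default [bn_model()] nested coding.
#' @param metric metric name (required for multi-metric tables).
#' @return A [variance_components()] with `method = "EMS"`.
#' @export
ems_components <- function(table, model = bn_model(), metric = NULL) {
  ems_refit(ems_prepare(table, model, metric),
            metric_slice(table, model, metric)$y)
}

#' EM-REML variance component estimation
#'
#' Restricted maximum likelihood for the Gaussian random-intercepts model,
#' fitted by the classical EM algorithm (each sweep updates every component
#' from the current BLUPs and their conditional variances). The restricted
#' log-likelihood is non-decreasing over iterations and is recorded in
#' `$loglik_trace`; components stay non-negative. Works on unbalanced
#' layouts, where the expected-mean-squares estimator does not apply.
#'
#' @param table an [observation_table()] (or compatible data.frame).
#' @param model a [model_spec()].
#' @param metric metric name (required for multi-metric tables).
#' @param tol convergence tolerance on the largest absolute component change
#'   between sweeps.
#' @param max_iter iteration cap; `converged` reports whether `tol` was met.
#' @return A [variance_components()] with `method = "REML"`.
#' @export
reml_components <- function(table, model = bn_model(), metric = NULL,
                            tol = 1e-8, max_iter = 500L) {
  sl <- metric_slice(table, model, metric)
  n <- sl$n
  if (n < 2L) {
    stop("singular residual stratum: need at least 2 observations",
         call. = FALSE)
  }
  facs <- model_factors(model, sl$factors)
  for (nm in names(facs)) {
    if (nlevels(facs[[nm]]) >= n) {
      stop("term '", nm, "' has one level per observation and is ",
           "confounded with the residual", call. = FALSE)
    }
  }
  y <- sl$y
  terms <- names(facs)
  k <- length(terms)
  vy <- stats::var(y)
  if (vy == 0) {
    return(variance_components(
      stats::setNames(numeric(k + 1L), c(terms, "Residual")),
      method = "REML", converged = TRUE, n_iterations = 0L,
      loglik_trace = numeric()
    ))
  }
  # EM over Henderson's mixed-model equations: the coefficient matrix is
  # (1 + total levels) square, so each sweep is cheap even for thousands of
  # iterations. Updates: sigma_t <- (u_t'u_t + sigma_e^2 tr(Cinv_tt)) / q_t,
  # sigma_e <- y'(y - X b - Z u) / (n - 1); both are the classical EM steps,
  # so the restricted likelihood never decreases.
  Z <- lapply(facs, function(f) {
    m <- matrix(0, n, nlevels(f))
    m[cbind(seq_len(n), as.integer(f))] <- 1
    m
  })
  q <- vapply(Z, ncol, 1L)
  Zall <- do.call(cbind, Z)
  blk <- rep(seq_len(k), q)                 # term of each u column
  W <- cbind(1, Zall)                       # [X Z], X = intercept
  WtW <- crossprod(W)
  Wty <- drop(crossprod(W, y))
  yty <- sum(y^2)
  sigma <- rep(vy / (k + 1L), k + 1L)       # terms then residual
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    se <- sigma[k + 1L]
    active <- which(sigma[seq_len(k)] > 0)
    keep <- c(1L, 1L + which(blk %in% active))
    Cmat <- WtW[keep, keep, drop = FALSE]
    ridge <- se / sigma[blk[keep[-1L] - 1L]]
    diag(Cmat)[-1L] <- diag(Cmat)[-1L] + ridge
    R <- chol(Cmat)
    Cinv <- chol2inv(R)
    theta <- drop(Cinv %*% Wty[keep])
    # restricted log-likelihood (up to an additive constant):
    # -2l = (n-q_act-1) log se + sum q_t log sigma_t + log|C| + y'Py
    q_act <- length(keep) - 1L
    yPy <- (yty - sum(theta * Wty[keep])) / se
    logdetC <- 2 * sum(log(diag(R)))
    trace <- c(trace, -0.5 * ((n - q_act - 1L) * log(se) +
                                sum(q[active] * log(sigma[active])) +
                                logdetC + yPy))
    new_sigma <- sigma
    for (t in active) {
      idx <- 1L + which(blk[keep[-1L] - 1L] == t)
      ut <- theta[idx]
      new_sigma[t] <- (sum(ut^2) + se * sum(diag(Cinv)[idx])) / q[t]
    }
    new_sigma[k + 1L] <- (yty - sum(theta * Wty[keep])) / (n - 1L)
    delta <- max(abs(new_sigma - sigma))
    sigma <- pmax(new_sigma, 0)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  variance_components(
    stats::setNames(sigma, c(terms, "Residual")),
    method = "REML", converged = converged, n_iterations = iter,
    loglik_trace = trace
  )
}
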