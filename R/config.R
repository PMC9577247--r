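#' Default correlated metric population
#'
#' A plausible covariance specification for the sample-level metric matrix of
#' the study system: the ten fibre-morphology metrics reported by automated
#' fibre analysis plus the three quality-bearing metrics (nanopaper tensile
#' index, sedimentation aspect ratio, water retention value). The correlation
#' structure is built from a three-factor loading model (a fibre length /
#' coarseness factor, a fines factor, and a consolidation-quality factor), so
#' it is positive definite by construction; means and spreads are on the
#' scales typical for cellulose nanofibre characterisation.
#'
#' @param n_samples number of samples (default 36, the
#'   variety x section x energy cells of [default_design()]).
#' @param seed integer seed.
#' @param sample_ids optional sample labels (default: [sample_ids()] of the
#'   default design when `n_samples` is 36).
#' @return A [metric_cov_spec()].
#' @export
default_metric_cov_spec <- function(n_samples = 36L, seed = 1L,
                                    sample_ids = NULL) {
  metrics <- c("fibre_L", "fibre_coarse", "fibre_cont", "fine_cont",
               "fine_n", "fibre_L.L", "fibre_A.L", "fine_cont.A",
               "fine_cont.L", "fine_cont.L.L",
               "tensile_index", "sed_aspect_ratio", "wrv")
  L <- rbind(
    fibre_L          = c(0.70,  0.00,  0.20),
    fibre_coarse     = c(0.60,  0.00, -0.40),
    fibre_cont       = c(0.30,  0.00,  0.55),
    fine_cont        = c(-0.20, 0.75,  0.00),
    fine_n           = c(0.00,  0.60,  0.00),
    fibre_L.L        = c(0.65,  0.00,  0.00),
    fibre_A.L        = c(0.55,  0.00,  0.00),
    fine_cont.A      = c(-0.10, 0.70,  0.00),
    fine_cont.L      = c(0.00,  0.70,  0.00),
    fine_cont.L.L    = c(0.00,  0.65,  0.00),
    tensile_index    = c(0.35,  0.00,  0.60),
    sed_aspect_ratio = c(0.30,  0.35,  0.40),
    wrv              = c(0.00,  0.40,  0.50)
  )
  corr <- tcrossprod(L) + diag(1 - rowSums(L^2))
  sds <- c(60, 0.04, 8, 10, 12, 50, 6, 9, 9, 8, 18, 25, 2.5)
  means <- c(480, 0.20, 35, 60, 55, 300, 28, 45, 52, 40, 60, 95, 10)
  sigma <- corr * tcrossprod(sds)
  if (is.null(sample_ids) && n_samples == 36L) {
    sample_ids <- sample_ids(default_design())
  }
  metric_cov_spec(metrics, means, sigma, n_samples, seed,
                  sample_ids = sample_ids)
}

#' Default quality definitions
#'
#' `Q1`: the nanopaper tensile index alone — quality as sheet strength.
#' `Q5`: equal-weight combination of the sedimentation aspect ratio and the
#' water retention value — quality as nanofibre-water interaction.
#'
#' @return Named list of [quality_definition()] objects.
#' @export
default_quality_definitions <- function() {
  list(
    Q1 = quality_definition("Q1", "tensile_index"),
    Q5 = quality_definition("Q5", c("sed_aspect_ratio", "wrv"))
  )
}

parse_quality_block <- function(q) {
  quality_definition(
    name = q$name,
    metrics = unlist(q$metrics),
    weights = if (!is.null(q$weights)) unlist(q$weights),
    directions = if (!is.null(q$directions)) unlist(q$directions)
  )
}

#' Read a run configuration
#'
#' Parses a YAML run configuration: exactly one of `input:` (paths to
#' existing CSVs) or `generator:` (a synthetic-data specification) must be
#' present; optional blocks set the model coding, genetic terms, clustering
#' options, quality definitions, seed and output directory.
#'
#' @param path YAML file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  has_input <- !is.null(cfg$input)
  has_gen <- !is.null(cfg$generator)
  if (has_input == has_gen) {
    stop("config must contain exactly one of 'input' or 'generator'",
         call. = FALSE)
  }
  seed <- as.integer(cfg$seed %||% 1L)
  coding <- cfg$model$coding %||% "nested"
  if (!coding %in% c("nested", "literal")) {
    stop("model coding must be 'nested' or 'literal'", call. = FALSE)
  }
  generator <- NULL
  if (has_gen) {
    g <- cfg$generator
    comps <- unlist(g$components)
    if (is.null(comps)) stop("generator needs components", call. = FALSE)
    generator <- generative_spec(
      design = default_design(),
      grand_mean = g$grand_mean %||% 0,
      components = comps,
      seed = as.integer(g$seed %||% seed),
      metric = g$metric %||% "tensile_index"
    )
  }
  quality <- if (!is.null(cfg$quality)) {
    defs <- lapply(cfg$quality, parse_quality_block)
    stats::setNames(defs, vapply(defs, `[[`, "", "name"))
  } else {
    default_quality_definitions()
  }
  clustering <- list(
    samples = list(
      measure = cfg$clustering$samples$measure %||% "euclidean",
      linkage = cfg$clustering$samples$linkage %||% "ward",
      k = as.integer(cfg$clustering$samples$k %||% 4L)
    ),
    metrics = list(
      measure = cfg$clustering$metrics$measure %||% "correlation",
      linkage = cfg$clustering$metrics$linkage %||% "average",
      k = as.integer(cfg$clustering$metrics$k %||% 3L)
    )
  )
  structure(
    list(
      input = cfg$input,
      generator = generator,
      coding = coding,
      genetic_terms = unlist(cfg$genetic_terms) %||%
        c("Variety", "Section:Variety"),
      clustering = clustering,
      quality = quality,
      seed = seed,
      output_dir = cfg$output_dir %||% "results"
    ),
    class = "run_config"
  )
}
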