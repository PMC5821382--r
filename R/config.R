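#' @title Experiment configuration
#' @name lv_config
NULL

# shorthand model names accepted in configuration files
MODEL_SHORTHANDS <- list(
  may = c("may_directed", "may_mixture"),
  mutualism = c("unstructured_paired", "mutualism"),
  competition = c("unstructured_paired", "competition"),
  predation = c("unstructured_paired", "predation"),
  cascade = c("cascade", "predation"),
  niche = c("niche", "predation"),
  nested_hierarchy = c("nested_hierarchy", "predation")
)

#' Growth-rate specification
#'
#' Describes how the intrinsic growth-rate vector `r` is chosen:
#' * `"structural"`: the deterministic mean structural vector, computed
#'   from the mean interaction matrix so that the mean-field equilibrium is
#'   the all-ones vector (most favourable to feasibility);
#' * `"iid_gaussian"`: i.i.d. `N(mean, sd)` entries;
#' * `"iid_uniform"`: i.i.d. `U(min, max)` entries;
#' * `"fixed"`: an explicit vector.
#'
#' @param kind one of `"structural"`, `"iid_gaussian"`, `"iid_uniform"`,
#'   `"fixed"`.
#' @param mean,sd moments for the Gaussian kind (defaults 1 and 0.5).
#' @param min,max bounds for the uniform kind (defaults 0.5 and 1.5).
#' @param values explicit vector for the fixed kind.
#' @return an `lv_rates` specification.
#' @export
growth_rate_spec <- function(kind = c("structural", "iid_gaussian",
                                      "iid_uniform", "fixed"),
                             mean = 1, sd = 0.5, min = 0.5, max = 1.5,
                             values = NULL) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    structural = list(kind = kind),
    iid_gaussian = {
      if (!is.finite(mean) || !is.finite(sd) || sd < 0)
        stop_param("iid_gaussian rates need finite `mean` and `sd` >= 0")
      list(kind = kind, mean = mean, sd = sd)
    },
    iid_uniform = {
      if (!is.finite(min) || !is.finite(max) || max < min)
        stop_param("iid_uniform rates need finite bounds with max >= min")
      list(kind = kind, min = min, max = max)
    },
    fixed = {
      if (is.null(values) || !is.numeric(values))
        stop_param("fixed rates need a numeric `values` vector")
      list(kind = kind, values = as.numeric(values))
    }
  )
  structure(spec, class = "lv_rates")
}

#' Draw a growth-rate vector from a specification
#'
#' Structural rates are deterministic and require the mean interaction
#' matrix; supply it as `A_bar` together with the scaling parameters.
#'
#' @param spec an [growth_rate_spec()].
#' @param S species richness.
#' @param A_bar,theta,C,delta needed for `kind = "structural"`.
#' @return a length-`S` numeric vector.
#' @export
draw_growth_rates <- function(spec, S, A_bar = NULL, theta = -1,
                              C = NULL, delta = NULL) {
  stopifnot(inherits(spec, "lv_rates"))
  switch(spec$kind,
    structural = {
      if (is.null(A_bar)) stop_param("structural rates require `A_bar`")
      structural_growth_rates(A_bar, theta, C, S, delta)
    },
    iid_gaussian = stats::rnorm(S, spec$mean, spec$sd),
    iid_uniform = stats::runif(S, spec$min, spec$max),
    fixed = {
      if (length(spec$values) != S)
        stop_param("fixed rates have length ", length(spec$values),
                   " but S = ", S)
      spec$values
    }
  )
}

# theoretical mean/variance of the growth-rate distribution (for the
# moderate-regime moments); structural rates are deterministic per species
# so only the i.i.d. kinds have population moments.
rates_moments <- function(spec) {
  switch(spec$kind,
    iid_gaussian = list(mean = spec$mean, var = spec$sd^2),
    iid_uniform = list(mean = (spec$min + spec$max) / 2,
                       var = (spec$max - spec$min)^2 / 12),
    stop_param("population moments are defined for i.i.d. rate kinds only")
  )
}

#' Community experiment configuration
#'
#' Bundles every parameter of a Monte-Carlo feasibility experiment:
#' species richness `S`, connectance parameter `C`, scaling exponent
#' `delta`, self-regulation `theta`, interaction strength `sigma`, the
#' network model, the interaction type, the growth-rate specification and
#' the number `M` of Monte-Carlo trials for the mean structural vector.
#'
#' The defaults mirror the baseline simulation conditions of the study
#' design: `C = 0.25`, `sigma = 0.4`, `theta = -1`, `M = 200`.
#'
#' @param model network/interaction model: one of `"may"`, `"mutualism"`,
#'   `"competition"`, `"predation"`, `"cascade"`, `"niche"`,
#'   `"nested_hierarchy"` (shorthand), or an explicit topology tag.
#' @param S species richness.
#' @param C connectance parameter in (0, 1).
#' @param delta interaction-strength scaling exponent in \[0, 1\]; may be
#'   given as a decimal string (e.g. `"0.5"`), which is parsed exactly.
#' @param theta intraspecific competition coefficient (negative).
#' @param sigma interaction strength standard deviation (>= 0).
#' @param rates an [growth_rate_spec()] or its kind as a string.
#' @param interaction optional explicit interaction type; inferred from
#'   `model` shorthands.
#' @param M Monte-Carlo trials for the mean structural vector.
#' @return an `lv_config`.
#' @examples
#' cfg <- community_config("may", S = 50, delta = 0.5)
#' @export
community_config <- function(model, S, C = 0.25, delta = 0.5, theta = -1,
                             sigma = 0.4, rates = "structural",
                             interaction = NULL, M = 200) {
  if (is.character(delta)) delta <- as.numeric(delta)
  if (is.character(rates)) rates <- growth_rate_spec(rates)
  if (!inherits(rates, "lv_rates")) stop_param("`rates` must be a growth_rate_spec")
  if (model %in% names(MODEL_SHORTHANDS)) {
    sh <- MODEL_SHORTHANDS[[model]]
    topo_model <- sh[1]
    if (is.null(interaction)) interaction <- sh[2]
  } else if (model %in% TOPOLOGY_MODELS) {
    topo_model <- model
    if (is.null(interaction))
      interaction <- switch(model,
        may_directed = "may_mixture",
        unstructured_paired = "predation",
        "predation")
  } else {
    stop_param("unknown model '", model, "'")
  }
  check_SC(S, C)
  if (!is.numeric(delta) || is.na(delta) || delta < 0 || delta > 1)
    stop_param("`delta` must lie in [0, 1]")
  if (!is.numeric(theta) || theta >= 0) stop_param("`theta` must be negative")
  if (!is.numeric(sigma) || sigma < 0) stop_param("`sigma` must be >= 0")
  if (!is.numeric(M) || M < 1) stop_param("`M` must be >= 1")
  if (!interaction %in% INTERACTION_TYPES)
    stop_param("unknown interaction type '", interaction, "'")
  ok <- switch(interaction,
    may_mixture = topo_model == "may_directed",
    mutualism = ,
    competition = topo_model == "unstructured_paired",
    predation = topo_model %in% c("unstructured_paired", STRUCTURED_MODELS)
  )
  if (!ok)
    stop_param("interaction '", interaction, "' is incompatible with model '",
               topo_model, "'")
  structure(
    list(model = topo_model, interaction = interaction,
         S = as.integer(S), C = C, delta = delta, theta = theta,
         sigma = sigma, rates = rates, M = as.integer(M)),
    class = "lv_config"
  )
}

#' Draw the topology described by a configuration
#'
#' @param config an `lv_config`.
#' @return an `lv_topology`.
#' @export
generate_topology <- function(config) {
  stopifnot(inherits(config, "lv_config"))
  switch(config$model,
    may_directed = generate_unstructured(config$S, config$C, "directed"),
    unstructured_paired = generate_unstructured(config$S, config$C, "paired"),
    cascade = generate_cascade(config$S, config$C),
    niche = generate_niche(config$S, config$C),
    nested_hierarchy = generate_nested_hierarchy(config$S, config$C)
  )
}

#' Load a configuration from YAML or JSON
#'
#' The format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#' Recognised keys: `model`, `interaction`, `S`, `C`, `sigma`, `theta`,
#' `delta` (decimal string recommended), `rates` (a kind string or a
#' mapping with `kind` and its parameters), `M`, `n_reps`, `seed`. Unknown
#' keys and out-of-domain values are rejected with a message listing every
#' violation. Defaults: `M = 200` structural-vector trials and
#' `n_reps = 1000` Monte-Carlo replicates.
#'
#' @param path configuration file.
#' @return an `lv_config`; the replicate count and seed (when given) are
#'   attached as attributes `n_reps` and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_param("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop_param("unsupported config format '.", ext, "' (use YAML or JSON)")
  }
  allowed <- c("model", "interaction", "S", "C", "sigma", "theta", "delta",
               "rates", "M", "n_reps", "seed")
  problems <- character(0)
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown) > 0)
    problems <- c(problems, paste0("unknown key(s): ", toString(unknown)))
  required <- c("model", "S", "sigma", "delta")
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0)
    problems <- c(problems, paste0("missing required key(s): ", toString(missing)))
  if (!is.null(doc$delta)) {
    dval <- suppressWarnings(as.numeric(doc$delta))
    if (is.na(dval) || dval < 0 || dval > 1)
      problems <- c(problems, paste0("delta '", doc$delta, "' outside [0, 1]"))
  }
  if (!is.null(doc$C) && (!is.numeric(doc$C) || doc$C <= 0 || doc$C >= 1))
    problems <- c(problems, "C must lie strictly between 0 and 1")
  if (!is.null(doc$theta) && (!is.numeric(doc$theta) || doc$theta >= 0))
    problems <- c(problems, "theta must be negative")
  if (!is.null(doc$sigma) && (!is.numeric(doc$sigma) || doc$sigma < 0))
    problems <- c(problems, "sigma must be non-negative")
  if (!is.null(doc$S) && (!is.numeric(doc$S) || doc$S < 2))
    problems <- c(problems, "S must be an integer >= 2")
  if (length(problems) > 0)
    stop_param("invalid configuration ", path, ":\n  - ",
               paste(problems, collapse = "\n  - "))

  rates <- doc$rates %||% "structural"
  if (is.list(rates)) rates <- do.call(growth_rate_spec, rates)
  cfg <- community_config(
    model = doc$model, S = doc$S,
    C = doc$C %||% 0.25, delta = doc$delta, theta = doc$theta %||% -1,
    sigma = doc$sigma, rates = rates, interaction = doc$interaction,
    M = doc$M %||% 200
  )
  attr(cfg, "n_reps") <- as.integer(doc$n_reps %||% 1000)
  if (!is.null(doc$seed)) attr(cfg, "seed") <- as.integer(doc$seed)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lv_config <- function(x, ...) {
  cat(sprintf(paste0("<lv_config> %s / %s, S = %d, C = %g, delta = %g (%s), ",
                     "theta = %g, sigma = %g, rates = %s\n"),
              x$model, x$interaction, x$S, x$C, x$delta,
              classify_regime(x$delta), x$theta, x$sigma, x$rates$kind))
  invisible(x)
}
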