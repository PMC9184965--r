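# Strict YAML/JSON configuration handling.

read_config_file <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

check_keys <- function(cfg, allowed, required, what) {
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop(sprintf("unknown key(s) in %s config: %s", what,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    stop(sprintf("missing key(s) in %s config: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a landscape-model configuration
#'
#' Schema (strict; unknown keys are rejected): `family` (catalogue name),
#' `theta` (numeric vector), `metric` (matrix rows or the string
#' `"identity"`), `sigma` (>= 0), optional `domain_box`
#' (`lower`/`upper`).
#'
#' @param path YAML or JSON file
#' @return a `landscape_model`
#' @export
load_model_config <- function(path) {
  cfg <- read_config_file(path)
  check_keys(cfg, c("family", "theta", "metric", "sigma", "domain_box"),
             c("family"), "model")
  opts <- list()
  if (!is.null(cfg$domain_box)) {
    opts$domain_box <- list(lower = as.numeric(cfg$domain_box$lower),
                            upper = as.numeric(cfg$domain_box$upper))
  }
  fam <- make_family(cfg$family, opts)
  metric <- if (is.null(cfg$metric) ||
                identical(cfg$metric, "identity")) {
    identity_metric(2L)
  } else {
    M <- cfg$metric
    if (is.list(M)) M <- do.call(rbind, M)
    riemannian_metric(matrix(as.numeric(M), 2L, 2L))
  }
  theta <- if (is.null(cfg$theta)) numeric(fam$n_params)
           else as.numeric(cfg$theta)
  sigma <- if (is.null(cfg$sigma)) 0 else as.numeric(cfg$sigma)
  landscape_model(fam, theta, metric, sigma)
}

#' Save a landscape-model configuration (YAML)
#'
#' Round-trips losslessly through [load_model_config()].
#' @param model a `landscape_model`
#' @param path output file (`.yaml`/`.yml` or `.json`)
#' @export
save_model_config <- function(model, path) {
  cfg <- list(
    family = model$family$name,
    theta = model$theta,
    metric = if (model$metric$is_constant &&
                 identical(unname(model$metric$matrix), diag(2))) "identity"
             else apply(model$metric$matrix, 1L, as.numeric,
                        simplify = FALSE),
    sigma = model$sigma,
    domain_box = model$family$domain_box)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

schedule_from_config <- function(cfg) {
  conds <- lapply(cfg$conditions, function(cc) {
    th <- cc$thetas
    if (is.list(th)) th <- do.call(rbind, th)
    signal_path(as.numeric(cc$t_grid), matrix(as.numeric(th),
                                              nrow = length(cc$t_grid)))
  })
  refs <- if (!is.null(cfg$fate_refs)) {
    lapply(cfg$fate_refs, as.numeric)
  } else NULL
  signal_schedule(
    conds,
    t_obs = as.numeric(cfg$t_obs),
    n_cells = if (is.null(cfg$n_cells)) 100L else as.integer(cfg$n_cells),
    x0 = list(point = as.numeric(cfg$x0$point),
              sd = if (is.null(cfg$x0$sd)) 0 else as.numeric(cfg$x0$sd)),
    fate_refs = refs,
    dt = if (is.null(cfg$dt)) 0.01 else as.numeric(cfg$dt))
}

#' Load a simulation configuration
#'
#' Schema: `model` (inline model config or a path), `conditions` (named
#' list, each with `t_grid` and `thetas`), `t_obs`, `n_cells`, `x0`
#' (`point`, optional `sd`), optional `fate_refs`, `dt`, `sigma`.
#'
#' @param path YAML or JSON file
#' @return list with `model` and `schedule`
#' @export
load_simulate_config <- function(path) {
  cfg <- read_config_file(path)
  check_keys(cfg, c("model", "conditions", "t_obs", "n_cells", "x0",
                    "fate_refs", "dt", "sigma"),
             c("model", "conditions", "t_obs", "x0"), "simulate")
  model <- if (is.character(cfg$model)) {
    load_model_config(cfg$model)
  } else {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(cfg$model, tmp, auto_unbox = TRUE, digits = NA)
    load_model_config(tmp)
  }
  if (!is.null(cfg$sigma)) {
    model <- landscape_model(model$family, model$theta, model$metric,
                             as.numeric(cfg$sigma))
  }
  list(model = model, schedule = schedule_from_config(cfg))
}
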