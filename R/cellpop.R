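# Population simulation under signal schedules, fate calling, and
# synthetic fate-proportion datasets.

#' Define a signal schedule for population simulation
#'
#' A schedule bundles one or more named experimental conditions (each a
#' [signal_path()] describing how the signals move the unfolding
#' parameters over time), the observation times at which fates are
#' scored, the number of cells per condition, and the initial-state rule.
#'
#' Fate labels: if `fate_refs` is supplied (a named list of phase points),
#' the attractor a cell's basin call converges to is labelled by the
#' nearest reference point. This keeps fate keys stable across conditions,
#' times and candidate parameter values, which the ABC fitting layer
#' relies on. Without `fate_refs`, attractors are labelled `f1`, `f2`, ...
#' in order of position (x, then y).
#'
#' @param conditions named list of `signal_path` objects
#' @param t_obs observation times (within each path's range)
#' @param n_cells cells per condition (>= 0)
#' @param x0 initial-state rule: list with `point` (phase point) and
#'   optional `sd` (Gaussian ball radius; 0 = deterministic start)
#' @param fate_refs optional named list of reference phase points
#' @param dt Euler--Maruyama step used for the population simulation
#' @return an object of class `signal_schedule`
#' @export
signal_schedule <- function(conditions, t_obs, n_cells = 100L,
                            x0 = list(point = c(0, 0), sd = 0),
                            fate_refs = NULL, dt = 0.01) {
  stopifnot(is.list(conditions), length(conditions) >= 1L)
  if (is.null(names(conditions)) || any(names(conditions) == "")) {
    names(conditions) <- paste0("cond", seq_along(conditions))
  }
  for (p in conditions) stopifnot(inherits(p, "signal_path"))
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  t_max <- min(vapply(conditions, function(p) max(p$t_grid), numeric(1)))
  if (any(t_obs > t_max + 1e-9) || any(t_obs < 0)) {
    stop("t_obs must lie within every condition's time range", call. = FALSE)
  }
  structure(list(conditions = conditions, t_obs = sort(t_obs),
                 n_cells = as.integer(n_cells), x0 = x0,
                 fate_refs = fate_refs, dt = dt),
            class = "signal_schedule")
}

new_fate_table <- function(df, metadata = list()) {
  structure(df, metadata = metadata, class = c("fate_table", "data.frame"))
}

#' @export
print.fate_table <- function(x, ...) {
  cat(sprintf("<fate_table: %d rows, %d condition(s)>\n", nrow(x),
              length(unique(x$condition))))
  print.data.frame(x, ...)
  invisible(x)
}

# label the attractor a converged state belongs to
fate_label_for <- function(pos, rest_points, fate_refs) {
  if (!is.null(fate_refs)) {
    d <- vapply(fate_refs, function(p) sqrt(sum((p - pos)^2)), numeric(1))
    return(names(fate_refs)[which.min(d)])
  }
  atts <- rest_points[rest_points$kind == "attractor", , drop = FALSE]
  atts <- atts[order(atts$x, atts$y), , drop = FALSE]
  d <- sqrt((atts$x - pos[1])^2 + (atts$y - pos[2])^2)
  paste0("f", which.min(d))
}

#' Simulate a population of cells through a landscape family
#'
#' Runs `n_cells` independent noisy gradient trajectories per condition
#' (Euler--Maruyama, all driven by streams derived deterministically from
#' the master seed) and scores each cell's fate at every observation time.
#' A cell's fate is the basin of attraction its current state relaxes to
#' under the landscape frozen at the instantaneous parameters
#' \eqn{\theta(t_{obs})}; cells that fail to relax onto an attractor are
#' reported as `undecided`, never dropped.
#'
#' @param model a `landscape_model` (its `sigma` sets the noise amplitude
#'   unless `sigma` is given)
#' @param schedule a `signal_schedule`
#' @param sigma optional noise-amplitude override
#' @param seed master integer seed
#' @return a `fate_table`: columns `condition`, `time`, `fate`, `count`,
#'   `proportion`, with per-run metadata attached
#' @export
simulate_population <- function(model, schedule, sigma = NULL, seed = 1L) {
  if (!is.null(sigma)) {
    model <- landscape_model(model$family, model$theta, model$metric, sigma)
  }
  if (model$sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  conds <- names(schedule$conditions)
  acc <- list(condition = character(0), time = numeric(0),
              fate = character(0), count = integer(0))
  rp_cache <- new.env(hash = TRUE)
  # per-condition streams derived from the master seed by a fixed affine
  # hash so conditions are independent and reproducible
  cond_seed <- (as.integer(seed) + 7919L * seq_along(conds)) %% .Machine$integer.max
  for (ci in seq_along(conds)) {
    path <- schedule$conditions[[ci]]
    n <- schedule$n_cells
    if (n == 0L) next
    obs_states <- with_seed(cond_seed[ci], {
      sd0 <- if (is.null(schedule$x0$sd)) 0 else schedule$x0$sd
      X0 <- matrix(rep(schedule$x0$point, each = n), n, 2L) +
        matrix(stats::rnorm(2L * n, sd = sd0), n, 2L)
      sde_population(model, X0, path, schedule$t_obs, schedule$dt)
    })
    for (ti in seq_along(schedule$t_obs)) {
      t_o <- schedule$t_obs[ti]
      th <- theta_at(path, t_o)
      rp_key <- paste(signif(th, 12), collapse = "|")
      rp <- rp_cache[[rp_key]]
      if (is.null(rp)) {
        rp <- tryCatch(find_rest_points(model, th, grid_n = 10L),
                       error = function(e) NULL)
        rp_cache[[rp_key]] <- rp
      }
      X <- obs_states[[ti]]
      fates <- rep("undecided", n)
      atts <- if (is.null(rp)) NULL else {
        rp[rp$kind == "attractor", , drop = FALSE]
      }
      if (!is.null(atts) && nrow(atts)) {
        att_lab <- vapply(seq_len(nrow(atts)), function(k) {
          fate_label_for(c(atts$x[k], atts$y[k]), rp, schedule$fate_refs)
        }, character(1))
        near_att <- function(Y, radius) {
          D2 <- vapply(seq_len(nrow(atts)), function(k) {
            (Y[, 1] - atts$x[k])^2 + (Y[, 2] - atts$y[k])^2
          }, numeric(nrow(Y)))
          D2 <- matrix(D2, nrow = nrow(Y))
          nearest <- max.col(-D2, ties.method = "first")
          d2min <- D2[cbind(seq_len(nrow(Y)), nearest)]
          list(idx = nearest, ok = is.finite(d2min) & d2min < radius^2,
               d2min = d2min)
        }
        # cells already sitting well inside an attractor's basin are
        # assigned directly; the safe radius per attractor is a fraction
        # of its distance to the nearest saddle, so near-fold flattening
        # cannot cause misassignment. Only the remainder needs relaxing.
        sads <- rp[rp$kind == "saddle1", , drop = FALSE]
        safe_r <- vapply(seq_len(nrow(atts)), function(k) {
          if (!nrow(sads)) return(0.12)
          min(0.12, 0.4 * min(sqrt((sads$x - atts$x[k])^2 +
                                     (sads$y - atts$y[k])^2)))
        }, numeric(1))
        assign_safe <- function(Y) {
          q <- near_att(Y, Inf)
          q$ok <- is.finite(q$d2min) & sqrt(q$d2min) < safe_r[q$idx]
          q
        }
        pre <- assign_safe(X)
        fates[pre$ok] <- att_lab[pre$idx[pre$ok]]
        todo <- which(!pre$ok)
        if (length(todo)) {
          Xr <- relax_population(model, X[todo, , drop = FALSE], th,
                                 dt = 0.04, max_steps = 3000L,
                                 rest_points = rp, attr_tol = 0.02)
          q <- near_att(Xr, 0.02)
          q$ok <- q$ok | (is.finite(q$d2min) &
                            sqrt(q$d2min) < safe_r[q$idx])
          fates[todo[q$ok]] <- att_lab[q$idx[q$ok]]
        }
      }
      # with reference fates the full label set is known: emit explicit
      # zero-count rows so tables from different runs align key-by-key
      tab <- if (!is.null(schedule$fate_refs)) {
        table(factor(fates, levels = c(names(schedule$fate_refs),
                                       "undecided")))
      } else table(fates)
      acc$condition <- c(acc$condition, rep(conds[ci], length(tab)))
      acc$time <- c(acc$time, rep(t_o, length(tab)))
      acc$fate <- c(acc$fate, names(tab))
      acc$count <- c(acc$count, as.integer(tab))
    }
  }
  df <- data.frame(condition = acc$condition, time = acc$time,
                   fate = acc$fate, count = acc$count,
                   proportion = if (length(acc$count)) {
                     acc$count / schedule$n_cells
                   } else numeric(0),
                   stringsAsFactors = FALSE)
  new_fate_table(df, metadata = list(
    seed = as.integer(seed), sigma = model$sigma,
    family = model$family$name, n_cells = schedule$n_cells,
    dt = schedule$dt, t_obs = schedule$t_obs))
}

#' Renormalize fate proportions
#'
#' @param table a `fate_table`
#' @param drop_undecided remove `undecided` rows before renormalizing
#' @return a `fate_table` with proportions summing to 1 per
#'   (condition, time) group
#' @export
fate_proportions <- function(table, drop_undecided = FALSE) {
  df <- as.data.frame(table)
  all_keys <- unique(paste(df$condition, df$time, sep = "\r"))
  if (drop_undecided) df <- df[df$fate != "undecided", , drop = FALSE]
  key <- paste(df$condition, df$time, sep = "\r")
  for (k in all_keys) {
    i <- key == k
    tot <- sum(df$count[i])
    if (tot == 0) {
      stop("all cells undecided in group ", gsub("\r", " / ", k),
           "; proportions undefined", call. = FALSE)
    }
    df$proportion[i] <- df$count[i] / tot
  }
  new_fate_table(df, metadata = attr(table, "metadata"))
}

#' Generate a synthetic fate-proportion dataset
#'
#' Simulates the population and then resamples the counts at each
#' (condition, time) multinomially at size `multinomial_n`, emulating the
#' finite sampling of a real experiment in which `multinomial_n` cells
#' are assayed. The generating parameters are recorded in the metadata
#' for parameter-recovery studies.
#'
#' @inheritParams simulate_population
#' @param multinomial_n assay sample size (>= 1)
#' @param true_params optional named vector recorded as ground truth
#' @return a `fate_table`
#' @export
synth_dataset <- function(model, schedule, sigma = NULL, seed = 1L,
                          multinomial_n = 200L, true_params = NULL) {
  if (multinomial_n < 1) stop("multinomial_n must be >= 1", call. = FALSE)
  tab <- simulate_population(model, schedule, sigma = sigma, seed = seed)
  df <- as.data.frame(tab)
  key <- paste(df$condition, df$time, sep = "\r")
  out <- with_seed(as.integer(seed) + 104729L, {
    for (k in unique(key)) {
      i <- which(key == k)
      p <- df$proportion[i]
      cnt <- as.integer(stats::rmultinom(1L, size = multinomial_n,
                                         prob = p / sum(p)))
      df$count[i] <- cnt
      df$proportion[i] <- cnt / multinomial_n
    }
    df
  })
  md <- attr(tab, "metadata")
  md$multinomial_n <- as.integer(multinomial_n)
  md$true_params <- if (is.null(true_params)) NULL else as.list(true_params)
  new_fate_table(out, metadata = md)
}

#' Write / read a fate table as CSV plus a JSON metadata sidecar
#'
#' @param table a `fate_table`
#' @param path CSV path; metadata goes to `<path>.meta.json`
#' @export
write_fate_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  md <- attr(table, "metadata")
  if (is.null(md)) md <- list()
  jsonlite::write_json(md, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fate_table
#' @export
read_fate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mp <- paste0(path, ".meta.json")
  md <- if (file.exists(mp)) jsonlite::read_json(mp, simplifyVector = TRUE)
        else list()
  new_fate_table(df, metadata = md)
}

#' Split a fate table by condition
#'
#' Utility for test/validation splits in fitting studies.
#' @param table a `fate_table`
#' @param conditions character vector of condition names for the first part
#' @return list with `selected` and `rest`
#' @export
split_fate_table <- function(table, conditions) {
  df <- as.data.frame(table)
  sel <- df$condition %in% conditions
  md <- attr(table, "metadata")
  list(selected = new_fate_table(df[sel, , drop = FALSE], md),
       rest = new_fate_table(df[!sel, , drop = FALSE], md))
}
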