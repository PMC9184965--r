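# Likelihood-free fitting of landscape parameters to fate-proportion
# tables: distance, ABC-SMC sampler, posterior summaries.

#' Uniform prior specification
#'
#' Independent uniform priors, one per free parameter.
#' @param lower,upper numeric vectors (named or use `names`)
#' @param names parameter names
#' @return object of class `prior_spec`
#' @export
prior_spec <- function(lower, upper, names = NULL) {
  if (is.null(names)) {
    names <- if (!is.null(base::names(lower))) base::names(lower)
             else paste0("theta", seq_along(lower))
  }
  if (length(lower) != length(upper) || any(lower >= upper)) {
    stop("each prior needs lower < upper", call. = FALSE)
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 names = names),
            class = "prior_spec")
}

prior_sample <- function(priors) {
  stats::runif(length(priors$lower), priors$lower, priors$upper)
}

prior_density <- function(priors, x) {
  if (any(x < priors$lower | x > priors$upper)) return(0)
  1 / prod(priors$upper - priors$lower)
}

#' Distance between two fate tables
#'
#' Mean absolute difference of proportions over all matched
#' (condition, time, fate) keys. The two tables must carry exactly the
#' same key set.
#'
#' @param observed,simulated `fate_table` objects
#' @return non-negative scalar
#' @export
fate_distance <- function(observed, simulated) {
  a <- as.data.frame(observed); b <- as.data.frame(simulated)
  ka <- paste(a$condition, a$time, a$fate, sep = "\r")
  kb <- paste(b$condition, b$time, b$fate, sep = "\r")
  missing_in_b <- setdiff(ka, kb)
  missing_in_a <- setdiff(kb, ka)
  if (length(missing_in_b) || length(missing_in_a)) {
    stop("fate tables do not align; missing keys: ",
         paste(gsub("\r", "/", c(missing_in_b, missing_in_a)),
               collapse = ", "),
         call. = FALSE)
  }
  m <- match(ka, kb)
  mean(abs(a$proportion - b$proportion[m]))
}

#' ABC-SMC fit of landscape parameters to fate proportions
#'
#' Sequential Monte Carlo approximate Bayesian computation. Generation 1
#' samples the prior (tolerance infinity); each later generation resamples
#' the previous weighted particles, perturbs with a Gaussian kernel whose
#' per-parameter variance is twice the weighted sample variance, simulates
#' a fate table, and accepts particles whose distance to the observed
#' table falls below the tolerance. The tolerance for each generation is
#' the `quantile` of the previous generation's accepted distances.
#' Importance weights follow the standard SMC formula
#' \eqn{w_i \propto \pi(\theta_i) / \sum_j w_j K(\theta_i | \theta_j)}.
#'
#' The simulator owns all stochasticity: it is called as
#' `simulator(theta, seed)` and must return a `fate_table` aligned with
#' `observed`. Per-particle seeds are derived deterministically from the
#' master seed, so a fixed seed gives an identical posterior.
#'
#' @param simulator function `(theta, seed) -> fate_table`
#' @param observed the observed `fate_table`
#' @param priors a `prior_spec`
#' @param n_particles particles per generation (>= 50)
#' @param n_generations total generations including the prior generation
#' @param quantile tolerance quantile (default 0.3)
#' @param seed master seed
#' @param max_attempts attempts per generation before declaring the
#'   acceptance rate too low (early stop with status `"stalled"`)
#' @param verbose print per-generation progress
#' @return object of class `abc_posterior`: `particles` (matrix),
#'   `weights`, `distances`, `epsilon_history`, `acceptance_rates`,
#'   `status`, `seed`
#' @export
abc_smc <- function(simulator, observed, priors, n_particles = 200L,
                    n_generations = 4L, quantile = 0.3, seed = 1L,
                    max_attempts = 60L * n_particles,
                    verbose = FALSE) {
  if (n_particles < 50L) stop("n_particles must be >= 50", call. = FALSE)
  np <- length(priors$lower)
  seed <- as.integer(seed)
  sim_counter <- 0L
  sim_seed <- function() {
    sim_counter <<- sim_counter + 1L
    (seed + 49979687L + 2L * sim_counter) %% .Machine$integer.max
  }
  with_seed(seed, {
    eps_hist <- numeric(0)
    acc_hist <- numeric(0)
    status <- "ok"
    # generation 1: prior, epsilon = Inf
    P <- matrix(NA_real_, n_particles, np)
    D <- numeric(n_particles)
    for (i in seq_len(n_particles)) {
      P[i, ] <- prior_sample(priors)
      D[i] <- fate_distance(observed, simulator(P[i, ], sim_seed()))
    }
    W <- rep(1 / n_particles, n_particles)
    eps_hist <- c(eps_hist, Inf)
    acc_hist <- c(acc_hist, 1)
    if (n_generations > 1L) for (g in 2:n_generations) {
      eps <- stats::quantile(D, quantile, names = FALSE)
      eps_hist <- c(eps_hist, eps)
      kern_sd <- sqrt(2 * pmax(wtd_var(P, W), 1e-12))
      newP <- matrix(NA_real_, n_particles, np)
      newD <- numeric(n_particles)
      accepted <- 0L
      attempts <- 0L
      while (accepted < n_particles && attempts < max_attempts) {
        attempts <- attempts + 1L
        j <- sample.int(n_particles, 1L, prob = W)
        cand <- P[j, ] + stats::rnorm(np, sd = kern_sd)
        if (prior_density(priors, cand) == 0) next
        d <- fate_distance(observed, simulator(cand, sim_seed()))
        if (d <= eps) {
          accepted <- accepted + 1L
          newP[accepted, ] <- cand
          newD[accepted] <- d
        }
      }
      rate <- accepted / attempts
      acc_hist <- c(acc_hist, rate)
      if (verbose) {
        message(sprintf(
          "generation %d: eps %.4f, acceptance %.3f (%d attempts)",
          g, eps, rate, attempts))
      }
      if (accepted < n_particles) {
        status <- "stalled"
        newP <- newP[seq_len(accepted), , drop = FALSE]
        newD <- newD[seq_len(accepted)]
        if (accepted == 0L) break
      }
      # importance weights
      newW <- vapply(seq_len(nrow(newP)), function(i) {
        ker <- sum(W * vapply(seq_len(n_particles), function(j2) {
          prod(stats::dnorm(newP[i, ], P[j2, ], kern_sd))
        }, numeric(1)))
        prior_density(priors, newP[i, ]) / max(ker, 1e-300)
      }, numeric(1))
      P <- newP; D <- newD
      W <- newW / sum(newW)
      if (status == "stalled") break
    }
    colnames(P) <- priors$names
    structure(list(particles = P, weights = W, distances = D,
                   epsilon_history = eps_hist,
                   acceptance_rates = acc_hist, status = status,
                   seed = seed, priors = priors,
                   n_simulations = sim_counter),
              class = "abc_posterior")
  })
}

wtd_var <- function(P, W) {
  mu <- colSums(P * W)
  colSums(W * (P - matrix(mu, nrow(P), ncol(P), byrow = TRUE))^2)
}

wtd_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][vapply(p, function(pp) which(cw >= pp - 1e-12)[1], integer(1))]
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf(
    "<abc_posterior: %d particle(s), %d generation(s), status %s>\n",
    nrow(x$particles), length(x$epsilon_history), x$status))
  print(posterior_summary(x))
  invisible(x)
}

#' Weighted posterior summaries
#'
#' @param posterior an `abc_posterior`
#' @return data frame with weighted mean, variance, 95% credible interval
#'   per parameter, plus the effective sample size as an attribute
#' @export
posterior_summary <- function(posterior) {
  P <- posterior$particles; W <- posterior$weights
  if (!nrow(P)) stop("empty posterior", call. = FALSE)
  ess <- 1 / sum(W^2)
  if (!is.finite(ess) || ess <= 0) {
    stop("zero effective sample size", call. = FALSE)
  }
  out <- data.frame(
    parameter = colnames(P),
    mean = colSums(P * W),
    variance = wtd_var(P, W),
    q2.5 = vapply(seq_len(ncol(P)), function(j) {
      wtd_quantile(P[, j], W, 0.025)
    }, numeric(1)),
    q97.5 = vapply(seq_len(ncol(P)), function(j) {
      wtd_quantile(P[, j], W, 0.975)
    }, numeric(1)))
  rownames(out) <- NULL
  attr(out, "ess") <- ess
  out
}

#' Export a posterior: particles+weights CSV and a JSON run-metadata file
#' @param posterior an `abc_posterior`
#' @param path CSV path; metadata goes to `<path>.meta.json`
#' @export
write_posterior <- function(posterior, path) {
  df <- as.data.frame(posterior$particles)
  df$weight <- posterior$weights
  df$distance <- posterior$distances
  utils::write.csv(df, path, row.names = FALSE)
  md <- list(seed = posterior$seed,
             epsilon_history = posterior$epsilon_history,
             acceptance_rates = posterior$acceptance_rates,
             status = posterior$status,
             n_simulations = posterior$n_simulations,
             priors = list(lower = posterior$priors$lower,
                           upper = posterior$priors$upper,
                           names = posterior$priors$names))
  jsonlite::write_json(md, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
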