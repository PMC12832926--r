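#' Swarm control parameters
#'
#' Defaults follow the empirically settled configuration for the diagnostic
#' task: 50 particles, 100 iterations, cognitive and social coefficients
#' c1 = c2 = 2.0, inertia decaying linearly from 0.9 to 0.4, Gaussian
#' mutation with probability 0.1 and standard deviation 0.1. Setting
#' `p_mutation = 0` and `w_max = w_min` degenerates the engine to standard
#' PSO (the ablation's comparison arm).
#'
#' @param n_particles swarm size (>= 2)
#' @param max_iterations stopping criterion (>= 1)
#' @param c1,c2 cognitive and social acceleration coefficients
#' @param w_max,w_min inertia endpoints, `0 < w_min <= w_max`
#' @param p_mutation per-particle, per-iteration mutation probability
#' @param sigma mutation standard deviation (in normalised coordinates)
#' @param v_max_fraction elementwise velocity clamp as a fraction of each
#'   dimension's \[0, 1\] range
#' @param seed RNG seed; the whole run is reproducible from it
#' @return a `swarm_config` list
#' @export
swarm_config <- function(n_particles = 50, max_iterations = 100,
                         c1 = 2.0, c2 = 2.0, w_max = 0.9, w_min = 0.4,
                         p_mutation = 0.1, sigma = 0.1,
                         v_max_fraction = 0.25, seed = 1) {
  stopifnot(n_particles >= 2, max_iterations >= 1,
            w_min > 0, w_min <= w_max,
            p_mutation >= 0, p_mutation <= 1, sigma >= 0,
            v_max_fraction > 0)
  structure(list(n_particles = n_particles, max_iterations = max_iterations,
                 c1 = c1, c2 = c2, w_max = w_max, w_min = w_min,
                 p_mutation = p_mutation, sigma = sigma,
                 v_max_fraction = v_max_fraction, seed = seed),
            class = "swarm_config")
}

#' Standard-PSO configuration (degenerate engine mode)
#'
#' Fixed inertia (`w_max = w_min`) and no mutation; otherwise identical to
#' [swarm_config()].
#' @param w the fixed inertia weight
#' @param ... passed to [swarm_config()]
#' @return a `swarm_config`
#' @export
standard_pso_config <- function(w = 0.7, ...) {
  swarm_config(w_max = w, w_min = w, p_mutation = 0, ...)
}

#' Linearly decaying inertia weight
#'
#' `w = w_max - (w_max - w_min) * iteration / max_iterations`: exploration
#' early, exploitation late.
#'
#' @param config a [swarm_config()]
#' @param iteration current iteration, in `0:max_iterations`
#' @return the inertia weight at that iteration
#' @examples
#' cfg <- swarm_config()
#' inertia_at(cfg, 0)    # 0.9
#' inertia_at(cfg, 50)   # 0.65
#' inertia_at(cfg, 100)  # 0.4
#' @export
inertia_at <- function(config, iteration) {
  if (iteration < 0 || iteration > config$max_iterations)
    stop("iteration out of range", call. = FALSE)
  config$w_max - (config$w_max - config$w_min) * iteration / config$max_iterations
}

clip01 <- function(x) pmin(1, pmax(0, x))

# one velocity update (fresh uniform r1, r2 per dimension), then clamp
step_velocity <- function(velocity, position, pbest, gbest, w, config) {
  d <- length(position)
  r1 <- stats::runif(d); r2 <- stats::runif(d)
  v <- w * velocity +
    config$c1 * r1 * (pbest - position) +
    config$c2 * r2 * (gbest - position)
  vmax <- config$v_max_fraction
  pmin(vmax, pmax(-vmax, v))
}

# Gaussian mutation: fires once per particle per iteration; when it fires,
# every coordinate gets an independent N(0, sigma) perturbation, then clip
maybe_mutate <- function(position, config) {
  if (config$p_mutation > 0 && stats::runif(1) < config$p_mutation)
    clip01(position + stats::rnorm(length(position), 0, config$sigma))
  else position
}

#' Run the improved particle swarm optimizer
#'
#' Maximises `fitness(position)` over the unit hypercube `[0,1]^n_dims`.
#' Per iteration: the inertia weight is recomputed, then each particle in
#' turn updates velocity (with fresh uniform draws per dimension) and
#' position, possibly mutates, is evaluated, and updates its personal best
#' and -- immediately, visible to later particles in the same sweep -- the
#' global best. Exactly `n_particles * (max_iterations + 1)` fitness
#' evaluations are performed (initial sweep plus one per iteration).
#'
#' @param n_dims dimensionality of the search space
#' @param fitness function mapping a position vector in `[0,1]^n_dims` to a
#'   scalar to be maximised; must be deterministic given the position
#' @param config a [swarm_config()]
#' @return a `swarm_state`: `gbest_position`, `gbest_fitness`, `history`
#'   (gbest fitness after initialisation and after each iteration, length
#'   `max_iterations + 1`, non-decreasing), `n_evaluations`, and the final
#'   particle positions
#' @examples
#' st <- ipso_optimize(2, function(x) -sum((x - 0.5)^2),
#'                     swarm_config(n_particles = 10, max_iterations = 20))
#' st$gbest_fitness
#' @export
ipso_optimize <- function(n_dims, fitness, config = swarm_config()) {
  stopifnot(n_dims >= 1)
  with_seed(config$seed, {
    n <- config$n_particles
    vmax <- config$v_max_fraction
    pos <- matrix(stats::runif(n * n_dims), nrow = n)
    vel <- matrix(stats::runif(n * n_dims, -vmax, vmax), nrow = n)
    evalf <- function(x) {
      f <- tryCatch(fitness(x), error = function(e)
        stop("fitness failed at position [",
             paste(signif(x, 4), collapse = ", "), "]: ",
             conditionMessage(e), call. = FALSE))
      if (is.na(f))
        stop("fitness returned NA at position [",
             paste(signif(x, 4), collapse = ", "), "]", call. = FALSE)
      f
    }
    fit <- numeric(n)
    for (i in seq_len(n)) fit[i] <- evalf(pos[i, ])
    pbest <- pos; pbest_fit <- fit
    g <- which.max(fit)                      # first-found wins on ties
    gbest <- pos[g, ]; gbest_fit <- fit[g]
    n_eval <- n
    history <- numeric(config$max_iterations + 1)
    history[1] <- gbest_fit

    for (t in seq_len(config$max_iterations)) {
      w <- inertia_at(config, t)
      for (i in seq_len(n)) {
        vel[i, ] <- step_velocity(vel[i, ], pos[i, ], pbest[i, ], gbest, w, config)
        pos[i, ] <- clip01(pos[i, ] + vel[i, ])
        pos[i, ] <- maybe_mutate(pos[i, ], config)
        f <- evalf(pos[i, ])
        n_eval <- n_eval + 1L
        if (f > pbest_fit[i]) { pbest[i, ] <- pos[i, ]; pbest_fit[i] <- f }
        if (f > gbest_fit) { gbest <- pos[i, ]; gbest_fit <- f }
      }
      history[t + 1] <- gbest_fit
    }

    structure(list(gbest_position = gbest, gbest_fitness = gbest_fit,
                   history = history, n_evaluations = n_eval,
                   positions = pos, pbest_fitness = pbest_fit,
                   config = config),
              class = "swarm_state")
  })
}

#' @export
print.swarm_state <- function(x, ...) {
  cat(sprintf("IPSO run: %d evaluations, gbest fitness %.6g\n",
              x$n_evaluations, x$gbest_fitness))
  invisible(x)
}
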