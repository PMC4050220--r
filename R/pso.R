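#' Swarm configuration
#'
#' Parameters of the particle swarm search. Defaults follow the common
#' global-best PSO settings for this problem class: 50 particles, 100
#' iterations, inertia weight linearly decreasing from 0.9 to 0.4, and
#' acceleration constants c1 = c2 = 2.
#'
#' @param k barcode size (number of SNPs selected per particle), `k >= 2`.
#' @param population_size number of particles (default 50).
#' @param max_iterations iteration budget; the search stops after exactly
#'   this many velocity/position updates (default 100).
#' @param w_max,w_min endpoints of the linearly decreasing inertia weight
#'   (defaults 0.9 and 0.4).
#' @param c1,c2 acceleration constants weighting the pull toward the
#'   particle's own best (`pbest`) and the swarm best (`gbest`).
#' @param v_max optional per-dimension velocity clamp of length `2k`; by
#'   default the range of each dimension (`m - 1` for SNP slots, `2` for
#'   genotype slots), resolved once the SNP count `m` is known.
#' @param objective `"signed"` maximizes HIGH-minus-LOW carrier counts;
#'   `"absolute"` maximizes the magnitude of the difference.
#' @param stochastic_scope whether the random factors r1, r2 are drawn once
#'   per particle per update (`"per_particle"`, default, one scalar per
#'   vector term) or independently per dimension (`"per_dimension"`).
#' @param seed optional RNG seed; a seeded run is fully reproducible.
#' @return an object of class `swarm_config`.
#' @export
swarm_config <- function(k, population_size = 50, max_iterations = 100,
                         w_max = 0.9, w_min = 0.4, c1 = 2, c2 = 2,
                         v_max = NULL,
                         objective = c("signed", "absolute"),
                         stochastic_scope = c("per_particle",
                                              "per_dimension"),
                         seed = NULL) {
  objective <- match.arg(objective)
  stochastic_scope <- match.arg(stochastic_scope)
  k <- as.integer(k)
  if (k < 2) stop("k must be at least 2")
  if (population_size < 2) stop("population_size must be at least 2")
  if (max_iterations < 1) stop("max_iterations must be at least 1")
  if (!(0 <= w_min && w_min <= w_max))
    stop("inertia weights must satisfy 0 <= w_min <= w_max")
  structure(list(k = k, population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 w_max = w_max, w_min = w_min, c1 = c1, c2 = c2,
                 v_max = v_max, objective = objective,
                 stochastic_scope = stochastic_scope, seed = seed),
            class = "swarm_config")
}

# Default velocity clamp: the full range of each dimension.
resolve_vmax <- function(cfg, m) {
  if (!is.null(cfg$v_max)) {
    stopifnot(length(cfg$v_max) == 2 * cfg$k, all(cfg$v_max > 0))
    return(cfg$v_max)
  }
  c(rep(m - 1, cfg$k), rep(2, cfg$k))
}

# Lower/upper clamps of the continuous position space.
position_bounds <- function(k, m) {
  list(lower = rep(1, 2 * k), upper = c(rep(m, k), rep(3, k)))
}

#' Linearly decreasing inertia weight
#'
#' `w(t) = (w_max - w_min) * (T - t) / T + w_min`, so `w(0) = w_max` and
#' `w(T) = w_min`, decreasing by a constant amount per iteration.
#'
#' @param iteration current iteration index, `0 <= iteration <= T`.
#' @param cfg a [swarm_config()] supplying `w_max`, `w_min`, and the
#'   iteration budget `T = max_iterations`.
#' @return scalar inertia weight.
#' @export
inertia_weight <- function(iteration, cfg) {
  stopifnot(iteration >= 0, iteration <= cfg$max_iterations)
  (cfg$w_max - cfg$w_min) *
    (cfg$max_iterations - iteration) / cfg$max_iterations + cfg$w_min
}

# Round half away from zero (positions live in positive space, but the rule
# is stated generally so velocity arithmetic cannot surprise it).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# sample() that treats a length-1 vector as a single candidate.
resample <- function(x, n = 1) x[sample.int(length(x), n)]

#' Velocity update
#'
#' `v_new = w * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)`, clamped
#' per dimension to `[-v_max, v_max]`. `r1` and `r2` are fresh U(0,1) draws;
#' pass them explicitly for deterministic arithmetic checks.
#'
#' @param velocity,position,pbest_position current state of one particle
#'   (numeric vectors of length `2k`).
#' @param gbest_position the swarm's best position.
#' @param w inertia weight for this iteration.
#' @param c1,c2 acceleration constants.
#' @param v_max per-dimension clamp (length `2k` or scalar).
#' @param r1,r2 optional random factors; scalars (per-particle scope) or
#'   vectors of length `2k` (per-dimension scope). Drawn as scalars when
#'   `NULL`.
#' @return the new, clamped velocity vector.
#' @export
update_velocity <- function(velocity, position, pbest_position,
                            gbest_position, w, c1 = 2, c2 = 2,
                            v_max = Inf, r1 = NULL, r2 = NULL) {
  if (is.null(r1)) r1 <- stats::runif(1)
  if (is.null(r2)) r2 <- stats::runif(1)
  v <- w * velocity + c1 * r1 * (pbest_position - position) +
    c2 * r2 * (gbest_position - position)
  pmin(pmax(v, -v_max), v_max)
}

#' Position update
#'
#' `x_new = x + v`, with coordinates kept inside the search box (SNP slots
#' in `[1, m]`, genotype slots in `[1, 3]`) by reflecting overshoots off
#' the walls. Reflection rather than hard clamping matters: when the swarm
#' best sits on a box corner, clamping absorbs every overshooting particle
#' exactly onto it, both attraction terms vanish, and the swarm freezes;
#' reflected particles keep oscillating around boundary attractors instead.
#'
#' @param position,velocity numeric vectors of length `2k`.
#' @param m number of SNPs in the panel.
#' @return the new, in-bounds position vector.
#' @export
update_position <- function(position, velocity, m) {
  k <- length(position) / 2
  b <- position_bounds(k, m)
  x <- position + velocity
  # |v| <= dimension range, so a couple of reflections always suffice
  repeat {
    lo <- x < b$lower
    hi <- x > b$upper
    if (!any(lo) && !any(hi)) break
    x[lo] <- 2 * b$lower[lo] - x[lo]
    x[hi] <- 2 * b$upper[hi] - x[hi]
  }
  x
}

#' Decode a continuous particle position into a valid barcode
#'
#' SNP and genotype slots are rounded to the nearest integer (halves away
#' from zero) and clamped to their ranges. If a rounded SNP index collides
#' with an earlier slot, the later slot is redrawn uniformly from the unused
#' indices and the particle's continuous coordinate is overwritten with the
#' repaired integer, so repeated SNPs can never occur.
#'
#' @param position numeric vector of length `2k` within the clamps.
#' @param m number of SNPs in the panel.
#' @return list with `barcode` (a canonical [snp_barcode()]) and `position`
#'   (the possibly repaired continuous position).
#' @export
decode_particle <- function(position, m) {
  k <- length(position) / 2
  snps <- integer(k)
  for (j in seq_len(k)) {
    v <- min(max(round_half_away(position[j]), 1L), m)
    if (v %in% snps[seq_len(j - 1)]) {
      v <- resample(setdiff(seq_len(m), snps[seq_len(j - 1)]))
      position[j] <- v
    }
    snps[j] <- v
  }
  codes <- pmin(pmax(round_half_away(position[(k + 1):(2 * k)]), 1L), 3L)
  list(barcode = snp_barcode(snps, codes), position = position)
}

# Evaluate a barcode against the dataset with memoization (the swarm
# revisits the same barcodes constantly on small panels).
eval_barcode <- function(ds, bc, objective, cache = NULL) {
  key <- format(bc)
  if (!is.null(cache)) {
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
  }
  nm <- count_matches(ds, bc)
  res <- list(fitness = barcode_fitness(nm[["n_high"]], nm[["n_low"]],
                                        objective),
              n_high = nm[["n_high"]], n_low = nm[["n_low"]],
              barcode = bc)
  if (!is.null(cache)) assign(key, res, envir = cache)
  res
}

#' Initialize the swarm
#'
#' Each particle's SNP slots are drawn uniformly without replacement from
#' the panel, genotype slots uniformly from `{1,2,3}`, and velocities
#' uniformly from `[-v_max, v_max]`. Personal bests start at the initial
#' positions; the global best is the best initial personal best.
#'
#' @param cfg a [swarm_config()].
#' @param ds a dichotomized [genotype_dataset()] (supplies the SNP count and
#'   the fitness of the initial positions).
#' @return a `swarm_state` list: position/velocity/pbest matrices
#'   (`population_size` x `2k`), pbest fitness, gbest state, iteration
#'   counter, and the evaluation cache.
#' @export
init_population <- function(cfg, ds) {
  m <- n_snps(ds)
  if (cfg$k > m)
    stop("k = ", cfg$k, " exceeds the number of SNPs (", m, ")")
  np <- cfg$population_size
  k <- cfg$k
  v_max <- resolve_vmax(cfg, m)
  positions <- t(vapply(seq_len(np), function(i) {
    c(sample.int(m, k), sample.int(3, k, replace = TRUE))
  }, numeric(2 * k)))
  velocities <- t(vapply(seq_len(np), function(i) {
    stats::runif(2 * k, -v_max, v_max)
  }, numeric(2 * k)))
  cache <- new.env(parent = emptyenv())
  evals <- lapply(seq_len(np), function(i) {
    eval_barcode(ds, decode_particle(positions[i, ], m)$barcode,
                 cfg$objective, cache)
  })
  pbest_fitness <- vapply(evals, `[[`, numeric(1), "fitness")
  best <- which.max(pbest_fitness)
  state <- list(positions = positions, velocities = velocities,
                pbest_positions = positions,
                pbest_fitness = pbest_fitness,
                gbest_position = positions[best, ],
                gbest_fitness = pbest_fitness[best],
                gbest_eval = evals[[best]],
                iteration = 0L, m = m, v_max = v_max, cache = cache)
  class(state) <- "swarm_state"
  state
}

#' Advance the swarm by one iteration
#'
#' For each particle: update velocity, update position, decode to a
#' barcode, and evaluate it. The personal best is replaced only on strict
#' improvement; the global best is replaced only if some personal best
#' strictly exceeds it, so the global best fitness never decreases.
#'
#' @param state a `swarm_state` from [init_population()] or a previous step.
#' @param ds the dichotomized dataset.
#' @param cfg the [swarm_config()].
#' @return the updated `swarm_state`.
#' @export
pso_step <- function(state, ds, cfg) {
  m <- state$m
  k <- cfg$k
  w <- inertia_weight(state$iteration, cfg)
  per_dim <- cfg$stochastic_scope == "per_dimension"
  for (i in seq_len(cfg$population_size)) {
    r1 <- if (per_dim) stats::runif(2 * k) else stats::runif(1)
    r2 <- if (per_dim) stats::runif(2 * k) else stats::runif(1)
    v <- update_velocity(state$velocities[i, ], state$positions[i, ],
                         state$pbest_positions[i, ], state$gbest_position,
                         w, cfg$c1, cfg$c2, state$v_max, r1, r2)
    x <- update_position(state$positions[i, ], v, m)
    dec <- decode_particle(x, m)
    state$velocities[i, ] <- v
    state$positions[i, ] <- dec$position
    ev <- eval_barcode(ds, dec$barcode, cfg$objective, state$cache)
    if (ev$fitness > state$pbest_fitness[i]) {
      state$pbest_fitness[i] <- ev$fitness
      state$pbest_positions[i, ] <- dec$position
      if (ev$fitness > state$gbest_fitness) {
        state$gbest_fitness <- ev$fitness
        state$gbest_position <- dec$position
        state$gbest_eval <- ev
      }
    }
  }
  state$iteration <- state$iteration + 1L
  state
}

#' Run the particle swarm barcode search
#'
#' Initializes a swarm and runs it for the configured number of iterations,
#' tracking the best barcode found (`gbest`).
#'
#' @param ds a dichotomized [genotype_dataset()].
#' @param cfg a [swarm_config()]; `cfg$seed` (if set) makes the run
#'   reproducible.
#' @return an object of class `pso_result`: the best `barcode`, its carrier
#'   counts `n_high`/`n_low` and `fitness`, a per-iteration `trace` data
#'   frame of the global best fitness, and the `config` used.
#' @examples
#' spec <- synthetic_spec(seed = 7)
#' ds <- dichotomize_by_mean(generate_dataset(spec))
#' run_pso(ds, swarm_config(k = 2, seed = 7))
#' @export
run_pso <- function(ds, cfg) {
  stopifnot(inherits(cfg, "swarm_config"))
  if (is.null(ds$group)) stop("dataset has not been dichotomized")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  state <- init_population(cfg, ds)
  trace <- data.frame(iteration = 0:cfg$max_iterations,
                      gbest_fitness = NA_real_)
  trace$gbest_fitness[1] <- state$gbest_fitness
  for (t in seq_len(cfg$max_iterations)) {
    state <- pso_step(state, ds, cfg)
    trace$gbest_fitness[t + 1] <- state$gbest_fitness
  }
  ev <- state$gbest_eval
  structure(list(barcode = ev$barcode, n_high = ev$n_high,
                 n_low = ev$n_low, fitness = ev$fitness,
                 trace = trace, config = cfg),
            class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat("PSO best barcode:", format(x$barcode), "\n")
  cat(sprintf("  carriers: HIGH %d, LOW %d; difference %d\n",
              x$n_high, x$n_low, x$fitness))
  invisible(x)
}
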