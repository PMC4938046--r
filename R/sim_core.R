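#' Draw the per-patch resource payoffs for the current turnover period
#'
#' In the `"no_variance"` regime every patch receives
#' `total_resource / n_patches`, constant over time. In the
#' `"high_variance"` regime `n_rich_patches` patches, chosen uniformly at
#' random, each receive `total_resource / n_rich_patches` and all other
#' patches receive 0. The caller (see [sim_step()]) redraws only at the
#' start of each turnover period and holds the vector fixed in between.
#' Either way the payoffs sum to `total_resource`.
#'
#' Randomness comes from R's global RNG stream; seed with [set.seed()] (or
#' run through [run_replicate()], which seeds per replicate).
#'
#' @param config A [world_config()].
#' @return Numeric vector of length `n_patches` summing to `total_resource`.
#' @examples
#' set.seed(1)
#' draw_patch_payoffs(world_config(regime = "high_variance",
#'                                 total_resource = 100))
#' @export
draw_patch_payoffs <- function(config) {
  validate_world_config(config)
  p <- config$n_patches
  if (config$regime == "no_variance") {
    rep(config$total_resource / p, p)
  } else {
    rich <- sample.int(p, config$n_rich_patches)
    payoffs <- numeric(p)
    payoffs[rich] <- config$total_resource / config$n_rich_patches
    payoffs
  }
}

#' Equal sharing of a patch payoff among its occupants
#'
#' Exploitative competition: every forager on a patch receives the same
#' per-capita share `patch_value / n_occupants`. An unoccupied patch yields
#' nothing (its payoff is wasted, not carried over).
#'
#' @param patch_value Non-negative resource value of the patch.
#' @param n_occupants Non-negative integer count of foragers on the patch.
#'   Both arguments recycle, so whole vectors of patches can be shared at
#'   once.
#' @return Per-capita intake (0 when `n_occupants` is 0).
#' @examples
#' share_patch_payoff(10, 4)   # 2.5 each
#' share_patch_payoff(0, 3)    # empty patch
#' @export
share_patch_payoff <- function(patch_value, n_occupants) {
  if (any(patch_value < 0)) stop("patch_value must be non-negative")
  if (any(n_occupants < 0)) stop("n_occupants must be non-negative")
  ifelse(n_occupants > 0, patch_value / pmax(n_occupants, 1), 0)
}

#' Memory-guided patch choice for a single forager
#'
#' With probability `explore_prob` the forager ignores its memory and
#' samples a uniformly random patch; otherwise it goes to the patch it
#' currently believes most profitable (the argmax of its memory vector),
#' with ties broken uniformly at random. Naive agents, whose memory is flat,
#' therefore start out choosing at random.
#'
#' @param memory Numeric vector of estimated per-capita intake per patch.
#' @param explore_prob Exploration probability in \[0, 1\].
#' @return A patch index in `1:length(memory)`.
#' @export
choose_patch <- function(memory, explore_prob) {
  stopifnot(length(memory) >= 1, explore_prob >= 0, explore_prob <= 1)
  p <- length(memory)
  if (explore_prob > 0 && stats::runif(1) < explore_prob)
    return(sample.int(p, 1L))
  best <- which(memory == max(memory))
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

#' Individual (personal) memory update
#'
#' An individual learner records the per-capita intake it just experienced
#' on the patch it visited, fully replacing its previous estimate for that
#' patch; all other entries are untouched. Replacement (rather than
#' smoothing) means depletion is learned in a single visit.
#'
#' @param memory Numeric memory vector.
#' @param patch Index of the patch visited this step.
#' @param observed_intake Realised per-capita intake on that patch.
#' @return The updated memory vector.
#' @export
update_memory_individual <- function(memory, patch, observed_intake) {
  stopifnot(patch >= 1, patch <= length(memory))
  memory[patch] <- observed_intake
  memory
}

#' Social memory update: observe one conspecific, keep own experience
#'
#' A social learner picks one other forager uniformly at random and records
#' that forager's per-capita intake for the patch it occupied. The observer
#' also records its own realised intake for its own patch — social learners
#' still experience their own payoff; without that own-experience write the
#' strategy collapses under competition because observers would never learn
#' that a crowded patch pays little. If the observed patch coincides with
#' the observer's own patch the observation (taken after all foraging is
#' resolved) wins.
#'
#' @param memory Observer's memory vector.
#' @param own_patch,own_intake The observer's patch and realised intake.
#' @param others_patches,others_intakes Parallel vectors describing every
#'   other forager's patch and intake this step. Empty vectors (a population
#'   of one) mean no observation occurs and only the own-experience write
#'   happens.
#' @return The updated memory vector.
#' @export
update_memory_social <- function(memory, own_patch, own_intake,
                                 others_patches = integer(),
                                 others_intakes = numeric()) {
  stopifnot(length(others_patches) == length(others_intakes))
  memory <- update_memory_individual(memory, own_patch, own_intake)
  if (length(others_patches) > 0) {
    j <- sample.int(length(others_patches), 1L)
    memory[others_patches[j]] <- others_intakes[j]
  }
  memory
}

# Fitness-proportional (roulette) parent sampling; uniform when all
# weights vanish. Exported for direct verification of the selection weights.

#' Sample parents with probability proportional to fitness
#'
#' @param fitness Non-negative fitness weights of the candidate parents.
#' @param n_offspring Number of parents to draw (with replacement).
#' @return Integer indices into `fitness`.
#' @export
roulette_sample <- function(fitness, n_offspring) {
  if (any(fitness < 0)) stop("fitness must be non-negative")
  if (length(fitness) == 0L) stop("no candidate parents")
  if (sum(fitness) > 0)
    sample.int(length(fitness), n_offspring, replace = TRUE, prob = fitness)
  else
    sample.int(length(fitness), n_offspring, replace = TRUE)
}

#' Death and fitness-proportional replacement
#'
#' Each agent independently dies with probability `death_rate`. Every death
#' is immediately filled by a newborn whose strategy is copied from a parent
#' drawn from the *surviving* agents with probability proportional to
#' accumulated fitness (uniformly if all survivor fitnesses are zero). If
#' the whole population dies in one step, parents are drawn from the
#' pre-death population by the same rule. Newborns start with zero fitness,
#' a flat memory at `memory_init`, and flip their inherited strategy with
#' probability `mutation_prob`. Population size never changes.
#'
#' @param population A list with elements `social` (logical vector),
#'   `fitness` (numeric vector) and `memory` (agents x patches matrix), as
#'   inside a [sim_state]. Returned in the same shape.
#' @param death_rate,mutation_prob Per-step death and strategy-flip
#'   probabilities.
#' @param memory_init Memory value given to newborns for every patch.
#' @param dead Optional logical vector overriding the random death draw —
#'   a hook for controlled experiments and tests.
#' @return The population list after turnover.
#' @export
mortality_and_reproduction <- function(population, death_rate, mutation_prob,
                                       memory_init = 0, dead = NULL) {
  n <- length(population$social)
  if (is.null(dead)) dead <- stats::runif(n) < death_rate
  stopifnot(length(dead) == n)
  nd <- sum(dead)
  if (nd == 0L) return(population)
  surv <- which(!dead)
  parents <- if (length(surv) > 0L) {
    surv[roulette_sample(population$fitness[surv], nd)]
  } else {
    roulette_sample(population$fitness, nd)
  }
  strategy <- population$social[parents]
  flip <- stats::runif(nd) < mutation_prob
  population$social[dead] <- xor(strategy, flip)
  population$fitness[dead] <- 0
  population$memory[dead, ] <- memory_init
  population
}

#' Initialise a simulation state
#'
#' @param config A [world_config()].
#' @return A `sim_state` list: `step` (completed steps), `payoffs`,
#'   `memory`, `social`, `fitness`, plus `last_choice`/`last_intake`
#'   diagnostics from the most recent step.
#' @export
init_sim_state <- function(config) {
  validate_world_config(config)
  n <- config$n_agents
  n_social <- round(config$initial_social_fraction * n)
  state <- list(
    step = 0L,
    payoffs = numeric(config$n_patches),
    memory = matrix(config$memory_init, nrow = n, ncol = config$n_patches),
    social = c(rep(TRUE, n_social), rep(FALSE, n - n_social)),
    fitness = numeric(n),
    last_choice = rep(NA_integer_, n),
    last_intake = rep(NA_real_, n)
  )
  class(state) <- "sim_state"
  state
}

#' Advance the simulation by one time step
#'
#' Executes, in order: (1) a payoff redraw when a turnover period starts,
#' (2) a patch choice for every forager (vectorised equivalent of
#' [choose_patch()]), (3) per-patch occupancy counts and equal sharing,
#' (4) fitness accrual, (5) memory updates — every forager records its own
#' realised intake, then each social learner additionally observes one
#' random conspecific — and (6) mortality and replacement. The within-step
#' order is part of the model definition: foraging and learning happen
#' before selection acts on the step's accumulated fitness.
#'
#' @param state A `sim_state` from [init_sim_state()] or a previous call.
#' @param config The matching [world_config()].
#' @return The updated `sim_state` with `step` incremented.
#' @export
sim_step <- function(state, config) {
  n <- config$n_agents
  p <- config$n_patches

  # (1) payoff redraw at the start of each turnover period
  if (config$regime == "high_variance") {
    if (state$step %% config$turnover_interval == 0L)
      state$payoffs <- draw_patch_payoffs(config)
  } else if (state$step == 0L) {
    state$payoffs <- draw_patch_payoffs(config)
  }

  # (2) patch choice: memory argmax with random tie-break, epsilon-explore
  choice <- max.col(state$memory, ties.method = "random")
  explore <- stats::runif(n) < config$explore_prob
  ne <- sum(explore)
  if (ne > 0L) choice[explore] <- sample.int(p, ne, replace = TRUE)

  # (3)-(4) equal sharing within patches, fitness accrual
  counts <- tabulate(choice, nbins = p)
  intake <- state$payoffs[choice] / counts[choice]
  state$fitness <- state$fitness + intake

  # (5) memory: own experience for everyone, then social observation
  state$memory[(choice - 1L) * n + seq_len(n)] <- intake
  observers <- which(state$social)
  no <- length(observers)
  if (no > 0L && n > 1L) {
    obs <- sample.int(n - 1L, no, replace = TRUE)
    obs <- obs + (obs >= observers)  # skip self
    state$memory[(choice[obs] - 1L) * n + observers] <- intake[obs]
  }

  # (6) turnover
  pop <- mortality_and_reproduction(
    list(social = state$social, fitness = state$fitness,
         memory = state$memory),
    config$death_rate, config$mutation_prob, config$memory_init
  )
  state$social <- pop$social
  state$fitness <- pop$fitness
  state$memory <- pop$memory

  state$last_choice <- choice
  state$last_intake <- intake
  state$step <- state$step + 1L
  state
}

#' Run one seeded simulation replicate
#'
#' Seeds R's RNG, runs `n_steps` of [sim_step()] and records the proportion
#' of social learners after every step. The evolved proportion is the time
#' average of that trajectory over the post-burn-in steps.
#'
#' @param config A [world_config()].
#' @param seed Integer seed; identical seed and config give a bit-identical
#'   trajectory.
#' @return A `replicate_result` list: `seed`, `trajectory` (length
#'   `n_steps`, values in \[0, 1\]) and `evolved_proportion`.
#' @examples
#' r <- run_replicate(world_config(n_steps = 100L), seed = 1)
#' r$evolved_proportion
#' @export
run_replicate <- function(config, seed) {
  validate_world_config(config)
  set.seed(as.integer(seed))
  state <- init_sim_state(config)
  traj <- numeric(config$n_steps)
  for (t in seq_len(config$n_steps)) {
    state <- sim_step(state, config)
    traj[t] <- mean(state$social)
  }
  burn <- floor(config$burn_in_fraction * config$n_steps)
  structure(
    list(seed = as.integer(seed), trajectory = traj,
         evolved_proportion = mean(traj[(burn + 1L):config$n_steps])),
    class = "replicate_result"
  )
}

#' @export
print.replicate_result <- function(x, ...) {
  cat(sprintf(
    "Simulation replicate (seed %d): %d steps, evolved proportion of social learners = %.3f\n",
    x$seed, length(x$trajectory), x$evolved_proportion))
  invisible(x)
}
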