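#' Simulation configuration for the multi-agent bandit
#'
#' Parameterizes a multi-agent multi-armed bandit in which `n_agents`
#' epsilon-greedy agents repeatedly choose among uncertain reward options,
#' optionally earning a cohesion bonus for co-choosing. Defaults mirror the
#' simulation-study conditions: 6 agents, the four movement-paradigm options,
#' epsilon = 0.1, 30 iterations with the first 3 forced to uniform
#' exploration, and 1,000 independent runs.
#'
#' `bonus_in_update` controls whether the cohesion bonus is folded into the
#' reward an agent uses to update its value estimates. When `TRUE` (the
#' default) the bonus obfuscates the option's feedback, which is how the
#' bonus undermines collective induction; `FALSE` corresponds to sessions
#' where bonus and payout are reported separately.
#'
#' @param n_agents number of agents per run.
#' @param options an [option_set()].
#' @param epsilon exploration probability in \[0, 1\].
#' @param n_iterations rounds per run.
#' @param forced_exploration_iterations initial iterations with uniform
#'   random choices for every agent.
#' @param n_runs number of independent runs (groups).
#' @param bonus a [bonus_scheme()].
#' @param seed master integer seed; per-run substreams are derived from it.
#' @param bonus_in_update logical; include the bonus in value updates.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_agents = 6L, options = movement_options(),
                       epsilon = 0.1, n_iterations = 30L,
                       forced_exploration_iterations = 3L,
                       n_runs = 1000L, bonus = bonus_scheme("none"),
                       seed = 1L, bonus_in_update = TRUE) {
  if (!inherits(options, "option_set"))
    stop("sim_config: 'options' must be an option_set")
  if (nrow(options) < 2L)
    stop("sim_config: 'options' must contain at least 2 options")
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon > 1)
    stop("sim_config: 'epsilon' must lie in [0, 1]")
  if (n_agents < 1L) stop("sim_config: 'n_agents' must be positive")
  if (n_iterations < 1L) stop("sim_config: 'n_iterations' must be positive")
  if (forced_exploration_iterations < 0L ||
      forced_exploration_iterations > n_iterations)
    stop("sim_config: 'forced_exploration_iterations' must lie in [0, n_iterations]")
  if (n_runs < 1L) stop("sim_config: 'n_runs' must be positive")
  if (!inherits(bonus, "bonus_scheme"))
    stop("sim_config: 'bonus' must be a bonus_scheme")
  structure(list(n_agents = as.integer(n_agents), options = options,
                 epsilon = as.numeric(epsilon),
                 n_iterations = as.integer(n_iterations),
                 forced_exploration_iterations =
                   as.integer(forced_exploration_iterations),
                 n_runs = as.integer(n_runs), bonus = bonus,
                 seed = as.integer(seed),
                 bonus_in_update = isTRUE(bonus_in_update)),
            class = "sim_config")
}

#' Epsilon-greedy action selection
#'
#' Draws `p ~ Uniform(0, 1)`; if `p < epsilon` the agent explores (uniform
#' choice over all options), otherwise it exploits the option with the
#' highest current value estimate, ties broken uniformly at random. The
#' measure-zero boundary `p == epsilon` counts as exploitation.
#'
#' @param estimates numeric vector of per-option value estimates.
#' @param epsilon exploration probability in \[0, 1\].
#' @param detail if `TRUE`, return a list with the chosen `option` and the
#'   logical `explored` flag instead of a bare option id.
#' @return Option id (index into `estimates`), or a list when
#'   `detail = TRUE`.
#' @export
epsilon_greedy_choose <- function(estimates, epsilon, detail = FALSE) {
  k <- length(estimates)
  if (k < 2L)
    stop("epsilon_greedy_choose: need at least 2 options")
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon > 1)
    stop("epsilon_greedy_choose: epsilon must lie in [0, 1]")
  explored <- stats::runif(1L) < epsilon
  if (explored) {
    choice <- sample.int(k, 1L)
  } else {
    maxima <- which(estimates == max(estimates))
    choice <- if (length(maxima) == 1L) maxima else
      maxima[sample.int(length(maxima), 1L)]
  }
  if (detail) list(option = choice, explored = explored) else choice
}

#' Incremental sample-average value update
#'
#' After observing `reward` from `option`, the agent's estimate for that
#' option becomes the arithmetic mean of all rewards observed from it
#' (incremental form `Q <- Q + (r - Q) / n`). Estimates start at 0 for all
#' options, so all options look equally profitable before any feedback.
#'
#' @param state list with `value_estimates` and `choice_counts` vectors, as
#'   created by [agent_state()].
#' @param option option id just chosen.
#' @param reward observed reward in cents.
#' @return The updated state.
#' @export
update_estimate <- function(state, option, reward) {
  if (option < 1L || option > length(state$value_estimates))
    stop("update_estimate: invalid option id")
  n <- state$choice_counts[option] + 1L
  state$choice_counts[option] <- n
  q <- state$value_estimates[option]
  state$value_estimates[option] <- q + (reward - q) / n
  state
}

#' @rdname update_estimate
#' @param n_options number of options.
#' @param initial initial value estimate for every option.
#' @export
agent_state <- function(n_options, initial = 0) {
  list(value_estimates = rep(as.numeric(initial), n_options),
       choice_counts = integer(n_options))
}

#' Run the multi-agent bandit simulation
#'
#' All agents in a run choose simultaneously each iteration; payouts are
#' then drawn independently per agent from the chosen option's Bernoulli
#' payout, and cohesion bonuses are computed from the joint choice vector of
#' that iteration. The first `forced_exploration_iterations` iterations use
#' uniform random choices for every agent, seeding the value estimates
#' before greedy play begins.
#'
#' Reproducibility: run `r` uses a substream seed derived deterministically
#' from `config$seed`, so identical configurations produce identical logs
#' and runs are independent of each other's ordering.
#'
#' @param config a [sim_config()].
#' @return A data frame with one row per agent-iteration and columns
#'   `run`, `iteration`, `agent`, `choice`, `payout_cent`, `bonus_cent`.
#' @seealso [iteration_counts()], [summarize_choice_frequencies()]
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("run_simulation: 'config' must be a sim_config")
  n_a <- config$n_agents
  k <- nrow(config$options)
  payout <- config$options$payout_cent
  prob <- config$options$success_prob
  t_max <- config$n_iterations
  forced <- config$forced_exploration_iterations
  eps <- config$epsilon
  scheme <- config$bonus

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  run_seeds <- sample.int(.Machine$integer.max, config$n_runs)

  n_rows <- config$n_runs * t_max * n_a
  run_col <- integer(n_rows); iter_col <- integer(n_rows)
  agent_col <- integer(n_rows); choice_col <- integer(n_rows)
  payout_col <- integer(n_rows); bonus_col <- integer(n_rows)
  pos <- 0L
  agent_idx <- seq_len(n_a)

  for (r in seq_len(config$n_runs)) {
    set.seed(run_seeds[r])
    est <- matrix(0, nrow = n_a, ncol = k)
    cnt <- matrix(0L, nrow = n_a, ncol = k)
    for (t in seq_len(t_max)) {
      if (t <= forced) {
        choice <- sample.int(k, n_a, replace = TRUE)
      } else {
        choice <- integer(n_a)
        for (a in agent_idx)
          choice[a] <- epsilon_greedy_choose(est[a, ], eps)
      }
      pay <- ifelse(stats::runif(n_a) < prob[choice], payout[choice], 0L)
      counts <- tabulate(choice, nbins = k)
      bon <- switch(scheme$kind,
                    none = integer(n_a),
                    additive = scheme$additive_amount_cent *
                      (counts[choice] - 1L),
                    multiplicative = as.integer(pay) * (counts[choice] - 1L))
      reward <- if (config$bonus_in_update) pay + bon else pay
      for (a in agent_idx) {
        j <- choice[a]
        n_j <- cnt[a, j] + 1L
        cnt[a, j] <- n_j
        est[a, j] <- est[a, j] + (reward[a] - est[a, j]) / n_j
      }
      idx <- pos + agent_idx
      run_col[idx] <- r; iter_col[idx] <- t; agent_col[idx] <- agent_idx
      choice_col[idx] <- choice; payout_col[idx] <- as.integer(pay)
      bonus_col[idx] <- as.integer(bon)
      pos <- pos + n_a
    }
  }
  out <- data.frame(run = run_col, iteration = iter_col, agent = agent_col,
                    choice = choice_col, payout_cent = payout_col,
                    bonus_cent = bonus_col)
  attr(out, "sim_config") <- config
  out
}

#' Per-iteration option counts
#'
#' Tabulates how many agents chose each option in every run and iteration.
#'
#' @param records agent-level output of [run_simulation()].
#' @param n_options number of options (defaults to the config carried on
#'   `records`, else `max(records$choice)`).
#' @return Data frame `run`, `iteration`, `option`, `count`; counts sum to
#'   the number of agents within each run-iteration.
#' @export
iteration_counts <- function(records, n_options = NULL) {
  if (is.null(n_options)) {
    cfg <- attr(records, "sim_config")
    n_options <- if (!is.null(cfg)) nrow(cfg$options) else max(records$choice)
  }
  tab <- table(run = records$run, iteration = records$iteration,
               option = factor(records$choice, levels = seq_len(n_options)))
  out <- as.data.frame(tab, responseName = "count")
  out$run <- as.integer(as.character(out$run))
  out$iteration <- as.integer(as.character(out$iteration))
  out$option <- as.integer(as.character(out$option))
  out <- out[order(out$run, out$iteration, out$option), ]
  rownames(out) <- NULL
  out
}

#' Overall choice frequencies by option
#'
#' Percentage of all agent-iteration choices falling on each option,
#' optionally restricted to a window of iterations.
#'
#' @param records agent-level output of [run_simulation()].
#' @param label optional condition label attached to every row.
#' @param iterations optional iteration window to restrict to.
#' @return Data frame `label`, `option`, `percent`; percentages sum to 100.
#' @export
summarize_choice_frequencies <- function(records, label = NA_character_,
                                         iterations = NULL) {
  if (!is.null(iterations))
    records <- records[records$iteration %in% iterations, ]
  if (nrow(records) == 0L)
    stop("summarize_choice_frequencies: no records to summarize")
  cfg <- attr(records, "sim_config")
  k <- if (!is.null(cfg)) nrow(cfg$options) else max(records$choice)
  tab <- tabulate(records$choice, nbins = k)
  data.frame(label = label, option = seq_len(k),
             percent = 100 * tab / sum(tab))
}
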