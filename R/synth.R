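#' Agent behavior profile for synthetic sessions
#'
#' Embodies the balance between goal-oriented and social motivation that the
#' generators use to plant recoverable ground truth. In card sessions an
#' agent with a `goal_option` plays it except on exploratory rounds (drawn
#' with probability `epsilon`), unless an explicit `switch_schedule` lists
#' the rounds at which it must change option. In movement sessions the agent
#' steps toward a point interpolating between its goal field and the group
#' centroid with weight `cohesion_weight`, and `leader_bias` raises its
#' propensity to move early in each turn.
#'
#' @param epsilon exploration probability in card sessions.
#' @param switch_schedule optional integer vector of rounds at which the
#'   agent deterministically changes option.
#' @param cohesion_weight non-negative attraction toward the group centroid.
#' @param leader_bias non-negative propensity to move first toward the goal.
#' @param goal_option target option id, or `NA` for a pure learner.
#' @return A list of class `agent_profile`.
#' @export
agent_profile <- function(epsilon = 0, switch_schedule = NULL,
                          cohesion_weight = 0, leader_bias = 0,
                          goal_option = 1L) {
  if (!is.finite(cohesion_weight) || cohesion_weight < 0)
    stop("agent_profile: cohesion_weight must be finite and >= 0")
  if (!is.finite(leader_bias) || leader_bias < 0)
    stop("agent_profile: leader_bias must be finite and >= 0")
  if (epsilon < 0 || epsilon > 1)
    stop("agent_profile: epsilon must lie in [0, 1]")
  structure(list(epsilon = epsilon, switch_schedule = switch_schedule,
                 cohesion_weight = cohesion_weight,
                 leader_bias = leader_bias,
                 goal_option = goal_option),
            class = "agent_profile")
}

#' World configuration for movement sessions
#'
#' @param board_radius hexagonal board radius (default 5, 91 cells).
#' @param reward_cells data frame `option_id`, `q`, `r` placing one cell per
#'   option; defaults to four cells at distance 4 from the center.
#' @param options an [option_set()] (default [card_options()], the
#'   reward-field distributions of the movement experiment).
#' @param n_rounds rounds per session.
#' @param moves_per_round cap on movement turns per agent per round.
#' @param bonus a [bonus_scheme()].
#' @param seed integer seed.
#' @return A list of class `world_config`.
#' @export
world_config <- function(board_radius = 5L, reward_cells = NULL,
                         options = card_options(), n_rounds = 30L,
                         moves_per_round = 10L,
                         bonus = bonus_scheme("additive"), seed = 1L) {
  board <- hex_board(board_radius)
  if (is.null(reward_cells))
    reward_cells <- data.frame(option_id = 1:4,
                               q = c(4L, 0L, -4L, 0L),
                               r = c(0L, 4L, 0L, -4L))
  if (nrow(reward_cells) != nrow(options))
    stop("world_config: one reward cell per option required")
  if (anyDuplicated(reward_cells[, c("q", "r")]))
    stop("world_config: reward cells must be distinct")
  if (!all(on_board(reward_cells$q, reward_cells$r, board)))
    stop("world_config: reward cell off board")
  structure(list(board = board, reward_cells = reward_cells,
                 options = options, n_rounds = as.integer(n_rounds),
                 moves_per_round = as.integer(moves_per_round),
                 bonus = bonus, seed = as.integer(seed)),
            class = "world_config")
}

draw_payout <- function(options, option) {
  ok <- stats::runif(length(option)) < options$success_prob[option]
  ifelse(ok, options$payout_cent[option], 0L)
}

#' Generate a synthetic card-choice session
#'
#' Emulates the structure of a card-choice experiment session: `n_rounds`
#' rounds in which each of the players picks one of the option stacks,
#' payouts are drawn from the option's Bernoulli payout distribution, and an
#' additive cohesion bonus of `amount * (m - 1)` cents is paid when `m`
#' players co-choose (the bonus is reported separately and never corrupts
#' anyone's feedback). Agents follow their [agent_profile()]: scheduled
#' switchers realize their switch rounds exactly; goal-directed agents stay
#' on their goal except on exploratory rounds; pure learners (goal `NA`) run
#' epsilon-greedy with sample-average updates.
#'
#' @param profiles list of [agent_profile()]s, one per player.
#' @param options an [option_set()] (default [card_options()]).
#' @param bonus a [bonus_scheme()].
#' @param seed integer seed.
#' @param n_rounds number of rounds (default 30).
#' @return A list of class `card_session` with `choices` (data frame
#'   `round`, `player`, `option`, `payout_cent`, `bonus_cent`) and `truth`
#'   (realized switch rounds and profile parameters per player).
#' @export
generate_card_session <- function(profiles, options = card_options(),
                                  bonus = bonus_scheme("additive"),
                                  seed = 1L, n_rounds = 30L) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "agent_profile")))
  n <- length(profiles)
  k <- nrow(options)
  if (n < 2L) stop("generate_card_session: need at least 2 profiles")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  states <- lapply(seq_len(n), function(i) agent_state(k))
  current <- vapply(profiles, function(p)
    if (is.na(p$goal_option)) sample.int(k, 1L) else as.integer(p$goal_option),
    integer(1))
  rows <- vector("list", n_rounds)
  for (t in seq_len(n_rounds)) {
    option <- integer(n)
    for (i in seq_len(n)) {
      p <- profiles[[i]]
      if (!is.null(p$switch_schedule)) {
        option[i] <- if (t %in% p$switch_schedule)
          (current[i] %% k) + 1L else current[i]
      } else if (!is.na(p$goal_option)) {
        option[i] <- if (stats::runif(1L) < p$epsilon)
          sample.int(k, 1L) else as.integer(p$goal_option)
      } else {
        option[i] <- epsilon_greedy_choose(states[[i]]$value_estimates,
                                           p$epsilon)
      }
    }
    payout <- draw_payout(options, option)
    counts <- tabulate(option, nbins = k)
    bon <- vapply(seq_len(n), function(i)
      as.integer(compute_bonus(counts, option[i], payout[i], bonus)),
      integer(1))
    for (i in seq_len(n))  # separated feedback: update on payout only
      if (is.na(profiles[[i]]$goal_option))
        states[[i]] <- update_estimate(states[[i]], option[i], payout[i])
    current <- option
    rows[[t]] <- data.frame(round = t, player = seq_len(n), option = option,
                            payout_cent = as.integer(payout),
                            bonus_cent = bon)
  }
  choices <- do.call(rbind, rows)
  truth <- list(
    switch_rounds = lapply(seq_len(n), function(i) {
      log <- choices[choices$player == i, ]
      opt <- log$option[order(log$round)]
      which(opt[-1L] != opt[-length(opt)]) + 1L
    }),
    goal_option = vapply(profiles, `[[`, numeric(1), "goal_option"),
    epsilon = vapply(profiles, `[[`, numeric(1), "epsilon"))
  structure(list(choices = choices, options = options, bonus = bonus,
                 seed = seed, profiles = profiles, truth = truth),
            class = "card_session")
}

#' Generate a synthetic movement session on the hexagonal board
#'
#' Emulates a movement-paradigm session: players start on the central ring
#' of the board and, each round, alternate single-cell steps (agents with
#' higher `leader_bias` tend to move earlier in each turn) toward a target
#' that interpolates between their goal reward field and the current group
#' centroid with weight `cohesion_weight`. An agent stops once no
#' neighboring cell improves its distance to the target, and each agent
#' takes at most `moves_per_round` steps per round. Positions persist across
#' rounds. A player's round option is the reward field it occupies at round
#' end (`NA` if off-field, in which case it earns nothing); payouts and
#' cohesion bonuses follow the world's option set and bonus scheme.
#'
#' The movement rule is a deliberately minimal goal/centroid interpolation:
#' it is not a model of human strategy, only a mechanism that plants graded,
#' recoverable leadership and cohesion signal.
#'
#' @param profiles list of [agent_profile()]s, one per player.
#' @param world a [world_config()].
#' @param start_positions optional data frame `player`, `q`, `r`; by
#'   default players occupy distinct cells of the central ring.
#' @return A list of class `honeycomb_session` with `moves`,
#'   `initial_positions`, `choices`, `world` and `truth`.
#' @export
generate_honeycomb_session <- function(profiles, world,
                                       start_positions = NULL) {
  stopifnot(inherits(world, "world_config"),
            all(vapply(profiles, inherits, logical(1), "agent_profile")))
  n <- length(profiles)
  ring <- hex_neighbors()
  if (is.null(start_positions) && n > nrow(ring))
    stop("generate_honeycomb_session: at most ", nrow(ring),
         " players fit on the central ring")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(world$seed)

  pos <- if (is.null(start_positions)) {
    data.frame(player = seq_len(n), q = ring$q[seq_len(n)],
               r = ring$r[seq_len(n)])
  } else {
    stopifnot(all(on_board(start_positions$q, start_positions$r,
                           world$board)))
    data.frame(player = seq_len(n), q = as.integer(start_positions$q),
               r = as.integer(start_positions$r))
  }
  initial_positions <- pos
  goal_cells <- world$reward_cells[
    match(vapply(profiles, `[[`, numeric(1), "goal_option"),
          world$reward_cells$option_id), c("q", "r")]
  w_coh <- vapply(profiles, `[[`, numeric(1), "cohesion_weight")
  bias <- vapply(profiles, `[[`, numeric(1), "leader_bias")
  nb <- hex_neighbors()
  moves <- vector("list", 0L)
  choice_rows <- vector("list", world$n_rounds)

  for (rd in seq_len(world$n_rounds)) {
    event <- 0L
    for (turn in seq_len(world$moves_per_round)) {
      order_idx <- sample.int(n, n, prob = bias + 0.1)
      moved_any <- FALSE
      for (i in order_idx) {
        cart <- hex_to_cart(pos$q, pos$r)
        centroid <- colMeans(cart)
        g <- hex_to_cart(goal_cells$q[i], goal_cells$r[i])
        target <- (g + w_coh[i] * rbind(centroid)) / (1 + w_coh[i])
        here <- sqrt(sum((cart[i, ] - target)^2))
        cand_q <- pos$q[i] + nb$q
        cand_r <- pos$r[i] + nb$r
        ok <- on_board(cand_q, cand_r, world$board)
        if (!any(ok)) next
        cand <- hex_to_cart(cand_q[ok], cand_r[ok])
        dd <- sqrt(rowSums((cand - rbind(target)[rep(1, nrow(cand)), ])^2))
        best <- which.min(dd)
        if (dd[best] < here - 1e-9) {
          event <- event + 1L
          moves[[length(moves) + 1L]] <- data.frame(
            round = rd, event_index = event, player = i,
            from_q = pos$q[i], from_r = pos$r[i],
            to_q = cand_q[ok][best], to_r = cand_r[ok][best])
          pos$q[i] <- cand_q[ok][best]
          pos$r[i] <- cand_r[ok][best]
          moved_any <- TRUE
        }
      }
      if (!moved_any) break
    }
    cell_key <- paste(pos$q, pos$r)
    field_key <- paste(world$reward_cells$q, world$reward_cells$r)
    option <- world$reward_cells$option_id[match(cell_key, field_key)]
    payout <- integer(n)
    on_field <- !is.na(option)
    payout[on_field] <- draw_payout(world$options, option[on_field])
    counts <- tabulate(option[on_field], nbins = nrow(world$options))
    bon <- integer(n)
    for (i in which(on_field))
      bon[i] <- as.integer(compute_bonus(counts, option[i], payout[i],
                                         world$bonus))
    choice_rows[[rd]] <- data.frame(round = rd, player = seq_len(n),
                                    option = option,
                                    payout_cent = payout, bonus_cent = bon)
  }
  moves <- if (length(moves)) do.call(rbind, moves) else
    data.frame(round = integer(0), event_index = integer(0),
               player = integer(0), from_q = integer(0), from_r = integer(0),
               to_q = integer(0), to_r = integer(0))
  truth <- list(cohesion_weight = w_coh, leader_bias = bias,
                goal_option = vapply(profiles, `[[`, numeric(1),
                                     "goal_option"))
  structure(list(moves = moves, initial_positions = initial_positions,
                 choices = do.call(rbind, choice_rows), world = world,
                 profiles = profiles, truth = truth),
            class = "honeycomb_session")
}

#' Ground-truth labels of a synthetic session
#'
#' Extracts the planted per-player labels (switch rounds, leader flags,
#' cohesion weights, goal options) from a session generated by
#' [generate_card_session()] or [generate_honeycomb_session()], in a flat
#' data frame joinable to metric outputs on `player`.
#'
#' @param session a `card_session` or `honeycomb_session`.
#' @param leader_threshold `leader_bias` above which a player is flagged as
#'   a designated leader.
#' @return A data frame with one row per player.
#' @export
ground_truth_labels <- function(session, leader_threshold = 1) {
  if (inherits(session, "card_session")) {
    n <- length(session$profiles)
    data.frame(player = seq_len(n),
               goal_option = session$truth$goal_option,
               epsilon = session$truth$epsilon,
               n_switches = vapply(session$truth$switch_rounds, length,
                                   integer(1)),
               switch_rounds = vapply(session$truth$switch_rounds,
                                      paste, character(1), collapse = ";"))
  } else if (inherits(session, "honeycomb_session")) {
    n <- length(session$profiles)
    data.frame(player = seq_len(n),
               goal_option = session$truth$goal_option,
               cohesion_weight = session$truth$cohesion_weight,
               leader_bias = session$truth$leader_bias,
               is_leader = session$truth$leader_bias > leader_threshold)
  } else {
    stop("ground_truth_labels: not a session generated by this package")
  }
}
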