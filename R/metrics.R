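#' Decision-quality choice score
#'
#' Sums per-round points over a player's choice log: 3 points for the
#' profitable option, 2 for a neutral option, 1 for the unprofitable option,
#' 0 for a missed round (no choice). The score ranges from 0 to
#' `3 * n_rounds` and quantifies overall decision quality; it is an analysis
#' statistic, not the player's earnings.
#'
#' @param choices data frame for one player with columns `round` and
#'   `option` (`NA` = missed round).
#' @param options an [option_set()] supplying each option's role, or a named
#'   character vector mapping option id to
#'   `"profitable"`/`"neutral"`/`"unprofitable"`.
#' @return Integer score.
#' @examples
#' opts <- card_options()
#' log <- data.frame(round = 1:3, option = c(1, 2, NA))
#' choice_score(log, opts)  # 3 + 2 + 0
#' @export
choice_score <- function(choices, options) {
  if (anyDuplicated(choices$round))
    stop("choice_score: duplicated round in choice log")
  roles <- option_roles(options)
  opt <- choices$option
  chosen <- !is.na(opt)
  if (any(chosen & !(opt %in% seq_along(roles))))
    stop("choice_score: unknown option id in choice log")
  points <- c(profitable = 3L, neutral = 2L, unprofitable = 1L)
  sum(points[roles[opt[chosen]]])
}

option_roles <- function(options) {
  if (inherits(options, "option_set")) {
    stats::setNames(options$role, options$option_id)
  } else if (is.character(options)) {
    options
  } else stop("expected an option_set or a named role vector")
}

#' Half-change round: length of the exploration phase
#'
#' A *change* occurs in round `t` when the option chosen in `t` differs from
#' the player's most recent prior choice (missed rounds are skipped, so a
#' change is only counted between two actual choices). The half-change round
#' is the earliest round by which at least half of the player's total
#' changes (`ceiling(total / 2)`) have occurred — an operationalization of
#' when exploration gives way to exploitation. A player who never changes
#' gets round 1 (immediate exploitation); the result then carries the
#' attribute `no_changes = TRUE` so such players can be excluded.
#'
#' @param choices data frame for one player with columns `round` and
#'   `option` (`NA` = missed), in any row order.
#' @return Integer round in `[1, n_rounds]`.
#' @examples
#' log <- data.frame(round = 1:6, option = c(1, 2, 3, 4, 1, 1))
#' half_change_round(log)  # changes in rounds 2:5; half reached in round 3
#' @export
half_change_round <- function(choices) {
  if (nrow(choices) == 0L)
    stop("half_change_round: empty choice log")
  if (anyDuplicated(choices$round))
    stop("half_change_round: duplicated round in choice log")
  choices <- choices[order(choices$round), ]
  opt <- choices$option[!is.na(choices$option)]
  rounds <- choices$round[!is.na(choices$option)]
  if (length(opt) >= 2L) {
    changed <- opt[-1L] != opt[-length(opt)]
    change_rounds <- rounds[-1L][changed]
  } else {
    change_rounds <- integer(0)
  }
  total <- length(change_rounds)
  if (total == 0L)
    return(structure(1L, no_changes = TRUE))
  cum <- seq_len(total)
  as.integer(change_rounds[match(TRUE, cum >= ceiling(total / 2))])
}

# Orders move events by round then event_index and checks they form a
# consistent trajectory (each move departs from the player's current cell,
# every cell on the board, from != to). Errors name the offending row.
#' Validate a movement trajectory
#'
#' @param moves data frame with columns `round`, `event_index`, `player`,
#'   `from_q`, `from_r`, `to_q`, `to_r`.
#' @param initial_positions data frame `player`, `q`, `r` at game start.
#' @param board a [hex_board()].
#' @return The ordered moves, invisibly.
#' @export
validate_trajectory <- function(moves, initial_positions, board = hex_board()) {
  need <- c("round", "event_index", "player", "from_q", "from_r", "to_q", "to_r")
  miss <- setdiff(need, names(moves))
  if (length(miss))
    stop("trajectory: missing columns: ", paste(miss, collapse = ", "))
  if (!all(on_board(initial_positions$q, initial_positions$r, board)))
    stop("trajectory: initial position off board")
  moves <- moves[order(moves$round, moves$event_index), ]
  for (rd in unique(moves$round)) {
    ei <- moves$event_index[moves$round == rd]
    if (any(diff(ei) <= 0))
      stop("trajectory: event_index not strictly increasing in round ", rd)
  }
  pos <- initial_positions
  rownames(pos) <- as.character(pos$player)
  for (i in seq_len(nrow(moves))) {
    m <- moves[i, ]
    p <- as.character(m$player)
    if (!p %in% rownames(pos))
      stop("trajectory: unknown player '", p, "' at row ", i)
    if (m$from_q == m$to_q && m$from_r == m$to_r)
      stop("trajectory: null move (from == to) at row ", i)
    if (!on_board(m$to_q, m$to_r, board))
      stop("trajectory: destination off board at row ", i)
    if (pos[p, "q"] != m$from_q || pos[p, "r"] != m$from_r)
      stop("trajectory: discontinuous move for player '", p, "' at row ", i,
           " (expected from (", pos[p, "q"], ",", pos[p, "r"], "))")
    pos[p, c("q", "r")] <- c(m$to_q, m$to_r)
  }
  invisible(moves)
}

#' Leadership-followership (L-F) scores from movement
#'
#' Every player starts each round with an L-F score of 0. Whenever a player
#' moves, the change in distance to every other player is evaluated pairwise:
#' if the mover's distance to another player increases, the mover gains 1
#' point and that player loses 1 (the mover leads away / the other is left
#' behind); if it decreases, the mover loses 1 and the other gains 1 (the
#' mover follows); no change leaves both untouched. Increments therefore sum
#' to zero across players on every move. Per-round scores summed over rounds
#' give the overall L-F score: positive values indicate leading, negative
#' values following.
#'
#' @inheritParams validate_trajectory
#' @param n_rounds number of rounds (defaults to the largest round seen).
#' @return A list with `per_round` (players x rounds integer matrix) and
#'   `total` (named integer vector).
#' @export
lf_scores <- function(moves, initial_positions, board = hex_board(),
                      n_rounds = NULL) {
  moves <- validate_trajectory(moves, initial_positions, board)
  players <- as.character(initial_positions$player)
  if (is.null(n_rounds))
    n_rounds <- max(c(1L, moves$round))
  per_round <- matrix(0L, nrow = length(players), ncol = n_rounds,
                      dimnames = list(players, NULL))
  pos <- initial_positions
  rownames(pos) <- as.character(pos$player)
  for (i in seq_len(nrow(moves))) {
    m <- moves[i, ]
    p <- as.character(m$player)
    others <- setdiff(players, p)
    d_before <- hex_distance(m$from_q, m$from_r, pos[others, "q"], pos[others, "r"])
    d_after <- hex_distance(m$to_q, m$to_r, pos[others, "q"], pos[others, "r"])
    delta <- sign(d_after - d_before)
    per_round[p, m$round] <- per_round[p, m$round] + sum(delta)
    per_round[others, m$round] <- per_round[others, m$round] - as.integer(delta)
    pos[p, c("q", "r")] <- c(m$to_q, m$to_r)
  }
  list(per_round = per_round,
       total = structure(as.integer(rowSums(per_round)), names = players))
}

#' Spatial cohesion: field distribution
#'
#' `field_distribution_pct` is the percentage of board cells occupied by any
#' player at any time during the game (fewer used fields = tighter group).
#' `field_distribution_move_pct` is the mean, over post-move snapshots, of
#' the percentage of board cells simultaneously occupied (at most
#' `n_players / n_cells * 100`). With no moves both are computed from the
#' initial configuration.
#'
#' @inheritParams lf_scores
#' @return A list with `field_distribution_pct` and
#'   `field_distribution_move_pct`.
#' @export
field_distribution <- function(moves, initial_positions, board = hex_board()) {
  moves <- validate_trajectory(moves, initial_positions, board)
  key <- function(q, r) paste(q, r)
  used <- unique(key(initial_positions$q, initial_positions$r))
  pos <- initial_positions
  rownames(pos) <- as.character(pos$player)
  occ_pct <- numeric(0)
  if (nrow(moves) > 0L) {
    for (i in seq_len(nrow(moves))) {
      m <- moves[i, ]
      pos[as.character(m$player), c("q", "r")] <- c(m$to_q, m$to_r)
      used <- union(used, key(m$to_q, m$to_r))
      occ_pct <- c(occ_pct, length(unique(key(pos$q, pos$r))))
    }
  } else {
    occ_pct <- length(unique(key(pos$q, pos$r)))
  }
  list(field_distribution_pct = 100 * length(used) / board$n_cells,
       field_distribution_move_pct = 100 * mean(occ_pct) / board$n_cells)
}

#' Spatial cohesion: weighted clustering (transitivity)
#'
#' Players form a complete undirected weighted graph whose edge weights
#' increase with spatial closeness: `w(i, j) = 1 / (1 + d(i, j))` by default
#' (finite for co-located players), or `1 / max(d, 1)` with
#' `weight = "inverse"`. The global clustering coefficient is the mean over
#' nodes of the local weighted clustering, using geometric-mean triangle
#' intensity (Onnela) by default or the Zhang-Horvath ratio form. Any
#' configuration with all pairwise distances equal — in particular a fully
#' stacked group — attains the maximum of 1; spatial dispersion with unequal
#' distances lowers it.
#'
#' @param positions data frame `player`, `q`, `r` for one snapshot, or a
#'   list of such snapshots (the mean over snapshots is returned).
#' @param weight edge-weight transform of hex distance.
#' @param variant weighted-clustering definition.
#' @return Transitivity in `[0, 1]`.
#' @export
transitivity <- function(positions, weight = c("inverse_plus_one", "inverse"),
                         variant = c("onnela", "zhang")) {
  weight <- match.arg(weight)
  variant <- match.arg(variant)
  if (is.data.frame(positions))
    positions <- list(positions)
  mean(vapply(positions, transitivity_snapshot, numeric(1),
              weight = weight, variant = variant))
}

transitivity_snapshot <- function(pos, weight, variant) {
  n <- nrow(pos)
  if (n < 3L)
    stop("transitivity: need at least 3 players")
  d <- outer(seq_len(n), seq_len(n), function(i, j)
    hex_distance(pos$q[i], pos$r[i], pos$q[j], pos$r[j]))
  w <- switch(weight,
              inverse_plus_one = 1 / (1 + d),
              inverse = 1 / pmax(d, 1))
  diag(w) <- 0
  w_hat <- w / max(w)
  local <- numeric(n)
  for (i in seq_len(n)) {
    jk <- setdiff(seq_len(n), i)
    if (variant == "onnela") {
      s <- 0
      pairs <- utils::combn(jk, 2L)
      for (p in seq_len(ncol(pairs))) {
        j <- pairs[1L, p]; k <- pairs[2L, p]
        s <- s + (w_hat[i, j] * w_hat[i, k] * w_hat[j, k])^(1 / 3)
      }
      local[i] <- s / choose(n - 1L, 2L)
    } else {
      num <- 0; den <- 0
      pairs <- utils::combn(jk, 2L)
      for (p in seq_len(ncol(pairs))) {
        j <- pairs[1L, p]; k <- pairs[2L, p]
        num <- num + w_hat[i, j] * w_hat[i, k] * w_hat[j, k]
        den <- den + w_hat[i, j] * w_hat[i, k]
      }
      local[i] <- if (den > 0) num / den else 0
    }
  }
  mean(local)
}

#' Group-level cohesion summary of a movement session
#'
#' Convenience wrapper computing both field-distribution percentages and the
#' mean post-move transitivity of a trajectory.
#'
#' @inheritParams lf_scores
#' @param ... passed to [transitivity()].
#' @return A list with `field_distribution_pct`,
#'   `field_distribution_move_pct` and `transitivity`.
#' @export
group_cohesion <- function(moves, initial_positions, board = hex_board(), ...) {
  moves <- validate_trajectory(moves, initial_positions, board)
  fd <- field_distribution(moves, initial_positions, board)
  snaps <- list()
  pos <- initial_positions
  rownames(pos) <- as.character(pos$player)
  if (nrow(moves) > 0L) {
    for (i in seq_len(nrow(moves))) {
      m <- moves[i, ]
      pos[as.character(m$player), c("q", "r")] <- c(m$to_q, m$to_r)
      snaps[[i]] <- pos
    }
  } else {
    snaps[[1L]] <- pos
  }
  c(fd, list(transitivity = transitivity(snaps, ...)))
}
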