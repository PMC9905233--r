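# Independent brute-force oracles and small fixture builders.

# Half-change round recomputed directly from the definition: walk the
# rounds, count a change whenever the chosen option differs from the most
# recent prior actual choice, then scan for the first round whose
# cumulative change count reaches ceiling(total / 2).
oracle_half_change <- function(rounds, options) {
  ord <- order(rounds)
  rounds <- rounds[ord]; options <- options[ord]
  last <- NA
  change_at <- logical(length(rounds))
  for (i in seq_along(rounds)) {
    if (is.na(options[i])) next
    if (!is.na(last) && options[i] != last) change_at[i] <- TRUE
    last <- options[i]
  }
  total <- sum(change_at)
  if (total == 0) return(1L)
  cum <- cumsum(change_at)
  for (i in seq_along(rounds))
    if (cum[i] >= ceiling(total / 2)) return(rounds[i])
}

# Weighted global clustering by explicit triple enumeration, O(n^3).
oracle_transitivity <- function(pos, weight = "inverse_plus_one",
                                variant = "onnela") {
  n <- nrow(pos)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    d[i, j] <- cohesim::hex_distance(pos$q[i], pos$r[i], pos$q[j], pos$r[j])
  w <- if (weight == "inverse_plus_one") 1 / (1 + d) else 1 / pmax(d, 1)
  diag(w) <- 0
  w <- w / max(w)
  local <- numeric(n)
  for (i in 1:n) {
    s <- 0; den <- 0; npairs <- 0
    for (j in 1:n) for (k in 1:n) {
      if (j >= k || j == i || k == i) next
      npairs <- npairs + 1
      if (variant == "onnela") {
        s <- s + (w[i, j] * w[i, k] * w[j, k])^(1 / 3)
      } else {
        s <- s + w[i, j] * w[i, k] * w[j, k]
        den <- den + w[i, j] * w[i, k]
      }
    }
    local[i] <- if (variant == "onnela") s / npairs else s / den
  }
  mean(local)
}

# The two-move three-player scenario: A steps away from both B and C, then
# B steps toward A and away from C.
worked_example_moves <- function() {
  list(initial = data.frame(player = c("A", "B", "C"),
                            q = c(0L, 0L, 1L), r = c(1L, 0L, 0L)),
       moves = data.frame(round = c(1L, 1L), event_index = c(1L, 2L),
                          player = c("A", "B"),
                          from_q = c(0L, 0L), from_r = c(1L, 0L),
                          to_q = c(-1L, -1L), to_r = c(2L, 1L)))
}

# Six default-parameter profiles locked on one goal option.
locked_profiles <- function(goal = 1L, n = 6L, ...) {
  replicate(n, cohesim::agent_profile(goal_option = goal, ...),
            simplify = FALSE)
}

random_cell <- function(board, n = 1L) {
  idx <- sample.int(nrow(board$cells), n, replace = TRUE)
  board$cells[idx, , drop = FALSE]
}
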