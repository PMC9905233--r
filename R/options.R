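#' Reward option sets
#'
#' A reward option is a stack/field/leader paying `payout_cent` with
#' probability `success_prob` on each round, independently across rounds and
#' players. An option set is a data frame with one row per option and columns
#' `option_id`, `payout_cent`, `success_prob` and `role`
#' (profitable / neutral / unprofitable).
#'
#' @param payout_cent integer vector of payouts in cents (>= 0).
#' @param success_prob numeric vector of per-round success probabilities in
#'   \[0, 1\].
#' @param role character vector classifying each option as `"profitable"`,
#'   `"neutral"` or `"unprofitable"`.
#' @return A data frame of class `option_set`.
#' @examples
#' opts <- option_set(c(20, 10, 20, 20), c(0.8, 0.9, 0.45, 0.2),
#'                    c("profitable", "neutral", "neutral", "unprofitable"))
#' expected_value(opts, n_rounds = 30)
#' @export
option_set <- function(payout_cent, success_prob,
                       role = c("profitable", "neutral", "neutral",
                                "unprofitable")) {
  k <- length(payout_cent)
  if (k < 2L)
    stop("option_set: need at least 2 options, got ", k)
  if (length(success_prob) != k || length(role) != k)
    stop("option_set: payout_cent, success_prob and role lengths differ")
  if (any(success_prob < 0 | success_prob > 1))
    stop("option_set: success_prob must lie in [0, 1]")
  if (any(payout_cent < 0))
    stop("option_set: payout_cent must be non-negative")
  role <- match.arg(role, c("profitable", "neutral", "unprofitable"),
                    several.ok = TRUE)
  out <- data.frame(option_id = seq_len(k),
                    payout_cent = as.integer(payout_cent),
                    success_prob = as.numeric(success_prob),
                    role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("option_set", "data.frame")
  out
}

#' Built-in option sets
#'
#' `movement_options()` is the four-leader set used in the simulation study
#' (profitable 20c/80%, secure neutral 10c/90%, risky neutral 20c/45%,
#' unprofitable 20c/20%). `card_options()` is the card-stack / reward-field
#' set of the behavioral sessions (30c/80%, 10c/90%, 30c/30%, 10c/20%),
#' where the profitable option is more clearly separated (expected value
#' 720c vs 270c for the neutral options over 30 rounds).
#'
#' @return An [option_set()].
#' @export
movement_options <- function() {
  option_set(c(20L, 10L, 20L, 20L), c(0.8, 0.9, 0.45, 0.2))
}

#' @rdname movement_options
#' @export
card_options <- function() {
  option_set(c(30L, 10L, 30L, 10L), c(0.8, 0.9, 0.3, 0.2))
}

#' Expected total payout of each option
#'
#' For a stationary option the expected number of successes over `n_rounds`
#' rounds is `n_rounds * success_prob`, and the expected value in cents is
#' `n_rounds * success_prob * payout_cent`.
#'
#' @param options an [option_set()].
#' @param n_rounds number of rounds (default 30).
#' @return A data frame with columns `option_id`, `expected_successes` and
#'   `expected_value_cent`.
#' @export
expected_value <- function(options, n_rounds = 30L) {
  stopifnot(inherits(options, "option_set"))
  data.frame(option_id = options$option_id,
             expected_successes = n_rounds * options$success_prob,
             expected_value_cent = n_rounds * options$success_prob *
               options$payout_cent)
}

#' Cohesion-bonus schemes
#'
#' Three bonus structures couple an agent's payoff to the number of
#' co-choosers `m` of the same option (including the agent itself):
#' `none` pays no bonus; `additive` pays a fixed amount (default 3 cents)
#' for each *other* co-chooser, i.e. `amount * (m - 1)`; `multiplicative`
#' multiplies the round's payout by `m`, i.e. a bonus increment of
#' `payout * (m - 1)` on top of the base payout.
#'
#' @param kind `"none"`, `"additive"` or `"multiplicative"`.
#' @param additive_amount_cent per-co-chooser amount for the additive
#'   scheme; ignored otherwise.
#' @return A list of class `bonus_scheme`.
#' @export
bonus_scheme <- function(kind = c("none", "additive", "multiplicative"),
                         additive_amount_cent = 3L) {
  kind <- match.arg(kind)
  if (additive_amount_cent < 0)
    stop("bonus_scheme: additive_amount_cent must be non-negative")
  structure(list(kind = kind,
                 additive_amount_cent = as.integer(additive_amount_cent)),
            class = "bonus_scheme")
}

#' Bonus earned by one agent in one round
#'
#' @param counts integer vector of agents per option for the round (the
#'   focal agent included).
#' @param chosen option id chosen by the focal agent.
#' @param payout the focal agent's base payout this round, in cents.
#' @param scheme a [bonus_scheme()].
#' @return Bonus in cents (the increment above the base payout).
#' @export
compute_bonus <- function(counts, chosen, payout, scheme) {
  stopifnot(inherits(scheme, "bonus_scheme"))
  m <- counts[chosen]
  if (is.na(m) || m < 1L)
    stop("compute_bonus: counts[chosen] must include the focal agent")
  switch(scheme$kind,
         none = 0L,
         additive = scheme$additive_amount_cent * (m - 1L),
         multiplicative = as.integer(payout) * (m - 1L))
}
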