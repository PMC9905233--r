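test_that("hex distance is the axial metric", {
  expect_equal(hex_distance(0, 0, 0, 0), 0)
  expect_equal(hex_distance(0, 0, 2, 0), 2)
  expect_equal(hex_distance(0, 0, 1, -1), 1)
  board <- hex_board(5)
  expect_equal(board$n_cells, 91)
  set.seed(3)
  for (i in 1:1000) {
    tri <- random_cell(board, 3)
    dab <- hex_distance(tri$q[1], tri$r[1], tri$q[2], tri$r[2])
    dbc <- hex_distance(tri$q[2], tri$r[2], tri$q[3], tri$r[3])
    dac <- hex_distance(tri$q[1], tri$r[1], tri$q[3], tri$r[3])
    expect_lte(dac, dab + dbc)
    expect_equal(dab, hex_distance(tri$q[2], tri$r[2], tri$q[1], tri$r[1]))
  }
})

test_that("choice score awards 3/2/1 points and 0 for missed rounds", {
  opts <- card_options()
  all_prof <- data.frame(round = 1:30, option = 1L)
  expect_identical(choice_score(all_prof, opts), 90L)
  mixed <- data.frame(round = 1:30,
                      option = c(rep(1L, 10), rep(2L, 5), rep(3L, 5),
                                 rep(4L, 5), rep(NA, 5)))
  expect_identical(choice_score(mixed, opts), 55L)
  expect_identical(choice_score(data.frame(round = 1:5, option = NA), opts), 0L)
  expect_error(choice_score(data.frame(round = 1, option = 9), opts),
               "unknown option")
  expect_error(choice_score(data.frame(round = c(1, 1), option = 1), opts),
               "duplicated round")
  # bounds on random logs
  set.seed(9)
  for (i in 1:20) {
    log <- data.frame(round = 1:30,
                      option = sample(c(1:4, NA), 30, replace = TRUE))
    sc <- choice_score(log, opts)
    expect_gte(sc, 0L); expect_lte(sc, 90L)
  }
})

test_that("half-change round matches the definition and its oracle", {
  ch <- function(opt) data.frame(round = seq_along(opt), option = opt)
  expect_identical(half_change_round(ch(c(1, 2, 3, 4, 1, 1))), 3L)
  single <- c(rep(1, 9), rep(2, 21))
  expect_identical(half_change_round(ch(single)), 10L)
  const <- half_change_round(ch(rep(2, 30)))
  expect_identical(as.integer(const), 1L)
  expect_true(attr(const, "no_changes"))
  # missed rounds are skipped: a change is between two actual choices
  expect_identical(as.integer(half_change_round(ch(c(1, NA, 1, NA, 2)))), 5L)
  expect_identical(as.integer(half_change_round(ch(c(1, NA, NA, NA, 1)))), 1L)
  expect_error(half_change_round(ch(integer(0))), "empty")
  # randomized comparison against the brute-force enumerator
  set.seed(21)
  for (i in 1:200) {
    opt <- sample(c(1:4, NA), 30, replace = TRUE)
    got <- as.integer(half_change_round(ch(opt)))
    expect_identical(got, as.integer(oracle_half_change(1:30, opt)))
    expect_gte(got, 1L); expect_lte(got, 30L)
  }
})

test_that("L-F scores replay the two-move worked example", {
  ex <- worked_example_moves()
  # move 1 alone: mover A gains per pair, B and C each lose 1
  lf1 <- lf_scores(ex$moves[1, ], ex$initial)
  expect_identical(lf1$total[c("B", "C")], c(B = -1L, C = -1L))
  expect_identical(lf1$total[["A"]], 2L)  # pairwise rule: +1 per other
  # move 2 increments: A +1 (followed), B net 0, C -1
  lf2 <- lf_scores(ex$moves, ex$initial)
  inc <- lf2$total - lf1$total
  expect_identical(inc, c(A = 1L, B = 0L, C = -1L))
  expect_identical(sum(lf2$total), 0L)
})

test_that("L-F increments are zero-sum and validation catches bad trajectories", {
  for (seed in 1:5) {
    w <- world_config(seed = seed)
    prof <- lapply(1:6, function(i)
      agent_profile(cohesion_weight = runif(1, 0, 3),
                    leader_bias = runif(1, 0, 3),
                    goal_option = sample(4, 1)))
    ses <- generate_honeycomb_session(prof, w)
    lf <- lf_scores(ses$moves, ses$initial_positions, w$board)
    expect_identical(sum(lf$total), 0L)
    expect_true(all(colSums(lf$per_round) == 0L))
  }
  # no moves in a round -> all zeros
  init <- data.frame(player = 1:3, q = c(0, 1, 2), r = c(0, 0, 0))
  no_moves <- data.frame(round = integer(0), event_index = integer(0),
                         player = integer(0), from_q = integer(0),
                         from_r = integer(0), to_q = integer(0),
                         to_r = integer(0))
  lf0 <- lf_scores(no_moves, init)
  expect_true(all(lf0$total == 0L))
  # teleporting player -> error naming the row
  bad <- data.frame(round = 1, event_index = 1, player = 1,
                    from_q = 3, from_r = 0, to_q = 4, to_r = 0)
  expect_error(lf_scores(bad, init), "discontinuous.*row 1")
})

test_that("field distribution counts used and occupied cells", {
  board <- hex_board(5)
  no_moves <- data.frame(round = integer(0), event_index = integer(0),
                         player = integer(0), from_q = integer(0),
                         from_r = integer(0), to_q = integer(0),
                         to_r = integer(0))
  init6 <- data.frame(player = 1:6, q = c(0, 1, -1, 0, 0, 1),
                      r = c(0, 0, 0, 1, -1, -1))
  fd <- field_distribution(no_moves, init6, board)
  expect_equal(fd$field_distribution_pct, 6 / 91 * 100)
  expect_equal(fd$field_distribution_move_pct, 6 / 91 * 100)
  # all players stacked on one cell for the whole game
  stacked <- data.frame(player = 1:6, q = 2, r = 0)
  fs <- field_distribution(no_moves, stacked, board)
  expect_equal(fs$field_distribution_move_pct, 1 / 91 * 100)
  # a walk covering every cell of a radius-1 board reaches 100%
  b1 <- hex_board(1)
  path <- data.frame(q = c(0, 1, 0, -1, -1, 0, 1), r = c(0, 0, 1, 1, 0, -1, -1))
  mv <- data.frame(round = 1, event_index = 1:6, player = 1,
                   from_q = path$q[-7], from_r = path$r[-7],
                   to_q = path$q[-1], to_r = path$r[-1])
  fw <- field_distribution(mv, data.frame(player = 1, q = 0, r = 0), b1)
  expect_equal(fw$field_distribution_pct, 100)
})

test_that("weighted transitivity is maximal for equidistant groups and matches the oracle", {
  stacked <- data.frame(player = 1:6, q = 2, r = 0)
  expect_equal(transitivity(stacked), 1)
  triangle <- data.frame(player = 1:3, q = c(0, 1, 0), r = c(0, 0, 1))
  expect_equal(transitivity(triangle), 1)
  expect_error(transitivity(stacked[1:2, ]), "at least 3")
  set.seed(31)
  board <- hex_board(5)
  for (i in 1:20) {
    pos <- cbind(player = 1:4, random_cell(board, 4))
    for (variant in c("onnela", "zhang")) {
      expect_equal(transitivity(pos, variant = variant),
                   oracle_transitivity(pos, variant = variant),
                   tolerance = 1e-12)
    }
    tv <- transitivity(pos)
    expect_gte(tv, 0); expect_lte(tv, 1)
  }
  # dispersion strictly lowers clustering relative to a stacked group
  spread <- data.frame(player = 1:4, q = c(5, -5, 0, 2),
                       r = c(0, 0, 5, -5))
  expect_lt(transitivity(spread), 1)
  # snapshot sequences average the per-snapshot values
  expect_equal(transitivity(list(stacked, triangle)), 1)
})

test_that("metrics are permutation-equivariant in player labels", {
  w <- world_config(seed = 8)
  prof <- c(list(agent_profile(leader_bias = 4, goal_option = 1)),
            lapply(2:6, function(i)
              agent_profile(cohesion_weight = 2, goal_option = 2)))
  ses <- generate_honeycomb_session(prof, w)
  perm <- c(3, 1, 2, 6, 4, 5)
  relabel <- function(df) {
    df$player <- perm[df$player]
    df
  }
  lf <- lf_scores(ses$moves, ses$initial_positions, w$board)
  lf_p <- lf_scores(relabel(ses$moves), relabel(ses$initial_positions),
                    w$board)
  expect_equal(unname(lf_p$total[as.character(perm)]), unname(lf$total))
  gc <- group_cohesion(ses$moves, ses$initial_positions, w$board)
  gc_p <- group_cohesion(relabel(ses$moves), relabel(ses$initial_positions),
                         w$board)
  expect_equal(gc_p, gc)
})
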