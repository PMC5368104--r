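test_that("Formula 1 and Medal scores follow the published weightings", {
  expect_equal(formula1_score(1L), 25L)
  expect_equal(formula1_score(11L), 0L)
  expect_equal(formula1_score(c(1L, 2L, 3L)), 58L)
  expect_equal(formula1_score(c(1L, NA, 12L)), 25L)
  expect_equal(medal_score(1L), 5L)
  expect_equal(medal_score(2L), 3L)
  expect_equal(medal_score(4L), 0L)
  expect_equal(medal_score(c(1L, 2L, 3L, 10L)), 9L)
})

test_that("the statistic panel counts rounded ranks and splits by ion mode", {
  ranks <- rank_table(
    rank_row("e1", "c1", 1),
    rank_row("e1", "c2", 1),
    rank_row("e1", "c3", 2),
    rank_row("e1", "c4", 11)
  )
  modes <- tibble::tibble(
    challenge_id = paste0("c", 1:4),
    ion_mode = c("positive", "negative", "positive", "positive")
  )
  panel <- summarize_entries(ranks, modes = modes)
  expect_equal(panel$top1, 2L)
  expect_equal(panel$top3, 3L)
  expect_equal(panel$top10, 3L)
  expect_equal(panel$top1_pos, 1L)
  expect_equal(panel$top1_neg, 1L)
  expect_equal(panel$top1, panel$top1_pos + panel$top1_neg)
  expect_equal(panel$formula1, 25L + 25L + 18L)
  expect_equal(panel$medal_score, 5L + 5L + 3L)
})

test_that("a tie-averaged rank 1.5 counts in Top 3 but not Top 1", {
  ranks <- rank_table(rank_row("e1", "c1", 1.5))
  panel <- summarize_entries(ranks)
  expect_equal(panel$top1, 0L)
  expect_equal(panel$top3, 1L)
  expect_equal(panel$medal_score, 3L) # silver, not gold
})

test_that("the panel equals a naive recount on randomized rank tables", {
  set.seed(99)
  for (rep in 1:10) {
    n <- 40
    avg <- sample(c(1, 1.5, 2, 3, 7.5, 12, 400), n, replace = TRUE)
    avg[runif(n) < 0.15] <- NA
    ranks <- rank_table(rank_row("e1", paste0("c", 1:n), avg, n_candidates = 500L))
    panel <- summarize_entries(ranks)
    want <- recount_oracle(avg)
    expect_equal(panel$top1, want$top1)
    expect_equal(panel$top3, want$top3)
    expect_equal(panel$top10, want$top10)
    expect_equal(panel$mean_rank, want$mean_rank)
    expect_equal(panel$median_rank, want$median_rank)
    expect_equal(panel$formula1, want$formula1)
    expect_equal(panel$medal_score, want$medal_score)
  }
})

test_that("quantiles interpolate order statistics of non-missing ranks", {
  ranks <- rank_table(rank_row("e1", paste0("c", 1:5), c(1, 2, 3, 4, NA)))
  panel <- summarize_entries(ranks)
  expect_equal(panel$q50, 2.5)
  expect_equal(panel$q25, unname(quantile(1:4, 0.25)))
})

test_that("missing ranks can be substituted by the candidate count", {
  ranks <- rank_table(
    rank_row("e1", "c1", 1),
    rank_row("e1", "c2", NA)
  )
  counts <- tibble::tibble(
    challenge_id = c("c1", "c2"), n_candidates = c(10L, 1000L)
  )
  excl <- summarize_entries(ranks)
  expect_equal(excl$mean_rank, 1)
  subst <- summarize_entries(ranks,
    missing_rank = "candidate_count",
    candidate_counts = counts
  )
  expect_equal(subst$mean_rank, (1 + 1000) / 2)
})

test_that("gold goes to the lowest-rank entries even outside the Top 10", {
  ranks <- rank_table(
    rank_row("A", "c1", 100),
    rank_row("B", "c1", 250)
  )
  board <- assign_medals(ranks)
  expect_equal(board$medal[board$entry == "A"], "gold")
  expect_equal(board$medal[board$entry == "B"], "silver")
  # single entry: gold regardless of rank
  solo <- assign_medals(rank_table(rank_row("A", "c1", 999)))
  expect_equal(solo$medal, "gold")
})

test_that("joint medals skip positions under competition ranking", {
  ranks <- rank_table(
    rank_row("A", "c1", 1),
    rank_row("B", "c1", 1),
    rank_row("C", "c1", 4)
  )
  board <- assign_medals(ranks)
  expect_setequal(board$entry[board$medal == "gold"], c("A", "B"))
  expect_equal(sum(board$medal == "silver"), 0L)
  expect_equal(board$entry[board$medal == "bronze"], "C")
  dense <- assign_medals(ranks, ties = "dense")
  expect_equal(dense$medal[dense$entry == "C"], "silver")
})

test_that("missing entries never medal; an all-missing challenge awards nothing", {
  ranks <- rank_table(
    rank_row("A", "c1", 5),
    rank_row("B", "c1", NA),
    rank_row("A", "c2", NA),
    rank_row("B", "c2", NA)
  )
  board <- assign_medals(ranks)
  expect_equal(board$medal[board$entry == "A" & board$challenge_id == "c1"], "gold")
  expect_equal(board$medal[board$entry == "B" & board$challenge_id == "c1"], "none")
  expect_true(all(board$medal[board$challenge_id == "c2"] == "none"))
})

test_that("exactly the minimal-rank entries hold gold on random boards", {
  set.seed(17)
  for (rep in 1:20) {
    ranks <- rank_table(rank_row(
      paste0("e", 1:6), "c1",
      sample(c(1, 2, 2, 5, NA, 10), 6, replace = TRUE)
    ))
    board <- assign_medals(ranks)
    if (all(is.na(ranks$average_rank))) {
      expect_true(all(board$medal == "none"))
    } else {
      minr <- min(ranks$average_rank, na.rm = TRUE)
      expect_setequal(
        board$entry[board$medal == "gold"],
        ranks$entry[!is.na(ranks$average_rank) & ranks$average_rank == minr]
      )
    }
  }
})

test_that("olympic tally orders by gold, then silver, then bronze", {
  board <- dplyr::bind_rows(
    assign_medals(rank_table(
      rank_row("A", "c1", 1), rank_row("B", "c1", 2)
    )),
    assign_medals(rank_table(
      rank_row("A", "c2", 2), rank_row("B", "c2", 1)
    )),
    assign_medals(rank_table(
      rank_row("A", "c3", 1), rank_row("B", "c3", 3)
    ))
  )
  tally <- olympic_tally(board)
  expect_equal(tally$entry[1], "A")
  expect_equal(tally$gold, c(2L, 1L))
  expect_equal(tally$position, c(1L, 2L))

  # equal golds: silvers decide
  board2 <- dplyr::bind_rows(
    assign_medals(rank_table(
      rank_row("A", "c1", 1), rank_row("B", "c1", 2), rank_row("C", "c1", 3)
    )),
    assign_medals(rank_table(
      rank_row("A", "c2", 3), rank_row("B", "c2", 1), rank_row("C", "c2", 2)
    )),
    assign_medals(rank_table(
      rank_row("A", "c3", 2), rank_row("B", "c3", 3), rank_row("C", "c3", 1)
    )),
    assign_medals(rank_table(
      rank_row("A", "c4", 5), rank_row("B", "c4", 4), rank_row("C", "c4", 6)
    ))
  )
  tally2 <- olympic_tally(board2)
  expect_equal(tally2$entry[1], "B") # 2 golds
  expect_equal(tally2$gold[1], 2L)
})

test_that("removing one entry changes the medal counts of the others", {
  ranks <- rank_table(
    rank_row("A", "c1", 1),
    rank_row("B", "c1", 2),
    rank_row("C", "c1", 3),
    rank_row("A", "c2", 1),
    rank_row("B", "c2", 2),
    rank_row("C", "c2", 3)
  )
  with_a <- olympic_tally(assign_medals(ranks))
  without_a <- olympic_tally(assign_medals(ranks[ranks$entry != "A", ]))
  expect_equal(with_a$gold[with_a$entry == "B"], 0L)
  expect_equal(without_a$gold[without_a$entry == "B"], 2L)
})

test_that("best-per-participant selection keeps one entry per participant", {
  board <- dplyr::bind_rows(
    assign_medals(rank_table(
      rank_row("m1_run1", "c1", 1), rank_row("m1_run2", "c1", 2),
      rank_row("m2", "c1", 3)
    ))
  )
  participants <- tibble::tibble(
    entry = c("m1_run1", "m1_run2", "m2"),
    participant = c("team1", "team1", "team2")
  )
  best <- olympic_tally(board, participants, best_per_participant = TRUE)
  expect_equal(nrow(best), 2L)
  expect_setequal(best$participant, c("team1", "team2"))
  expect_equal(best$entry[best$participant == "team1"], "m1_run1")
})

test_that("improving a single rank never worsens any score or medal", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 12
    avg <- sample(c(1, 2, 3, 5, 8, 15, 30), n, replace = TRUE)
    ranks <- rank_table(
      rank_row("A", paste0("c", 1:n), avg),
      rank_row("B", paste0("c", 1:n), sample(c(1, 4, 9, 20), n, replace = TRUE))
    )
    eligible <- which(ranks$entry == "A" & ranks$average_rank > 1)
    pick <- eligible[sample(length(eligible), 1)]
    improved <- ranks
    improved$average_rank[pick] <- improved$average_rank[pick] - 1
    improved$rounded_rank[pick] <- as.integer(ceiling(improved$average_rank[pick]))

    before <- summarize_entries(ranks)
    after <- summarize_entries(improved)
    # silver/bronze counts alone are not monotone (a silver can upgrade to
    # gold); the per-challenge medal level below is
    for (colname in c("top1", "top3", "top10", "formula1", "medal_score",
                      "gold")) {
      expect_gte(
        after[[colname]][after$entry == "A"],
        before[[colname]][before$entry == "A"]
      )
    }
    medal_level <- c(none = 0, bronze = 1, silver = 2, gold = 3)
    mb <- assign_medals(ranks)
    ma <- assign_medals(improved)
    ch <- ranks$challenge_id[pick]
    expect_gte(
      medal_level[ma$medal[ma$entry == "A" & ma$challenge_id == ch]],
      medal_level[mb$medal[mb$entry == "A" & mb$challenge_id == ch]]
    )
  }
})

test_that("scores are invariant to challenge order", {
  avg <- c(1, 3, 2, 11, 1.5)
  ranks <- rank_table(rank_row("e1", paste0("c", 1:5), avg))
  shuffled <- ranks[sample(nrow(ranks)), ]
  expect_equal(
    summarize_entries(ranks)$formula1,
    summarize_entries(shuffled)$formula1
  )
  expect_equal(
    summarize_entries(ranks)$medal_score,
    summarize_entries(shuffled)$medal_score
  )
})

test_that("leave-out filtering keeps only challenges unseen by every training set", {
  sol <- tibble::tibble(
    challenge_id = paste0("c", 1:4),
    solution_skeleton = fake_skeleton(1:4),
    ion_mode = c("positive", "positive", "negative", "negative")
  )
  expect_equal(nrow(suppressMessages(filter_leaveout(sol, list()))), 4L)
  kept <- suppressMessages(filter_leaveout(sol, list(
    teamA = fake_inchikey(c(1, 7)),
    teamB = fake_skeleton(3)
  )))
  expect_setequal(kept$challenge_id, c("c2", "c4"))
  # synthetic contest with planted overlaps: exact set-difference oracle
  set.seed(12)
  contest <- generate_contest(contest_config(
    n_challenges = 30, candidate_meanlog = log(5), candidate_sdlog = 0.2,
    seed = 5
  ))
  planted <- sample(contest$solutions$solution_skeleton, 11)
  kept2 <- suppressMessages(
    filter_leaveout(contest$solutions, list(planted))
  )
  expect_setequal(
    kept2$solution_skeleton,
    setdiff(contest$solutions$solution_skeleton, planted)
  )
})
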