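test_that("saturation grid enumerates all step-35 values inside the channel range", {
  g <- build_saturation_grid(46)
  expect_equal(g$values, c(11L, 46L, 81L, 116L, 151L, 186L, 221L))
  expect_true(46 %in% g$values)

  # target at the channel floor: 8 values (derived by direct enumeration)
  expect_equal(build_saturation_grid(0)$values, seq(0L, 245L, by = 35L))
  expect_length(build_saturation_grid(0)$values, 8)

  expect_error(build_saturation_grid(300), "outside")
  expect_error(build_saturation_grid(46, step = 0), "positive")
})

test_that("every 0-255 target yields a 7- or 8-value grid and 1-4 candidate windows", {
  for (s in 0:255) {
    g <- build_saturation_grid(s)
    expect_true(length(g$values) %in% c(7L, 8L))
    w <- enumerate_candidate_windows(g)
    expect_true(length(w) %in% 1:4)
    # every window has 5 consecutive grid values and contains the target
    for (win in w) {
      expect_length(win, 5)
      expect_equal(diff(win), rep(35L, 4))
      expect_true(s %in% win)
    }
    # windows in ascending start order
    starts <- vapply(w, `[`, integer(1), 1)
    expect_true(all(diff(starts) > 0))
  }
})

test_that("candidate windows match the worked example and brute force", {
  w <- enumerate_candidate_windows(build_saturation_grid(46))
  expect_equal(w, list(c(11L, 46L, 81L, 116L, 151L),
                       c(46L, 81L, 116L, 151L, 186L)))

  # 8-value grid with target at the first position: brute force over the 4
  # windows keeps only the one containing position 1
  g0 <- build_saturation_grid(0)
  expect_length(enumerate_candidate_windows(g0), 1)
  expect_equal(enumerate_candidate_windows(g0)[[1]], g0$values[1:5])

  short <- build_saturation_grid(46)
  short$values <- short$values[1:4]
  expect_error(enumerate_candidate_windows(short), "fewer than 5")
})

test_that("sample_candidate_set picks windows uniformly and preserves structure", {
  target <- hsl_color(120, 46, 150)
  set.seed(42)
  draws <- replicate(4000, sample_candidate_set(target)$saturations[1])
  # S = 46 has two admissible windows starting at 11 and 46
  expect_setequal(unique(draws), c(11L, 46L))
  expect_lt(abs(mean(draws == 11L) - 0.5), 0.03)

  cs <- sample_candidate_set(target)
  expect_length(unique(cs$saturations), 5)
  expect_equal(cs$saturations[cs$target_index], 46L)
  same_hl <- vapply(cs$colors, function(cc)
    cc[["hue"]] == 120L && cc[["lightness"]] == 150L, logical(1))
  expect_true(all(same_hl))

  expect_error(sample_candidate_set(hsl_color(120, 46, 90)), "lightness")
})

test_that("target positions follow the enumerated distribution over uniform targets", {
  # brute-force enumeration over all 256 saturations of the position
  # distribution (each admissible window of a target equally likely); the
  # distribution is symmetric about the middle position and every position
  # carries substantial mass, so no position betrays the target
  expected <- rep(0, 5)
  for (s in 0:255) {
    wins <- enumerate_candidate_windows(build_saturation_grid(s))
    for (w in wins)
      expected[match(s, w)] <- expected[match(s, w)] + 1 / length(wins)
  }
  expected <- expected / 256
  expect_equal(expected, rev(expected))            # symmetric
  expect_true(all(expected > 0.1))                 # no starved position
  # counting every (target, window) pair once instead recovers exact
  # uniformity: each grid contributes 5 * (G - 4) pairs, one per cell
  pair_counts <- rep(0, 5)
  for (s in 0:255) {
    wins <- enumerate_candidate_windows(build_saturation_grid(s))
    for (w in wins)
      pair_counts[match(s, w)] <- pair_counts[match(s, w)] + 1
  }
  expect_equal(pair_counts / sum(pair_counts), rep(0.2, 5), tolerance = 1e-12)

  set.seed(7)
  n <- 100000
  pos <- integer(n)
  ss <- sample(0:255, n, replace = TRUE)
  for (i in seq_len(n))
    pos[i] <- sample_candidate_set(hsl_color(0, ss[i], 150))$target_index
  gof <- suppressWarnings(chisq.test(tabulate(pos, 5), p = expected))
  expect_gt(gof$p.value, 0.001)
})

test_that("sample_target_colors stratifies hue and bounds lightness", {
  set.seed(1)
  cols <- sample_target_colors(10)
  L <- vapply(cols, `[[`, integer(1), "lightness")
  expect_true(all(L >= 100 & L <= 200))
  H <- vapply(cols, `[[`, integer(1), "hue")
  # exactly one hue per decile bin of [0, 255]
  bins <- findInterval(H, floor(seq(0, 256, length.out = 11)),
                       rightmost.closed = FALSE)
  expect_setequal(bins, 1:10)

  set.seed(99); a <- sample_target_colors(2)
  set.seed(99); b <- sample_target_colors(2)
  expect_identical(a, b)
  expect_error(sample_target_colors(0), "at least 1")
  expect_error(sample_target_colors(257), "exceed 256")
})

test_that("session plans have 4 block-permutations of 10 associations", {
  set.seed(3)
  plan <- build_session_plan(sample_target_colors(10), "EL")
  expect_equal(nrow(plan), 40)
  expect_equal(attr(plan, "condition"), "EL")
  for (b in 1:4)
    expect_setequal(plan$assoc_id[plan$block == b], 1:10)
  expect_true(all(plan$target_position %in% 1:5))
  # the target's saturation sits at the recorded display position, and the
  # five candidates are consecutive step-35 values
  for (r in seq_len(nrow(plan))) {
    p <- plan$target_position[r]
    sats <- unname(unlist(plan[r, sprintf("s%d", 1:5)]))
    expect_equal(unname(diff(sort(sats))), rep(35L, 4))
    expect_equal(plan[[sprintf("s%d", p)]][r], plan$target_saturation[r])
  }

  dup <- sample_target_colors(10)
  names(dup)[2] <- names(dup)[1]
  expect_error(build_session_plan(dup, "EL"), "unique")
  expect_error(build_session_plan(sample_target_colors(9), "EL"), "exactly 10")
})

test_that("target display positions are uniform across trials", {
  set.seed(11)
  pos <- unlist(lapply(1:100, function(i)
    build_session_plan(sample_target_colors(10), "TE")$target_position))
  freq <- tabulate(pos, 5) / length(pos)
  expect_true(all(abs(freq - 0.2) < 0.03))
})

test_that("test scoring is 10 points per correct response", {
  all_right <- data.frame(chosen = rep(1:5, 8), correct = rep(1:5, 8))
  expect_equal(score_test(all_right), 400L)
  none <- data.frame(chosen = rep(1, 40), correct = rep(2, 40))
  expect_equal(score_test(none), 0L)
  some <- data.frame(chosen = c(rep(1, 19), rep(2, 21)), correct = rep(1, 40))
  expect_equal(score_test(some), 190L)
  expect_error(score_test(all_right[1:39, ]), "40 trials")
})

test_that("session plans round-trip through TSV", {
  set.seed(5)
  plan <- build_session_plan(sample_target_colors(10), "TE")
  f <- tempfile(fileext = ".tsv")
  write_session_plan(plan, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# condition: TE", lines)))
  body <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  expect_equal(nrow(body), 40)
  expect_equal(body$target_position, plan$target_position)
})
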