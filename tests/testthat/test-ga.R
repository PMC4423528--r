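test_that("chromosomes validate and decode back to their sequences", {
  seqs <- list(c("2.7.1", "1.1.1"), c("5.3.1", "1.1.1", "4.1.2"))
  ch <- new_chromosome(list(c(1L, 0L, 1L), c(1L, 1L, 1L)), seqs)
  a <- decode_chromosome(ch)
  expect_equal(a$grid[1, ], c("2.7.1", NA, "1.1.1"))
  expect_equal(a$grid[2, ], c("5.3.1", "1.1.1", "4.1.2"))
  expect_error(new_chromosome(list(c(1L, 1L), c(1L, 1L)), seqs), "1-counts")
  expect_error(new_chromosome(list(c(1L, 1L, 0L)), seqs), NULL)
})

test_that("init_population is deterministic, sized, and decode-invariant", {
  seqs <- list(A = c("2.7.1", "1.1.1"), B = c("5.3.1", "1.1.1", "4.1.2"))
  p <- ga_params(population_size = 30L, seed = 9L)
  pop1 <- init_population(seqs, p)
  pop2 <- init_population(seqs, p)
  expect_length(pop1, 30L)
  expect_identical(pop1, pop2)
  for (ch in pop1) {
    a <- decode_chromosome(ch)
    expect_equal(a$grid[1, !is.na(a$grid[1, ])], seqs$A)
    expect_equal(a$grid[2, !is.na(a$grid[2, ])], seqs$B)
    # no all-gap columns
    expect_true(all(colSums(!is.na(a$grid)) > 0))
  }
})

test_that("crossover preserves content and is closed under self-crossover", {
  seqs <- list(c("2.7.1", "1.1.1", "3.2.1"), c("5.3.1", "1.1.1"))
  p1 <- new_chromosome(list(c(1L, 1L, 0L, 1L), c(0L, 1L, 1L, 0L)), seqs)
  p2 <- new_chromosome(list(c(1L, 1L, 1L, 0L), c(1L, 0L, 0L, 1L)), seqs)
  for (cut in 1:3) {
    off <- crossover(p1, p2, cut)
    for (o in off) {
      a <- decode_chromosome(o)
      expect_equal(a$grid[1, !is.na(a$grid[1, ])], seqs[[1]])
      expect_equal(a$grid[2, !is.na(a$grid[2, ])], seqs[[2]])
    }
  }
  # self-crossover of a normalized parent returns the parent exactly
  for (cut in 1:3) {
    off <- crossover(p1, p1, cut)
    expect_identical(off[[1]]$masks, p1$masks)
    expect_identical(off[[2]]$masks, p1$masks)
  }
  expect_error(crossover(p1, new_chromosome(list(c(1L, 1L), c(1L, 1L)),
                                            list(c("2.7.1", "1.1.1"),
                                                 c("5.3.1", "1.1.1"))),
                         1), "same sequences")
})

test_that("mutation preserves content under both policies", {
  seqs <- list(c("2.7.1", "1.1.1", "3.2.1"), c("5.3.1", "1.1.1"))
  ch <- new_chromosome(list(c(1L, 1L, 1L, 0L), c(1L, 1L, 0L, 0L)), seqs)
  set.seed(3)
  for (policy in c("per_individual", "per_position")) {
    p <- ga_params(mutation_policy = policy, mutation_rate = 0.2)
    for (i in 1:200) {
      m <- mutate_chromosome(ch, p)
      a <- decode_chromosome(m)
      expect_equal(a$grid[1, !is.na(a$grid[1, ])], seqs[[1]])
      expect_equal(a$grid[2, !is.na(a$grid[2, ])], seqs[[2]])
      expect_true(all(colSums(!is.na(a$grid)) > 0))
    }
  }
})

test_that("tournament selection returns a minimum of its sample", {
  seqs <- list(c("2.7.1"), c("1.1.1"))
  pop <- init_population(seqs, ga_params(population_size = 10L, seed = 2L))
  pop <- evaluate_population(pop)
  fits <- vapply(pop, function(ch) ch$score$objective, numeric(1))
  set.seed(4)
  for (i in 1:50) {
    sel <- tournament_select(pop, ga_params(tournament_size = 10L))
    # with the tournament as large as the population the best must win
    expect_equal(sel$score$objective, min(fits))
  }
})

test_that("ga_align is deterministic and symmetric in its arguments", {
  sa <- c("2.7.1", "1.1.1", "3.2.1", "5.3.1")
  sb <- c("2.7.1", "1.1.1", "5.3.1")
  p <- ga_params(seed = 7L)
  r1 <- ga_align(list(A = sa, B = sb), p)
  r2 <- ga_align(list(A = sa, B = sb), p)
  expect_identical(r1$grid, r2$grid)
  r3 <- ga_align(list(B = sb, A = sa), p)
  expect_equal(r3$score$objective, r1$score$objective)
  # rows follow the input order
  expect_equal(r1$ids, c("A", "B"))
  expect_equal(r3$ids, c("B", "A"))
  expect_equal(r3$grid[1, ], r1$grid[2, ])
})

test_that("ga result is never worse than the trivially padded stack", {
  set.seed(21)
  alphabet <- default_ec_alphabet()
  for (i in 1:20) {
    lens <- sample(2:6, 2, replace = TRUE)
    seqs <- lapply(lens, rand_seq, alphabet = alphabet)
    W <- max(lens)
    trivial <- decode_chromosome(new_chromosome(
      lapply(seqs, function(s) c(rep(1L, length(s)), rep(0L, W - length(s)))),
      seqs))
    g <- ga_align(seqs, fast_params(seed = i))
    expect_lte(g$score$objective, objective(trivial)$objective + 1e-12)
  }
})

test_that("brute force oracle: hand cases and input validation", {
  # identical pair: optimum is the gapless stack at 0.05
  b <- brute_force_align(c("2.7.1", "1.1.1"), c("2.7.1", "1.1.1"))
  expect_equal(b$score$objective, 0.05)
  expect_equal(ncol(b$grid), 2L)
  # single symbols, fully distinct: single column at 0.59 beats any gap layout
  b <- brute_force_align("2.7.2", "1.1.1")
  expect_equal(b$score$objective, 0.59)
  expect_equal(ncol(b$grid), 1L)
  expect_error(brute_force_align(rep("1.1.1", 7), "2.7.1"), "length")
  expect_error(brute_force_align("1.1.1", "2.7.1", max_width = 5), "max_width")
})

test_that("ga matches the brute-force optimum on seeded short pairs", {
  set.seed(31)
  alphabet <- small_alphabet()
  hits <- 0L
  n <- 25L
  for (i in seq_len(n)) {
    sa <- rand_seq(sample(2:4, 1), alphabet)
    sb <- rand_seq(sample(2:4, 1), alphabet)
    g <- ga_align(list(A = sa, B = sb), ga_params(seed = i))$score$objective
    b <- brute_force_align(sa, sb)$score$objective
    expect_gte(g, b - 1e-9)
    if (abs(g - b) < 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n))
})

test_that("dp_align minimizes its additive cost and re-scores correctly", {
  # identical sequences: diagonal path, gapless, 0.05
  d <- dp_align(c("2.7.1", "1.1.1", "5.3.1"), c("2.7.1", "1.1.1", "5.3.1"))
  expect_equal(d$score$objective, 0.05)
  expect_equal(ncol(d$grid), 3L)
  # substitution cheaper than two gaps: 0.6 * entropy < 2.0 always
  d <- dp_align("2.7.1", "2.7.2")
  expect_equal(ncol(d$grid), 1L)
  # length difference forces exactly |la - lb| gaps
  d <- dp_align(c("2.7.1", "1.1.1", "5.3.1"), c("2.7.1", "5.3.1"))
  expect_equal(ncol(d$grid), 3L)
  expect_equal(sum(is.na(d$grid)), 1L)
  expect_error(dp_align(character(0), "1.1.1"), "empty")
})

test_that("ga engine honors generation cap and improves over generations", {
  sa <- c("2.7.1", "1.1.1", "3.2.1")
  sb <- c("3.2.1", "2.7.1", "1.1.1")
  capped <- ga_params(seed = 1L, max_generations = 1L, replicates = 1L)
  full <- ga_params(seed = 1L, replicates = 1L)
  expect_gte(ga_align(list(sa, sb), capped)$score$objective,
             ga_align(list(sa, sb), full)$score$objective - 1e-12)
})
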