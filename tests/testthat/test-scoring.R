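test_that("column entropies match hand arithmetic", {
  # [2.7.1, 2.7.2]: levels 1 and 2 agree, level 3 splits -> (5 * 1) / 30
  expect_equal(column_ec_entropy(c("2.7.1", "2.7.2")), 1 / 6)
  # identical symbols: zero at every level
  expect_equal(column_ec_entropy(c("2.7.1", "2.7.1")), 0)
  # fully distinct level-1 classes: maximal entropy at every level
  expect_equal(column_ec_entropy(c("1.1.1", "2.2.2")), 1)
  # a gap counts as one more symbol
  expect_equal(column_level_entropy(c("2", NA)), 1)
  expect_error(column_level_entropy("2"), "at least 2")
})

test_that("column homogeneity and gap fraction match hand values", {
  expect_equal(column_gap_fraction(c("2.7.1", NA)), 1)
  expect_equal(column_gap_fraction(c("2.7.1", "1.1.1", NA)), 0.5)
  expect_error(column_gap_fraction(c(NA_character_, NA)), "all-gap")
  # [EC, GAP] column: 0.6 * 1 + 0.4 * 1 = 1.0
  expect_equal(column_homogeneity(c("2.7.1", NA)), 1.0)
  expect_equal(column_homogeneity(c("2.7.1", "2.7.1")), 0)
})

test_that("objective equals its hand values on reference alignments", {
  # identical gapless pair: 0.9*0 + 0.05*0 + 0.05*1 = 0.05
  a <- aln(c("2.7.1", "1.1.1"), c("2.7.1", "1.1.1"))
  expect_equal(objective(a)$objective, 0.05)
  # fully distinct ungapped equal-length pair: 0.9*0.6 + 0 + 0.05 = 0.59
  b <- aln(c("1.1.1", "3.2.1"), c("2.7.2", "4.1.3"))
  expect_equal(objective(b)$objective, 0.59)
})

test_that("gap concentration distinguishes block shapes, ignores terminal gaps", {
  # one internal block of 2 gaps: (2/1) / 2 = 1
  g1 <- aln(c("1.1.1", NA, NA, "2.2.2"),
            c("1.1.1", "3.3.3", "4.4.4", "2.2.2"))
  expect_equal(gap_concentration(g1), 1.0)
  # two internal single gaps: (1/1) / 2 = 0.5
  g2 <- aln(c("1.1.1", NA, "2.2.2", NA, "5.5.5"),
            c("1.1.1", "3.3.3", "2.2.2", "4.4.4", "5.5.5"))
  expect_equal(gap_concentration(g2), 0.5)
  # leading/trailing gaps are not internal
  g3 <- aln(c(NA, "1.1.1", "2.2.2"), c("3.3.3", "1.1.1", NA))
  expect_equal(gap_concentration(g3), 0)
  # inverted mode: GP / (mean_block * C1)
  ctrl <- scoring_control(gap_concentration_mode = "inverted")
  expect_equal(gap_concentration(g1, ctrl), 2 / (2 * 4))
})

test_that("column increment is longest sequence over width", {
  g <- new_alignment(rbind(c(rep("1.1.1", 5), rep(NA, 5)),
                           c(rep(NA, 5), rep("2.2.2", 5))))
  expect_equal(ncol(g$grid), 10L)
  expect_equal(column_increment(g), 0.5)
  ctrl <- scoring_control(column_increment_mode = "inverted")
  expect_equal(column_increment(g, ctrl), 0.5)
  g2 <- aln(c("1.1.1", "2.2.2"), c("1.1.1", "2.2.2"))
  expect_equal(column_increment(g2), 1)
})

test_that("all-gap columns are removed on construction", {
  grid <- rbind(c("1.1.1", NA, "2.2.2"), c("1.1.1", NA, "2.2.2"))
  a <- new_alignment(grid)
  expect_equal(ncol(a$grid), 2L)
  expect_error(new_alignment(rbind(NA_character_, NA_character_)),
               "no non-gap")
})

test_that("entropy normalization by symbol count is available", {
  # 3 rows, 2 distinct symbols: rows-normalization divides by log2(3),
  # symbols-normalization by log2(2)
  col <- c("1.1.1", "1.1.1", "2.2.2")
  h_rows <- column_level_entropy(ec_levels(col)[, 1])
  ctrl <- scoring_control(entropy_norm = "symbols")
  h_sym <- column_level_entropy(ec_levels(col)[, 1], ctrl)
  p <- c(2, 1) / 3
  H <- -sum(p * log2(p))
  expect_equal(h_rows, H / log2(3))
  expect_equal(h_sym, H / log2(2))
})

test_that("R and C++ scorers agree on random alignments", {
  set.seed(11)
  alphabet <- default_ec_alphabet()
  for (case in 1:100) {
    n <- sample(2:4, 1)
    lens <- sample(2:6, n, replace = TRUE)
    seqs <- lapply(lens, rand_seq, alphabet = alphabet)
    W <- max(lens) + sample(0:3, 1)
    masks <- lapply(seqs, function(s) {
      m <- integer(W); m[sample.int(W, length(s))] <- 1L; m
    })
    keep <- Reduce(`+`, masks) > 0
    masks <- lapply(masks, function(m) m[keep])
    a <- decode_chromosome(new_chromosome(masks, seqs))
    for (ctrl in list(scoring_control(),
                      scoring_control(gap_concentration_mode = "inverted",
                                      column_increment_mode = "inverted"),
                      scoring_control(entropy_norm = "symbols"))) {
      r <- objective(a, ctrl)
      cpp <- essalign:::score_alignment_cpp(a, ctrl)
      expect_equal(cpp$objective, r$objective, tolerance = 1e-12)
      expect_equal(cpp$homogeneity, r$homogeneity, tolerance = 1e-12)
      expect_equal(cpp$gap_penalty, r$gap_penalty, tolerance = 1e-12)
      expect_equal(cpp$column_increment, r$column_increment, tolerance = 1e-12)
    }
  }
})

test_that("objective components stay in their theoretical ranges", {
  set.seed(12)
  alphabet <- default_ec_alphabet()
  for (case in 1:50) {
    lens <- sample(2:6, 2, replace = TRUE)
    seqs <- lapply(lens, rand_seq, alphabet = alphabet)
    a <- ga_align(seqs, fast_params(seed = case))
    s <- a$score
    expect_gte(s$homogeneity, 0); expect_lte(s$homogeneity, 1)
    expect_gte(s$gap_penalty, 0); expect_lte(s$gap_penalty, 1)
    expect_gt(s$column_increment, 0); expect_lte(s$column_increment, 1)
    expect_equal(s$objective,
                 0.9 * s$homogeneity + 0.05 * s$gap_penalty +
                   0.05 * s$column_increment)
  }
})

test_that("alignment io round-trips and tidiers are well-formed", {
  a <- aln(c("2.7.1", NA, "1.1.1"), c("2.7.1", "5.3.1", "1.1.1"),
           ids = c("x", "y"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_alignment(a, path)
  back <- read_alignment(path)
  expect_equal(back$grid, a$grid)
  expect_equal(back$ids, a$ids)

  td <- tidy(a)
  expect_equal(nrow(td), 6L)
  expect_true(all(c("ess_id", "row", "column", "ec") %in% names(td)))
  gl <- glance(a)
  expect_equal(gl$objective, objective(a)$objective)
  expect_s3_class(autoplot(a), "ggplot")
})
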