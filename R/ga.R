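#' Genetic-algorithm parameters
#'
#' Defaults follow the published protocol: a population of 100 chromosomes, a
#' 90% crossover rate, mutation applied per individual each generation,
#' termination after 20 generations without improvement of the objective, and
#' 10 independent replicates of which the best result is kept.
#'
#' The mutation protocol is stated two ways in the source method ("a 1%
#' mutation rate" vs. "an individual will be mutated each generation"); both
#' readings are available. Under `mutation_policy = "per_individual"`
#' (default) every non-elite individual receives one mutation event per
#' generation with probability `per_individual_rate` (default 1). Under
#' `"per_position"` the number of events per individual is
#' Binomial(rows x columns, `mutation_rate`).
#'
#' @param population_size chromosomes per generation.
#' @param mutation_rate per-position mutation probability (used by the
#'   `"per_position"` policy).
#' @param crossover_rate probability that a selected pair is recombined.
#' @param stagnation_generations stop after this many generations without
#'   improvement of the best objective.
#' @param replicates independent GA runs; the best result is returned.
#' @param tournament_size individuals sampled (with replacement) per
#'   tournament.
#' @param max_extra_columns gap budget of the initial population: initial
#'   widths are uniform on `[Lmax, Lmax + max_extra_columns]`. `NULL` means
#'   `max(2, ceiling(Lmax / 2))`, chosen at run time.
#' @param seed root seed; replicate `r` uses sub-seed `seed + r`.
#' @param mutation_policy `"per_individual"` or `"per_position"`.
#' @param per_individual_rate probability that an individual is mutated in a
#'   generation under the per-individual policy.
#' @param max_generations hard cap on generations per replicate (safety
#'   valve; stagnation normally triggers first).
#' @return an object of class `ga_params`.
#' @export
ga_params <- function(population_size = 100L,
                      mutation_rate = 0.01,
                      crossover_rate = 0.90,
                      stagnation_generations = 20L,
                      replicates = 10L,
                      tournament_size = 2L,
                      max_extra_columns = NULL,
                      seed = 1L,
                      mutation_policy = c("per_individual", "per_position"),
                      per_individual_rate = 1.0,
                      max_generations = 100000L) {
  stopifnot(population_size >= 2, replicates >= 1, tournament_size >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            stagnation_generations >= 1)
  structure(
    list(population_size = as.integer(population_size),
         mutation_rate = mutation_rate,
         crossover_rate = crossover_rate,
         stagnation_generations = as.integer(stagnation_generations),
         replicates = as.integer(replicates),
         tournament_size = as.integer(tournament_size),
         max_extra_columns = if (is.null(max_extra_columns)) NULL
                             else as.integer(max_extra_columns),
         seed = as.integer(seed),
         mutation_policy = match.arg(mutation_policy),
         per_individual_rate = per_individual_rate,
         max_generations = as.integer(max_generations)),
    class = "ga_params")
}

default_extra_columns <- function(params, lmax) {
  if (!is.null(params$max_extra_columns)) params$max_extra_columns
  else max(2L, as.integer(ceiling(lmax / 2)))
}

policy_code <- function(params) {
  switch(params$mutation_policy, per_individual = 0L, per_position = 1L)
}

policy_rate <- function(params) {
  switch(params$mutation_policy,
         per_individual = params$per_individual_rate,
         per_position = params$mutation_rate)
}

# ---- chromosomes ----------------------------------------------------------

#' Chromosomes: binary gap codification of an alignment
#'
#' A chromosome stores, for each sequence (row), a binary mask over the
#' alignment columns where 1 marks an enzyme and 0 a gap. Masks all have the
#' same length and no column is 0 in every row; decoding a mask against its
#' sequence reproduces the alignment row, so EC content is invariant under
#' every operator.
#'
#' @param masks list of integer 0/1 vectors, one per sequence, equal lengths.
#' @param seqs list of character EC step vectors (the unaligned sequences).
#' @param ids sequence ids.
#' @return `new_chromosome()`: an `ess_chromosome`. `decode_chromosome()`:
#'   the corresponding [new_alignment()].
#' @export
new_chromosome <- function(masks, seqs, ids = NULL) {
  stopifnot(length(masks) == length(seqs),
            length(unique(lengths(masks))) == 1)
  ones <- vapply(masks, function(m) sum(m == 1L), integer(1))
  if (!all(ones == lengths(seqs))) {
    stop("mask 1-counts must equal sequence lengths", call. = FALSE)
  }
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  structure(list(masks = lapply(masks, as.integer), seqs = seqs, ids = ids),
            class = "ess_chromosome")
}

#' @rdname new_chromosome
#' @param ch an `ess_chromosome`.
#' @export
decode_chromosome <- function(ch) {
  W <- length(ch$masks[[1]])
  grid <- matrix(NA_character_, nrow = length(ch$seqs), ncol = W)
  for (i in seq_along(ch$seqs)) {
    grid[i, ch$masks[[i]] == 1L] <- ch$seqs[[i]]
  }
  new_alignment(grid, ids = ch$ids, seq_lengths = lengths(ch$seqs))
}

#' Random initial population of variable-width chromosomes
#'
#' Each chromosome picks an alignment width uniformly on
#' `[Lmax, Lmax + max_extra_columns]` and places each row's gaps at uniformly
#' random positions; all-gap columns are removed. Every chromosome decodes to
#' the original sequences.
#'
#' @param seqs list of >= 2 character EC step vectors.
#' @param params a [ga_params()] object (uses `population_size`,
#'   `max_extra_columns`, `seed`).
#' @param ids optional sequence ids.
#' @return list of `ess_chromosome` objects.
#' @export
init_population <- function(seqs, params = ga_params(), ids = NULL) {
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  lmax <- max(lengths(seqs))
  extra <- default_extra_columns(params, lmax)
  withr::with_seed(params$seed, {
    lapply(seq_len(params$population_size), function(i) {
      W <- lmax + sample.int(extra + 1L, 1L) - 1L
      masks <- lapply(seqs, function(s) {
        m <- integer(W)
        m[sample.int(W, length(s))] <- 1L
        m
      })
      new_chromosome(normalize_masks_r(masks), seqs, ids)
    })
  })
}

normalize_masks_r <- function(masks) {
  keep <- Reduce(`+`, masks) > 0L
  lapply(masks, function(m) m[keep])
}

#' Tournament selection
#'
#' Samples `tournament_size` individuals uniformly with replacement and
#' returns the one with the smallest objective; ties go to the first sampled.
#'
#' @param population list of `ess_chromosome` objects carrying a `score`
#'   field (see [evaluate_population()]).
#' @param params a [ga_params()].
#' @return the selected `ess_chromosome`.
#' @export
tournament_select <- function(population, params = ga_params()) {
  if (length(population) == 0) stop("empty population", call. = FALSE)
  idx <- sample.int(length(population), params$tournament_size, replace = TRUE)
  fits <- vapply(population[idx], function(ch) ch$score$objective, numeric(1))
  population[[idx[which.min(fits)]]]
}

#' @rdname tournament_select
#' @param control a [scoring_control()].
#' @export
evaluate_population <- function(population, control = scoring_control()) {
  lapply(population, function(ch) {
    if (is.null(ch$score)) ch$score <- objective(decode_chromosome(ch), control)
    ch
  })
}

#' One-point crossover of two chromosomes
#'
#' A cut column is chosen on the first parent; the second parent is cut,
#' row by row, just after it has consumed the same number of enzymes as the
#' first parent holds left of the cut. Offspring combine left and right
#' sides, padding the shorter sides with gaps so each offspring stays
#' rectangular; EC content per row is unchanged and all-gap columns are
#' removed.
#'
#' @param parent1,parent2 `ess_chromosome` objects over the same sequences.
#' @param cut_column integer, `1 <= cut_column < width(parent1)`.
#' @return list of two `ess_chromosome` offspring.
#' @export
crossover <- function(parent1, parent2, cut_column) {
  if (!identical(parent1$seqs, parent2$seqs)) {
    stop("parents must encode the same sequences", call. = FALSE)
  }
  W1 <- length(parent1$masks[[1]])
  stopifnot(cut_column >= 1, cut_column < W1)
  off <- cpp_crossover(parent1$masks, parent2$masks, as.integer(cut_column))
  list(new_chromosome(off$offspring1, parent1$seqs, parent1$ids),
       new_chromosome(off$offspring2, parent1$seqs, parent1$ids))
}

#' Gap mutation of a chromosome
#'
#' One uniformly chosen (row, position): a gap is extended or removed by one
#' unit with equal probability; an enzyme position gets a gap inserted before
#' it. The chromosome is re-rectangularized and all-gap columns removed; EC
#' content is never touched.
#'
#' @param ch an `ess_chromosome`.
#' @param params a [ga_params()] (mutation policy and rates).
#' @return the mutated `ess_chromosome`.
#' @export
mutate_chromosome <- function(ch, params = ga_params()) {
  masks <- cpp_mutate(ch$masks, policy_code(params), policy_rate(params))
  new_chromosome(masks, ch$seqs, ch$ids)
}

# ---- the aligners ---------------------------------------------------------

# Run the C++ GA over a list of blocks (character matrices, NA = gap).
# Returns masks, score and generations of the best replicate.
run_engine <- function(blocks, params, control, seed_trivial = TRUE) {
  enc <- encode_seqs(list(stats::na.omit(unlist(lapply(blocks, as.vector)))))
  iblocks <- lapply(blocks, function(b) {
    m <- matrix(match(b, enc$tokens), nrow = nrow(b))
    m[is.na(m)] <- 0L
    m
  })
  lmax <- max(vapply(iblocks, ncol, integer(1)))
  extra <- default_extra_columns(params, lmax)
  cc <- control_codes(control)
  best <- NULL
  for (r in seq_len(params$replicates)) {
    sub_seed <- (params$seed + r) %% .Machine$integer.max
    res <- withr::with_seed(sub_seed, cpp_ga_run(
      iblocks, enc$levels,
      params$population_size, params$crossover_rate, policy_code(params),
      policy_rate(params), params$tournament_size,
      params$stagnation_generations, extra, seed_trivial,
      control$level_weights[1], control$level_weights[2],
      control$level_weights[3], cc$gc, cc$ci, cc$norm,
      params$max_generations))
    if (is.null(best) || res$objective < best$objective - 1e-12) best <- res
  }
  best$tokens <- enc$tokens
  best
}

# Expand engine masks + character blocks into an alignment grid.
decode_blocks <- function(blocks, masks) {
  W <- length(masks[[1]])
  rows <- list()
  for (g in seq_along(blocks)) {
    b <- blocks[[g]]
    expand <- matrix(NA_character_, nrow = nrow(b), ncol = W)
    expand[, masks[[g]] == 1L] <- b
    rows[[g]] <- expand
  }
  do.call(rbind, rows)
}

#' Align sequences with the genetic algorithm
#'
#' Runs `replicates` independent GA searches (tournament selection, one-point
#' crossover with probability `crossover_rate`, gap mutation, elitism of the
#' best individual, stop after `stagnation_generations` without improvement)
#' and returns the best alignment found, scored with the full objective. The
#' trivially padded stack of the sequences is seeded into each initial
#' population, so the result is never worse than that feasible solution.
#'
#' For reproducibility and symmetry, sequences are canonically ordered (by id,
#' falling back to their step strings) before the search, so
#' `ga_align(A, B)` and `ga_align(B, A)` attain the same objective under the
#' same seed; rows of the returned alignment follow the input order.
#'
#' @param seqs list of >= 2 character EC step vectors.
#' @param params a [ga_params()].
#' @param control a [scoring_control()].
#' @param ids optional sequence ids.
#' @return an [new_alignment()] whose `score` field holds the `ess_score`.
#' @export
ga_align <- function(seqs, params = ga_params(), control = scoring_control(),
                     ids = NULL) {
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(ids)) ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  key <- vapply(seqs, paste, character(1), collapse = ",")
  ord <- order(ids, key, method = "radix")
  blocks <- lapply(seqs[ord], function(s) matrix(s, nrow = 1))
  res <- run_engine(blocks, params, control, seed_trivial = TRUE)
  grid <- decode_blocks(blocks, res$masks)
  grid <- grid[order(ord), , drop = FALSE]
  new_alignment(grid, ids = ids, seq_lengths = lengths(seqs),
                score = new_score(res$homogeneity, res$gap_penalty,
                                  res$column_increment))
}

#' Exact brute-force pairwise alignment (oracle)
#'
#' Enumerates every gap placement of two short sequences up to `max_width`
#' columns, scores each alignment with the full objective and returns the
#' global minimum. Because every pairwise alignment without all-gap columns
#' has at most `length(A) + length(B)` columns, the default `max_width` makes
#' this the exact global optimum. Ties resolve to fewest columns, then the
#' first alignment in enumeration order of the gap patterns.
#'
#' @param seq_a,seq_b character EC step vectors, each of length <= 6.
#' @param max_width maximal number of columns to enumerate.
#' @param control a [scoring_control()].
#' @return an [new_alignment()] with the optimal `score`.
#' @export
brute_force_align <- function(seq_a, seq_b,
                              max_width = length(seq_a) + length(seq_b),
                              control = scoring_control()) {
  if (length(seq_a) > 6 || length(seq_b) > 6) {
    stop("brute force restricted to sequences of length <= 6", call. = FALSE)
  }
  if (max_width > length(seq_a) + length(seq_b)) {
    stop("max_width may not exceed length(seq_a) + length(seq_b)",
         call. = FALSE)
  }
  if (max_width < max(length(seq_a), length(seq_b))) {
    stop("max_width smaller than the longest sequence", call. = FALSE)
  }
  enc <- encode_seqs(list(seq_a, seq_b))
  cc <- control_codes(control)
  res <- cpp_brute_force(enc$seqs[[1]], enc$seqs[[2]], enc$levels,
                         as.integer(max_width),
                         control$level_weights[1], control$level_weights[2],
                         control$level_weights[3], cc$gc, cc$ci, cc$norm)
  blocks <- list(matrix(seq_a, nrow = 1), matrix(seq_b, nrow = 1))
  grid <- decode_blocks(blocks, res$masks)
  new_alignment(grid, ids = c("A", "B"),
                seq_lengths = c(length(seq_a), length(seq_b)),
                score = new_score(res$homogeneity, res$gap_penalty,
                                  res$column_increment))
}

#' Needleman-Wunsch baseline alignment
#'
#' Global dynamic-programming alignment minimizing the column-decomposable
#' part of the objective: pairing two EC codes costs `0.6 *` their two-cell
#' column entropy and a gap column costs 1 (the homogeneity of an EC-vs-gap
#' column). The gap-concentration and column-increment terms are global and
#' cannot enter the recursion, so the returned alignment is re-scored with
#' the full objective to be comparable with [ga_align()]. Ties in the
#' traceback prefer diagonal, then a gap in the second sequence.
#'
#' @inheritParams brute_force_align
#' @return an [new_alignment()] with the re-scored `score`.
#' @export
dp_align <- function(seq_a, seq_b, control = scoring_control()) {
  if (length(seq_a) == 0 || length(seq_b) == 0) {
    stop("cannot align an empty sequence", call. = FALSE)
  }
  la <- length(seq_a); lb <- length(seq_b)
  toks <- unique(c(seq_a, seq_b))
  sub <- matrix(0, length(toks), length(toks),
                dimnames = list(toks, toks))
  for (i in seq_along(toks)) {
    for (j in seq_along(toks)) {
      if (i < j) {
        sub[i, j] <- sub[j, i] <-
          0.6 * column_ec_entropy(c(toks[i], toks[j]), control)
      }
    }
  }
  gapcost <- 1.0
  D <- matrix(0, la + 1, lb + 1)
  D[, 1] <- (0:la) * gapcost
  D[1, ] <- (0:lb) * gapcost
  for (i in 1:la) {
    for (j in 1:lb) {
      D[i + 1, j + 1] <- min(
        D[i, j] + sub[seq_a[i], seq_b[j]],
        D[i, j + 1] + gapcost,
        D[i + 1, j] + gapcost)
    }
  }
  # traceback, diagonal preferred, then up (gap in B), then left
  i <- la; j <- lb
  ra <- character(0); rb <- character(0)
  eps <- 1e-12
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        abs(D[i + 1, j + 1] - (D[i, j] + sub[seq_a[i], seq_b[j]])) < eps) {
      ra <- c(seq_a[i], ra); rb <- c(seq_b[j], rb); i <- i - 1; j <- j - 1
    } else if (i > 0 &&
               abs(D[i + 1, j + 1] - (D[i, j + 1] + gapcost)) < eps) {
      ra <- c(seq_a[i], ra); rb <- c(NA_character_, rb); i <- i - 1
    } else {
      ra <- c(NA_character_, ra); rb <- c(seq_b[j], rb); j <- j - 1
    }
  }
  aln <- new_alignment(rbind(ra, rb), ids = c("A", "B"),
                       seq_lengths = c(la, lb))
  aln$score <- objective(aln, control)
  aln
}
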