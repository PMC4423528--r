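# Hand-built maps and collections shared across test files.

# A linear chain E1(1.1.1) -> E2(2.7.1) -> E3(5.3.1), no external links.
toy_chain_map <- function() {
  metabolic_map(
    map_id = "chain", name = "toy chain",
    nodes = tibble::tibble(
      node_id = c("E1", "E2", "E3"),
      ec = c("1.1.1", "2.7.1", "5.3.1"),
      reversible = FALSE,
      substrates = list("g", "a", "b"),
      products = list("a", "b", "c"),
      external_substrates = list(character(0), character(0), character(0))))
}

# An 8-node map with a branch point at n2 (its product feeds n3 and n4) and
# a second branch point at n4; two initialization nodes (n1 by the
# unproduced-substrate criterion, n8 by the external-substrate criterion).
#
#   n1(2.7.1) -\
#               n2(5.3.1) -> n3(2.2.1) -> n5(1.1.1)
#   n8(6.3.2) -/         \-> n4(4.1.2) -> n6(3.1.3)
#                                     \-> n7(2.7.7)
toy_branched_map <- function() {
  metabolic_map(
    map_id = "toy8", name = "toy branched",
    nodes = tibble::tibble(
      node_id = paste0("n", 1:8),
      ec = c("2.7.1", "5.3.1", "2.2.1", "4.1.2", "1.1.1", "3.1.3",
             "2.7.7", "6.3.2"),
      reversible = FALSE,
      substrates = list("G", "A", "B", "B", "C", "D", "D", "X"),
      products = list("A", "B", "C", "D", "E", "F", "H", "A"),
      external_substrates = list(
        character(0), character(0), character(0), character(0),
        character(0), character(0), character(0), "X")))
}

# Hand enumeration of the branched map's ESS (root-to-leaf EC paths).
toy_branched_hand_ess <- function() {
  list(
    n1 = list(c("2.7.1", "5.3.1", "2.2.1", "1.1.1"),
              c("2.7.1", "5.3.1", "4.1.2", "3.1.3"),
              c("2.7.1", "5.3.1", "4.1.2", "2.7.7")),
    n8 = list(c("6.3.2", "5.3.1", "2.2.1", "1.1.1"),
              c("6.3.2", "5.3.1", "4.1.2", "3.1.3"),
              c("6.3.2", "5.3.1", "4.1.2", "2.7.7")))
}

# Minimal ESS tibble from a named list of step vectors.
toy_collection <- function(seqs) {
  tibble::tibble(ess_id = names(seqs), map_id = "toy", root_id = "r",
                 steps = unname(seqs))
}

# Alignment matrix helper: character vector rows, NA = gap.
aln <- function(..., ids = NULL) {
  rows <- list(...)
  new_alignment(do.call(rbind, rows), ids = ids)
}

# Random EC sequence from an alphabet.
rand_seq <- function(len, alphabet) sample(alphabet, len, replace = TRUE)

small_alphabet <- function() c("2.7.1", "2.7.2", "1.1.1")

# Fast GA settings for tests that only need a feasible (not optimal) result.
fast_params <- function(seed = 1L) {
  ga_params(population_size = 20L, replicates = 2L,
            stagnation_generations = 5L, seed = seed)
}
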