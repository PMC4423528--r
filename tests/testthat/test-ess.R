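test_that("initialization criteria: chain, isolated node, external+neighbors", {
  # chain E1 -> E2 -> E3, no external links: only E1 qualifies
  expect_equal(find_initialization_nodes(toy_chain_map()), "E1")

  # a single isolated node qualifies vacuously
  lone <- metabolic_map("m", "", tibble::tibble(
    node_id = "E1", ec = "1.1.1", reversible = FALSE,
    substrates = list("s"), products = list("p"),
    external_substrates = list(character(0))))
  expect_equal(find_initialization_nodes(lone), "E1")

  # external substrate but 3 neighbors, all substrates produced in-map:
  # fails both criteria
  hub <- metabolic_map("m", "", tibble::tibble(
    node_id = c("H", "A", "B", "C"),
    ec = c("1.1.1", "2.2.2", "3.3.3", "4.4.4"),
    reversible = FALSE,
    substrates = list(c("a", "ext"), "s1", "s2", "h"),
    products = list("h", "a", "a", "z"),
    external_substrates = list("ext", character(0), character(0),
                               character(0))))
  expect_equal(graph_neighbors(hub, "H"), c("A", "B", "C"))
  expect_false("H" %in% find_initialization_nodes(hub))
})

test_that("an in-edge not supplying a substrate does not disqualify a root", {
  # m1 -> m2 exists via compound p only because m2 is reversible, but p is
  # not one of m2's substrates, so m2 still satisfies criterion (i)
  map <- metabolic_map("m", "", tibble::tibble(
    node_id = c("m1", "m2"),
    ec = c("1.1.1", "2.2.2"),
    reversible = c(FALSE, TRUE),
    substrates = list("s1", "q"),
    products = list("p", "p"),
    external_substrates = list(character(0), character(0))))
  expect_true(any(map$edges$from == "m1" & map$edges$to == "m2"))
  expect_equal(find_initialization_nodes(map), c("m1", "m2"))
})

test_that("build_bfs_tree gives deterministic parents and single discovery", {
  map <- toy_chain_map()
  tr <- build_bfs_tree(map, "E1")
  expect_equal(tr[["E2"]], "E1")
  expect_equal(tr[["E3"]], "E2")
  expect_true(is.na(tr[["E1"]]))

  # diamond: E4 discovered once, parent is the first-visited child (ascending
  # id order => E2)
  diamond <- metabolic_map("d", "", tibble::tibble(
    node_id = c("E1", "E2", "E3", "E4"),
    ec = c("1.1.1", "2.2.2", "3.3.3", "4.4.4"),
    reversible = FALSE,
    substrates = list("s", "a", "a", "b"),
    products = list("a", "b", "b", "c"),
    external_substrates = list(character(0), character(0), character(0),
                               character(0))))
  tr <- build_bfs_tree(diamond, "E1")
  expect_equal(sum(names(tr) == "E4"), 1L)
  expect_equal(tr[["E4"]], "E2")
  expect_error(build_bfs_tree(diamond, "nope"), "unknown root")

  # root with no out-edges
  tr <- build_bfs_tree(diamond, "E4")
  expect_equal(names(tr), "E4")
})

test_that("extract_ess on the branched toy map matches the hand enumeration", {
  coll <- extract_ess(toy_branched_map())
  hand <- toy_branched_hand_ess()
  expect_equal(nrow(coll), 6L)
  for (root in c("n1", "n8")) {
    got <- coll$steps[coll$root_id == root]
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(hand[[root]], paste, character(1), collapse = ","))
  }
  expect_false(anyDuplicated(coll$ess_id) > 0)
})

test_that("every ESS walks edges of the source graph; leaves = branches", {
  map <- toy_branched_map()
  coll <- extract_ess(map)
  ec_of <- stats::setNames(map$nodes$ec, map$nodes$node_id)
  edge_ecs <- paste(ec_of[map$edges$from], ec_of[map$edges$to])
  for (steps in coll$steps) {
    if (length(steps) < 2) next
    pairs <- paste(steps[-length(steps)], steps[-1])
    expect_true(all(pairs %in% edge_ecs))
  }
  # one ESS per leaf of each BFS tree
  for (root in c("n1", "n8")) {
    tr <- build_bfs_tree(map, root)
    n_leaves <- sum(!(names(tr) %in% tr))
    expect_equal(sum(coll$root_id == root), n_leaves)
  }
})

test_that("extract_ess warns and returns empty on rootless maps", {
  # 2-cycle: each node's substrate is produced by the other
  cyc <- metabolic_map("c", "", tibble::tibble(
    node_id = c("a", "b"), ec = c("1.1.1", "2.2.2"), reversible = FALSE,
    substrates = list("x", "y"), products = list("y", "x"),
    external_substrates = list(character(0), character(0))))
  expect_warning(out <- extract_ess(cyc), "no initialization nodes")
  expect_equal(nrow(out), 0L)
})

test_that("min_length filters and duplicates collapse", {
  map <- toy_chain_map()
  coll <- extract_ess(map, min_length = 4L)
  expect_equal(nrow(coll), 0L)
  # two parallel identical branches produce one collapsed ESS
  dup <- metabolic_map("dup", "", tibble::tibble(
    node_id = c("r", "a", "b"),
    ec = c("1.1.1", "2.7.1", "2.7.1"),
    reversible = FALSE,
    substrates = list("s", "p", "p"),
    products = list("p", "q1", "q2"),
    external_substrates = list(character(0), character(0), character(0))))
  coll <- extract_ess(dup)
  expect_equal(nrow(coll), 1L)
  expect_equal(coll$steps[[1]], c("1.1.1", "2.7.1"))
})

test_that("ess_statistics computes hand values per map", {
  coll <- tibble::tibble(
    ess_id = c("a", "b", "c"),
    map_id = c("m1", "m1", "m2"),
    root_id = "r",
    steps = list(rep("1.1.1", 3), rep("1.1.1", 5), rep("2.2.2", 4)))
  st <- ess_statistics(coll)
  m1 <- st[st$map_id == "m1", ]
  expect_equal(m1$n_ess, 2L)
  expect_equal(m1$mean_length, 4)
  expect_equal(m1$sd_length, sd(c(3, 5)))
  m2 <- st[st$map_id == "m2", ]
  expect_equal(m2$n_ess, 1L)
  expect_equal(m2$sd_length, 0)
  expect_error(ess_statistics(empty_collection <- tibble::tibble(
    ess_id = character(0), map_id = character(0), steps = list())), "empty")
})

test_that("write_ess/read_ess round-trip and bind_ess enforces unique ids", {
  coll <- extract_ess(toy_branched_map())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ess(coll, path)
  back <- read_ess(path)
  expect_equal(back$ess_id, coll$ess_id)
  expect_equal(back$steps, coll$steps)

  expect_error(bind_ess(coll, coll), "duplicate")
  both <- bind_ess(coll, extract_ess(toy_chain_map()))
  expect_equal(nrow(both), nrow(coll) + 1L)
})
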