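test_that("new_similarity validates symmetry and dimnames", {
  m <- matrix(c(0, .2, .2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  s <- new_similarity(m)
  expect_equal(s$ids, c("a", "b"))
  m[1, 2] <- 0.3
  expect_error(new_similarity(m), "symmetric")
  expect_error(new_similarity(matrix(0, 2, 2)), NULL)
})

test_that("all_vs_all is symmetric with zero diagonal and caches pairs", {
  coll <- toy_collection(list(
    a = c("2.7.1", "1.1.1"), b = c("2.7.1", "1.1.1"),
    c = c("5.3.1", "4.1.2", "3.2.1")))
  p <- fast_params(seed = 2L)
  cache <- withr::local_tempfile(fileext = ".tsv")
  s1 <- all_vs_all(coll, p, cache = cache)
  expect_equal(diag(s1$values), c(a = 0, b = 0, c = 0))
  expect_equal(s1$values, t(s1$values))
  # identical sequences attain the optimum
  expect_equal(s1$values["a", "b"], 0.05)
  expect_equal(nrow(read.table(cache, sep = "\t")), 3L)
  # second run is served from the cache and reproduces the matrix
  s2 <- all_vs_all(coll, p, cache = cache)
  expect_equal(s2$values, s1$values)
  expect_equal(nrow(read.table(cache, sep = "\t")), 3L)

  td <- tidy(s1)
  expect_equal(nrow(td), 3L)
  expect_s3_class(autoplot(s1), "ggplot")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_similarity(s1, path)
  expect_equal(read_similarity(path)$values, s1$values)
})

test_that("shuffle_ess conserves the EC pool and the length vector", {
  coll <- toy_collection(list(
    a = c("2.7.1", "1.1.1", "3.2.1"), b = c("5.3.1", "1.1.1"),
    c = c("4.1.2", "4.1.2", "2.7.1", "6.3.2")))
  sh <- shuffle_ess(coll, seed = 5L)
  expect_equal(lengths(sh$steps), lengths(coll$steps))
  expect_equal(sort(unlist(sh$steps)), sort(unlist(coll$steps)))
  expect_equal(sh$ess_id, coll$ess_id)
  # deterministic per seed, different across seeds (with high probability)
  expect_identical(shuffle_ess(coll, seed = 5L), sh)
})

test_that("significance threshold and fraction_below are exact", {
  scores <- c(0.6, 0.7, 0.8) # mean 0.7, sd 0.1
  expect_true(abs(significance_threshold(scores) - 0.4) < 1e-12)
  expect_error(significance_threshold(0.5), "at least 2")
  expect_equal(fraction_below(c(0.1, 0.4, 0.5), 0.4), 1 / 3)
  expect_equal(fraction_below(c(0.1, 0.4, 0.5), 0.4, strict = FALSE), 2 / 3)
  expect_error(fraction_below(numeric(0), 0.4), "empty")
})

test_that("ess_significance separates planted structure from its null", {
  # length 10: the shuffle conserves composition and lengths, so for short
  # sequences over a small token pool null pairs align below the cutoff
  # nearly as often as planted ones; random-pair objectives concentrate
  # above the cutoff only as length grows
  blocks <- generate_ess_blocks(2, 4, 10, divergence = 0.1, seed = 8L)
  p <- fast_params(seed = 3L)
  ns <- ess_significance(blocks$collection, p, n_sets = 2L, seed = 1L,
                         threshold = 0.4)
  expect_s3_class(ns, "ess_null_model")
  expect_length(ns$null_fractions, 2L)
  expect_gt(ns$real_fraction, mean(ns$null_fractions))
  gl <- glance(ns)
  expect_equal(gl$threshold, 0.4)
  expect_equal(gl$real_fraction, ns$real_fraction)
})

test_that("kmedoids recovers a hand-built block structure", {
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3")
  m <- matrix(0.9, 6, 6, dimnames = list(ids, ids))
  m[1:3, 1:3] <- 0.1
  m[4:6, 4:6] <- 0.1
  diag(m) <- 0
  cl <- kmedoids(new_similarity(m), k = 2, seed = 1L)
  expect_equal(cl$k, 2L)
  expect_length(unique(cl$assignment[1:3]), 1L)
  expect_length(unique(cl$assignment[4:6]), 1L)
  expect_false(cl$assignment[1] == cl$assignment[4])
  # medoids belong to their own clusters
  expect_equal(unname(cl$assignment[cl$medoids]), seq_len(2L))
  expect_error(kmedoids(new_similarity(m), k = 6), "k must")

  td <- tidy(cl)
  expect_equal(sum(td$is_medoid), 2L)
  expect_equal(glance(cl)$n, 6L)
})

test_that("kmedoids quality matches cluster::pam on separable data", {
  skip_if_not_installed("cluster")
  set.seed(14)
  blocks <- generate_ess_blocks(2, 4, 4, divergence = 0, seed = 4L)
  sim <- all_vs_all(blocks$collection, fast_params(seed = 6L))
  ours <- kmedoids(sim, k = 2, seed = 1L)
  pam <- cluster::pam(as.dist(sim$values), k = 2)
  # same partition up to label switching
  expect_equal(length(unique(paste(ours$assignment, pam$clustering))), 2L)
})

test_that("elbow_select finds the planted k and reports the curve", {
  blocks <- generate_ess_blocks(3, 4, 5, divergence = 0.05, seed = 9L)
  sim <- all_vs_all(blocks$collection, fast_params(seed = 5L))
  el <- elbow_select(sim, k_min = 2L, k_max = 6L, replicates = 5L, seed = 1L)
  expect_equal(el$k, 3L)
  expect_equal(el$curve$k, 2:6)
  expect_true(all(diff(el$curve$quality) <= 1e-9)) # quality non-increasing
  expect_equal(tidy(el), el$curve)
  expect_s3_class(autoplot(el), "ggplot")
  expect_error(elbow_select(sim, k_min = 2L, k_max = 20L), "smaller")
})

test_that("depurate removes high-fitness members once and is idempotent", {
  ids <- c("a1", "a2", "a3", "bad")
  m <- matrix(0.1, 4, 4, dimnames = list(ids, ids))
  m["bad", 1:3] <- m[1:3, "bad"] <- 0.8
  diag(m) <- 0
  sim <- new_similarity(m)
  model <- structure(list(
    k = 1L, medoids = "a1",
    assignment = stats::setNames(rep(1L, 4), ids),
    quality = 0, removed_by_depuration = character(0)),
    class = "ess_clusters")
  dep <- depurate(model, sim, cutoff = 0.4)
  expect_equal(dep$removed_by_depuration, "bad")
  expect_equal(names(dep$assignment), c("a1", "a2", "a3"))
  dep2 <- depurate(dep, sim, cutoff = 0.4)
  expect_equal(dep2$assignment, dep$assignment)
  # singletons survive
  single <- structure(list(
    k = 1L, medoids = "a1",
    assignment = c(a1 = 1L), quality = 0,
    removed_by_depuration = character(0)), class = "ess_clusters")
  expect_equal(names(depurate(single, sim, cutoff = 0)$assignment), "a1")
})

test_that("write_clusters emits valid JSON and TSV", {
  ids <- c("a", "b", "c")
  m <- matrix(0.2, 3, 3, dimnames = list(ids, ids)); diag(m) <- 0
  cl <- kmedoids(new_similarity(m), k = 2, seed = 1L)
  pj <- withr::local_tempfile(fileext = ".json")
  write_clusters(cl, pj, format = "json")
  j <- jsonlite::read_json(pj)
  expect_equal(j$k, 2L)
  expect_length(j$clusters, 2L)
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_clusters(cl, pt, format = "tsv")
  expect_equal(nrow(read.table(pt, header = TRUE, sep = "\t")), 3L)
})
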