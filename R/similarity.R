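#' Similarity (fitness) matrices of ESS collections
#'
#' A symmetric matrix of best alignment objectives over a collection; lower
#' values mean more similar sequences, and the diagonal is 0 by convention.
#'
#' @param values square numeric matrix with dimnames set to the ess ids.
#' @return an object of class `ess_similarity` with fields `ids`, `values`.
#' @export
new_similarity <- function(values) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)),
            identical(rownames(values), colnames(values)))
  if (max(abs(values - t(values))) > 1e-12) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  structure(list(ids = rownames(values), values = values),
            class = "ess_similarity")
}

#' @export
print.ess_similarity <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat("ESS similarity matrix: ", length(x$ids), " sequences, fitness range [",
      sprintf("%.3f", min(off)), ", ", sprintf("%.3f", max(off)), "]\n",
      sep = "")
  invisible(x)
}

#' All-against-all pairwise GA alignment
#'
#' Runs [ga_align()] on every unordered pair of the collection and stores the
#' best objective symmetrically; the diagonal is 0. Results can be cached in
#' a long-format TSV keyed by the id pair and a parameter fingerprint, making
#' long runs resumable.
#'
#' @param coll an ESS tibble (`ess_id`, `steps`, ...).
#' @param params a [ga_params()].
#' @param control a [scoring_control()].
#' @param cache optional path to a TSV cache file.
#' @param progress print progress every `progress` pairs (0 = silent).
#' @return an [new_similarity()] object.
#' @export
all_vs_all <- function(coll, params = ga_params(),
                       control = scoring_control(), cache = NULL,
                       progress = 0) {
  check_ess(coll)
  n <- nrow(coll)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  ids <- coll$ess_id
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  phash <- params_fingerprint(params, control)
  cached <- load_pair_cache(cache, phash)
  con <- if (!is.null(cache)) file(cache, open = "a") else NULL
  on.exit(if (!is.null(con)) close(con), add = TRUE)
  done <- 0L
  total <- n * (n - 1) / 2
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      key <- paste(sort(c(ids[i], ids[j])), collapse = "\r")
      hit <- cached[[key]]
      if (!is.null(hit)) {
        fit <- hit
      } else {
        aln <- ga_align(coll$steps[c(i, j)], params, control,
                        ids = ids[c(i, j)])
        fit <- aln$score$objective
        if (!is.null(con)) {
          writeLines(paste(ids[i], ids[j], format(fit, digits = 17), phash,
                           sep = "\t"), con)
        }
      }
      vals[i, j] <- vals[j, i] <- fit
      done <- done + 1L
      if (progress > 0 && done %% progress == 0) {
        message("all_vs_all: ", done, "/", total, " pairs")
      }
    }
  }
  new_similarity(vals)
}

params_fingerprint <- function(params, control) {
  paste(c(unlist(params[c("population_size", "mutation_rate",
                          "crossover_rate", "stagnation_generations",
                          "replicates", "tournament_size", "seed",
                          "mutation_policy", "per_individual_rate")]),
          unlist(control)), collapse = "|")
}

load_pair_cache <- function(cache, phash) {
  out <- new.env(parent = emptyenv())
  if (is.null(cache) || !file.exists(cache)) return(out)
  lines <- readLines(cache)
  for (p in strsplit(lines, "\t", fixed = TRUE)) {
    if (length(p) == 4 && p[4] == phash) {
      assign(paste(sort(p[1:2]), collapse = "\r"), as.numeric(p[3]), out)
    }
  }
  out
}

#' Tidy a similarity matrix into long format
#'
#' One row per unordered pair (`id_a < id_b` in the collection order).
#'
#' @param x an `ess_similarity`.
#' @param ... unused.
#' @return tibble with `id_a`, `id_b`, `fitness`.
#' @export
tidy.ess_similarity <- function(x, ...) {
  n <- length(x$ids)
  ut <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(id_a = x$ids[ut[, 1]], id_b = x$ids[ut[, 2]],
                 fitness = x$values[ut])
}

#' @rdname tidy.ess_similarity
#' @param object an `ess_similarity`.
#' @export
autoplot.ess_similarity <- function(object, ...) {
  d <- expand.grid(id_a = object$ids, id_b = object$ids,
                   stringsAsFactors = FALSE)
  d$fitness <- as.vector(object$values)
  ggplot2::ggplot(d, ggplot2::aes(.data$id_a, .data$id_b,
                                  fill = .data$fitness)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "fitness") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Read and write similarity matrices
#'
#' Wide format: TSV with a header row and a leading id column. Long format:
#' `id_a`, `id_b`, `fitness` (see [tidy.ess_similarity()]).
#'
#' @param sim an `ess_similarity`.
#' @param path file path.
#' @param format `"wide"` or `"long"`.
#' @return `read_similarity()` returns an `ess_similarity`; the writer
#'   returns `path` invisibly.
#' @export
write_similarity <- function(sim, path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (format == "wide") {
    df <- data.frame(ess_id = sim$ids, sim$values, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(tidy(sim), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_similarity(m)
}

# ---- significance ----------------------------------------------------------

#' Shuffle the EC numbers of a collection
#'
#' Pools every EC token of the collection, permutes the pool uniformly and
#' redistributes the tokens into sequences of the original lengths in the
#' original order, conserving both the length vector and the overall EC
#' composition.
#'
#' @param coll an ESS tibble.
#' @param seed integer seed.
#' @return an ESS tibble of the same shape with shuffled `steps`.
#' @export
shuffle_ess <- function(coll, seed = 1L) {
  check_ess(coll)
  if (nrow(coll) == 0) return(coll)
  pool <- unlist(coll$steps, use.names = FALSE)
  pool <- withr::with_seed(seed, sample(pool))
  lens <- lengths(coll$steps)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  out <- coll
  out$steps <- lapply(seq_along(lens), function(i) pool[starts[i]:ends[i]])
  out
}

#' Significance threshold from a score distribution
#'
#' `mean(scores) - 3 * sd(scores)` (sample standard deviation): alignment
#' fitness values below this are considered significant.
#'
#' @param real_scores numeric vector of >= 2 alignment objectives.
#' @return numeric threshold.
#' @export
significance_threshold <- function(real_scores) {
  if (length(real_scores) < 2) stop("need at least 2 scores", call. = FALSE)
  mean(real_scores) - 3 * stats::sd(real_scores)
}

#' Fraction of scores below a threshold
#'
#' @param scores numeric vector.
#' @param threshold numeric cutoff.
#' @param strict use strict inequality (default) or `<=`.
#' @return numeric in `[0, 1]`.
#' @export
fraction_below <- function(scores, threshold, strict = TRUE) {
  if (length(scores) == 0) stop("empty score vector", call. = FALSE)
  if (strict) mean(scores < threshold) else mean(scores <= threshold)
}

#' Shuffled-sequence null model for alignment significance
#'
#' Builds `n_sets` shuffled copies of the collection (lengths and EC
#' composition conserved), computes their all-against-all GA fitness values,
#' and compares the fraction of real pairs below the fitness threshold with
#' the per-set fractions of the shuffled pairs.
#'
#' @param coll an ESS tibble.
#' @param params a [ga_params()].
#' @param control a [scoring_control()].
#' @param n_sets number of shuffled sets.
#' @param seed seed for the shuffles (set `s` uses `seed + s`).
#' @param threshold fitness cutoff; `NULL` derives it from the real scores
#'   via [significance_threshold()].
#' @param real_sim optionally, a precomputed [all_vs_all()] matrix of `coll`.
#' @return an object of class `ess_null_model`: list with the threshold, the
#'   real fraction below it, per-set shuffled fractions, and the raw score
#'   vectors.
#' @export
ess_significance <- function(coll, params = ga_params(),
                             control = scoring_control(), n_sets = 10L,
                             seed = 1L, threshold = NULL, real_sim = NULL) {
  check_ess(coll)
  if (is.null(real_sim)) real_sim <- all_vs_all(coll, params, control)
  real_scores <- real_sim$values[upper.tri(real_sim$values)]
  if (is.null(threshold)) threshold <- significance_threshold(real_scores)
  null_scores <- lapply(seq_len(n_sets), function(s) {
    shuffled <- shuffle_ess(coll, seed = (seed + s) %% .Machine$integer.max)
    sim <- all_vs_all(shuffled, params, control)
    sim$values[upper.tri(sim$values)]
  })
  structure(list(
    threshold = threshold,
    real_fraction = fraction_below(real_scores, threshold),
    null_fractions = vapply(null_scores, fraction_below, numeric(1),
                            threshold = threshold),
    real_scores = real_scores,
    null_scores = null_scores,
    n_sets = n_sets), class = "ess_null_model")
}

#' @export
print.ess_null_model <- function(x, ...) {
  cat(sprintf(
    "Null model (%d shuffled sets): threshold %.4f; real fraction below %.4f; shuffled %.4f +/- %.4f\n",
    x$n_sets, x$threshold, x$real_fraction, mean(x$null_fractions),
    stats::sd(x$null_fractions)))
  invisible(x)
}

#' @rdname tidy.ess_clusters
#' @export
glance.ess_null_model <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, real_fraction = x$real_fraction,
                 null_fraction_mean = mean(x$null_fractions),
                 null_fraction_sd = stats::sd(x$null_fractions),
                 n_sets = x$n_sets)
}

# ---- clustering ------------------------------------------------------------

#' k-medoids clustering of a similarity matrix
#'
#' Alternating assignment/medoid-update on the precomputed fitness values,
#' restarted from `replicates` random medoid sets; the model with the
#' smallest total within-cluster dissimilarity (the quality) is returned.
#' Assignment ties and medoid-update ties break to the lowest index.
#'
#' @param sim an [new_similarity()] object.
#' @param k number of clusters, `2 <= k < n`.
#' @param replicates random initializations.
#' @param seed integer seed.
#' @return an object of class `ess_clusters`: `k`, `medoids` (ids),
#'   `assignment` (named integer vector), `quality`,
#'   `removed_by_depuration` (empty until [depurate()]).
#' @export
kmedoids <- function(sim, k, replicates = 20L, seed = 1L) {
  stopifnot(inherits(sim, "ess_similarity"))
  n <- length(sim$ids)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < n", call. = FALSE)
  d <- sim$values
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(replicates)) {
      med <- sort(sample.int(n, k))
      iter <- 0L
      repeat {
        iter <- iter + 1L
        assign_idx <- apply(d[, med, drop = FALSE], 1, which.min)
        assign_idx[med] <- seq_len(k) # a medoid belongs to its own cluster
        new_med <- vapply(seq_len(k), function(c) {
          members <- which(assign_idx == c)
          if (length(members) == 0) return(med[c])
          costs <- colSums(d[members, members, drop = FALSE])
          members[which.min(costs)]
        }, integer(1))
        new_med <- new_med[order(new_med)]
        if (identical(new_med, med) || iter >= 100L) break
        med <- new_med
      }
      assign_idx <- apply(d[, med, drop = FALSE], 1, which.min)
      assign_idx[med] <- seq_len(k)
      quality <- sum(d[cbind(seq_len(n), med[assign_idx])])
      if (is.null(best) || quality < best$quality - 1e-12) {
        best <- list(med = med, assign = assign_idx, quality = quality)
      }
    }
  })
  structure(list(
    k = as.integer(k),
    medoids = sim$ids[best$med],
    assignment = stats::setNames(as.integer(best$assign), sim$ids),
    quality = best$quality,
    removed_by_depuration = character(0)), class = "ess_clusters")
}

#' @export
print.ess_clusters <- function(x, ...) {
  cat("k-medoids model: k = ", x$k, ", quality = ",
      sprintf("%.4f", x$quality), ", ", length(x$removed_by_depuration),
      " sequences removed by depuration\n", sep = "")
  invisible(x)
}

#' Tidiers for cluster models
#'
#' `tidy()` gives one row per sequence (cluster, medoid flag, removed flag);
#' `glance()` the one-row model summary.
#'
#' @param x an `ess_clusters` (or `ess_null_model` for its glance method).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.ess_clusters <- function(x, ...) {
  ids <- names(x$assignment)
  tibble::tibble(ess_id = ids, cluster = unname(x$assignment),
                 is_medoid = ids %in% x$medoids,
                 removed = ids %in% x$removed_by_depuration)
}

#' @rdname tidy.ess_clusters
#' @export
glance.ess_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, quality = x$quality,
                 n = length(x$assignment),
                 n_removed = length(x$removed_by_depuration))
}

#' Choose k with the elbow criterion
#'
#' Computes the best-of-`replicates` k-medoids quality for each `k` in
#' `[k_min, k_max]` and returns the `k` maximizing the discrete second
#' derivative `Q(k-1) - 2 Q(k) + Q(k+1)` (the sharpest bend of the quality
#' curve). All candidate peaks are reported so higher-order peaks can be
#' inspected; ties resolve to the smallest `k` with a warning.
#'
#' @inheritParams kmedoids
#' @param k_min,k_max range of `k` values (needs at least 3 points and
#'   `k_max < n`).
#' @return an object of class `ess_elbow`: the selected `k`, the quality
#'   `curve` tibble (`k`, `quality`, `second_diff`) and the `peaks` (k values
#'   ordered by decreasing second difference).
#' @export
elbow_select <- function(sim, k_min = 2L, k_max = 100L, replicates = 20L,
                         seed = 1L) {
  stopifnot(inherits(sim, "ess_similarity"))
  n <- length(sim$ids)
  if (k_max >= n) stop("k_max must be smaller than the number of sequences",
                       call. = FALSE)
  ks <- seq.int(k_min, k_max)
  if (length(ks) < 3) stop("elbow needs at least 3 k values", call. = FALSE)
  q <- vapply(ks, function(k)
    kmedoids(sim, k, replicates = replicates,
             seed = (seed + k) %% .Machine$integer.max)$quality, numeric(1))
  d2 <- rep(NA_real_, length(ks))
  inner <- 2:(length(ks) - 1)
  d2[inner] <- q[inner - 1] - 2 * q[inner] + q[inner + 1]
  mx <- max(d2[inner])
  hits <- ks[inner][d2[inner] >= mx - 1e-12]
  if (length(hits) > 1) {
    warning("no unique elbow; returning the smallest k among ties",
            call. = FALSE)
  }
  peaks <- ks[inner][order(d2[inner], decreasing = TRUE)]
  structure(list(k = min(hits),
                 curve = tibble::tibble(k = ks, quality = q, second_diff = d2),
                 peaks = peaks),
            class = "ess_elbow")
}

#' @export
print.ess_elbow <- function(x, ...) {
  cat("Elbow selection: k = ", x$k, " (top peaks: ",
      paste(utils::head(x$peaks, 5), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @rdname tidy.ess_clusters
#' @export
tidy.ess_elbow <- function(x, ...) x$curve

#' Plot the elbow curve
#'
#' Cluster quality against k with the selected elbow marked.
#'
#' @param object an `ess_elbow`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ess_elbow <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$k, .data$quality)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed",
                        color = "red") +
    ggplot2::labs(x = "k", y = "total within-cluster dissimilarity") +
    ggplot2::theme_minimal()
}

#' Depurate clusters at a fitness cutoff
#'
#' Removes every sequence whose mean fitness with the other members of its
#' cluster exceeds `cutoff`. By default the means are computed against the
#' original membership and removals are applied in a single pass (so the
#' operation is idempotent); `cascade = TRUE` re-evaluates against the
#' surviving members until a fixpoint. Singleton clusters are retained.
#'
#' @param model an `ess_clusters` model.
#' @param sim the [new_similarity()] matrix the model was fitted on.
#' @param cutoff fitness cutoff (the published analysis used 0.4).
#' @param cascade re-evaluate after removals until stable.
#' @return the depurated `ess_clusters` model (removed ids recorded in
#'   `removed_by_depuration` and dropped from `assignment`).
#' @export
depurate <- function(model, sim, cutoff = 0.4, cascade = FALSE) {
  stopifnot(inherits(model, "ess_clusters"), inherits(sim, "ess_similarity"))
  if (cutoff < 0) stop("cutoff must be non-negative", call. = FALSE)
  assign <- model$assignment
  removed <- character(0)
  repeat {
    ids <- names(assign)
    drop <- vapply(ids, function(id) {
      mates <- setdiff(ids[assign == assign[id]], id)
      if (length(mates) == 0) return(FALSE)
      mean(sim$values[id, mates]) > cutoff
    }, logical(1))
    if (!any(drop)) break
    removed <- c(removed, ids[drop])
    assign <- assign[!drop]
    if (!cascade) break
  }
  model$assignment <- assign
  model$removed_by_depuration <- c(model$removed_by_depuration, removed)
  model$quality <- sum(vapply(names(assign), function(id)
    sim$values[id, model$medoids[assign[id]]], numeric(1)))
  model
}

#' Write a cluster model
#'
#' JSON (`k`, `medoids`, `clusters` with members, `removed`) or a flat TSV
#' (`ess_id`, `cluster`, `removed_flag`).
#'
#' @param model an `ess_clusters`.
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(model, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    clusters <- lapply(seq_len(model$k), function(c) list(
      id = c, members = names(model$assignment)[model$assignment == c]))
    jsonlite::write_json(
      list(k = model$k, medoids = model$medoids, clusters = clusters,
           removed = model$removed_by_depuration),
      path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(tidy(model), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
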