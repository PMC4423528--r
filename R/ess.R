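#' Initialization nodes of a metabolic map
#'
#' The roots from which step sequences are traced, representing the metabolic
#' inputs of a pathway. A node qualifies when (i) none of its substrates is
#' produced by another enzyme of the same map (no in-edge supplies any of its
#' substrates), or (ii) at least one of its substrates arrives from another
#' metabolic map (a cross-map link) and the node has at most two neighbors in
#' the graph.
#'
#' @param map a [metabolic_map()].
#' @return character vector of node ids (sorted).
#' @export
find_initialization_nodes <- function(map) {
  stopifnot(inherits(map, "metabolic_map"))
  nodes <- map$nodes
  sel <- vapply(seq_len(nrow(nodes)), function(i) {
    nid <- nodes$node_id[i]
    subs <- nodes$substrates[[i]]
    supplied <- map$edges$compound[map$edges$to == nid &
                                     map$edges$from != nid]
    crit1 <- length(intersect(subs, supplied)) == 0
    crit2 <- length(nodes$external_substrates[[i]]) > 0 &&
      length(graph_neighbors(map, nid)) <= 2
    crit1 || crit2
  }, logical(1))
  sort(nodes$node_id[sel])
}

#' Breadth-first search tree of a map
#'
#' Standard BFS over the directed edges from `root`; each reachable node
#' appears once with a single parent. Children are enqueued in ascending
#' `node_id` order, making trees deterministic.
#'
#' @param map a [metabolic_map()].
#' @param root node id used as the tree root.
#' @return named character vector mapping each reached node (except the root)
#'   to its parent; the root is included with parent `NA`.
#' @export
build_bfs_tree <- function(map, root) {
  stopifnot(inherits(map, "metabolic_map"))
  if (!(root %in% map$nodes$node_id)) {
    stop("unknown root node: ", root, call. = FALSE)
  }
  children_of <- split(map$edges$to, map$edges$from)
  parent <- stats::setNames(NA_character_, root)
  queue <- root
  while (length(queue) > 0) {
    u <- queue[1]
    queue <- queue[-1]
    kids <- sort(unique(children_of[[u]]))
    kids <- kids[!(kids %in% names(parent))]
    for (k in kids) parent[k] <- u
    queue <- c(queue, kids)
  }
  parent
}

bfs_leaf_paths <- function(parent) {
  nodes <- names(parent)
  leaves <- nodes[!(nodes %in% parent)]
  lapply(sort(leaves), function(leaf) {
    path <- leaf
    while (!is.na(parent[path[1]])) path <- c(parent[[path[1]]], path)
    path
  })
}

#' Extract enzymatic step sequences from a map
#'
#' For every initialization node, builds its BFS tree and emits one ESS per
#' root-to-leaf branch; the steps of an ESS are the three-level EC codes
#' along the path. Exact duplicates (same map, root and step string) are
#' collapsed. Length-1 sequences are kept by default.
#'
#' @param map a [metabolic_map()].
#' @param min_length drop sequences shorter than this (default 1 keeps all).
#' @return an ESS collection: a tibble with columns `ess_id`, `map_id`,
#'   `root_id` and the list-column `steps` (character EC vectors).
#' @export
extract_ess <- function(map, min_length = 1L) {
  stopifnot(inherits(map, "metabolic_map"))
  roots <- find_initialization_nodes(map)
  if (length(roots) == 0) {
    warning("map ", map$map_id, " has no initialization nodes", call. = FALSE)
    return(empty_ess())
  }
  ec_of <- stats::setNames(map$nodes$ec, map$nodes$node_id)
  rows <- list()
  for (root in roots) {
    parent <- build_bfs_tree(map, root)
    for (path in bfs_leaf_paths(parent)) {
      steps <- unname(ec_of[path])
      if (length(steps) < min_length) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        map_id = map$map_id, root_id = root, steps = list(steps))
    }
  }
  if (length(rows) == 0) return(empty_ess())
  out <- dplyr::bind_rows(rows)
  key <- paste(out$map_id, out$root_id,
               vapply(out$steps, paste, character(1), collapse = ","))
  out <- out[!duplicated(key), ]
  out$ess_id <- paste0(out$map_id, "_", out$root_id, "_b",
                       stats::ave(seq_len(nrow(out)),
                                  paste(out$map_id, out$root_id),
                                  FUN = seq_along))
  dplyr::select(out, "ess_id", "map_id", "root_id", "steps")
}

empty_ess <- function() {
  tibble::tibble(ess_id = character(0), map_id = character(0),
                 root_id = character(0), steps = list())
}

#' Combine per-map ESS into one collection
#'
#' @param ... ESS tibbles (from [extract_ess()]) or a list of them.
#' @return one ESS tibble with unique `ess_id`s.
#' @export
bind_ess <- function(...) {
  pieces <- list(...)
  if (length(pieces) == 1 && is.list(pieces[[1]]) &&
      !is.data.frame(pieces[[1]])) {
    pieces <- pieces[[1]]
  }
  out <- dplyr::bind_rows(pieces)
  if (anyDuplicated(out$ess_id)) {
    stop("duplicate ess_id across collections", call. = FALSE)
  }
  out
}

#' Per-map summary statistics of an ESS collection
#'
#' ESS count, mean length and sample standard deviation of length per map
#' (SD reported as 0 for single-sequence maps).
#'
#' @param coll an ESS tibble (columns `ess_id`, `map_id`, `steps`).
#' @return tibble with `map_id`, `n_ess`, `mean_length`, `sd_length`.
#' @export
ess_statistics <- function(coll) {
  check_ess(coll)
  if (nrow(coll) == 0) stop("empty ESS collection", call. = FALSE)
  coll |>
    dplyr::mutate(len = lengths(.data$steps)) |>
    dplyr::group_by(.data$map_id) |>
    dplyr::summarise(
      n_ess = dplyr::n(),
      mean_length = mean(.data$len),
      sd_length = if (dplyr::n() > 1) stats::sd(.data$len) else 0,
      .groups = "drop")
}

check_ess <- function(coll) {
  req <- c("ess_id", "map_id", "steps")
  if (!is.data.frame(coll) || !all(req %in% names(coll))) {
    stop("expected an ESS collection tibble with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  invisible(coll)
}

#' Read and write ESS collections as TSV
#'
#' Columns `ess_id`, `map_id`, `root_id`, `steps` with the EC codes of
#' `steps` joined by commas.
#'
#' @param coll an ESS tibble.
#' @param path file path.
#' @return `read_ess()` returns the ESS tibble; `write_ess()` returns `path`
#'   invisibly.
#' @export
write_ess <- function(coll, path) {
  check_ess(coll)
  df <- data.frame(
    ess_id = coll$ess_id, map_id = coll$map_id,
    root_id = if ("root_id" %in% names(coll)) coll$root_id else NA,
    steps = vapply(coll$steps, paste, character(1), collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ess
#' @export
read_ess <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  tibble::tibble(
    ess_id = df$ess_id, map_id = df$map_id, root_id = df$root_id,
    steps = strsplit(df$steps, ",", fixed = TRUE))
}
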