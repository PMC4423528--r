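#' Guide order for progressive alignment
#'
#' Orders the members of a cluster by similarity: the most similar pair (the
#' minimal pairwise fitness) comes first, and each subsequent sequence is the
#' unplaced member with minimal mean fitness to the already-placed set. All
#' ties break lexicographically by id.
#'
#' @param members character vector of >= 2 ess ids.
#' @param sim an [new_similarity()] covering the members.
#' @return character vector: the members in guide order.
#' @export
build_guide_order <- function(members, sim) {
  stopifnot(inherits(sim, "ess_similarity"))
  if (length(members) < 2) stop("need at least 2 members", call. = FALSE)
  if (!all(members %in% sim$ids)) {
    stop("members missing from the similarity matrix", call. = FALSE)
  }
  members <- sort(members)
  d <- sim$values[members, members, drop = FALSE]
  # most similar pair, ties to lexicographically first (i, j)
  best <- c(1L, 2L)
  for (i in seq_len(length(members) - 1)) {
    for (j in (i + 1):length(members)) {
      if (d[i, j] < d[best[1], best[2]] - 1e-12) best <- c(i, j)
    }
  }
  placed <- members[best]
  rest <- setdiff(members, placed)
  while (length(rest) > 0) {
    means <- vapply(rest, function(id) mean(sim$values[id, placed]),
                    numeric(1))
    nxt <- rest[which.min(means)] # rest is sorted, so ties break by id
    placed <- c(placed, nxt)
    rest <- setdiff(rest, nxt)
  }
  placed
}

#' Progressive GA multiple alignment of a cluster
#'
#' Aligns the first two sequences of the guide order with [ga_align()], then
#' extends the alignment one sequence at a time: the existing rows form a
#' frozen block whose internal gap pattern never changes ("once a gap, always
#' a gap"), while the GA may insert whole gap columns into the block and gaps
#' into the new row. The objective is evaluated over the full block, and the
#' trivially padded solution is seeded into every initial population, so each
#' extension is at least as good as naive stacking.
#'
#' @param coll the ESS tibble holding the members' steps.
#' @param members character vector of >= 2 ess ids to align.
#' @param sim an [new_similarity()] used to build the guide order (pass
#'   `NULL` to keep `members` order as given).
#' @param params a [ga_params()].
#' @param control a [scoring_control()].
#' @return an [new_alignment()] with rows in guide order and the final
#'   `ess_score` attached.
#' @export
progressive_msa <- function(coll, members, sim = NULL, params = ga_params(),
                            control = scoring_control()) {
  check_ess(coll)
  missing_ids <- setdiff(members, coll$ess_id)
  if (length(missing_ids) > 0) {
    stop("members without sequences in the collection: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  ord <- if (is.null(sim)) members else build_guide_order(members, sim)
  steps_of <- stats::setNames(coll$steps, coll$ess_id)
  seqs <- steps_of[ord]

  # first two sequences: ordinary pairwise GA, rows kept in guide order
  blocks <- lapply(seqs[1:2], function(s) matrix(s, nrow = 1))
  res <- run_engine(blocks, params, control, seed_trivial = TRUE)
  grid <- decode_blocks(blocks, res$masks)

  for (i in seq_along(ord)[-(1:2)]) {
    blocks <- list(grid, matrix(seqs[[i]], nrow = 1))
    res <- run_engine(blocks, params, control, seed_trivial = TRUE)
    grid <- decode_blocks(blocks, res$masks)
  }
  new_alignment(grid, ids = ord, seq_lengths = lengths(seqs),
                score = new_score(res$homogeneity, res$gap_penalty,
                                  res$column_increment))
}

#' Conserved columns of a multiple alignment
#'
#' Columns whose modal non-gap EC code accounts for at least `min_identity`
#' of the non-gap cells, flagging cores of enzymatic reactions shared across
#' the aligned pathways.
#'
#' @param aln an [new_alignment()].
#' @param min_identity fraction in `(0, 1]`.
#' @return tibble with `column`, `modal_ec`, `identity` for the conserved
#'   columns.
#' @export
conserved_columns <- function(aln, min_identity = 0.8) {
  stopifnot(inherits(aln, "ess_alignment"))
  rows <- lapply(seq_len(ncol(aln$grid)), function(j) {
    col <- aln$grid[, j]
    col <- col[!is.na(col)]
    tab <- sort(table(col), decreasing = TRUE)
    tibble::tibble(column = j, modal_ec = names(tab)[1],
                   identity = as.numeric(tab[1]) / length(col))
  })
  out <- dplyr::bind_rows(rows)
  out[out$identity >= min_identity - 1e-12, ]
}

#' Per-column annotation of a multiple alignment
#'
#' One row per column: modal EC code, identity fraction and gap count,
#' supporting rendered cluster-alignment figures.
#'
#' @inheritParams conserved_columns
#' @return a tibble with `column`, `modal_ec`, `identity`, `n_gaps`.
#' @export
column_annotation <- function(aln) {
  stopifnot(inherits(aln, "ess_alignment"))
  ann <- conserved_columns(aln, min_identity = 0)
  ann$n_gaps <- colSums(is.na(aln$grid))
  ann
}
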