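#' Scoring options for the alignment objective function
#'
#' The objective function (minimized; lower = more similar) is
#' `0.9 * Homogeneity + 0.05 * GapPenalty + 0.05 * ColumnIncrement`.
#' Homogeneity is the column mean of `0.6 * E + 0.4 * GapFraction`, where `E`
#' is the weighted normalized Shannon entropy over the three EC levels
#' (weights 15, 10, 5) with the gap counted as one more symbol, and
#' GapFraction is `gaps / (S - 1)` for `S` aligned sequences. The gap penalty
#' is the gap-concentration term: mean internal gap-block length divided by
#' the total number of internal gaps (leading and trailing gaps are ignored;
#' 0 when there are no internal gaps). The column increment is `C0 / C1`,
#' the longest unaligned sequence length over the aligned width.
#'
#' The printed formulas for the gap-concentration and column-increment terms
#' run opposite to their stated intent under minimization (concentrated gap
#' blocks and added columns *lower* these terms as printed). The literal
#' formulas are the default; `"inverted"` variants are provided for
#' exploration: inverted gap concentration is
#' `total_gaps / (mean_block_length * n_columns)` and inverted column
#' increment is `1 - C0/C1`.
#'
#' @param level_weights numeric length-3 weights for EC levels 1..3.
#' @param gap_concentration_mode `"literal"` (printed formula) or `"inverted"`.
#' @param column_increment_mode `"literal"` or `"inverted"`.
#' @param entropy_norm normalize per-level entropy by `log2` of the number of
#'   sequences (`"rows"`, the maximum achievable column entropy) or of the
#'   number of distinct symbols in the column (`"symbols"`).
#' @return an object of class `ess_scoring` (a list of the options).
#' @export
scoring_control <- function(level_weights = c(15, 10, 5),
                            gap_concentration_mode = c("literal", "inverted"),
                            column_increment_mode = c("literal", "inverted"),
                            entropy_norm = c("rows", "symbols")) {
  stopifnot(is.numeric(level_weights), length(level_weights) == 3,
            all(level_weights > 0))
  structure(
    list(level_weights = as.numeric(level_weights),
         gap_concentration_mode = match.arg(gap_concentration_mode),
         column_increment_mode = match.arg(column_increment_mode),
         entropy_norm = match.arg(entropy_norm)),
    class = "ess_scoring"
  )
}

control_codes <- function(control) {
  list(gc = match(control$gap_concentration_mode, c("literal", "inverted")) - 1L,
       ci = match(control$column_increment_mode, c("literal", "inverted")) - 1L,
       norm = match(control$entropy_norm, c("rows", "symbols")) - 1L)
}

#' Construct an alignment of enzymatic step sequences
#'
#' An alignment is a rectangular grid whose cells are three-level EC codes or
#' gaps (`NA`); each row, read left to right with gaps dropped, is exactly
#' one ESS. Columns consisting only of gaps are removed on construction (they
#' carry no information and are excluded from scoring by definition).
#'
#' @param grid character matrix of EC codes, `NA` for gaps. Row names (or
#'   `ids`) identify the sequences.
#' @param ids optional character vector of sequence ids.
#' @param seq_lengths optional integer vector of the *unaligned* sequence
#'   lengths; defaults to the per-row non-gap counts.
#' @param score optional `ess_score` attached by the aligners.
#' @return an object of class `ess_alignment`.
#' @export
new_alignment <- function(grid, ids = NULL, seq_lengths = NULL, score = NULL) {
  stopifnot(is.matrix(grid), is.character(grid), nrow(grid) >= 1)
  if (is.null(ids)) ids <- rownames(grid)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(grid)))
  keep <- colSums(!is.na(grid)) > 0
  grid <- grid[, keep, drop = FALSE]
  if (ncol(grid) == 0) stop("alignment has no non-gap columns", call. = FALSE)
  rownames(grid) <- ids
  if (is.null(seq_lengths)) seq_lengths <- rowSums(!is.na(grid))
  structure(list(grid = grid, ids = ids,
                 seq_lengths = as.integer(seq_lengths), score = score),
            class = "ess_alignment")
}

#' @export
print.ess_alignment <- function(x, ...) {
  cat("ESS alignment: ", nrow(x$grid), " sequences x ", ncol(x$grid),
      " columns\n", sep = "")
  txt <- x$grid
  txt[is.na(txt)] <- "-"
  for (i in seq_len(nrow(txt))) {
    cat(format(x$ids[i], width = max(nchar(x$ids))), " ",
        paste(txt[i, ], collapse = " "), "\n", sep = "")
  }
  if (!is.null(x$score)) print(x$score)
  invisible(x)
}

#' @export
dim.ess_alignment <- function(x) dim(x$grid)

#' Normalized Shannon entropy of one level of an alignment column
#'
#' Entropy `-sum(p * log2(p))` over the symbol frequencies of a column at one
#' EC level, with the gap counted as one more symbol, normalized so the value
#' lies in `[0, 1]`. Identical symbols give 0; for two sequences, two
#' distinct symbols give 1.
#'
#' @param symbols character vector of level tokens, `NA` for gap; length = the
#'   number of aligned sequences (must be >= 2).
#' @param control an [scoring_control()] object.
#' @return numeric in `[0, 1]`.
#' @export
column_level_entropy <- function(symbols, control = scoring_control()) {
  S <- length(symbols)
  if (S < 2) stop("column entropy needs at least 2 sequences", call. = FALSE)
  sym <- ifelse(is.na(symbols), "\u0001gap", symbols)
  counts <- table(sym)
  if (length(counts) == 1) return(0)
  p <- as.numeric(counts) / S
  H <- -sum(p * log2(p))
  denom <- if (control$entropy_norm == "rows") log2(S) else log2(length(counts))
  min(H / denom, 1)
}

#' Weighted EC entropy of an alignment column
#'
#' Per-level normalized entropies combined with weights (15, 10, 5 by
#' default), so disagreement at the EC class level counts more than at the
#' sub-subclass level. Gap cells contribute the gap symbol at every level.
#'
#' @param column character vector of EC codes (`NA` = gap), length >= 2.
#' @inheritParams column_level_entropy
#' @return numeric in `[0, 1]`.
#' @export
column_ec_entropy <- function(column, control = scoring_control()) {
  lv <- ec_levels(column)
  w <- control$level_weights
  e <- vapply(1:3, function(k) column_level_entropy(lv[, k], control),
              numeric(1))
  sum(w * e) / sum(w)
}

#' Gap fraction of an alignment column
#'
#' Number of gap cells divided by `S - 1`; compensates for the "false
#' homogeneity" a gap-heavy column would otherwise show.
#'
#' @inheritParams column_ec_entropy
#' @return numeric in `[0, 1]`.
#' @export
column_gap_fraction <- function(column) {
  S <- length(column)
  if (S < 2) stop("gap fraction needs at least 2 sequences", call. = FALSE)
  gaps <- sum(is.na(column))
  if (gaps == S) stop("all-gap column must be removed before scoring",
                      call. = FALSE)
  gaps / (S - 1)
}

#' Homogeneity of one alignment column
#'
#' `0.6 * EC-entropy + 0.4 * gap fraction`; 0 for a perfectly conserved
#' gap-free column.
#'
#' @inheritParams column_ec_entropy
#' @return numeric in `[0, 1]`.
#' @export
column_homogeneity <- function(column, control = scoring_control()) {
  0.6 * column_ec_entropy(column, control) + 0.4 * column_gap_fraction(column)
}

#' Homogeneity of a whole alignment
#'
#' Mean of [column_homogeneity()] over all columns (all-gap columns have been
#' removed on construction).
#'
#' @param aln an [new_alignment()] object.
#' @inheritParams column_ec_entropy
#' @return numeric in `[0, 1]`.
#' @export
homogeneity <- function(aln, control = scoring_control()) {
  stopifnot(inherits(aln, "ess_alignment"))
  if (nrow(aln$grid) < 2) stop("homogeneity needs at least 2 rows", call. = FALSE)
  cols <- vapply(seq_len(ncol(aln$grid)),
                 function(j) column_homogeneity(aln$grid[, j], control),
                 numeric(1))
  mean(cols)
}

#' Gap-concentration penalty of an alignment
#'
#' Maximal runs of gaps are identified within each row; runs touching either
#' end of a row (leading/trailing gaps) are ignored. The literal term is the
#' mean internal run length divided by the total number of internal gaps, and
#' 0 when there are no internal gaps.
#'
#' @inheritParams homogeneity
#' @return numeric `>= 0`.
#' @export
gap_concentration <- function(aln, control = scoring_control()) {
  stopifnot(inherits(aln, "ess_alignment"))
  total <- 0L
  nblocks <- 0L
  for (i in seq_len(nrow(aln$grid))) {
    g <- is.na(aln$grid[i, ])
    r <- rle(g)
    if (length(r$values) == 0) next
    idx <- which(r$values)
    # drop runs at either end of the row
    idx <- idx[idx != 1L & idx != length(r$values)]
    total <- total + sum(r$lengths[idx])
    nblocks <- nblocks + length(idx)
  }
  if (total == 0L) return(0)
  mean_block <- total / nblocks
  if (control$gap_concentration_mode == "literal") {
    mean_block / total
  } else {
    total / (mean_block * ncol(aln$grid))
  }
}

#' Column-increment penalty of an alignment
#'
#' Ratio `C0 / C1` of the longest unaligned member sequence to the aligned
#' width; 1 when no columns were added.
#'
#' @inheritParams homogeneity
#' @return numeric in `(0, 1]` for the literal mode.
#' @export
column_increment <- function(aln, control = scoring_control()) {
  stopifnot(inherits(aln, "ess_alignment"))
  ci <- max(aln$seq_lengths) / ncol(aln$grid)
  if (control$column_increment_mode == "literal") ci else 1 - ci
}

#' Objective function of an alignment
#'
#' `0.9 * homogeneity + 0.05 * gap concentration + 0.05 * column increment`,
#' minimized by the aligners; 0.05 is the optimum for identical gap-free
#' sequences (homogeneity 0, no gaps, no added columns).
#'
#' @inheritParams homogeneity
#' @return an `ess_score` object with fields `homogeneity`, `gap_penalty`,
#'   `column_increment` and `objective`.
#' @export
objective <- function(aln, control = scoring_control()) {
  h <- homogeneity(aln, control)
  g <- gap_concentration(aln, control)
  ci <- column_increment(aln, control)
  new_score(h, g, ci)
}

new_score <- function(h, g, ci) {
  structure(list(homogeneity = h, gap_penalty = g, column_increment = ci,
                 objective = 0.9 * h + 0.05 * g + 0.05 * ci),
            class = "ess_score")
}

#' @export
print.ess_score <- function(x, ...) {
  cat(sprintf(
    "objective %.6f  (homogeneity %.6f, gap penalty %.6f, column increment %.6f)\n",
    x$objective, x$homogeneity, x$gap_penalty, x$column_increment))
  invisible(x)
}

# Fast path: score an alignment via the C++ engine (used by the GA; kept in
# lockstep with the R reference implementation by a property test).
score_alignment_cpp <- function(aln, control = scoring_control()) {
  enc <- encode_seqs(list(stats::na.omit(as.vector(aln$grid))))
  grid <- matrix(match(aln$grid, enc$tokens), nrow = nrow(aln$grid))
  grid[is.na(grid)] <- 0L
  cc <- control_codes(control)
  masks <- list(rep(1L, ncol(grid)))
  res <- cpp_score_masks(list(grid), masks, enc$levels,
                         control$level_weights[1], control$level_weights[2],
                         control$level_weights[3], cc$gc, cc$ci, cc$norm)
  new_score(res$homogeneity, res$gap_penalty, res$column_increment)
}

#' Read and write alignments as text
#'
#' One row per line, cells separated by tabs, gaps rendered as `-`; row ids
#' in the first field.
#'
#' @param aln an `ess_alignment`.
#' @param path file path.
#' @return `read_alignment()` returns an `ess_alignment`;
#'   `write_alignment()` returns `path` invisibly.
#' @export
write_alignment <- function(aln, path) {
  txt <- aln$grid
  txt[is.na(txt)] <- "-"
  lines <- vapply(seq_len(nrow(txt)), function(i)
    paste(c(aln$ids[i], txt[i, ]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  cells <- lapply(parts, function(p) p[-1])
  grid <- do.call(rbind, cells)
  grid[grid == "-"] <- NA_character_
  new_alignment(grid, ids = ids)
}

#' Tidiers for alignments
#'
#' `tidy()` returns one row per cell (sequence id, row, column, EC code, gap
#' flag); `glance()` returns the one-row score breakdown (computing it if the
#' alignment does not carry one).
#'
#' @param x an `ess_alignment`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.ess_alignment <- function(x, ...) {
  tibble::tibble(
    ess_id = rep(x$ids, times = ncol(x$grid)),
    row = rep(seq_len(nrow(x$grid)), times = ncol(x$grid)),
    column = rep(seq_len(ncol(x$grid)), each = nrow(x$grid)),
    ec = as.vector(x$grid),
    is_gap = is.na(as.vector(x$grid))
  )
}

#' @rdname tidy.ess_alignment
#' @export
glance.ess_alignment <- function(x, ...) {
  s <- if (!is.null(x$score)) x$score else objective(x)
  tibble::tibble(objective = s$objective, homogeneity = s$homogeneity,
                 gap_penalty = s$gap_penalty,
                 column_increment = s$column_increment,
                 n_sequences = nrow(x$grid), n_columns = ncol(x$grid))
}

#' Plot an alignment as a tile grid
#'
#' Columns along x, sequences along y, tiles colored by EC code and labelled;
#' gaps are blank.
#'
#' @param object an `ess_alignment`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ess_alignment <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$column,
                                  y = factor(.data$ess_id,
                                             levels = rev(object$ids)))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$ec), color = "grey40",
                       show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$is_gap, "-", .data$ec)),
                       size = 3) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(object$grid))) +
    ggplot2::labs(x = "alignment column", y = NULL) +
    ggplot2::theme_minimal()
}
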