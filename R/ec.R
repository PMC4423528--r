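#' Enzyme Commission codes truncated to three levels
#'
#' The comparison method represents every enzyme by the first three levels of
#' its EC number (class, subclass, sub-subclass), written `"a.b.c"`.
#' Unresolved levels (written `-` or `x` in annotation sources) are kept as
#' the sentinel token `"x"`, which compares equal only to itself. A gap is
#' *not* an EC code; gaps are represented as `NA` in alignment grids.
#'
#' `ec_truncate()` shortens full (four-level) EC strings to the canonical
#' three-level form; `ec_levels()` splits codes into their three level
#' tokens; `is_ec()` validates the canonical form.
#'
#' @param x character vector of EC codes (possibly four-level, possibly with
#'   unresolved `-`/`x` levels).
#' @return `ec_truncate()`: character vector of canonical `"a.b.c"` codes.
#'   `ec_levels()`: a character matrix with one row per code and columns
#'   `level1`..`level3`. `is_ec()`: logical vector.
#' @examples
#' ec_truncate("2.7.1.2")
#' ec_levels(c("2.7.1", "5.x.x"))
#' @export
ec_truncate <- function(x) {
  vapply(x, function(code) {
    if (is.na(code)) return(NA_character_)
    parts <- strsplit(code, ".", fixed = TRUE)[[1]]
    parts <- sub("^ec:", "", parts)
    parts[parts %in% c("-", "")] <- "x"
    parts <- c(parts, rep("x", 3))[1:3]
    paste(parts, collapse = ".")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname ec_truncate
#' @export
ec_levels <- function(x) {
  parts <- strsplit(x, ".", fixed = TRUE)
  bad <- lengths(parts) != 3L & !is.na(x)
  if (any(bad)) {
    stop("not canonical three-level EC codes: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  m <- matrix(NA_character_, nrow = length(x), ncol = 3,
              dimnames = list(NULL, c("level1", "level2", "level3")))
  ok <- !is.na(x)
  if (any(ok)) m[ok, ] <- do.call(rbind, parts[ok])
  m
}

#' @rdname ec_truncate
#' @export
is_ec <- function(x) {
  !is.na(x) & grepl("^[0-9x]+\\.[0-9x]+\\.[0-9x]+$", x)
}

# Integer token table for the C++ engine: tokens are the distinct EC codes of
# a sequence set; each of the three levels gets its own id space (>= 1, with 0
# reserved for the gap symbol). The sentinel "x" is just another level value.
ec_token_table <- function(codes) {
  tokens <- unique(codes)
  lv <- ec_levels(tokens)
  ids <- matrix(0L, nrow = length(tokens), ncol = 3)
  for (k in 1:3) {
    vals <- unique(lv[, k])
    ids[, k] <- match(lv[, k], vals)
  }
  list(tokens = tokens, levels = ids)
}

# Encode character step vectors as integer token vectors for the engine.
encode_seqs <- function(seqs) {
  tt <- ec_token_table(unlist(seqs, use.names = FALSE))
  enc <- lapply(seqs, function(s) match(s, tt$tokens))
  list(tokens = tt$tokens, levels = tt$levels, seqs = enc)
}
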