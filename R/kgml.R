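#' Metabolic maps as directed enzyme graphs
#'
#' A metabolic map is a directed graph whose nodes are enzymes (identified by
#' three-level EC codes) and whose edges record a shared compound: an edge
#' `(u, v, c)` exists when `c` is a product of `u` and a substrate of `v`.
#' Reversible reactions are directionless for edge construction: a reversible
#' node offers both its substrates and products on either side. Self-loops
#' are never emitted.
#'
#' `metabolic_map()` builds a map from a node table, deriving the edges; the
#' node table needs columns `node_id`, `ec`, `reversible`, and list-columns
#' `substrates`, `products` and (optionally) `external_substrates` marking
#' compounds that arrive from another map.
#'
#' @param map_id map identifier (e.g. a KEGG map number).
#' @param name free-text map title.
#' @param nodes a data frame of enzyme nodes as described above.
#' @return an object of class `metabolic_map` with fields `map_id`, `name`,
#'   `nodes` (tibble) and `edges` (tibble with `from`, `to`, `compound`).
#' @export
metabolic_map <- function(map_id, name, nodes) {
  nodes <- tibble::as_tibble(nodes)
  req <- c("node_id", "ec", "reversible", "substrates", "products")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols) > 0) {
    stop("node table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!("external_substrates" %in% names(nodes))) {
    nodes$external_substrates <- replicate(nrow(nodes), character(0),
                                           simplify = FALSE)
  }
  if (anyDuplicated(nodes$node_id)) {
    stop("node_id values must be unique within a map", call. = FALSE)
  }
  if (!all(is_ec(nodes$ec))) {
    stop("nodes carry non-canonical EC codes", call. = FALSE)
  }
  structure(list(map_id = as.character(map_id), name = as.character(name),
                 nodes = nodes, edges = build_edges(nodes)),
            class = "metabolic_map")
}

build_edges <- function(nodes) {
  n <- nrow(nodes)
  outc <- lapply(seq_len(n), function(i) {
    if (nodes$reversible[i]) {
      union(nodes$products[[i]], nodes$substrates[[i]])
    } else nodes$products[[i]]
  })
  inc <- lapply(seq_len(n), function(i) {
    if (nodes$reversible[i]) {
      union(nodes$substrates[[i]], nodes$products[[i]])
    } else nodes$substrates[[i]]
  })
  from <- character(0); to <- character(0); compound <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- intersect(outc[[i]], inc[[j]])
      if (length(shared) > 0) {
        from <- c(from, rep(nodes$node_id[i], length(shared)))
        to <- c(to, rep(nodes$node_id[j], length(shared)))
        compound <- c(compound, sort(shared))
      }
    }
  }
  tibble::tibble(from = from, to = to, compound = compound)
}

#' @export
print.metabolic_map <- function(x, ...) {
  cat("Metabolic map ", x$map_id, if (nzchar(x$name)) paste0(" (", x$name, ")"),
      ": ", nrow(x$nodes), " enzyme nodes, ", nrow(x$edges), " edges\n",
      sep = "")
  invisible(x)
}

parse_condition <- function(msg, class) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = NULL))
}

#' Parse a KGML file into a metabolic map
#'
#' Reads a KGML (KEGG Markup Language) XML document and builds the directed
#' enzyme graph. Enzyme- and gene-type entries carrying `ec:` annotations
#' become nodes (one node per EC code when an entry lists several, all
#' sharing the entry's compounds); entries without any EC annotation are
#' dropped with a warning. Substrates and products come from the entry's
#' `reaction` elements, which also carry reversibility; `ECrel` relations are
#' used as a fallback edge source when a file has no reaction data. Compounds
#' linked to an entry through `maplink` relations are recorded as
#' external-origin substrates (used by the initialization-node criteria).
#' EC codes are truncated to three levels; unresolved levels become the
#' sentinel `x`.
#'
#' @param path path to a KGML XML file (or an `xml2` document).
#' @return a [metabolic_map()].
#' @export
parse_kgml <- function(path) {
  doc <- if (inherits(path, "xml_document")) path else {
    tryCatch(xml2::read_xml(path), error = function(e) {
      stop(parse_condition(
        paste0("malformed KGML XML in '", path, "': ", conditionMessage(e)),
        "essalign_parse_error"))
    })
  }
  root <- xml2::xml_root(doc)
  map_id <- xml2::xml_attr(root, "number")
  if (is.na(map_id)) map_id <- xml2::xml_attr(root, "name")
  if (is.na(map_id)) map_id <- "unknown"
  name <- xml2::xml_attr(root, "title")
  if (is.na(name)) name <- ""

  entries <- xml2::xml_find_all(root, ".//entry")
  etype <- xml2::xml_attr(entries, "type")
  enz <- entries[etype %in% c("enzyme", "gene", "ortholog")]

  # reactions keyed by name
  reactions <- xml2::xml_find_all(root, ".//reaction")
  rx <- list()
  for (r in reactions) {
    nm <- xml2::xml_attr(r, "name")
    subs <- xml2::xml_attr(xml2::xml_find_all(r, "./substrate"), "name")
    prods <- xml2::xml_attr(xml2::xml_find_all(r, "./product"), "name")
    rev <- identical(xml2::xml_attr(r, "type"), "reversible")
    for (one in strsplit(nm, " +")[[1]]) {
      rx[[one]] <- list(substrates = subs, products = prods, reversible = rev)
    }
  }

  # maplink relations: entry id -> compounds arriving from another map
  ext <- list()
  relations <- xml2::xml_find_all(root, ".//relation")
  rel_rows <- list()
  for (rel in relations) {
    type <- xml2::xml_attr(rel, "type")
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    cpd <- xml2::xml_attr(
      xml2::xml_find_all(rel, "./subtype[@name='compound']"), "value")
    if (identical(type, "maplink")) {
      for (e in c(e1, e2)) {
        ext[[e]] <- union(ext[[e]], cpd)
      }
    } else if (identical(type, "ECrel")) {
      rel_rows[[length(rel_rows) + 1]] <- c(e1, e2, cpd[1] %||% NA)
    }
  }

  rows <- list()
  dropped <- 0L
  for (e in enz) {
    eid <- xml2::xml_attr(e, "id")
    nm <- xml2::xml_attr(e, "name")
    ecs <- regmatches(nm, gregexpr("ec:[0-9x.-]+", nm))[[1]]
    if (length(ecs) == 0) { dropped <- dropped + 1L; next }
    ecs <- unique(ec_truncate(sub("^ec:", "", ecs)))
    rnames <- strsplit(xml2::xml_attr(e, "reaction") %||% "", " +")[[1]]
    subs <- character(0); prods <- character(0); rev <- FALSE
    for (rn in rnames) {
      if (!is.null(rx[[rn]])) {
        subs <- union(subs, rx[[rn]]$substrates)
        prods <- union(prods, rx[[rn]]$products)
        rev <- rev || rx[[rn]]$reversible
      }
    }
    for (k in seq_along(ecs)) {
      nid <- if (length(ecs) == 1) eid else paste0(eid, "#", k)
      rows[[length(rows) + 1]] <- tibble::tibble(
        node_id = nid, ec = ecs[k], reversible = rev,
        substrates = list(subs), products = list(prods),
        external_substrates = list(ext[[eid]] %||% character(0)))
    }
  }
  if (dropped > 0) {
    warning(dropped, " entries without EC annotation dropped from map ",
            map_id, call. = FALSE)
  }
  if (length(rows) == 0) {
    stop(parse_condition(
      paste0("KGML map '", map_id, "' contains no EC-annotated enzyme entries"),
      "essalign_empty_map"))
  }
  nodes <- dplyr::bind_rows(rows)
  map <- metabolic_map(map_id, name, nodes)

  # fallback: no reaction data at all -> use ECrel relations as edges
  if (nrow(map$edges) == 0 && length(rx) == 0 && length(rel_rows) > 0) {
    id_of <- function(entry_id) nodes$node_id[startsWith(nodes$node_id, entry_id)]
    from <- character(0); to <- character(0); compound <- character(0)
    for (rr in rel_rows) {
      for (u in id_of(rr[1])) for (v in id_of(rr[2])) {
        if (u == v) next
        from <- c(from, u); to <- c(to, v)
        compound <- c(compound, rr[3])
      }
    }
    map$edges <- tibble::tibble(from = from, to = to, compound = compound)
  }
  map
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Neighbors of a node in a metabolic map
#'
#' The set of nodes adjacent to `node_id` (union of in- and out-neighbors;
#' each neighbor counted once).
#'
#' @param map a [metabolic_map()].
#' @param node_id a node identifier present in the map.
#' @return character vector of neighbor node ids.
#' @export
graph_neighbors <- function(map, node_id) {
  stopifnot(inherits(map, "metabolic_map"))
  if (!(node_id %in% map$nodes$node_id)) {
    stop("unknown node_id: ", node_id, call. = FALSE)
  }
  out <- map$edges$to[map$edges$from == node_id]
  inn <- map$edges$from[map$edges$to == node_id]
  sort(unique(c(out, inn)))
}

#' Serialize and re-read the internal map representation
#'
#' `write_map()` stores the node table and derived edge list as two TSV
#' sections in one file; `read_map()` reconstructs the identical
#' `metabolic_map`. `write_edge_list()` writes just the edges
#' (`map_id`, `from`, `to`, `compound`) for inspection.
#'
#' @param map a [metabolic_map()].
#' @param path output file path.
#' @return `read_map()` returns a `metabolic_map`; the writers return `path`
#'   invisibly.
#' @export
write_map <- function(map, path) {
  pack <- function(x) vapply(x, paste, character(1), collapse = ",")
  nodes <- map$nodes
  hdr <- paste0("#map\t", map$map_id, "\t", map$name)
  node_lines <- paste("N", nodes$node_id, nodes$ec,
                      as.integer(nodes$reversible),
                      pack(nodes$substrates), pack(nodes$products),
                      pack(nodes$external_substrates), sep = "\t")
  writeLines(c(hdr, node_lines), path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  unpack <- function(s) if (is.na(s) || s == "") character(0) else
    strsplit(s, ",", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  nodes <- dplyr::bind_rows(lapply(rows, function(p) tibble::tibble(
    node_id = p[2], ec = p[3], reversible = p[4] == "1",
    substrates = list(unpack(p[5])), products = list(unpack(p[6])),
    external_substrates = list(unpack(p[7]))
  )))
  metabolic_map(hdr[2], if (length(hdr) >= 3) hdr[3] else "", nodes)
}

#' @rdname write_map
#' @export
write_edge_list <- function(map, path) {
  df <- dplyr::mutate(map$edges, map_id = map$map_id, .before = 1)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
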