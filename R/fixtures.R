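#' A default three-level EC alphabet for synthetic data
#'
#' A deterministic set of 54 three-level codes spanning the six EC classes,
#' with variation at every level so the graded entropy weights are exercised.
#'
#' @return character vector of EC codes.
#' @export
default_ec_alphabet <- function() {
  g <- expand.grid(l3 = c(1, 3, 9), l2 = c(1, 2, 7), l1 = 1:6)
  paste(g$l1, g$l2, g$l3, sep = ".")
}

#' Specification of a synthetic map set
#'
#' Controls the generator of KGML-like metabolic maps: random branching
#' reaction graphs with a planted contiguous enzyme motif in designated maps,
#' optional reversible reactions and cross-map (external) substrates, and a
#' guaranteed initialization node per map (the root consumes a compound no
#' other enzyme produces).
#'
#' @param n_maps number of maps.
#' @param nodes_per_map integer range `c(min, max)` of enzymes per map.
#' @param ec_alphabet EC codes to draw from.
#' @param motif EC codes planted as a contiguous chain (length >= 2).
#' @param motif_maps indices of the maps receiving the motif.
#' @param reversibility_prob probability a reaction is reversible.
#' @param external_substrate_prob probability a node gets an extra substrate
#'   marked as arriving from another map.
#' @param seed integer seed.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_maps = 3L,
                         nodes_per_map = c(6L, 10L),
                         ec_alphabet = default_ec_alphabet(),
                         motif = c("5.3.1", "2.7.1"),
                         motif_maps = seq_len(n_maps),
                         reversibility_prob = 0.1,
                         external_substrate_prob = 0.2,
                         seed = 1L) {
  stopifnot(length(motif) >= 2, length(ec_alphabet) >= 1,
            reversibility_prob >= 0, reversibility_prob <= 1,
            external_substrate_prob >= 0, external_substrate_prob <= 1)
  if (length(nodes_per_map) == 1) nodes_per_map <- rep(nodes_per_map, 2)
  if (length(motif) > nodes_per_map[1]) {
    stop("motif longer than the smallest map", call. = FALSE)
  }
  structure(list(n_maps = as.integer(n_maps),
                 nodes_per_map = as.integer(nodes_per_map),
                 ec_alphabet = ec_alphabet, motif = motif,
                 motif_maps = as.integer(motif_maps),
                 reversibility_prob = reversibility_prob,
                 external_substrate_prob = external_substrate_prob,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate synthetic metabolic maps
#'
#' Each map is a random branching reaction graph: node `i > 1` consumes the
#' product compound of a random earlier node, so the graph is a directed tree
#' plus whatever extra connectivity reversibility induces. In motif maps the
#' first nodes form a chain carrying the motif EC codes starting at the root,
#' so at least one extracted ESS contains the motif contiguously. The root's
#' input compound is produced by no other enzyme, guaranteeing an
#' initialization node.
#'
#' @param spec a [fixture_spec()].
#' @param dir if non-`NULL`, minimal KGML files (one per map) are written
#'   here.
#' @return list of [metabolic_map()] objects; when `dir` is given the file
#'   paths are attached as attribute `"paths"`.
#' @export
generate_maps <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  maps <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_maps), function(m) generate_one_map(spec, m))
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(maps, function(map) {
      p <- file.path(dir, paste0("map", map$map_id, ".xml"))
      write_kgml(map, p)
      p
    }, character(1))
    attr(maps, "paths") <- paths
  }
  maps
}

generate_one_map <- function(spec, m) {
  sizes <- seq.int(spec$nodes_per_map[1], spec$nodes_per_map[2])
  n <- sizes[sample.int(length(sizes), 1)]
  has_motif <- m %in% spec$motif_maps
  lm <- length(spec$motif)
  ids <- sprintf("n%02d", seq_len(n))
  ecs <- sample(spec$ec_alphabet, n, replace = TRUE)
  if (has_motif) ecs[seq_len(lm)] <- spec$motif
  cpd <- function(i) sprintf("C%s_%02d", m, i)

  parent <- integer(n)
  parent[1] <- 0L
  if (n >= 2) {
    for (i in 2:n) {
      parent[i] <- if (has_motif && i <= lm) i - 1L
                   else sample.int(i - 1L, 1)
    }
  }
  substrates <- vector("list", n)
  products <- vector("list", n)
  substrates[[1]] <- cpd(0) # produced by nobody: root is an initialization node
  for (i in seq_len(n)) products[[i]] <- cpd(i)
  if (n >= 2) for (i in 2:n) substrates[[i]] <- cpd(parent[i])

  reversible <- stats::runif(n) < spec$reversibility_prob
  reversible[1] <- FALSE # keep the root's input unproduced

  external <- vector("list", n)
  ext_draw <- stats::runif(n) < spec$external_substrate_prob
  for (i in seq_len(n)) {
    external[[i]] <- if (ext_draw[i]) sprintf("X%s_%02d", m, i) else character(0)
    substrates[[i]] <- union(substrates[[i]], external[[i]])
  }

  metabolic_map(
    map_id = sprintf("9%03d", m), name = sprintf("synthetic map %d", m),
    nodes = tibble::tibble(node_id = ids, ec = ecs, reversible = reversible,
                           substrates = substrates, products = products,
                           external_substrates = external))
}

#' Serialize a metabolic map as minimal KGML
#'
#' Emits `entry` elements of type `enzyme` (name `ec:a.b.c`), one `reaction`
#' per enzyme with its substrate/product compounds and reversibility, and a
#' `maplink` relation to a map-type entry for every external substrate, so
#' [parse_kgml()] round-trips the map. No graphics elements are written.
#'
#' @param map a [metabolic_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_kgml <- function(map, path) {
  stopifnot(inherits(map, "metabolic_map"))
  doc <- xml2::xml_new_root("pathway",
                            name = paste0("path:syn", map$map_id),
                            number = map$map_id, title = map$name)
  nodes <- map$nodes
  n <- nrow(nodes)
  rxn_name <- function(i) paste0("rn:R", map$map_id, "_", i)
  has_ext <- any(lengths(nodes$external_substrates) > 0)
  ext_entry_id <- as.character(n + 1L)
  for (i in seq_len(n)) {
    xml2::xml_add_child(doc, "entry", id = nodes$node_id[i],
                        name = paste0("ec:", nodes$ec[i]),
                        type = "enzyme", reaction = rxn_name(i))
  }
  if (has_ext) {
    xml2::xml_add_child(doc, "entry", id = ext_entry_id,
                        name = "path:other", type = "map")
  }
  for (i in seq_len(n)) {
    rx <- xml2::xml_add_child(doc, "reaction", id = as.character(i),
                              name = rxn_name(i),
                              type = if (nodes$reversible[i]) "reversible"
                                     else "irreversible")
    for (s in nodes$substrates[[i]]) {
      xml2::xml_add_child(rx, "substrate", id = s, name = s)
    }
    for (p in nodes$products[[i]]) {
      xml2::xml_add_child(rx, "product", id = p, name = p)
    }
  }
  for (i in seq_len(n)) {
    for (x in nodes$external_substrates[[i]]) {
      rel <- xml2::xml_add_child(doc, "relation", entry1 = nodes$node_id[i],
                                 entry2 = ext_entry_id, type = "maplink")
      xml2::xml_add_child(rel, "subtype", name = "compound", value = x)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Generate an ESS collection with planted cluster structure
#'
#' Each cluster has a template sequence; at every position the templates are
#' drawn from distinct first-level EC classes (where the alphabet permits),
#' falling back to distinct codes and then to free sampling when it does not.
#' Class distinctness matters under the graded level weights: a first-level
#' mismatch costs at least half the maximal column cost, so template pairs
#' are guaranteed to score well above the within-cluster level — merely
#' distinct codes can share class and subclass and score arbitrarily low.
#' Members are copies of their template with a `divergence` fraction of
#' positions substituted; half of the substitutions change only the third EC
#' level (exercising the graded level weights), the rest swap in a different
#' alphabet code. Optional outliers are uniform random sequences of *half*
#' the cluster length (at least one step, and never equal to `length`).
#' The length mismatch is what makes them outliers by construction: any
#' pairwise alignment of a length-`l` outlier against a length-`L` member
#' needs at least `L - l` single-gap columns of maximal cost, which bounds
#' the objective at or above 0.5 for `l = L/2` — regardless of the EC
#' content and of how well the aligner optimizes. Same-length random
#' sequences would not do: under the graded level weights their expected
#' pairwise objective sits near the conventional 0.4 membership cutoff, so
#' they are statistically indistinguishable from genuine non-members.
#' Outliers carry no cluster label.
#'
#' @param n_clusters number of planted clusters.
#' @param per_cluster members per cluster.
#' @param length sequence length.
#' @param divergence fraction of positions substituted per member, in
#'   `[0, 1]`.
#' @param seed integer seed.
#' @param alphabet EC codes to draw from.
#' @param n_outliers random unlabelled sequences appended to the collection.
#' @return list with `collection` (an ESS tibble; outliers have map_id
#'   `"outlier"`) and `truth` (tibble `ess_id`, `cluster`; outliers get
#'   `NA`).
#' @export
generate_ess_blocks <- function(n_clusters, per_cluster, length,
                                divergence, seed = 1L,
                                alphabet = default_ec_alphabet(),
                                n_outliers = 0L) {
  stopifnot(divergence >= 0, divergence <= 1, n_clusters >= 1,
            per_cluster >= 1, length >= 1)
  withr::with_seed(seed, {
    n_templates <- n_clusters
    classes <- sub("\\..*$", "", alphabet)
    templates <- lapply(seq_len(length), function(p) {
      if (base::length(unique(classes)) >= n_templates) {
        cls <- sample(unique(classes), n_templates)
        vapply(cls, function(cl) {
          pool <- alphabet[classes == cl]
          pool[sample.int(base::length(pool), 1)]
        }, character(1), USE.NAMES = FALSE)
      } else if (base::length(alphabet) >= n_templates) {
        sample(alphabet, n_templates)
      } else {
        sample(alphabet, n_templates, replace = TRUE)
      }
    })
    templates <- lapply(seq_len(n_templates), function(c)
      vapply(templates, `[[`, character(1), c))
    n_sub <- round(divergence * length)
    rows <- list()
    for (c in seq_len(n_clusters)) {
      for (s in seq_len(per_cluster)) {
        steps <- templates[[c]]
        if (n_sub > 0) {
          pos <- sample.int(length, n_sub)
          for (p in pos) steps[p] <- diverge_code(steps[p], alphabet)
        }
        rows[[base::length(rows) + 1]] <- tibble::tibble(
          ess_id = sprintf("c%02d_m%02d", c, s),
          map_id = sprintf("cluster%02d", c), root_id = NA_character_,
          steps = list(steps), cluster = c)
      }
    }
    outlier_length <- max(1L, as.integer(ceiling(length / 2)))
    if (outlier_length == length) outlier_length <- length + 1L
    for (o in seq_len(n_outliers)) {
      rows[[base::length(rows) + 1]] <- tibble::tibble(
        ess_id = sprintf("out_%02d", o), map_id = "outlier",
        root_id = NA_character_,
        steps = list(sample(alphabet, outlier_length, replace = TRUE)),
        cluster = NA_integer_)
    }
    all <- dplyr::bind_rows(rows)
    list(collection = dplyr::select(all, -"cluster"),
         truth = dplyr::select(all, "ess_id", "cluster"))
  })
}

diverge_code <- function(code, alphabet) {
  if (stats::runif(1) < 0.5) {
    lv <- strsplit(code, ".", fixed = TRUE)[[1]]
    digits <- setdiff(as.character(1:9), lv[3])
    lv[3] <- sample(digits, 1)
    paste(lv, collapse = ".")
  } else {
    sample(setdiff(alphabet, code), 1)
  }
}
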