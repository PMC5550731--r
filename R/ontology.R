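#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr filter mutate select arrange distinct group_by summarise
#'   ungroup left_join inner_join anti_join bind_rows n pull rename
#' @importFrom tibble tibble as_tibble
#' @import Rcpp
#' @useDynLib procpharm, .registration = TRUE
NULL

PROPAGATING_RELATIONS <- c("is_a", "part_of")
ALL_RELATIONS <- c("is_a", "part_of", "regulates")

#' Construct an ontology object
#'
#' An `ontology` is a directed acyclic graph of terms connected by typed
#' edges (`is_a`, `part_of`, `regulates`), the in-memory form of a Gene
#' Ontology subset. Users normally obtain one from [read_obo()]; this
#' constructor is exposed so synthetic ontologies can be built in code.
#'
#' @param terms Tibble with columns `id`, `name`.
#' @param edges Tibble with columns `child`, `parent`, `relation`; `relation`
#'   must be one of `is_a`, `part_of`, `regulates`.
#' @return An object of class `ontology`: a list with elements `terms`
#'   (tibble) and `edges` (tibble).
#' @export
ontology <- function(terms, edges) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  stopifnot(all(c("id", "name") %in% names(terms)))
  if (nrow(edges) == 0L) {
    edges <- tibble(child = character(), parent = character(),
                    relation = character())
  }
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  if (anyDuplicated(terms$id)) {
    abort("duplicate term ids in ontology")
  }
  bad_rel <- setdiff(unique(edges$relation), ALL_RELATIONS)
  if (length(bad_rel)) {
    abort(paste0("unknown edge relation(s): ", paste(bad_rel, collapse = ", ")))
  }
  dangling <- setdiff(unique(edges$parent), terms$id)
  if (length(dangling)) {
    abort(paste0("dangling parent id(s): ",
                 paste(utils::head(dangling, 5), collapse = ", ")))
  }
  cyc <- find_cycle_edge(terms$id, edges)
  if (!is.null(cyc)) {
    abort(paste0("cycle detected in ontology (edge ", cyc[1], " -> ",
                 cyc[2], ")"))
  }
  structure(list(terms = terms, edges = edges), class = "ontology")
}

# Kahn peel on the child -> parent digraph; returns one edge on a cycle, or
# NULL when the graph is acyclic.
find_cycle_edge <- function(ids, edges) {
  if (nrow(edges) == 0L) return(NULL)
  out_deg <- table(factor(edges$child, levels = ids)) # edges point child->parent
  out_deg <- stats::setNames(as.integer(out_deg), ids)
  by_parent <- split(edges$child, edges$parent)
  queue <- ids[out_deg == 0L]
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (c in by_parent[[v]] %||% character()) {
      out_deg[[c]] <- out_deg[[c]] - 1L
      if (out_deg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  left <- names(out_deg)[out_deg > 0L]
  if (!length(left)) return(NULL)
  # walk parents inside the leftover set until a node repeats
  by_child <- split(edges$parent, edges$child)
  v <- left[[1]]; seen <- character()
  repeat {
    seen <- c(seen, v)
    nxt <- intersect(by_child[[v]], left)[1]
    if (nxt %in% seen) return(c(v, nxt))
    v <- nxt
  }
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("<ontology> %d terms, %d edges (%d roots)\n",
              nrow(x$terms), nrow(x$edges), length(ontology_roots(x))))
  invisible(x)
}

#' Root terms of an ontology
#'
#' @param onto An [ontology()].
#' @return Character vector of term ids with no parents.
#' @export
ontology_roots <- function(onto) {
  setdiff(onto$terms$id, unique(onto$edges$child))
}

#' Parse an OBO-format ontology subset
#'
#' Reads `[Term]` stanzas with `id`, `name`, `is_a` and
#' `relationship: part_of|regulates` lines. Terms flagged `is_obsolete: true`
#' are dropped (together with edges touching them); unknown stanza keys and
#' non-Term stanzas are ignored. The resulting graph is validated to be
#' acyclic with no dangling parent references.
#'
#' @param path Path to an OBO file.
#' @return An [ontology()].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  stanza_starts <- grep("^\\[", lines)
  if (!length(stanza_starts)) abort("no stanzas found in OBO file")
  bounds <- c(stanza_starts, length(lines) + 1L)
  terms <- list(); edges <- list()
  for (i in seq_along(stanza_starts)) {
    block <- lines[stanza_starts[i]:(bounds[i + 1L] - 1L)]
    if (block[1] != "[Term]") next
    body <- block[-1]
    get1 <- function(key) {
      hit <- grep(paste0("^", key, ":"), body, value = TRUE)
      if (!length(hit)) return(NA_character_)
      trimws(sub(paste0("^", key, ":"), "", hit[1]))
    }
    id <- get1("id")
    if (is.na(id) || !nzchar(id)) next
    if (identical(get1("is_obsolete"), "true")) next
    name <- get1("name")
    # "is_a: ID ! comment"
    isa <- grep("^is_a:", body, value = TRUE)
    isa_ids <- vapply(isa, function(l) {
      strsplit(trimws(sub("^is_a:", "", l)), "\\s*!")[[1]][1]
    }, character(1), USE.NAMES = FALSE)
    rel <- grep("^relationship:", body, value = TRUE)
    rel_parsed <- lapply(rel, function(l) {
      parts <- strsplit(trimws(sub("^relationship:", "", l)), "\\s+")[[1]]
      if (length(parts) < 2 || !parts[1] %in% c("part_of", "regulates")) {
        return(NULL)
      }
      c(parts[1], parts[2])
    })
    rel_parsed <- Filter(Negate(is.null), rel_parsed)
    terms[[length(terms) + 1L]] <- tibble(
      id = id, name = if (is.na(name)) id else name)
    if (length(isa_ids)) {
      edges[[length(edges) + 1L]] <- tibble(
        child = id, parent = isa_ids, relation = "is_a")
    }
    for (rp in rel_parsed) {
      edges[[length(edges) + 1L]] <- tibble(
        child = id, parent = rp[2], relation = rp[1])
    }
  }
  terms <- bind_rows(terms)
  if (nrow(terms) == 0L) abort("no [Term] stanzas in OBO file")
  edges <- bind_rows(edges)
  if (nrow(edges)) {
    # edges to obsolete/unlisted children were dropped with their stanza;
    # edges whose parent stanza was obsolete are dropped silently too
    edges <- filter(edges, .data$child %in% terms$id)
  }
  ontology(terms, edges)
}

#' Ancestors of a term along selected relation kinds
#'
#' Transitive closure over the requested edge relations, excluding the term
#' itself.
#'
#' @param onto An [ontology()].
#' @param term_id A single term id.
#' @param relations Subset of `c("is_a", "part_of", "regulates")`.
#' @return Character vector of ancestor term ids (unordered).
#' @export
term_ancestors <- function(onto, term_id,
                           relations = PROPAGATING_RELATIONS) {
  if (!term_id %in% onto$terms$id) {
    abort(paste0("unknown term id: ", term_id))
  }
  adj <- parent_adjacency(onto, relations)
  bfs_ancestors(adj, term_id)
}

parent_adjacency <- function(onto, relations) {
  e <- onto$edges[onto$edges$relation %in% relations, , drop = FALSE]
  split(e$parent, e$child)
}

bfs_ancestors <- function(adj, start) {
  seen <- character()
  frontier <- adj[[start]] %||% character()
  while (length(frontier)) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(adj[frontier], use.names = FALSE)
  }
  seen
}

# Ancestor sets for every term in `ids`, memoized over a shared adjacency.
ancestor_sets <- function(onto, ids, relations = PROPAGATING_RELATIONS) {
  adj <- parent_adjacency(onto, relations)
  memo <- new.env(parent = emptyenv())
  get_anc <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    memo[[t]] <- character() # guards against accidental re-entry
    parents <- adj[[t]] %||% character()
    anc <- parents
    for (p in parents) anc <- c(anc, get_anc(p))
    anc <- unique(anc)
    memo[[t]] <- anc
    anc
  }
  stats::setNames(lapply(ids, get_anc), ids)
}

#' Read a gene-to-term annotation table
#'
#' Two-column TSV (`gene_id`, `term_id`); a header row is optional and `#`
#' comment lines are skipped. Rows referencing terms absent from `onto` are
#' dropped with a warning giving the count. The returned table is
#' unpropagated.
#'
#' @param path Path to the TSV.
#' @param onto An [ontology()] used to validate term ids.
#' @return An annotation table: a tibble with columns `gene_id`, `term_id`
#'   and attributes `propagated` (FALSE) and `n_universe` (count of distinct
#'   annotated genes).
#' @export
read_annotations <- function(path, onto) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("gene_id", "term_id"),
                          colClasses = "character", blank.lines.skip = TRUE)
  df <- as_tibble(df)
  # tolerate a header row
  if (nrow(df) && df$gene_id[1] %in% c("gene_id", "gene") &&
      df$term_id[1] %in% c("term_id", "term")) {
    df <- df[-1, , drop = FALSE]
  }
  if (nrow(df) == 0L) abort("no parseable annotation rows")
  known <- df$term_id %in% onto$terms$id
  if (any(!known)) {
    warn(sprintf("dropped %d annotation row(s) referencing unknown terms",
                 sum(!known)))
  }
  df <- distinct(df[known, , drop = FALSE])
  if (nrow(df) == 0L) abort("no annotation rows with known terms")
  new_annotation_table(df, propagated = FALSE)
}

new_annotation_table <- function(df, propagated) {
  df <- as_tibble(df)[, c("gene_id", "term_id")]
  structure(df,
            class = c("annotation_tbl", class(tibble())),
            propagated = propagated,
            n_universe = length(unique(df$gene_id)))
}

#' Is an annotation table propagated?
#' @param anno An annotation table.
#' @return Logical flag.
#' @export
is_propagated <- function(anno) isTRUE(attr(anno, "propagated"))

#' Annotation universe size
#'
#' Number of distinct annotated genes, the default background universe N of
#' the over-representation test.
#'
#' @param anno An annotation table.
#' @return Integer count.
#' @export
annotation_universe <- function(anno) attr(anno, "n_universe")

#' Propagate annotations up the ontology (true-path closure)
#'
#' A gene annotated to a term becomes annotated to every ancestor reachable
#' via `is_a` and `part_of` edges. `regulates` edges stay in the graph for
#' traversal but do not transmit annotations. Idempotent; the universe size
#' is unchanged.
#'
#' @param anno Annotation table (tibble with `gene_id`, `term_id`).
#' @param onto An [ontology()].
#' @return A propagated annotation table.
#' @export
propagate_annotations <- function(anno, onto) {
  used <- unique(anno$term_id)
  anc <- ancestor_sets(onto, used, PROPAGATING_RELATIONS)
  extra <- tidyr::unnest(
    tibble(term_orig = used, term_id = unname(lapply(anc, identity))),
    "term_id")
  joined <- inner_join(anno, extra,
                       by = c("term_id" = "term_orig"),
                       relationship = "many-to-many")
  out <- distinct(bind_rows(
    anno[, c("gene_id", "term_id")],
    tibble(gene_id = joined$gene_id, term_id = joined$term_id.y)))
  out <- arrange(out, .data$gene_id, .data$term_id)
  new_annotation_table(out, propagated = TRUE)
}
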