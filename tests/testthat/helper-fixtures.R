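# In-code fixtures and independent oracles shared across the suite.

# Write an OBO file from stanza descriptions: list of lists with id, name,
# is_a (chr), part_of (chr), regulates (chr), obsolete (lgl).
write_obo_fixture <- function(stanzas, path = tempfile(fileext = ".obo")) {
  lines <- c("format-version: 1.2", "")
  for (s in stanzas) {
    lines <- c(lines, "[Term]", paste0("id: ", s$id),
               paste0("name: ", s$name %||% s$id))
    for (p in s$is_a %||% character()) lines <- c(lines, paste0("is_a: ", p))
    for (p in s$part_of %||% character()) {
      lines <- c(lines, paste0("relationship: part_of ", p))
    }
    for (p in s$regulates %||% character()) {
      lines <- c(lines, paste0("relationship: regulates ", p))
    }
    if (isTRUE(s$obsolete)) lines <- c(lines, "is_obsolete: true")
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# chain a is_a b is_a c, used by several parser tests
chain_obo <- function() {
  write_obo_fixture(list(list(id = "c"), list(id = "b", is_a = "c"),
                         list(id = "a", is_a = "b")))
}

write_anno_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  path
}

make_annotations <- function(gene_id, term_id, onto, propagate = TRUE) {
  path <- write_anno_fixture(data.frame(gene_id, term_id))
  anno <- read_annotations(path, onto)
  if (propagate) propagate_annotations(anno, onto) else anno
}

# random layered DAG as an ontology object (acyclic by construction)
random_dag <- function(n_terms, n_layers = 4) {
  ids <- sprintf("T%03d", seq_len(n_terms))
  layer <- sort(sample(0:(n_layers - 1), n_terms, replace = TRUE))
  layer[1] <- 0
  edges <- list()
  for (i in which(layer > 0)) {
    prev <- ids[layer < layer[i]]
    parents <- sample(prev, min(length(prev), sample(1:2, 1)))
    edges[[length(edges) + 1]] <- tibble::tibble(
      child = ids[i], parent = parents,
      relation = sample(c("is_a", "part_of", "regulates"), length(parents),
                        replace = TRUE, prob = c(0.6, 0.3, 0.1)))
  }
  ontology(tibble::tibble(id = ids, name = ids), dplyr::bind_rows(edges))
}

# --- independent oracles -------------------------------------------------

# brute-force DFS cycle search on a child->parent edge table
oracle_has_cycle <- function(ids, edges) {
  adj <- split(edges$parent, edges$child)
  state <- stats::setNames(rep(0L, length(ids)), ids) # 0 new 1 open 2 done
  found <- FALSE
  visit <- function(v) {
    if (found || state[[v]] == 2L) return()
    if (state[[v]] == 1L) { found <<- TRUE; return() }
    state[[v]] <<- 1L
    for (p in adj[[v]]) visit(p)
    state[[v]] <<- 2L
  }
  for (v in ids) visit(v)
  found
}

# exhaustive ancestor closure by repeated edge expansion
oracle_ancestors <- function(edges, start, relations) {
  e <- edges[edges$relation %in% relations, , drop = FALSE]
  anc <- character(); frontier <- start
  repeat {
    nxt <- setdiff(unique(e$parent[e$child %in% frontier]), anc)
    if (!length(nxt)) return(anc)
    anc <- c(anc, nxt); frontier <- nxt
  }
}

# exhaustive hypergeometric upper tail: sum of C(K,i) C(N-K, n-i) / C(N, n)
oracle_upper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hand implementation of the BH step-up rule
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(m)
  running <- Inf
  for (idx in seq_along(o)) {
    i <- o[idx]
    rank_i <- m - idx + 1
    running <- min(running, p[i] * m / rank_i)
    adj[i] <- min(1, running)
  }
  adj
}

oracle_bonferroni <- function(p) pmin(1, p * length(p))

# triple-loop matrix product
oracle_product <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b), dimnames = list(rownames(a), colnames(b)))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(b))) {
      s <- 0
      for (l in seq_len(ncol(a))) s <- s + a[i, l] * b[l, j]
      out[i, j] <- s
    }
  }
  out
}

# toroidal distance by brute force over all wrap images
oracle_torus_distance <- function(p, q, rows, cols) {
  best <- Inf
  for (dr in c(-rows, 0, rows)) {
    for (dc in c(-cols, 0, cols)) {
      d <- sqrt((p[1] - q[1] + dr)^2 + (p[2] - q[2] + dc)^2)
      best <- min(best, d)
    }
  }
  best
}

quantization_error <- function(model, data) {
  mean(apply(data, 1, function(x) {
    min(sqrt(colSums((t(model$weights) - x)^2)))
  }))
}
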