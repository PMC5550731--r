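#' Information content of a term (bits)
#'
#' The negative base-2 log of the term's annotation frequency `K/N` in the
#' background: rare, specific terms carry many bits, a term annotating the
#' whole universe carries zero.
#'
#' @param anno A propagated annotation table.
#' @param term_id Term id(s).
#' @return Bits, one value per term.
#' @export
information_content <- function(anno, term_id) {
  N <- annotation_universe(anno)
  K <- vapply(term_id, function(t)
    length(unique(anno$gene_id[anno$term_id == t])), integer(1))
  if (any(K == 0L)) {
    abort(paste0("term(s) with no background annotation: ",
                 paste(term_id[K == 0L], collapse = ", ")))
  }
  unname(-log2(K / N))
}

#' Reduce a significant-term DAG to headline "functional areas"
#'
#' Greedy weighted set cover over the significant terms: repeatedly pick the
#' candidate maximizing (number of newly covered significant terms) x
#' (information content), where a headline covers itself and its
#' `is_a`/`part_of` descendants within the significant set. Chosen headlines
#' exclude their own ancestors and descendants from the candidate pool, so
#' the returned set is non-redundant. Selection stops when `min_cover` of
#' the significant terms is covered or `max_headlines` areas were chosen;
#' if the target coverage is unreachable the best-effort set is returned
#' with a warning. Ties in the greedy score are broken by higher
#' information content, then by lexicographic term id.
#'
#' @param sig_dag A `sig_dag` from [significant_subdag()].
#' @param anno Propagated annotation table (background frequencies).
#' @param onto The [ontology()].
#' @param query_genes The trait gene set (for per-area gene counts).
#' @param max_headlines Maximum number of areas (default 10).
#' @param min_cover Target fraction of significant terms to cover
#'   (default 0.95).
#' @return A tibble of class `functional_areas` with columns `term_id`,
#'   `name`, `n_genes`, `n_covered`, `information_bits` and a list-column
#'   `covered_terms`; attributes `residual` (uncovered significant terms)
#'   and `coverage` (achieved fraction).
#' @export
select_functional_areas <- function(sig_dag, anno, onto, query_genes,
                                    max_headlines = 10, min_cover = 0.95) {
  sig <- sig_dag$terms$id
  if (!length(sig)) abort("significant DAG is empty")
  anc <- ancestor_sets(onto, sig, PROPAGATING_RELATIONS)
  # descendants within the significant set, from the ancestor map
  cover_sets <- stats::setNames(lapply(sig, function(h) {
    below <- sig[vapply(sig, function(s) h %in% anc[[s]], logical(1))]
    unique(c(h, below))
  }), sig)
  info <- stats::setNames(information_content(anno, sig), sig)

  pool <- sig
  uncovered <- sig
  chosen <- character()
  while (length(pool) && length(uncovered) &&
         (length(sig) - length(uncovered)) / length(sig) < min_cover &&
         length(chosen) < max_headlines) {
    gain <- vapply(pool, function(h)
      length(intersect(cover_sets[[h]], uncovered)), numeric(1))
    score <- gain * info[pool]
    if (max(gain) == 0) break
    ord <- order(-score, -info[pool], pool)
    best <- pool[ord[1]]
    chosen <- c(chosen, best)
    uncovered <- setdiff(uncovered, cover_sets[[best]])
    related <- c(anc[[best]],
                 sig[vapply(sig, function(s) best %in% anc[[s]], logical(1))])
    pool <- setdiff(pool, c(best, related))
  }
  achieved <- (length(sig) - length(uncovered)) / length(sig)
  if (achieved < min_cover) {
    warn(sprintf(
      "coverage target %.2f unreachable within %d headlines; achieved %.2f",
      min_cover, max_headlines, achieved))
  }
  n_genes <- vapply(chosen, function(h) area_gene_count(anno, h, query_genes),
                    integer(1), USE.NAMES = FALSE)
  res <- tibble(
    term_id = chosen,
    name = sig_dag$terms$name[match(chosen, sig_dag$terms$id)],
    n_genes = n_genes,
    n_covered = vapply(chosen, function(h) length(cover_sets[[h]]),
                       integer(1), USE.NAMES = FALSE),
    information_bits = unname(info[chosen]),
    covered_terms = unname(cover_sets[chosen]))
  structure(res,
            class = c("functional_areas", class(tibble())),
            residual = uncovered, coverage = achieved)
}

#' Count query genes annotated to a headline term
#'
#' @param anno Propagated annotation table.
#' @param term_id Headline term id.
#' @param query_genes Gene set.
#' @return Integer count of distinct query genes annotated to the term.
#' @export
area_gene_count <- function(anno, term_id, query_genes) {
  length(unique(anno$gene_id[anno$term_id == term_id &
                               anno$gene_id %in% query_genes]))
}

#' @export
glance.functional_areas <- function(x, ...) {
  tibble(n_areas = nrow(x),
         coverage = attr(x, "coverage"),
         n_residual = length(attr(x, "residual")))
}

#' Write the functional-area table as TSV
#'
#' @param areas A `functional_areas` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_area_report <- function(areas, path) {
  flat <- areas |>
    mutate(covered_terms = vapply(.data$covered_terms, paste,
                                  character(1), collapse = ","))
  readr::write_tsv(as_tibble(flat), path)
  invisible(path)
}
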