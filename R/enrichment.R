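#' Upper-tail hypergeometric probability for over-representation
#'
#' Probability of observing `k` or more query genes annotated to a term when
#' `n` query genes are drawn without replacement from a universe of `N`
#' genes of which `K` carry the annotation: `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`. This is the one-sided Fisher exact test
#' used by the over-representation analysis.
#'
#' Vectorized over its arguments.
#'
#' @param k Observed overlap count(s).
#' @param n Query-set size(s).
#' @param K Background annotation count(s).
#' @param N Background universe size(s).
#' @return Probability in `(0, 1]`.
#' @export
fisher_upper_tail <- function(k, n, K, N) {
  ok <- k >= 0 & K <= N & n <= N & k <= pmin(n, K) & k >= pmax(0, n + K - N)
  if (any(!ok)) {
    abort("fisher_upper_tail: contingency bounds violated (need 0 <= k <= min(n, K), k >= n + K - N, n <= N, K <= N)")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' @param p Numeric vector of raw p-values in `(0, 1]`.
#' @param correction `"fdr_bh"` (Benjamini-Hochberg step-up) or
#'   `"bonferroni"`.
#' @return Adjusted p-values in the original order, clipped at 1.
#' @export
adjust_p <- function(p, correction = c("fdr_bh", "bonferroni")) {
  correction <- match.arg(correction)
  if (!length(p)) return(numeric())
  if (any(p <= 0 | p > 1 | !is.finite(p))) {
    abort("p-values must lie in (0, 1]")
  }
  method <- switch(correction, fdr_bh = "BH", bonferroni = "bonferroni")
  stats::p.adjust(p, method = method)
}

#' Over-representation analysis of a gene set
#'
#' Tests every term with at least one background annotation for
#' over-representation in `query_genes` relative to the propagated
#' annotation background, with one-sided Fisher tests and multiple-testing
#' correction. Query genes absent from the background are dropped with a
#' warning before testing.
#'
#' @param anno A propagated annotation table (see
#'   [propagate_annotations()]).
#' @param query_genes Character vector of gene ids.
#' @param onto Optional [ontology()] supplying term names (and required by
#'   downstream [significant_subdag()]).
#' @param t_p Significance threshold applied to adjusted p-values
#'   (`p_adj <= t_p`).
#' @param correction Multiple-testing correction, see [adjust_p()].
#' @param universe_size Override for the background universe N; defaults to
#'   the number of distinct annotated genes.
#' @return A tibble of class `ora_result` with columns `term_id`, `name`,
#'   `k`, `n`, `K`, `N`, `p_raw`, `p_adj`, `significant`, sorted by
#'   ascending `p_raw` then `term_id`.
#' @export
run_ora <- function(anno, query_genes, onto = NULL, t_p = 0.05,
                    correction = c("fdr_bh", "bonferroni"),
                    universe_size = NULL) {
  correction <- match.arg(correction)
  if (!(t_p > 0 && t_p <= 1)) abort("t_p must lie in (0, 1]")
  if (!is_propagated(anno)) {
    abort("annotation table must be propagated before ORA; see propagate_annotations()")
  }
  background_genes <- unique(anno$gene_id)
  query <- unique(query_genes)
  missing <- setdiff(query, background_genes)
  if (length(missing)) {
    warn(sprintf("dropped %d query gene(s) absent from the annotation background",
                 length(missing)))
    query <- setdiff(query, missing)
  }
  if (!length(query)) abort("no query gene overlaps the annotation background")
  N <- universe_size %||% annotation_universe(anno)
  n <- length(query)
  per_term <- anno |>
    group_by(.data$term_id) |>
    summarise(K = dplyr::n_distinct(.data$gene_id),
              k = dplyr::n_distinct(.data$gene_id[.data$gene_id %in% query])) |>
    filter(.data$K >= 1L)
  res <- per_term |>
    mutate(n = n, N = N,
           p_raw = fisher_upper_tail(.data$k, n, .data$K, N)) |>
    mutate(p_adj = adjust_p(.data$p_raw, correction),
           significant = .data$p_adj <= t_p) |>
    arrange(.data$p_raw, .data$term_id) |>
    select("term_id", "k", "n", "K", "N", "p_raw", "p_adj", "significant")
  name_tbl <- if (!is.null(onto)) onto$terms else tibble(id = res$term_id,
                                                         name = res$term_id)
  res <- res |>
    left_join(rename(name_tbl, term_id = "id"), by = "term_id") |>
    mutate(name = dplyr::coalesce(.data$name, .data$term_id)) |>
    select("term_id", "name", dplyr::everything())
  structure(res,
            class = c("ora_result", class(tibble())),
            t_p = t_p, correction = correction,
            query_size = n, universe_size = N)
}

#' @export
glance.ora_result <- function(x, ...) {
  tibble(n_terms = nrow(x),
         n_significant = sum(x$significant),
         query_size = attr(x, "query_size"),
         universe_size = attr(x, "universe_size"),
         t_p = attr(x, "t_p"),
         correction = attr(x, "correction"))
}

#' Sub-DAG of significant terms
#'
#' Restricts the ontology to the ORA-significant terms and connects a
#' significant term to its nearest significant ancestors: an edge `s -> t`
#' is present iff `t` is an ancestor of `s` (over all edge kinds) with no
#' other significant term strictly between them (transitive reduction over
#' the significant node set).
#'
#' @param ora An `ora_result` from [run_ora()].
#' @param onto The [ontology()] the ORA was run against.
#' @return A list of class `sig_dag` with `terms` (tibble `id`, `name`,
#'   `p_adj`) and `edges` (tibble `child`, `parent`).
#' @export
significant_subdag <- function(ora, onto) {
  sig <- ora$term_id[ora$significant]
  if (!length(sig)) {
    warn("no significant terms; returning an empty DAG")
    return(structure(list(terms = tibble(id = character(), name = character(),
                                         p_adj = numeric()),
                          edges = tibble(child = character(),
                                         parent = character())),
                     class = "sig_dag"))
  }
  anc <- ancestor_sets(onto, sig, ALL_RELATIONS)
  edges <- purrr::map(sig, function(s) {
    sig_anc <- intersect(anc[[s]], sig)
    if (!length(sig_anc)) return(NULL)
    # drop ancestors reachable through another significant ancestor
    shadowed <- unique(unlist(lapply(sig_anc, function(u)
      intersect(anc[[u]], sig_anc)), use.names = FALSE))
    keep <- setdiff(sig_anc, shadowed)
    tibble(child = s, parent = keep)
  }) |> bind_rows()
  terms <- ora |>
    filter(.data$significant) |>
    select(id = "term_id", "name", "p_adj") |>
    arrange(.data$id)
  structure(list(terms = terms, edges = edges), class = "sig_dag")
}

#' @export
print.sig_dag <- function(x, ...) {
  cat(sprintf("<sig_dag> %d significant terms, %d reduced edges\n",
              nrow(x$terms), nrow(x$edges)))
  invisible(x)
}

#' Write an ORA report as TSV
#'
#' @param ora An `ora_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ora_report <- function(ora, path) {
  readr::write_tsv(as_tibble(ora), path)
  invisible(path)
}
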