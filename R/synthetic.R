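#' Specification for the synthetic benchmark data
#'
#' Describes a synthetic Gene-Ontology-like world with a planted,
#' recoverable repurposing signal: a layered random term DAG, genes with
#' uniform background annotations, a trait gene set and a subset of
#' "planted" drugs whose targets share the trait genes' planted biological
#' processes. Planted drugs draw their targets from a dedicated signal gene
#' pool; signal-pool genes and trait genes are annotated to each planted
#' process with probability `signal_strength`, every other gene with
#' probability `background_noise`. With `signal_strength ==
#' background_noise` the data contain no recoverable structure (negative
#' control).
#'
#' @param n_terms Total ontology terms (default 150).
#' @param dag_depth Number of DAG layers below aggregation into the root
#'   layer (default 5).
#' @param branching Mean layer growth factor (default 3).
#' @param n_genes Gene universe size (default 400).
#' @param annotation_density Background annotations per gene (default 4).
#' @param n_drugs Number of drugs (default 300).
#' @param targets_per_drug Inclusive range of targets per drug (default
#'   `c(18, 22)`): target multiplicities on the scale of the trait gene set,
#'   so that drug process counts and the virtual drug's counts (about
#'   `signal_strength * n_trait_genes` per planted process) live in the
#'   same range and the planted cluster is recoverable in raw count space.
#' @param n_trait_genes Trait gene-set size (default 20, as for the pain
#'   insensitivity gene set).
#' @param n_planted_processes Planted process terms, drawn from the deepest
#'   layer (default 10).
#' @param n_planted_drugs Planted drugs (default 30).
#' @param n_druggable_genes Size of the druggable gene pool all drugs draw
#'   targets from, disjoint from the trait genes (default 150).
#' @param n_signal_genes Size of the signal target pool, a subset of the
#'   druggable pool (default 60). Planted drugs draw targets only from this
#'   subset; background drugs draw from the whole druggable pool and so
#'   overlap it partially, giving the drug-to-virtual-drug distances the
#'   continuum that real target repertoires produce.
#' @param signal_strength Annotation probability tying trait genes and
#'   signal-pool genes to planted processes (default 0.9).
#' @param background_noise Same probability for all other genes (default
#'   0.05).
#' @param seed Master seed; one RNG substream per emitted artifact.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_terms = 150, dag_depth = 5, branching = 3,
                           n_genes = 400, annotation_density = 4,
                           n_drugs = 300, targets_per_drug = c(18, 22),
                           n_trait_genes = 20, n_planted_processes = 10,
                           n_planted_drugs = 30, n_druggable_genes = 150,
                           n_signal_genes = 60, signal_strength = 0.9,
                           background_noise = 0.05, seed = 1L) {
  spec <- list(n_terms = n_terms, dag_depth = dag_depth,
               branching = branching, n_genes = n_genes,
               annotation_density = annotation_density, n_drugs = n_drugs,
               targets_per_drug = targets_per_drug,
               n_trait_genes = n_trait_genes,
               n_planted_processes = n_planted_processes,
               n_planted_drugs = n_planted_drugs,
               n_druggable_genes = n_druggable_genes,
               n_signal_genes = n_signal_genes,
               signal_strength = signal_strength,
               background_noise = background_noise, seed = as.integer(seed))
  if (!(background_noise <= signal_strength && signal_strength <= 1 &&
        background_noise >= 0)) {
    abort("need 0 <= background_noise <= signal_strength <= 1")
  }
  if (n_planted_drugs > n_drugs || n_planted_processes >= n_terms ||
      n_trait_genes + n_druggable_genes > n_genes ||
      n_signal_genes > n_druggable_genes) {
    abort("planted counts exceed totals")
  }
  if (n_terms < dag_depth + 1 || dag_depth < 2) {
    abort("infeasible DAG shape: need n_terms >= dag_depth + 1 and depth >= 2")
  }
  if (floor(branching)^dag_depth + dag_depth < 1) abort("infeasible branching")
  structure(spec, class = "synthetic_spec")
}

# Layer sizes: one root, then geometric growth rescaled to n_terms.
synthetic_layers <- function(spec) {
  raw <- spec$branching^(0:spec$dag_depth)
  sizes <- pmax(1L, round(raw / sum(raw) * spec$n_terms))
  sizes[1] <- 1L
  # adjust the deepest layer so the total is exact
  sizes[length(sizes)] <- sizes[length(sizes)] +
    (spec$n_terms - sum(sizes))
  if (sizes[length(sizes)] < 1L) abort("infeasible branching for n_terms")
  sizes
}

#' Generate synthetic pipeline inputs with a planted signal
#'
#' Writes the four input files the pipeline consumes — `ontology.obo`,
#' `annotations.tsv`, `drug_targets.tsv`, `trait_genes.txt` — plus
#' `ground_truth.json`, all deterministic for a given `spec$seed` (one RNG
#' substream per artifact). The DAG is layered random (each non-root term
#' takes 1-2 parents from the previous layer, first parent always a
#' propagating relation), annotations are assigned to mid/leaf terms and
#' left unpropagated so the pipeline exercises its own closure.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @return A list of class `ground_truth`: `planted_processes`,
#'   `planted_drugs`, `trait_genes`, `files`.
#' @export
generate_synthetic <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  sub <- sample.int(.Machine$integer.max, 4)

  # --- ontology ---------------------------------------------------------
  set.seed(sub[1])
  sizes <- synthetic_layers(spec)
  layer_of <- rep(seq_along(sizes) - 1L, sizes)
  ids <- sprintf("ST:%04d", seq_len(spec$n_terms))
  edges <- list()
  for (t in which(layer_of > 0L)) {
    prev <- ids[layer_of == layer_of[t] - 1L]
    n_par <- sample(1:2, 1)
    parents <- sample(prev, min(n_par, length(prev)))
    rel1 <- sample(c("is_a", "part_of"), 1, prob = c(0.75, 0.25))
    rels <- c(rel1, if (length(parents) > 1)
      sample(c("is_a", "part_of", "regulates"), length(parents) - 1,
             replace = TRUE, prob = c(0.6, 0.25, 0.15)))
    edges[[length(edges) + 1L]] <- tibble(child = ids[t], parent = parents,
                                          relation = rels)
  }
  edges <- bind_rows(edges)
  terms <- tibble(id = ids, name = paste("synthetic process", seq_along(ids)))
  onto <- ontology(terms, edges)
  deepest <- ids[layer_of == max(layer_of)]
  planted_processes <- sort(sample(deepest, spec$n_planted_processes))

  # --- gene pools -------------------------------------------------------
  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  trait_genes <- genes[seq_len(spec$n_trait_genes)]
  druggable <- genes[spec$n_trait_genes + seq_len(spec$n_druggable_genes)]
  signal_pool <- druggable[seq_len(spec$n_signal_genes)]

  # --- annotations ------------------------------------------------------
  set.seed(sub[2])
  non_root <- ids[layer_of > 0L]
  bg <- tibble(
    gene_id = rep(genes, each = spec$annotation_density),
    term_id = sample(non_root, spec$n_genes * spec$annotation_density,
                     replace = TRUE))
  tied <- c(trait_genes, signal_pool)
  planted_rows <- tidyr::expand_grid(gene_id = genes,
                                     term_id = planted_processes)
  p_hit <- ifelse(planted_rows$gene_id %in% tied,
                  spec$signal_strength, spec$background_noise)
  planted_rows <- planted_rows[stats::runif(nrow(planted_rows)) < p_hit, ]
  anno <- distinct(arrange(bind_rows(bg, planted_rows),
                           .data$gene_id, .data$term_id))

  # --- drugs ------------------------------------------------------------
  set.seed(sub[3])
  drug_ids <- sprintf("D%03d", seq_len(spec$n_drugs))
  planted_drugs <- drug_ids[seq_len(spec$n_planted_drugs)]
  tpd <- spec$targets_per_drug
  drugs <- purrr::map(seq_len(spec$n_drugs), function(i) {
    pool <- if (drug_ids[i] %in% planted_drugs) signal_pool else druggable
    k <- if (tpd[1] == tpd[2]) tpd[1] else sample(tpd[1]:tpd[2], 1)
    k <- min(k, length(pool))
    tibble(drug_id = drug_ids[i],
           drug_name = paste("compound", i),
           gene_id = sample(pool, k))
  }) |> bind_rows()

  # --- emit files -------------------------------------------------------
  files <- list(
    ontology = file.path(out_dir, "ontology.obo"),
    annotations = file.path(out_dir, "annotations.tsv"),
    drug_targets = file.path(out_dir, "drug_targets.tsv"),
    trait_genes = file.path(out_dir, "trait_genes.txt"),
    ground_truth = file.path(out_dir, "ground_truth.json"))
  write_obo(onto, files$ontology)
  readr::write_tsv(anno, files$annotations, col_names = FALSE)
  readr::write_tsv(drugs, files$drug_targets, col_names = FALSE)
  writeLines(trait_genes, files$trait_genes)
  truth <- structure(list(planted_processes = planted_processes,
                          planted_drugs = planted_drugs,
                          trait_genes = trait_genes,
                          files = files),
                     class = "ground_truth")
  jsonlite::write_json(truth[c("planted_processes", "planted_drugs",
                               "trait_genes")],
                       files$ground_truth, pretty = TRUE)
  truth
}

#' Serialize an ontology to the OBO subset dialect
#'
#' @param onto An [ontology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  by_child <- split(seq_len(nrow(onto$edges)), onto$edges$child)
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(onto$terms))) {
    id <- onto$terms$id[i]
    stanza <- c("[Term]", paste0("id: ", id),
                paste0("name: ", onto$terms$name[i]))
    for (j in by_child[[id]]) {
      rel <- onto$edges$relation[j]
      parent <- onto$edges$parent[j]
      stanza <- c(stanza, if (rel == "is_a") paste0("is_a: ", parent)
                  else paste0("relationship: ", rel, " ", parent))
    }
    lines <- c(lines, stanza, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Recovery score of a candidate list against the ground truth
#'
#' @param truth A [generate_synthetic()] `ground_truth`.
#' @param candidates Candidate drug labels (e.g.
#'   `cluster_result$members`).
#' @return Tibble with `recall`, `precision`, `n_candidates`, `n_planted`
#'   and an `empty` flag; an empty candidate list scores 0/0 with the flag
#'   set.
#' @export
score_recovery <- function(truth, candidates) {
  planted <- truth$planted_drugs
  hit <- length(intersect(candidates, planted))
  empty <- length(candidates) == 0L
  tibble(recall = if (length(planted)) hit / length(planted) else 0,
         precision = if (empty) 0 else hit / length(candidates),
         n_candidates = length(candidates),
         n_planted = length(planted),
         empty = empty)
}
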