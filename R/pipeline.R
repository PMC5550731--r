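#' Pipeline configuration
#'
#' Bundles the input paths and every tunable of the two analysis arms. The
#' defaults encode the reference settings: trait ORA at `t_p = 0.05` with
#' Benjamini-Hochberg FDR; the gene-process filter ORA at the conservative
#' `t_p = 1e-15` with Bonferroni correction (intended for genome-scale
#' annotation backgrounds — disable with `filter_tp = 1` or relax on small
#' synthetic worlds); depth-2 nested ABC; a 50 x 80 toroid ESOM trained 50
#' epochs.
#'
#' @param ontology_path,annotations_path,drug_targets_path Input files.
#' @param trait_genes Character vector of trait gene ids, or a path to a
#'   one-per-line text file.
#' @param trait_tp,trait_correction Trait-arm ORA settings.
#' @param filter_tp,filter_correction Gene-process filter ORA settings.
#' @param max_headlines,min_cover Functional-abstraction settings.
#' @param abc_depth Nested ABC depth (default 2).
#' @param esom An [esom_config()]; its seed is overridden by `seed`.
#' @param vd_label Virtual-drug label.
#' @param scale_columns Standardize process columns before distances
#'   (default FALSE; raw counts).
#' @param smooth_umatrix Smooth U-heights before watershed (default TRUE).
#' @param seed Master seed fanned out to the ESOM substreams.
#' @param out_dir Optional report directory; when set, stage reports are
#'   written there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ontology_path, annotations_path,
                            drug_targets_path, trait_genes,
                            trait_tp = 0.05, trait_correction = "fdr_bh",
                            filter_tp = 1e-15,
                            filter_correction = "bonferroni",
                            max_headlines = 10, min_cover = 0.95,
                            abc_depth = 2, esom = esom_config(),
                            vd_label = "PainInsensitivity",
                            scale_columns = FALSE, smooth_umatrix = TRUE,
                            seed = 42L, out_dir = NULL) {
  if (length(trait_genes) == 1L && file.exists(trait_genes)) {
    trait_genes <- readLines(trait_genes, warn = FALSE)
    trait_genes <- trait_genes[nzchar(trimws(trait_genes))]
  }
  stopifnot(trait_tp > 0, trait_tp <= 1, filter_tp > 0, filter_tp <= 1,
            abc_depth >= 1)
  structure(list(ontology_path = ontology_path,
                 annotations_path = annotations_path,
                 drug_targets_path = drug_targets_path,
                 trait_genes = trait_genes,
                 trait_tp = trait_tp, trait_correction = trait_correction,
                 filter_tp = filter_tp,
                 filter_correction = filter_correction,
                 max_headlines = max_headlines, min_cover = min_cover,
                 abc_depth = abc_depth, esom = esom, vd_label = vd_label,
                 scale_columns = scale_columns,
                 smooth_umatrix = smooth_umatrix,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `esom`
#' key is a mapping passed to [esom_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$esom)) y$esom <- do.call(esom_config, y$esom)
  do.call(pipeline_config, y)
}

load_pipeline_inputs <- function(cfg) {
  onto <- read_obo(cfg$ontology_path)
  anno <- read_annotations(cfg$annotations_path, onto) |>
    propagate_annotations(onto)
  drugs <- read_drug_targets(cfg$drug_targets_path)
  list(onto = onto, anno = anno, drugs = drugs)
}

#' Run the functional arm: trait-set ORA and functional abstraction
#'
#' Chains ontology loading, annotation propagation, over-representation
#' analysis of the trait gene set, reduction to the significant-term DAG
#' and greedy functional abstraction into headline areas.
#'
#' @param cfg A [pipeline_config()].
#' @param inputs Optional preloaded inputs (internal reuse).
#' @return List with `ora` (tibble), `sig_dag`, `areas`
#'   (`functional_areas`).
#' @export
run_functional_arm <- function(cfg, inputs = NULL) {
  inputs <- inputs %||% load_pipeline_inputs(cfg)
  ora <- run_ora(inputs$anno, cfg$trait_genes, inputs$onto,
                 t_p = cfg$trait_tp, correction = cfg$trait_correction)
  sig_dag <- significant_subdag(ora, inputs$onto)
  areas <- if (nrow(sig_dag$terms)) {
    select_functional_areas(sig_dag, inputs$anno, inputs$onto,
                            cfg$trait_genes,
                            max_headlines = cfg$max_headlines,
                            min_cover = cfg$min_cover)
  } else NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ora_report(ora, file.path(cfg$out_dir, "trait_ora.tsv"))
    if (!is.null(areas)) {
      write_area_report(areas, file.path(cfg$out_dir,
                                         "functional_areas.tsv"))
    }
  }
  list(ora = ora, sig_dag = sig_dag, areas = areas)
}

#' Run the repurposing arm: process-space similarity to the virtual drug
#'
#' Chains the drug-by-gene and ORA-filtered gene-by-process incidence
#' matrices, their product, the virtual drug, restriction to shared
#' processes, Euclidean distances, nested ABC pruning of reciprocal
#' distances, ESOM training on the surviving drugs plus the virtual-drug
#' row, U-matrix computation, and extraction of the watershed basin
#' containing the virtual drug. The candidate list excludes the virtual
#' drug and is always a subset of the ABC survivors.
#'
#' @param cfg A [pipeline_config()].
#' @param inputs Optional preloaded inputs (internal reuse).
#' @return A list of class `run_report`: `distances`, `survivors`,
#'   `candidates`, `cluster`, `umatrix`, `bmus`, `restricted`,
#'   `kept_columns`, `provenance`.
#' @export
run_repurposing_arm <- function(cfg, inputs = NULL) {
  inputs <- inputs %||% load_pipeline_inputs(cfg)
  target_genes <- intersect(unique(inputs$drugs$gene_id),
                            unique(inputs$anno$gene_id))
  if (!length(target_genes)) abort("no drug target is annotated")
  dg <- build_drug_gene(inputs$drugs, target_genes)
  gp <- build_gene_process(inputs$anno, target_genes, inputs$onto,
                           t_p = cfg$filter_tp,
                           correction = cfg$filter_correction)
  dp <- drug_process_product(dg, gp)
  vd <- build_virtual_drug(inputs$anno, cfg$trait_genes, colnames(gp),
                           label = cfg$vd_label)
  restricted <- restrict_shared(dp, vd)
  dist_tbl <- distances_to_virtual(restricted,
                                   scale_columns = cfg$scale_columns)
  recip <- 1 / dist_tbl$distance # Inf for identical vectors; handled below
  sel <- nested_abc(recip, depth = cfg$abc_depth)
  survivors <- dist_tbl$drug_id[sel]
  train_rows <- restricted$matrix[c(survivors, cfg$vd_label), ,
                                  drop = FALSE]
  ecfg <- cfg$esom
  ecfg$seed <- derive_seed(cfg$seed, "esom")
  model <- esom_init(train_rows, ecfg) |> esom_train(train_rows)
  um <- compute_umatrix(model)
  bmus <- map_bmus(model, train_rows)
  cluster <- extract_cluster(um, bmus, seed_label = cfg$vd_label,
                             smooth = cfg$smooth_umatrix)
  report <- structure(list(
    distances = dist_tbl,
    survivors = survivors,
    candidates = cluster$members,
    cluster = cluster,
    umatrix = um,
    bmus = bmus,
    model = model,
    restricted = restricted,
    kept_columns = restricted$kept_columns,
    provenance = list(seed = cfg$seed, esom = unclass(ecfg),
                      trait_tp = cfg$trait_tp,
                      filter_tp = cfg$filter_tp,
                      abc_depth = cfg$abc_depth,
                      n_drugs = nrow(dg), n_target_genes = ncol(dg),
                      n_processes = ncol(gp))),
    class = "run_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(dist_tbl, file.path(cfg$out_dir, "distances.tsv"))
    writeLines(restricted$kept_columns,
               file.path(cfg$out_dir, "kept_processes.txt"))
    writeLines(survivors, file.path(cfg$out_dir, "abc_survivors.txt"))
    readr::write_tsv(tidy(cluster),
                     file.path(cfg$out_dir, "candidates.tsv"))
    jsonlite::write_json(
      c(report$provenance,
        list(candidates = cluster$members,
             n_survivors = length(survivors))),
      file.path(cfg$out_dir, "run_report.json"),
      auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> %d drugs -> %d shared processes -> %d ABC survivors -> %d candidate(s)\n",
    x$provenance$n_drugs, length(x$kept_columns), length(x$survivors),
    length(x$candidates)))
  invisible(x)
}

#' @export
glance.run_report <- function(x, ...) {
  tibble(n_drugs = x$provenance$n_drugs,
         n_target_genes = x$provenance$n_target_genes,
         n_processes = x$provenance$n_processes,
         n_shared_processes = length(x$kept_columns),
         n_survivors = length(x$survivors),
         n_candidates = length(x$candidates))
}

#' Planted-cluster recovery benchmark
#'
#' Generates a synthetic world with [generate_synthetic()], runs the full
#' repurposing arm on it, and scores the candidate list against the
#' planted drugs. The gene-process filter runs with `t_p = 1` (disabled):
#' the conservative genome-scale filter has no pruning role on a
#' 150-term ontology, and a strict filter would abort the
#' signal-free negative control. The ESOM is scaled to a 20 x 30 toroid
#' (radius 10 to 1, rate 0.5 to 0.1, 50 epochs), keeping the
#' neurons-per-drug ratio of the full-size map.
#'
#' @param seed Master seed for generation and training.
#' @param spec A [synthetic_spec()]; its seed is overridden by `seed`.
#' @param esom An [esom_config()] for the scaled map.
#' @param out_dir Where generated files go (a tempdir subdirectory by
#'   default).
#' @return One-row tibble: `seed`, `recall`, `precision`, `n_candidates`,
#'   `n_survivors`, `n_shared_processes`.
#' @export
benchmark_recovery <- function(seed,
                               spec = synthetic_spec(),
                               esom = esom_config(rows = 20, cols = 30,
                                                  radius_start = 10),
                               out_dir = NULL) {
  spec$seed <- as.integer(seed)
  out_dir <- out_dir %||%
    file.path(tempdir(), sprintf("procpharm_bench_%d", seed))
  truth <- generate_synthetic(spec, out_dir)
  cfg <- pipeline_config(
    ontology_path = truth$files$ontology,
    annotations_path = truth$files$annotations,
    drug_targets_path = truth$files$drug_targets,
    trait_genes = truth$files$trait_genes,
    filter_tp = 1, esom = esom, seed = seed)
  rep <- run_repurposing_arm(cfg)
  sc <- score_recovery(truth, rep$candidates)
  tibble(seed = seed, recall = sc$recall, precision = sc$precision,
         n_candidates = sc$n_candidates,
         n_survivors = length(rep$survivors),
         n_shared_processes = length(rep$kept_columns))
}

# Deterministic 31-bit substream seed from a master seed and a stream name.
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L) + 1L
}
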