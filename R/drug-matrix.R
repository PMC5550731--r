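#' Read a drug-target table
#'
#' Three-column TSV (`drug_id`, `drug_name`, `gene_id`); `#` comment lines
#' are skipped and duplicate (drug, target) rows collapse to one.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `drug_id`, `drug_name`, `gene_id`.
#' @export
read_drug_targets <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          col.names = c("drug_id", "drug_name", "gene_id"),
                          colClasses = "character", blank.lines.skip = TRUE)
  df <- as_tibble(df)
  if (nrow(df) && df$drug_id[1] == "drug_id") df <- df[-1, , drop = FALSE]
  if (nrow(df) == 0L) abort("no parseable drug-target rows")
  distinct(df)
}

#' Binary drug-by-gene incidence matrix
#'
#' @param drug_targets Tibble with `drug_id`, `gene_id` (e.g. from
#'   [read_drug_targets()]).
#' @param gene_universe Genes eligible as columns; targets outside it are
#'   discarded, and drugs left without any retained target are dropped with
#'   a warning.
#' @return Integer 0/1 matrix, rows = drug ids, columns = genes (the union
#'   of retained targets), both sorted.
#' @export
build_drug_gene <- function(drug_targets, gene_universe) {
  kept <- filter(drug_targets, .data$gene_id %in% gene_universe)
  dropped <- setdiff(unique(drug_targets$drug_id), unique(kept$drug_id))
  if (length(dropped)) {
    warn(sprintf("dropped %d drug(s) with no target in the gene universe",
                 length(dropped)))
  }
  if (nrow(kept) == 0L) abort("no drug has a target in the gene universe")
  drugs <- sort(unique(kept$drug_id))
  genes <- sort(unique(kept$gene_id))
  m <- matrix(0L, nrow = length(drugs), ncol = length(genes),
              dimnames = list(drugs, genes))
  m[cbind(match(kept$drug_id, drugs), match(kept$gene_id, genes))] <- 1L
  m
}

#' Binary gene-by-process incidence matrix, ORA-filtered
#'
#' Runs an over-representation analysis of the drug-target gene set against
#' the annotation background and keeps the significant terms as process
#' columns; here the ORA acts purely as a filter selecting the process
#' vocabulary, not as a functional interpretation. With `t_p = 1` the
#' filter is disabled and every term with at least one background
#' annotation is kept. Rows are the target genes (all of them — a gene with
#' no significant-term annotation keeps an all-zero row); an entry is 1 iff
#' the gene is (propagated-)annotated to the term.
#'
#' @param anno Propagated annotation table.
#' @param target_genes Drug-target gene ids (matrix rows).
#' @param onto The [ontology()].
#' @param t_p Filter threshold (default the conservative 1e-15).
#' @param correction Correction for the filter ORA (default Bonferroni).
#' @return Integer 0/1 matrix, rows = target genes, columns = retained
#'   process term ids.
#' @export
build_gene_process <- function(anno, target_genes, onto, t_p = 1e-15,
                               correction = "bonferroni") {
  ora <- run_ora(anno, target_genes, onto, t_p = t_p, correction = correction)
  terms <- sort(ora$term_id[ora$significant])
  if (!length(terms)) {
    abort("no process term passes the filter; relax t_p or use a milder correction")
  }
  genes <- sort(unique(target_genes))
  hits <- filter(anno, .data$gene_id %in% genes, .data$term_id %in% terms)
  m <- matrix(0L, nrow = length(genes), ncol = length(terms),
              dimnames = list(genes, terms))
  if (nrow(hits)) {
    m[cbind(match(hits$gene_id, genes), match(hits$term_id, terms))] <- 1L
  }
  m
}

#' Drug-by-process association counts
#'
#' Label-aligned matrix product of the drug-by-gene and gene-by-process
#' incidence matrices: entry (drug, process) counts the drug's targets
#' annotated to the process.
#'
#' @param dg Drug-by-gene 0/1 matrix.
#' @param gp Gene-by-process 0/1 matrix.
#' @return Integer count matrix, rows = drugs, columns = processes.
#' @export
drug_process_product <- function(dg, gp) {
  if (!setequal(colnames(dg), rownames(gp))) {
    abort("gene labels of the two matrices do not match")
  }
  dp <- dg %*% gp[colnames(dg), , drop = FALSE]
  storage.mode(dp) <- "integer"
  dp
}

#' Build the virtual drug
#'
#' A single vector over process terms whose entries count how many trait
#' genes are annotated to each process — the trait gene set rendered as a
#' drug-like row for similarity search.
#'
#' @param anno Propagated annotation table.
#' @param trait_genes The trait gene set.
#' @param process_terms Process vocabulary (column order of the counts).
#' @param label Row label (default `"PainInsensitivity"`).
#' @return Named integer vector of class `virtual_drug` with a `label`
#'   attribute; errors if every count is zero.
#' @export
build_virtual_drug <- function(anno, trait_genes, process_terms,
                               label = "PainInsensitivity") {
  slice <- filter(anno, .data$gene_id %in% trait_genes,
                  .data$term_id %in% process_terms)
  counts <- vapply(process_terms, function(p)
    length(unique(slice$gene_id[slice$term_id == p])), integer(1))
  if (all(counts == 0L)) {
    abort("virtual drug is all-zero: trait functions do not overlap the drug-addressable processes")
  }
  structure(counts, label = label, class = "virtual_drug")
}

#' Restrict the drug-by-process matrix to shared processes
#'
#' Keeps the processes addressed by both sides: columns where the virtual
#' drug count is positive and at least one drug has a positive count. Drug
#' rows left all-zero are dropped, and the virtual drug is appended as the
#' final row, so the result has (retained drugs + 1) rows.
#'
#' @param dp Drug-by-process count matrix.
#' @param vd A [build_virtual_drug()] vector on the same process vocabulary.
#' @return List of class `restricted_dp`: `matrix` (drugs + virtual-drug
#'   row), `kept_columns`, `dropped_drugs`, `vd_label`.
#' @export
restrict_shared <- function(dp, vd) {
  shared <- intersect(colnames(dp), names(vd))
  if (!length(shared)) abort("no shared process vocabulary")
  dp <- dp[, shared, drop = FALSE]
  vdv <- as.integer(vd[shared])
  keep <- vdv > 0L & colSums(dp) > 0
  if (!any(keep)) {
    abort("no process is addressed by both the drugs and the virtual drug")
  }
  kept_columns <- shared[keep]
  m <- dp[, keep, drop = FALSE]
  nonzero <- rowSums(m) > 0
  dropped <- rownames(m)[!nonzero]
  m <- m[nonzero, , drop = FALSE]
  m <- rbind(m, matrix(vdv[keep], nrow = 1,
                       dimnames = list(attr(vd, "label"), kept_columns)))
  structure(list(matrix = m, kept_columns = kept_columns,
                 dropped_drugs = dropped, vd_label = attr(vd, "label")),
            class = "restricted_dp")
}

#' @export
print.restricted_dp <- function(x, ...) {
  cat(sprintf("<restricted_dp> %d drugs + virtual drug x %d shared processes (%d drugs dropped)\n",
              nrow(x$matrix) - 1L, length(x$kept_columns),
              length(x$dropped_drugs)))
  invisible(x)
}

#' Euclidean distances of all drugs to the virtual drug
#'
#' Computed on the raw association counts of the restricted drug-by-process
#' matrix; no column scaling is applied (see `scale_columns`).
#'
#' @param restricted A [restrict_shared()] result.
#' @param scale_columns Standardize columns to unit variance before the
#'   distance computation (off by default; the analysis operates on raw
#'   counts).
#' @return Tibble with columns `drug_id`, `distance`, the virtual drug
#'   excluded, in matrix row order.
#' @export
distances_to_virtual <- function(restricted, scale_columns = FALSE) {
  m <- restricted$matrix
  if (scale_columns) {
    sds <- apply(m, 2, stats::sd)
    sds[sds == 0] <- 1
    m <- sweep(m, 2, sds, "/")
  }
  vd_row <- which(rownames(m) == restricted$vd_label)
  d <- sqrt(colSums((t(m) - m[vd_row, ])^2))
  tibble(drug_id = rownames(m)[-vd_row], distance = unname(d[-vd_row]))
}

#' Write a labeled matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_column Name of the first (row-label) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_column = "id") {
  df <- as_tibble(as.data.frame(m), rownames = id_column)
  readr::write_tsv(df, path)
  invisible(path)
}
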