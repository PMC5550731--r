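test_that("drug-gene matrix is binary with drops and warnings as specified", {
  dt <- tibble::tibble(drug_id = c("d1", "d1", "d2", "d3", "d3"),
                       drug_name = "x",
                       gene_id = c("g1", "g2", "g1", "g9", "g1"))
  m <- build_drug_gene(dt, c("g1", "g2"))
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(colSums(m)[1]), 3) # g1 shared by all three drugs
  expect_equal(m["d1", ], c(g1 = 1L, g2 = 1L))
  # drug whose only target is outside the universe is dropped with warning
  dt2 <- tibble::tibble(drug_id = c("d1", "d2"), drug_name = "x",
                        gene_id = c("g1", "g9"))
  expect_warning(m2 <- build_drug_gene(dt2, "g1"), "dropped 1 drug")
  expect_equal(rownames(m2), "d1")
  expect_error(suppressWarnings(build_drug_gene(dt2, "g7")), "no drug")
})

test_that("duplicate drug-target rows collapse to one", {
  path <- tempfile()
  writeLines(c("# comment", "d1\tDrug One\tg1", "d1\tDrug One\tg1",
               "d2\tDrug Two\tg2"), path)
  dt <- read_drug_targets(path)
  expect_equal(nrow(dt), 2L)
})

gp_fixture <- function() {
  onto <- ontology(
    tibble::tibble(id = c("R", "P", "Q"), name = c("root", "p", "q")),
    tibble::tibble(child = c("P", "Q"), parent = c("R", "R"),
                   relation = "is_a"))
  genes <- sprintf("g%02d", 1:40)
  # targets g01..g10 all annotated to P; background genes to Q
  df <- rbind(data.frame(gene_id = genes[1:10], term_id = "P"),
              data.frame(gene_id = genes[11:40], term_id = "Q"))
  anno <- make_annotations(df$gene_id, df$term_id, onto)
  list(onto = onto, anno = anno, genes = genes)
}

test_that("gene-process matrix keeps ORA-passing columns; the filter can be disabled or over-strict", {
  fx <- gp_fixture()
  targets <- fx$genes[1:10]
  # strongly enriched planted term passes a mild Bonferroni filter
  gp <- build_gene_process(fx$anno, targets, fx$onto, t_p = 0.05,
                           correction = "bonferroni")
  expect_equal(colnames(gp), "P")
  expect_equal(unname(rowSums(gp)), rep(1L, 10))
  # t_p = 1 disables the filter: every term with K >= 1 is kept
  gp_all <- build_gene_process(fx$anno, targets, fx$onto, t_p = 1)
  expect_setequal(colnames(gp_all), c("R", "P", "Q"))
  # rows are conserved even when all-zero
  gp_q <- gp_all[, "Q", drop = FALSE]
  expect_true(any(gp_q == 0))
  expect_equal(nrow(gp_all), 10L)
  # an impossible threshold raises the too-strict error
  expect_error(build_gene_process(fx$anno, targets, fx$onto, t_p = 1e-300),
               "relax")
})

test_that("drug-process product equals the brute-force triple loop", {
  # worked example: drug with 2 targets annotated to the same process
  dg <- matrix(c(1L, 1L), 1, 2, dimnames = list("d1", c("g1", "g2")))
  gp <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("g1", "g2"), "p1"))
  expect_equal(drug_process_product(dg, gp)["d1", "p1"], 2L)
  # identity-like drug-gene matrix returns the gene-process matrix
  dgI <- diag(3L); dimnames(dgI) <- list(paste0("d", 1:3), paste0("g", 1:3))
  gp3 <- matrix(rbinom(6, 1, 0.5), 3, 2,
                dimnames = list(paste0("g", 1:3), paste0("p", 1:2)))
  prodI <- drug_process_product(dgI, gp3)
  expect_equal(unname(prodI), unname(gp3))
  # label alignment beats positional order
  gp3_shuffled <- gp3[c(3, 1, 2), , drop = FALSE]
  expect_equal(drug_process_product(dgI, gp3_shuffled), prodI)
  expect_error(drug_process_product(dgI, gp3[1:2, , drop = FALSE]),
               "labels")
  # random fixtures against the oracle
  set.seed(13)
  for (rep in 1:100) {
    nd <- sample(2:20, 1); ng <- sample(2:20, 1); np <- sample(2:20, 1)
    a <- matrix(rbinom(nd * ng, 1, 0.4), nd, ng,
                dimnames = list(paste0("d", 1:nd), paste0("g", 1:ng)))
    b <- matrix(rbinom(ng * np, 1, 0.4), ng, np,
                dimnames = list(paste0("g", 1:ng), paste0("p", 1:np)))
    expect_equal(unname(drug_process_product(a, b)),
                 unname(oracle_product(a, b)))
  }
})

test_that("virtual drug counts equal column sums of the trait-gene annotation slice", {
  fx <- gp_fixture()
  vd <- build_virtual_drug(fx$anno, fx$genes[1:10], c("P", "Q", "R"))
  expect_equal(unname(vd["P"]), 10L)
  expect_equal(unname(vd["Q"]), 0L)
  expect_equal(unname(vd["R"]), 10L) # via propagation
  expect_equal(attr(vd, "label"), "PainInsensitivity")
  # single gene, saturation bound, and the all-zero error
  vd1 <- build_virtual_drug(fx$anno, fx$genes[1], "P")
  expect_equal(unname(vd1["P"]), 1L)
  expect_error(build_virtual_drug(fx$anno, fx$genes[1:10], "Q"),
               "all-zero")
  # conservation: counts match explicit column sums on a staggered fixture
  onto <- fx$onto
  anno <- make_annotations(c("a", "a", "b", "c"), c("P", "Q", "P", "Q"),
                           onto)
  vd2 <- build_virtual_drug(anno, c("a", "b", "c"), c("P", "Q"))
  expect_equal(as.integer(vd2), c(2L, 2L))
})

test_that("restriction keeps only mutually addressed processes and drops empty drugs", {
  dp <- matrix(c(2L, 0L, 5L,
                 0L, 0L, 1L,
                 0L, 3L, 0L), 3, 3, byrow = TRUE,
               dimnames = list(c("d1", "d2", "d3"), c("p1", "p2", "p3")))
  vd <- structure(c(p1 = 4L, p2 = 0L, p3 = 2L), label = "VD",
                  class = "virtual_drug")
  r <- restrict_shared(dp, vd)
  # p2 dropped (vd = 0) despite drug mass; all else kept
  expect_equal(r$kept_columns, c("p1", "p3"))
  # d3 supported only by the dropped column: removed
  expect_equal(r$dropped_drugs, "d3")
  expect_equal(rownames(r$matrix), c("d1", "d2", "VD"))
  expect_equal(unname(r$matrix["VD", ]), c(4L, 2L))
  # nothing dropped when vd and drugs cover all columns
  vd_all <- structure(c(p1 = 1L, p2 = 1L, p3 = 1L), label = "VD",
                      class = "virtual_drug")
  r2 <- restrict_shared(dp, vd_all)
  expect_equal(nrow(r2$matrix), 4L)
  # idempotence: restricting the restricted matrix changes nothing
  r3 <- restrict_shared(r$matrix[1:2, , drop = FALSE], vd)
  expect_equal(r3$matrix[1:2, ], r$matrix[1:2, ])
  dpz <- dp
  dpz[, "p2"] <- 0L
  expect_error(restrict_shared(dpz, structure(c(p2 = 5L), label = "VD",
                                              class = "virtual_drug")),
               "no process")
  expect_error(restrict_shared(dp, structure(c(p9 = 5L), label = "VD",
                                             class = "virtual_drug")),
               "no shared process")
})

test_that("distances to the virtual drug follow raw-count Euclidean geometry", {
  m <- matrix(c(0, 4,
                3, 0,
                3, 0), 3, 2, byrow = TRUE,
              dimnames = list(c("d1", "d2", "VD"), c("p1", "p2")))
  r <- structure(list(matrix = m, kept_columns = c("p1", "p2"),
                      dropped_drugs = character(), vd_label = "VD"),
                 class = "restricted_dp")
  d <- distances_to_virtual(r)
  expect_equal(d$drug_id, c("d1", "d2"))
  expect_equal(d$distance, c(5, 0)) # 3-4-5 triangle; identical vector -> 0
  # brute-force check and column-permutation invariance on a random fixture
  set.seed(14)
  mm <- matrix(rpois(44, 3), 11, 4,
               dimnames = list(c(paste0("d", 1:10), "VD"), paste0("p", 1:4)))
  rr <- structure(list(matrix = mm, kept_columns = colnames(mm),
                       dropped_drugs = character(), vd_label = "VD"),
                  class = "restricted_dp")
  dd <- distances_to_virtual(rr)
  for (i in 1:10) {
    expect_equal(dd$distance[i], sqrt(sum((mm[i, ] - mm[11, ])^2)))
  }
  rr_perm <- rr
  rr_perm$matrix <- mm[, c(3, 1, 4, 2)]
  expect_equal(distances_to_virtual(rr_perm)$distance, dd$distance)
})
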