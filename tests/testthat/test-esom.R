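small_cfg <- function(...) {
  esom_config(rows = 6, cols = 8, epochs = 10, radius_start = 3,
              radius_end = 1, seed = 5, ...)
}

test_that("weights initialize inside the per-column data range, reproducibly", {
  cfg <- esom_config(rows = 20, cols = 50, seed = 11)
  data <- cbind(a = runif(30, 2, 6), b = rep(0, 30))
  m1 <- esom_init(data, cfg)
  m2 <- esom_init(data, cfg)
  expect_identical(m1$weights, m2$weights) # fixed seed, bitwise
  # constant column pins the component
  expect_true(all(m1$weights[, "b"] == 0))
  # 1000 draws: bounded by the range, mean near the midpoint
  w <- m1$weights[, "a"]
  expect_gte(min(w), min(data[, "a"]))
  expect_lte(max(w), max(data[, "a"]))
  rng <- range(data[, "a"])
  se <- diff(rng) / sqrt(12) / sqrt(length(w))
  expect_lt(abs(mean(w) - mean(rng)), 3 * se)
})

test_that("grid distance wraps on the torus and matches the brute-force oracle", {
  cfg <- esom_config(rows = 50, cols = 80)
  expect_equal(grid_distance(c(3, 3), c(3, 3), cfg), 0)
  expect_equal(grid_distance(c(1, 4), c(50, 4), cfg), 1) # torus edge
  expect_equal(grid_distance(c(1, 1), c(3, 4), cfg), sqrt(13))
  expect_error(grid_distance(c(0, 1), c(1, 1), cfg), "outside")
  set.seed(31)
  for (rep in 1:200) {
    p <- c(sample(50, 1), sample(80, 1))
    q <- c(sample(50, 1), sample(80, 1))
    expect_equal(grid_distance(p, q, cfg),
                 oracle_torus_distance(p, q, 50, 80))
  }
})

test_that("toroidal grid distance is a metric", {
  cfg <- esom_config(rows = 7, cols = 9)
  set.seed(32)
  for (rep in 1:1000) {
    pts <- replicate(3, c(sample(7, 1), sample(9, 1)), simplify = FALSE)
    dab <- grid_distance(pts[[1]], pts[[2]], cfg)
    dba <- grid_distance(pts[[2]], pts[[1]], cfg)
    dac <- grid_distance(pts[[1]], pts[[3]], cfg)
    dcb <- grid_distance(pts[[3]], pts[[2]], cfg)
    expect_identical(dab, dba)
    expect_equal(dab == 0, identical(pts[[1]], pts[[2]]))
    expect_lte(dab, dac + dcb + 1e-12)
  }
})

test_that("best matching unit equals the exhaustive-scan oracle with lexicographic ties", {
  set.seed(33)
  for (rep in 1:50) {
    cfg <- esom_config(rows = sample(3:8, 1), cols = sample(3:8, 1),
                       seed = rep)
    d <- sample(2:5, 1)
    data <- matrix(rnorm(20 * d), 20, d)
    model <- esom_init(data, cfg)
    x <- rnorm(d)
    got <- best_matching_unit(model, x)
    d2 <- colSums((t(model$weights) - x)^2)
    u <- which(d2 == min(d2))[1]
    expect_equal(unname(got),
                 c((u - 1) %/% cfg$cols + 1, (u - 1) %% cfg$cols + 1))
  }
  # all-identical weights resolve to neuron (1, 1)
  cfg <- small_cfg()
  model <- esom_init(matrix(0, 5, 3), cfg)
  expect_equal(unname(best_matching_unit(model, c(0, 0, 0))), c(1, 1))
  expect_error(best_matching_unit(model, c(0, 0)), "dimension")
})

test_that("training is bitwise-reproducible and a zero learning rate is a no-op", {
  cfg <- small_cfg()
  set.seed(100)
  data <- matrix(rnorm(24), 8, 3)
  m <- esom_init(data, cfg)
  t1 <- esom_train(m, data)
  t2 <- esom_train(m, data)
  expect_identical(t1$weights, t2$weights)
  expect_true(t1$trained)
  cfg0 <- esom_config(rows = 6, cols = 8, epochs = 5, radius_start = 3,
                      radius_end = 1, rate_start = 0, rate_end = 0,
                      seed = 5)
  m0 <- esom_init(data, cfg0)
  t0 <- esom_train(m0, data)
  expect_identical(t0$weights, m0$weights)
})

test_that("the BMU weight contracts onto a lone data point", {
  cfg <- esom_config(rows = 5, cols = 6, epochs = 50, radius_start = 2,
                     radius_end = 0, rate_start = 0.5, rate_end = 0.3,
                     seed = 9)
  x <- c(2, -1, 0.5)
  data <- matrix(x, 1, 3, byrow = TRUE)
  trained <- esom_train(esom_init(data, cfg), data)
  bmu <- best_matching_unit(trained, x)
  w <- trained$weights[(bmu[1] - 1) * cfg$cols + bmu[2], ]
  expect_lt(sqrt(sum((w - x)^2)), 1e-6)
})

test_that("training two separated blobs reduces quantization error and keeps blobs contiguous", {
  for (s in 1:5) {
    set.seed(s)
    blob1 <- matrix(rnorm(40, mean = 0, sd = 0.3), 20, 2)
    blob2 <- matrix(rnorm(40, mean = 8, sd = 0.3), 20, 2)
    data <- rbind(blob1, blob2)
    rownames(data) <- c(paste0("a", 1:20), paste0("b", 1:20))
    cfg <- esom_config(rows = 10, cols = 14, epochs = 30, radius_start = 5,
                       radius_end = 1, seed = s)
    init <- esom_init(data, cfg)
    trained <- esom_train(init, data)
    expect_lte(quantization_error(trained, data),
               quantization_error(init, data))
    bm <- map_bmus(trained, data)
    # each blob's BMUs occupy its own grid region: mean within-blob BMU
    # distance is smaller than the mean between-blob BMU distance
    coords <- as.matrix(bm[, c("row", "col")])
    pair_mean <- function(ii, jj) {
      mean(unlist(lapply(ii, function(i) vapply(jj, function(j)
        grid_distance(coords[i, ], coords[j, ], cfg), numeric(1)))))
    }
    within <- (pair_mean(1:20, 1:20) + pair_mean(21:40, 21:40)) / 2
    between <- pair_mean(1:20, 21:40)
    expect_lt(within, between)
  }
})

test_that("the U-matrix matches hand-computed heights and is translation-invariant", {
  # 2x2 planar grid with one outlier weight: hand-computed means
  cfg <- esom_config(rows = 2, cols = 2, toroid = FALSE, seed = 2)
  model <- esom_init(matrix(rnorm(8), 4, 2), cfg)
  model$weights <- matrix(c(0, 0,
                            0, 0,
                            0, 0,
                            3, 4), 4, 2, byrow = TRUE)
  model$trained <- TRUE
  um <- compute_umatrix(model)
  # neurons 1..3 have neighbors {0-weights and the outlier at distance 5}
  expect_equal(unclass(um), matrix(c(5 / 3, 5 / 3, 5 / 3, 5), 2, 2,
                                   byrow = TRUE),
               ignore_attr = TRUE)
  shifted <- model
  shifted$weights <- model$weights + 100
  expect_equal(unclass(compute_umatrix(shifted)), unclass(um))
  # constant weights give an all-zero U-matrix
  flat <- model
  flat$weights[] <- 7
  expect_true(all(compute_umatrix(flat) == 0))
})

test_that("toroid and planar U-matrices differ only through edge neighborhoods", {
  set.seed(35)
  data <- matrix(rnorm(30), 10, 3)
  cfg_t <- esom_config(rows = 5, cols = 6, epochs = 5, radius_start = 2,
                       radius_end = 1, seed = 3, toroid = TRUE)
  m <- esom_train(esom_init(data, cfg_t), data)
  um_t <- compute_umatrix(m)
  m_p <- m
  m_p$config$toroid <- FALSE
  um_p <- compute_umatrix(m_p)
  # interior neurons agree; borders use fewer neighbors on the plane
  expect_equal(um_t[2:4, 2:5], um_p[2:4, 2:5])
  expect_false(isTRUE(all.equal(um_t[1, 1], um_p[1, 1])))
})
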