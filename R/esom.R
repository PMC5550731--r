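#' Configuration of an emergent self-organizing map
#'
#' Defaults encode a 50 x 80 toroid lattice (4,000 neurons) trained online
#' for 50 epochs, with a Gaussian neighborhood whose radius decays linearly
#' from 24 to 1 grid units and a learning rate decaying linearly from 0.5
#' to 0.1 — conventional settings for an emergent (large) SOM of this size.
#' For smaller grids scale `radius_start` with the short axis (about half
#' of it).
#'
#' @param rows,cols Grid dimensions (default 50 x 80).
#' @param epochs Training epochs (default 50).
#' @param toroid Wrap opposite edges (default TRUE).
#' @param radius_start,radius_end Neighborhood radius schedule (linear
#'   decay per epoch).
#' @param rate_start,rate_end Learning-rate schedule (linear decay per
#'   epoch).
#' @param seed RNG seed for weight initialization and sample shuffling.
#' @return A list of class `esom_config`.
#' @export
esom_config <- function(rows = 50, cols = 80, epochs = 50, toroid = TRUE,
                        radius_start = 24, radius_end = 1,
                        rate_start = 0.5, rate_end = 0.1, seed = 42L) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              epochs = as.integer(epochs), toroid = isTRUE(toroid),
              radius_start = radius_start, radius_end = radius_end,
              rate_start = rate_start, rate_end = rate_end,
              seed = as.integer(seed))
  stopifnot(cfg$rows * cfg$cols >= 4L, cfg$epochs >= 1L,
            cfg$radius_start >= cfg$radius_end, cfg$radius_end >= 0,
            cfg$rate_start >= 0, cfg$rate_end >= 0)
  structure(cfg, class = "esom_config")
}

# Neurons are indexed row-major: unit = (row - 1) * cols + col, rows and
# cols 1-based, so increasing unit index is lexicographic (row, col) order.
grid_coords <- function(cfg) {
  tibble(unit = seq_len(cfg$rows * cfg$cols),
         row = rep(seq_len(cfg$rows), each = cfg$cols),
         col = rep(seq_len(cfg$cols), times = cfg$rows))
}

#' Distance between two grid positions
#'
#' Euclidean distance between neuron coordinates; on a toroid grid each
#' axis difference wraps (`delta = min(|delta|, size - |delta|)`).
#'
#' @param p,q Length-2 integer vectors `c(row, col)`, 1-based.
#' @param cfg An [esom_config()].
#' @return Non-negative distance in grid units.
#' @export
grid_distance <- function(p, q, cfg) {
  for (pt in list(p, q)) {
    if (pt[1] < 1 || pt[1] > cfg$rows || pt[2] < 1 || pt[2] > cfg$cols) {
      abort("coordinate outside the grid")
    }
  }
  dr <- abs(p[1] - q[1]); dc <- abs(p[2] - q[2])
  if (cfg$toroid) {
    dr <- min(dr, cfg$rows - dr)
    dc <- min(dc, cfg$cols - dc)
  }
  sqrt(dr^2 + dc^2)
}

#' Initialize ESOM weights from the data ranges
#'
#' Each weight component j is drawn uniformly from `[min_j, max_j]` of data
#' column j (a constant column pins that component to the constant), using
#' the seeded RNG so initialization is reproducible.
#'
#' @param data Numeric matrix, rows = data points (with rownames as
#'   labels), columns = features.
#' @param cfg An [esom_config()].
#' @return A list of class `esom_model`: `weights` (units x features),
#'   `config`, `trained` flag.
#' @export
esom_init <- function(data, cfg = esom_config()) {
  data <- as.matrix(data)
  if (!nrow(data) || !all(is.finite(data))) {
    abort("data must be non-empty and finite")
  }
  n_units <- cfg$rows * cfg$cols
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  w <- vapply(seq_len(ncol(data)), function(j) {
    rng <- range(data[, j])
    stats::runif(n_units, rng[1], rng[2])
  }, numeric(n_units))
  w <- matrix(w, nrow = n_units, ncol = ncol(data),
              dimnames = list(NULL, colnames(data)))
  shuffle_seed <- sample.int(.Machine$integer.max, 1)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(list(weights = w, config = cfg, trained = FALSE,
                 shuffle_seed = shuffle_seed),
            class = "esom_model")
}

#' Train an ESOM online
#'
#' Per epoch, all data rows are presented in a freshly shuffled order drawn
#' from the seeded stream; for each row the best-matching unit is found and
#' every neuron is moved toward the row by
#' `alpha(t) * exp(-g^2 / (2 r(t)^2))` of the difference, with `g` the
#' (toroidal) grid distance to the BMU. Radius and rate decay linearly per
#' epoch from their start to end values. Deterministic for a fixed seed.
#'
#' @param model An [esom_init()] model.
#' @param data The matrix the model was initialized on.
#' @param cfg Configuration; defaults to the model's.
#' @return The trained `esom_model`.
#' @export
esom_train <- function(model, data, cfg = model$config) {
  data <- as.matrix(data)
  if (ncol(data) != ncol(model$weights)) abort("feature dimension mismatch")
  if (!all(is.finite(data))) abort("data must be finite")
  E <- cfg$epochs
  sched <- function(a, b) if (E == 1L) a else a + (b - a) * (seq_len(E) - 1) / (E - 1)
  radii <- sched(cfg$radius_start, cfg$radius_end)
  rates <- sched(cfg$rate_start, cfg$rate_end)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(model$shuffle_seed)
  orders <- vapply(seq_len(E), function(e) sample.int(nrow(data)),
                   integer(nrow(data)))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  w <- esom_train_cpp(model$weights, data, matrix(orders, ncol = E),
                      cfg$rows, cfg$cols, cfg$toroid, radii, rates)
  model$weights <- w
  model$trained <- TRUE
  model$config <- cfg
  model
}

#' @export
print.esom_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<esom_model> %d x %d %s grid, d = %d, %strained\n",
              cfg$rows, cfg$cols, if (cfg$toroid) "toroid" else "planar",
              ncol(x$weights), if (x$trained) "" else "un"))
  invisible(x)
}

#' @export
glance.esom_model <- function(x, ...) {
  cfg <- x$config
  tibble(rows = cfg$rows, cols = cfg$cols, toroid = cfg$toroid,
         epochs = cfg$epochs, d = ncol(x$weights), trained = x$trained)
}

#' Best-matching unit of a data point
#'
#' The neuron whose weight vector minimizes Euclidean distance to `x`;
#' ties resolve to the smallest (row, col) coordinate.
#'
#' @param model An `esom_model`.
#' @param x Numeric vector of the model's feature dimension.
#' @return Length-2 integer vector `c(row, col)`.
#' @export
best_matching_unit <- function(model, x) {
  if (length(x) != ncol(model$weights)) abort("dimension mismatch")
  d2 <- colSums((t(model$weights) - x)^2)
  u <- which.min(d2) # first minimum = smallest unit index = lexicographic
  unit_to_coord(u, model$config)
}

unit_to_coord <- function(unit, cfg) {
  c(row = (unit - 1L) %/% cfg$cols + 1L, col = (unit - 1L) %% cfg$cols + 1L)
}

coord_to_unit <- function(row, col, cfg) (row - 1L) * cfg$cols + col

#' Map data points to their best-matching units
#'
#' @param model A trained `esom_model`.
#' @param data Matrix with rownames used as labels.
#' @return Tibble of class `bmu_map`: `label`, `unit`, `row`, `col`. A
#'   single neuron may be the BMU of several points.
#' @export
map_bmus <- function(model, data) {
  data <- as.matrix(data)
  labels <- rownames(data) %||% as.character(seq_len(nrow(data)))
  coords <- t(apply(data, 1, function(x) best_matching_unit(model, x)))
  structure(tibble(label = labels,
                   unit = coord_to_unit(coords[, 1], coords[, 2],
                                        model$config),
                   row = as.integer(coords[, 1]),
                   col = as.integer(coords[, 2])),
            class = c("bmu_map", class(tibble())))
}

# Row/col index matrices of the 8-neighborhood (offsets excluding self).
neighbor_shifts <- function() {
  expand.grid(dr = -1:1, dc = -1:1) |>
    filter(!(.data$dr == 0 & .data$dc == 0))
}

# For a rows x cols field, returns for each of the 8 shifts the shifted
# linear index (NA outside a planar grid).
shifted_index <- function(rows, cols, toroid) {
  g <- grid_coords(list(rows = rows, cols = cols))
  shifts <- neighbor_shifts()
  lapply(seq_len(nrow(shifts)), function(s) {
    r <- g$row + shifts$dr[s]
    c <- g$col + shifts$dc[s]
    if (toroid) {
      r <- ((r - 1L) %% rows) + 1L
      c <- ((c - 1L) %% cols) + 1L
    }
    ok <- r >= 1L & r <= rows & c >= 1L & c <= cols
    idx <- rep(NA_integer_, nrow(g))
    idx[ok] <- (r[ok] - 1L) * cols + c[ok]
    idx
  })
}

#' U-matrix of a trained ESOM
#'
#' Per-neuron U-height: the mean Euclidean distance between the neuron's
#' weight vector and the weights of its 8 grid neighbors (toroid wrap per
#' the configuration; on a planar grid boundary neurons average over their
#' existing neighbors). Valleys of the resulting height field are clusters,
#' ridges are cluster borders.
#'
#' @param model A trained `esom_model`.
#' @return A rows x cols numeric matrix of class `esom_umatrix` with the
#'   configuration attached.
#' @export
compute_umatrix <- function(model) {
  cfg <- model$config
  w <- model$weights
  idx <- shifted_index(cfg$rows, cfg$cols, cfg$toroid)
  acc <- matrix(0, nrow(w), 1)
  cnt <- numeric(nrow(w))
  for (ix in idx) {
    ok <- !is.na(ix)
    dd <- sqrt(rowSums((w[which(ok), , drop = FALSE] -
                          w[ix[ok], , drop = FALSE])^2))
    acc[which(ok)] <- acc[which(ok)] + dd
    cnt[ok] <- cnt[ok] + 1
  }
  heights <- matrix(acc / cnt, nrow = cfg$rows, ncol = cfg$cols,
                    byrow = TRUE)
  structure(heights, class = "esom_umatrix", config = cfg)
}

#' Smooth a U-matrix with a 3 x 3 mean filter
#'
#' One pass of a 3 x 3 box mean (including the center, toroid-aware)
#' suppresses single-neuron micro-basins before watershed clustering.
#'
#' @param um An `esom_umatrix`.
#' @return Smoothed `esom_umatrix`.
#' @export
smooth_umatrix <- function(um) {
  cfg <- attr(um, "config")
  h <- as.vector(t(unclass(um))) # row-major
  idx <- shifted_index(cfg$rows, cfg$cols, cfg$toroid)
  acc <- h
  cnt <- rep(1, length(h))
  for (ix in idx) {
    ok <- !is.na(ix)
    acc[ok] <- acc[ok] + h[ix[ok]]
    cnt[ok] <- cnt[ok] + 1
  }
  structure(matrix(acc / cnt, nrow = cfg$rows, ncol = cfg$cols, byrow = TRUE),
            class = "esom_umatrix", config = cfg)
}

#' @export
tidy.esom_umatrix <- function(x, ...) {
  cfg <- attr(x, "config")
  g <- grid_coords(cfg)
  mutate(g, height = as.vector(t(unclass(x))))
}

#' @rdname compute_umatrix
#' @param object An `esom_umatrix`.
#' @param bmus Optional [map_bmus()] tibble overlaid as points.
#' @param ... Unused.
#' @export
autoplot.esom_umatrix <- function(object, bmus = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = c("#1f6f43", "#8a6b3b", "#ffffff")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "column", y = "row", fill = "U-height",
                  title = "U-matrix") +
    ggplot2::theme_minimal()
  if (!is.null(bmus)) {
    p <- p + ggplot2::geom_point(
      data = bmus, ggplot2::aes(x = .data$col, y = .data$row),
      inherit.aes = FALSE, colour = "red", size = 1)
  }
  p
}
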