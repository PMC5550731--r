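#' Watershed basins of a height field
#'
#' Steepest-descent watershed over the 8-neighborhood (toroid wrap per the
#' configuration): each cell follows its lowest neighbor downhill until a
#' local minimum, and cells draining into the same minimum form one basin.
#' On plateaus the descent follows the neighbor with the lowest
#' (height, row, col) in lexicographic order, moving only if that key is
#' smaller than the cell's own — a deterministic tie rule that merges flat
#' regions into a single basin and guarantees termination.
#'
#' Basins whose pit is shallower than `min_depth` below their lowest
#' saddle are merged into the neighbor across that saddle (h-minima
#' suppression), removing the ripple-scale micro-basins a sparsely
#' populated map produces while preserving ridges that reflect genuine
#' gaps in the data; `min_depth = 0` disables merging.
#'
#' @param heights Numeric matrix (or `esom_umatrix`).
#' @param toroid Wrap edges; defaults to the attached configuration, else
#'   TRUE.
#' @param min_depth Minimum pit depth (same units as `heights`) a basin
#'   must have relative to its lowest saddle to survive as a separate
#'   basin (default 0: plain watershed).
#' @return Integer matrix of basin ids (arbitrary but deterministic,
#'   numbered by first occurrence in row-major order).
#' @export
watershed_basins <- function(heights, toroid = NULL, min_depth = 0) {
  cfg <- attr(heights, "config")
  if (is.null(toroid)) toroid <- if (!is.null(cfg)) cfg$toroid else TRUE
  rows <- nrow(heights); cols <- ncol(heights)
  h <- as.vector(t(unclass(heights))) # row-major linear index
  n <- length(h)
  idx <- shifted_index(rows, cols, toroid)
  # lowest-neighbor pointer under the (height, index) lexicographic key
  best_h <- rep(Inf, n)
  best_i <- rep(NA_integer_, n)
  for (ix in idx) {
    ok <- which(!is.na(ix))
    nh <- h[ix[ok]]
    ni <- ix[ok]
    better <- nh < best_h[ok] | (nh == best_h[ok] & ni < best_i[ok])
    better[is.na(better)] <- TRUE # first neighbor seen
    upd <- ok[better]
    best_h[upd] <- h[ix[upd]]
    best_i[upd] <- ix[upd]
  }
  self_key_gt <- best_h < h | (best_h == h & best_i < seq_len(n))
  ptr <- ifelse(self_key_gt, best_i, seq_len(n))
  # resolve pointer chains (each step strictly decreases the key, so this
  # terminates); path-compress iteratively
  root <- ptr
  repeat {
    nxt <- ptr[root]
    if (all(nxt == root)) break
    root <- nxt
  }
  if (min_depth > 0) root <- merge_shallow_basins(h, root, idx, min_depth)
  ids <- match(root, unique(root))
  matrix(ids, nrow = rows, ncol = cols, byrow = TRUE)
}

# Iteratively dissolve the basin with the smallest dynamics (pit depth
# below its lowest saddle) while that depth is < min_depth, reassigning it
# across the saddle. Saddle height between basins a and b = min over
# adjacent cell pairs (p in a, q in b) of max(h[p], h[q]).
merge_shallow_basins <- function(h, root, idx, min_depth) {
  repeat {
    basins <- unique(root)
    if (length(basins) <= 1L) return(root)
    pit <- vapply(basins, function(b) min(h[root == b]), numeric(1))
    # lowest saddle from each basin to any neighboring basin
    saddle <- rep(Inf, length(basins))
    target <- rep(NA_integer_, length(basins))
    for (ix in idx) {
      ok <- which(!is.na(ix))
      p <- ok; q <- ix[ok]
      cross <- root[p] != root[q]
      if (!any(cross)) next
      p <- p[cross]; q <- q[cross]
      s <- pmax(h[p], h[q])
      bi <- match(root[p], basins)
      o <- order(s)
      first <- o[!duplicated(bi[o])] # lowest saddle per source basin
      upd <- s[first] < saddle[bi[first]]
      saddle[bi[first][upd]] <- s[first][upd]
      target[bi[first][upd]] <- root[q][first][upd]
    }
    depth <- saddle - pit
    m <- which.min(depth)
    if (!is.finite(depth[m]) || depth[m] >= min_depth) return(root)
    root[root == basins[m]] <- target[m]
  }
}

#' Extract the U-matrix cluster containing a seed label
#'
#' Computes watershed basins of the (optionally smoothed) U-heights and
#' returns the labels whose best-matching unit falls in the same basin as
#' the seed label's BMU — the repurposing candidate list when the seed is
#' the virtual drug. The seed itself is excluded from the member list.
#'
#' @param um An `esom_umatrix`.
#' @param bmus A [map_bmus()] tibble covering the seed label.
#' @param seed_label Label whose basin is extracted (default
#'   `"PainInsensitivity"`).
#' @param smooth Apply [smooth_umatrix()] first (default TRUE).
#' @param min_depth_frac Basins shallower than this fraction of the
#'   (smoothed) height range are dissolved into their neighbors before
#'   membership is read off (see [watershed_basins()]; default 0.5, 0
#'   disables).
#' @return A list of class `cluster_result`: `members` (labels in the
#'   seed's basin, seed excluded), `excluded` (all other labels), `basins`
#'   (id matrix), `seed_basin`, `seed_label`.
#' @export
extract_cluster <- function(um, bmus, seed_label = "PainInsensitivity",
                            smooth = TRUE, min_depth_frac = 0.5) {
  if (!seed_label %in% bmus$label) {
    abort(paste0("seed label not in BMU map: ", seed_label))
  }
  field <- if (smooth) smooth_umatrix(um) else um
  basins <- watershed_basins(field,
                             min_depth = min_depth_frac * diff(range(field)))
  bmu_basin <- basins[cbind(bmus$row, bmus$col)]
  seed_basin <- bmu_basin[bmus$label == seed_label][1]
  members <- setdiff(bmus$label[bmu_basin == seed_basin], seed_label)
  excluded <- setdiff(bmus$label, c(members, seed_label))
  structure(list(members = members, excluded = excluded, basins = basins,
                 seed_basin = seed_basin, seed_label = seed_label),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> seed '%s' in basin %d with %d member(s); %d label(s) outside\n",
              x$seed_label, x$seed_basin, length(x$members),
              length(x$excluded)))
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) {
  tibble(label = c(x$members, x$excluded),
         in_cluster = c(rep(TRUE, length(x$members)),
                        rep(FALSE, length(x$excluded))))
}
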