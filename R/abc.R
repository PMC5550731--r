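#' ABC curve of a positive value set
#'
#' Values are sorted in decreasing order (ties keep their original order)
#' and accumulated: point i is (i/n, cumulative share of the total). The
#' curve runs from near the origin to (1, 1) and is concave for positive
#' values, the discrete analogue of a Lorenz/Pareto curve read from the
#' large end.
#'
#' @param values Positive finite numeric vector.
#' @return A tibble of class `abc_curve` with columns `item` (original
#'   index), `value`, `x`, `y`, in decreasing-value order; attribute
#'   `slopes` holds the per-segment slopes.
#' @export
abc_curve <- function(values) {
  if (!length(values)) abort("abc_curve needs at least one value")
  if (any(!is.finite(values) | values <= 0)) {
    abort("abc_curve requires strictly positive finite values")
  }
  ord <- order(-values, seq_along(values)) # ties keep original index order
  v <- values[ord]
  n <- length(v)
  total <- sum(v)
  y <- cumsum(v) / total
  x <- seq_len(n) / n
  # segment slope on equal x-steps of 1/n reduces to n * v_i / total
  slopes <- n * v / total
  structure(tibble(item = ord, value = v, x = x, y = y),
            class = c("abc_curve", class(tibble())),
            slopes = slopes)
}

# Count of items in set A: the first curve segment whose slope has come
# down to 1 closes A. Slope comparisons use a small relative tolerance so
# that exactly-uniform inputs land on the equality branch.
a_boundary <- function(curve) {
  s <- attr(curve, "slopes")
  tol <- 1e-9
  at_one <- abs(s - 1) <= tol
  below <- s < 1 - tol
  i <- which(at_one | below)[1] # exists: slopes average to 1
  if (below[i] && i > 1L) i - 1L else i
}

#' Computed ABC partition
#'
#' Splits positive values into the "important few" (A), an intermediate set
#' (B) and the "trivial many" (C). Set A ends where the slope of the ABC
#' curve first comes down to 1 (uniform input degenerates to a single-item
#' A so that nested application terminates); the B|C boundary is the curve
#' point closest to (1, 1) among the items after A. Every value in A is >=
#' every value in B, which is >= every value in C.
#'
#' @param values Positive finite numeric vector.
#' @return A list of class `abc_partition` with integer index vectors `A`,
#'   `B`, `C` (original indices), counts `boundary_ab`, `boundary_bc`, and
#'   the `curve`.
#' @export
abc_partition <- function(values) {
  curve <- abc_curve(values)
  n <- nrow(curve)
  ab <- a_boundary(curve)
  if (ab >= n) {
    part <- list(A = curve$item, B = integer(), C = integer(),
                 boundary_ab = n, boundary_bc = n)
  } else {
    tail_idx <- (ab + 1L):n
    d2 <- (1 - curve$x[tail_idx])^2 + (1 - curve$y[tail_idx])^2
    bc <- tail_idx[which.min(d2)]
    part <- list(A = curve$item[seq_len(ab)],
                 B = curve$item[(ab + 1L):bc],
                 C = if (bc < n) curve$item[(bc + 1L):n] else integer(),
                 boundary_ab = ab, boundary_bc = bc)
  }
  structure(c(part, list(curve = curve)), class = "abc_partition")
}

#' @export
print.abc_partition <- function(x, ...) {
  cat(sprintf("<abc_partition> |A| = %d, |B| = %d, |C| = %d of %d items\n",
              length(x$A), length(x$B), length(x$C), nrow(x$curve)))
  invisible(x)
}

#' @export
tidy.abc_partition <- function(x, ...) {
  sets <- rep(NA_character_, nrow(x$curve))
  sets[match(x$A, x$curve$item)] <- "A"
  sets[match(x$B, x$curve$item)] <- "B"
  sets[match(x$C, x$curve$item)] <- "C"
  mutate(x$curve, set = sets)
}

#' Nested ABC selection
#'
#' Applies the ABC partition `depth` times, each pass re-submitting only
#' the previous A-set, shrinking the selection monotonically toward the
#' most profitable items. Infinite values (here: reciprocal distances of
#' drugs at distance zero from the virtual drug) bypass the analysis and
#' are force-retained in the selection with a message.
#'
#' @param values Positive numeric vector, `Inf` allowed.
#' @param depth Number of passes (default 2).
#' @return Sorted integer vector of selected original indices.
#' @export
nested_abc <- function(values, depth = 2) {
  stopifnot(depth >= 1)
  forced <- which(is.infinite(values))
  if (length(forced)) {
    rlang::inform(sprintf(
      "%d item(s) with infinite value bypass the ABC analysis and are retained",
      length(forced)))
  }
  idx <- setdiff(seq_along(values), forced)
  for (i in seq_len(depth)) {
    if (length(idx) <= 1L) break
    part <- abc_partition(values[idx])
    idx <- idx[part$A]
  }
  sort(c(forced, idx))
}

#' @rdname abc_partition
#' @param object An `abc_partition`.
#' @param ... Unused.
#' @export
autoplot.abc_partition <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$set)) +
    ggplot2::geom_step(ggplot2::aes(group = 1), colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "cumulative fraction of items",
                  y = "cumulative fraction of total value",
                  colour = "set", title = "ABC curve") +
    ggplot2::theme_minimal()
}
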