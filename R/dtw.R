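#' Local cost matrix between two multichannel sequences
#'
#' Entry (j, i) is the squared Euclidean distance between frame j of `X`
#' and frame i of `M` across all channels.
#'
#' @param X J x C numeric matrix (frames x channels).
#' @param M I x C numeric matrix with the same channel count.
#' @return J x I matrix of non-negative local costs.
#' @export
local_cost_matrix <- function(X, M) {
  X <- as.matrix(X); M <- as.matrix(M)
  if (nrow(X) == 0L || nrow(M) == 0L) stop("empty sequence")
  if (ncol(X) != ncol(M)) {
    stop("channel mismatch: ", ncol(X), " vs ", ncol(M))
  }
  # ||x||^2 + ||m||^2 - 2 x.m, clipped at 0 against rounding
  sx <- rowSums(X^2)
  sm <- rowSums(M^2)
  C <- outer(sx, sm, "+") - 2 * tcrossprod(X, M)
  C[C < 0] <- 0
  C
}

#' Dynamic time warping alignment
#'
#' Aligns two variable-length multichannel sequences by a monotone warping
#' path minimizing the accumulated squared-distance local cost, via the
#' standard cumulative-cost recursion
#' `D(j,i) = min(D(j-1,i-1), D(j-1,i), D(j,i-1)) + c(j,i)` with
#' `D(1,1) = c(1,1)` and border cells accumulating along their only
#' predecessor. No warping-window or slope constraint is applied. The
#' optimal path is recovered by backtracking with deterministic
#' diagonal-first tie-breaking.
#'
#' @param X,M Numeric matrices (frames x channels), equal channel counts.
#' @return An object of class `dtw_result`: `cumulative_cost` (`D(J,I)`),
#'   `normalized_cost` (`cumulative_cost / K` with `K` the path length, the
#'   quantity compared against the data-selection threshold `k`), and
#'   `path` (K x 2 matrix of (j, i) pairs from (1,1) to (J,I)).
#' @details Cycle lengths vary from stride to stride, so the raw cumulative
#'   cost is not comparable across cycles; all thresholding elsewhere in
#'   the package uses `normalized_cost`.
#' @export
#' @examples
#' X <- matrix(c(0, 2), ncol = 1)
#' M <- matrix(c(0, 1, 2), ncol = 1)
#' dtw_align(X, M)$cumulative_cost
dtw_align <- function(X, M) {
  C <- local_cost_matrix(X, M)
  res <- .dtw_core(C)
  structure(
    list(cumulative_cost = res$cumulative_cost,
         normalized_cost = res$cumulative_cost / nrow(res$path),
         path = res$path),
    class = "dtw_result")
}

#' @export
print.dtw_result <- function(x, ...) {
  cat(sprintf("<dtw_result> D = %.6g, normalized = %.6g, path length %d\n",
              x$cumulative_cost, x$normalized_cost, nrow(x$path)))
  invisible(x)
}
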