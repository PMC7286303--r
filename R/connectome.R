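#' Connectome objects
#'
#' A connectome is a symmetric, non-negative, zero-diagonal weighted
#' adjacency matrix over named brain regions, tagged with a weight kind:
#' `fa_w` (mean fractional anisotropy per connection, in `[0, 1]`),
#' `fd_w` (fiber density), `struct_binary`, `func_w` (Fisher-z partial
#' correlation, negatives removed) or `func_binary`. Binary kinds may
#' contain only 0 and 1.
#'
#' @param weights square numeric matrix.
#' @param nodes character region names (defaults to `rownames(weights)`).
#' @param kind one of `"fa_w"`, `"fd_w"`, `"struct_binary"`, `"func_w"`,
#'   `"func_binary"`.
#' @param subject_id,timepoint_index optional provenance tags.
#' @return An object of class `connectome`.
#' @export
connectome <- function(weights, nodes = rownames(weights), kind,
                       subject_id = NA_character_,
                       timepoint_index = NA_integer_) {
  kind <- match.arg(kind, c("fa_w", "fd_w", "struct_binary",
                            "func_w", "func_binary"))
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (ncol(weights) != n) stop("weights must be square")
  if (is.null(nodes)) nodes <- sprintf("node%03d", seq_len(n))
  if (length(nodes) != n) stop("nodes length must match matrix dimension")
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-12,
                        check.attributes = FALSE)))
    stop("weights must be symmetric")
  weights <- (weights + t(weights)) / 2   # enforce exact symmetry
  diag(weights) <- 0
  if (any(weights < 0)) stop("weights must be non-negative")
  if (is_binary_kind(kind) && !all(weights %in% c(0, 1)))
    stop("binary connectomes may contain only 0 and 1")
  if (kind == "fa_w" && any(weights > 1))
    stop("fa_w weights must lie in [0, 1]")
  dimnames(weights) <- list(nodes, nodes)
  structure(
    list(nodes = nodes, weights = weights, kind = kind,
         subject_id = subject_id,
         timepoint_index = as.integer(timepoint_index)),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> kind=%s  %d nodes  density=%.1f%%",
              x$kind, length(x$nodes), connectome_density(x)))
  if (!is.na(x$subject_id))
    cat(sprintf("  subject=%s tp=%s", x$subject_id, x$timepoint_index))
  cat("\n")
  invisible(x)
}

#' Connection density of a connectome
#'
#' Percentage of possible edges present:
#' `100 * nonzero upper-triangle entries / (N (N - 1) / 2)`.
#'
#' @param x a `connectome` (at least 2 nodes).
#' @return density in percent.
#' @examples
#' w <- matrix(1, 4, 4); diag(w) <- 0
#' connectome_density(connectome(w, letters[1:4], "struct_binary"))  # 100
#' @export
connectome_density <- function(x) {
  stopifnot(inherits(x, "connectome"))
  n <- length(x$nodes)
  if (n < 2) stop("density requires at least 2 nodes")
  100 * sum(x$weights[upper.tri(x$weights)] != 0) / (n * (n - 1) / 2)
}

#' @rdname connectome_density
#' @param ... ignored.
#' @export
density.connectome <- function(x, ...) connectome_density(x)

#' Keep only edges strictly above a weight threshold
#'
#' Strictly-greater-than filter (the display convention for strongest
#' connections, e.g. FA-w > 0.3 or z > 0.05): weights `<= min_weight`
#' are set to zero; the kind tag is preserved.
#'
#' @param x a `connectome`.
#' @param min_weight non-negative threshold.
#' @return a filtered `connectome`.
#' @examples
#' w <- matrix(c(0, .2, .31, .2, 0, .3, .31, .3, 0), 3, 3)
#' f <- filter_edges(connectome(w, letters[1:3], "fa_w"), 0.3)
#' sum(f$weights[upper.tri(f$weights)] > 0)  # 1: only 0.31 survives
#' @export
filter_edges <- function(x, min_weight) {
  stopifnot(inherits(x, "connectome"), min_weight >= 0)
  w <- x$weights
  w[w <= min_weight] <- 0
  x$weights <- w
  x
}
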