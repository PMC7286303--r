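#' Network-based statistic
#'
#' Permutation inference on connected components of suprathreshold
#' edges: edgewise two-sample t statistics are thresholded, connected
#' components of the surviving edges are measured by extent (edge
#' count), and the maximal null component extent is built by permuting
#' subject group labels (whole subjects, preserving within-subject edge
#' dependence).
#'
#' @name nbs
NULL

# Stack a list of connectomes (identical node sets) into an n x n x S
# array.
#' Stack connectomes into a 3-D array
#' @param connectomes list of `connectome` objects sharing one node set.
#' @return nodes x nodes x subjects array.
#' @export
connectome_stack <- function(connectomes) {
  stopifnot(length(connectomes) >= 1)
  nodes <- connectomes[[1]]$nodes
  for (c_ in connectomes)
    if (!identical(c_$nodes, nodes))
      stop("all connectomes must share an identical node set")
  arr <- array(0, dim = c(length(nodes), length(nodes), length(connectomes)),
               dimnames = list(nodes, nodes, NULL))
  for (s in seq_along(connectomes)) arr[, , s] <- connectomes[[s]]$weights
  arr
}

as_stack <- function(x) {
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.list(x)) return(connectome_stack(x))
  stop("expected a 3-D array or a list of connectomes")
}

# subjects x n_edges matrix of upper-triangle weights
stack_edge_matrix <- function(stack) {
  n <- dim(stack)[1]
  ut <- upper.tri(matrix(0, n, n))
  t(apply(stack, 3, function(m) m[ut]))
}

# vectorized pooled-variance two-sample t per column; zero pooled
# variance yields t = 0 (degenerate rule).
pooled_t_cols <- function(Ea, Eb) {
  na <- nrow(Ea); nb <- nrow(Eb)
  m1 <- colMeans(Ea); m2 <- colMeans(Eb)
  v1 <- colSums(sweep(Ea, 2, m1)^2) / (na - 1)
  v2 <- colSums(sweep(Eb, 2, m2)^2) / (nb - 1)
  sp2 <- ((na - 1) * v1 + (nb - 1) * v2) / (na + nb - 2)
  tt <- (m1 - m2) / sqrt(sp2 * (1 / na + 1 / nb))
  tt[!is.finite(tt)] <- 0
  tt
}

#' Edgewise two-sample t statistics
#'
#' Pooled-variance t statistic per edge (group a minus group b) across
#' two stacks of connectomes. Edges with zero variance in both groups
#' (including edges absent in every subject) get t = 0.
#'
#' @param stack_a,stack_b 3-D arrays (nodes x nodes x subjects) or lists
#'   of `connectome` objects with identical node sets; at least 2
#'   subjects per group.
#' @return symmetric matrix of t values, zero diagonal.
#' @examples
#' a <- array(rep(c(0.6, 0.7, 0.8), each = 4), c(2, 2, 3))
#' b <- array(rep(c(0.3, 0.4, 0.5), each = 4), c(2, 2, 3))
#' for (s in 1:3) { a[1, 1, s] <- a[2, 2, s] <- 0; b[1, 1, s] <- b[2, 2, s] <- 0 }
#' round(edgewise_t(a, b)[1, 2], 3)  # 3.674
#' @export
edgewise_t <- function(stack_a, stack_b) {
  sa <- as_stack(stack_a); sb <- as_stack(stack_b)
  if (!identical(dim(sa)[1:2], dim(sb)[1:2]))
    stop("stacks must share the node set")
  if (dim(sa)[3] < 2 || dim(sb)[3] < 2)
    stop("need at least 2 subjects per group")
  n <- dim(sa)[1]
  tt <- pooled_t_cols(stack_edge_matrix(sa), stack_edge_matrix(sb))
  out <- matrix(0, n, n, dimnames = dimnames(sa)[1:2])
  out[upper.tri(out)] <- tt
  out + t(out)
}

# union-find over edges (i, j); returns component id per edge
edge_component_ids <- function(i, j, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (e in seq_along(i)) {
    ri <- find(i[e]); rj <- find(j[e])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_along(i), function(e) find(i[e]), integer(1))
}

max_component_extent <- function(i, j, n) {
  if (!length(i)) return(0L)
  ids <- edge_component_ids(i, j, n)
  max(tabulate(match(ids, unique(ids))))
}

#' Connected components of suprathreshold edges
#'
#' Keeps edges with `t > threshold` and returns the connected components
#' (node-linked) of the surviving edge set, largest extent first.
#'
#' @param t_matrix symmetric matrix of edgewise statistics.
#' @param threshold positive edge-inclusion threshold.
#' @return list of components; each has `edges` (data frame `region_a`,
#'   `region_b`, `t`) and `extent` (edge count).
#' @examples
#' tm <- matrix(0, 6, 6)
#' tm[1, 2] <- tm[2, 3] <- tm[5, 6] <- 4; tm <- tm + t(tm)
#' lengths <- vapply(suprathreshold_components(tm, 3.1),
#'                   function(co) co$extent, numeric(1))
#' lengths  # 2 1
#' @export
suprathreshold_components <- function(t_matrix, threshold) {
  stopifnot(threshold > 0)
  n <- nrow(t_matrix)
  nodes <- rownames(t_matrix) %||% as.character(seq_len(n))
  ut <- which(upper.tri(t_matrix) & t_matrix > threshold, arr.ind = TRUE)
  if (!nrow(ut)) return(list())
  ids <- edge_component_ids(ut[, 1], ut[, 2], n)
  comps <- lapply(split(seq_len(nrow(ut)), ids), function(e) {
    list(edges = data.frame(region_a = nodes[ut[e, 1]],
                            region_b = nodes[ut[e, 2]],
                            t = t_matrix[ut[e, , drop = FALSE]],
                            stringsAsFactors = FALSE),
         extent = length(e))
  })
  comps <- unname(comps)
  comps[order(vapply(comps, function(co) co$extent, numeric(1)),
              decreasing = TRUE)]
}

#' Network-based statistic permutation test
#'
#' Observed suprathreshold components (per direction) are assessed
#' against the null distribution of the maximal component extent under
#' `n_perm` random relabelings of subjects. Component p-values use the
#' add-one estimator `p = (1 + #{null >= extent}) / (1 + n_perm)`, so
#' `p >= 1 / (1 + n_perm)` always. Both directions are tested by default
#' (increased and decreased subnetworks), applying the threshold to the
#' signed t in separate one-sided passes.
#'
#' @param stack_a,stack_b connectome stacks (arrays or lists), e.g.
#'   transgenic and control groups.
#' @param t_threshold edge-inclusion t threshold (default 3.1).
#' @param n_perm number of permutations (default 5000, minimum 100).
#' @param alpha component significance level (default 0.05).
#' @param direction `"both"`, `"a_greater"` or `"b_greater"`.
#' @param seed integer seed for the permutation stream.
#' @return object of class `nbs_result`: per tested direction a list
#'   with `components`, `p_values`, `significant`, `null_max_extent`;
#'   plus `observed_t` and `settings`.
#' @examples
#' set.seed(1)
#' a <- array(rnorm(6 * 6 * 5), c(6, 6, 5))
#' b <- array(rnorm(6 * 6 * 5), c(6, 6, 5))
#' for (s in 1:5) {
#'   a[, , s] <- (a[, , s] + t(a[, , s])) / 2; diag(a[, , s]) <- 0
#'   b[, , s] <- (b[, , s] + t(b[, , s])) / 2; diag(b[, , s]) <- 0
#' }
#' res <- nbs_test(a, b, t_threshold = 2, n_perm = 200, seed = 1)
#' @export
nbs_test <- function(stack_a, stack_b, t_threshold = 3.1, n_perm = 5000,
                     alpha = 0.05, direction = c("both", "a_greater",
                                                 "b_greater"), seed = 1) {
  direction <- match.arg(direction)
  if (n_perm < 100) stop("n_perm must be >= 100")
  sa <- as_stack(stack_a); sb <- as_stack(stack_b)
  if (!identical(dim(sa)[1:2], dim(sb)[1:2]))
    stop("stacks must share the node set")
  n <- dim(sa)[1]
  na_ <- dim(sa)[3]; nb_ <- dim(sb)[3]
  if (na_ < 2 || nb_ < 2) stop("need at least 2 subjects per group")

  E <- rbind(stack_edge_matrix(sa), stack_edge_matrix(sb))
  S <- na_ + nb_
  n_edges <- ncol(E)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)

  t_obs <- pooled_t_cols(E[seq_len(na_), , drop = FALSE],
                         E[na_ + seq_len(nb_), , drop = FALSE])
  if (all(t_obs == 0))
    message("all edgewise statistics are zero (identical data?)")
  t_mat <- matrix(0, n, n, dimnames = dimnames(sa)[1:2])
  t_mat[upper.tri(t_mat)] <- t_obs
  t_mat <- t_mat + t(t_mat)

  dirs <- if (direction == "both") c("a_greater", "b_greater") else direction
  set.seed(substream_seed(seed, 777L))
  null_a <- numeric(n_perm)
  null_b <- numeric(n_perm)
  E2 <- E^2
  chunk <- 250L
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    Pa <- matrix(0, m, S)
    for (r in seq_len(m)) Pa[r, sample.int(S, na_)] <- 1
    M1 <- (Pa %*% E) / na_
    M2 <- ((1 - Pa) %*% E) / nb_
    V1 <- ((Pa %*% E2) - na_ * M1^2) / (na_ - 1)
    V2 <- (((1 - Pa) %*% E2) - nb_ * M2^2) / (nb_ - 1)
    SP2 <- ((na_ - 1) * V1 + (nb_ - 1) * V2) / (S - 2)
    Tm <- (M1 - M2) / sqrt(SP2 * (1 / na_ + 1 / nb_))
    Tm[!is.finite(Tm)] <- 0
    for (r in seq_len(m)) {
      pos <- Tm[r, ] > t_threshold
      neg <- -Tm[r, ] > t_threshold
      null_a[done + r] <- if (any(pos))
        max_component_extent(ut[pos, 1], ut[pos, 2], n) else 0
      null_b[done + r] <- if (any(neg))
        max_component_extent(ut[neg, 1], ut[neg, 2], n) else 0
    }
    done <- done + m
  }

  result_dir <- function(sign_, null_max) {
    comps <- suprathreshold_components(sign_ * t_mat, t_threshold)
    pv <- vapply(comps, function(co)
      (1 + sum(null_max >= co$extent)) / (1 + n_perm), numeric(1))
    list(components = comps, p_values = pv, significant = pv < alpha,
         null_max_extent = null_max)
  }
  out <- list()
  if ("a_greater" %in% dirs) out$a_greater <- result_dir(1, null_a)
  if ("b_greater" %in% dirs) out$b_greater <- result_dir(-1, null_b)

  structure(
    list(directions = out, observed_t = t_mat,
         settings = list(t_threshold = t_threshold, n_perm = n_perm,
                         alpha = alpha, direction = direction, seed = seed,
                         n_a = na_, n_b = nb_)),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<nbs_result> t>%.2f, %d permutations, groups %d vs %d\n",
              s$t_threshold, s$n_perm, s$n_a, s$n_b))
  for (d in names(x$directions)) {
    r <- x$directions[[d]]
    if (!length(r$components)) {
      cat(sprintf("  %s: no suprathreshold components\n", d))
    } else {
      for (k in seq_along(r$components))
        cat(sprintf("  %s: component %d, extent %d, p = %.4f%s\n", d, k,
                    r$components[[k]]$extent, r$p_values[k],
                    if (r$significant[k]) " *" else ""))
    }
  }
  invisible(x)
}
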