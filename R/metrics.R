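#' Graph measures of brain networks
#'
#' The five measures summarizing network density, integration and
#' segregation: nodal degree and strength, clustering coefficient, and
#' global and local efficiency. Binary connectomes use hop-count
#' distances and the triangle-fraction clustering; weighted connectomes
#' map edge weights to lengths `1 / w` for paths and use the
#' geometric-mean-of-triangles (Onnela) clustering with weights rescaled
#' by the matrix maximum, the conventions of the standard brain
#' connectivity toolbox. Unreachable pairs contribute zero efficiency.
#'
#' @name graph_metrics
NULL

#' Nodal degree and strength
#'
#' Degree is the count of a node's connections; strength is the sum of
#' its connection weights. Network degree and strength are the nodal
#' values averaged over all regions.
#'
#' @param x a `connectome`.
#' @return list with `degree`, `strength` (named per node),
#'   `network_degree`, `network_strength`.
#' @examples
#' w <- matrix(1, 4, 4); diag(w) <- 0
#' nodal_degree_strength(connectome(w, letters[1:4], "struct_binary"))
#' @export
nodal_degree_strength <- function(x) {
  stopifnot(inherits(x, "connectome"))
  w <- x$weights
  deg <- rowSums(w != 0)
  str <- rowSums(w)
  list(degree = deg, strength = str,
       network_degree = mean(deg), network_strength = mean(str))
}

#' Clustering coefficient
#'
#' Binary: `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of
#' triangles at node i. Weighted: Onnela's geometric-mean formula on
#' weights normalized by the global maximum,
#' `C_i = 2 sum_{jk} (w'_ij w'_jk w'_ik)^(1/3) / (k_i (k_i - 1))`.
#' Nodes with fewer than 2 neighbors have `C_i = 0`.
#'
#' @param x a `connectome`.
#' @return list with `nodal` (per-node values) and `network` (mean).
#' @examples
#' w <- matrix(c(0, .2, .8, .2, 0, .4, .8, .4, 0), 3, 3)
#' clustering_coef(connectome(w, letters[1:3], "fa_w"))$nodal  # all 0.5
#' @export
clustering_coef <- function(x) {
  stopifnot(inherits(x, "connectome"))
  w <- x$weights
  k <- rowSums(w != 0)
  if (is_binary_kind(x$kind)) {
    A <- (w != 0) * 1
    t3 <- diag(A %*% A %*% A) / 2
  } else {
    mx <- max(w)
    Wn <- if (mx > 0) (w / mx)^(1 / 3) else w
    t3 <- diag(Wn %*% Wn %*% Wn) / 2
  }
  C <- ifelse(k < 2, 0, 2 * t3 / (k * (k - 1)))
  names(C) <- x$nodes
  list(nodal = C, network = mean(C))
}

#' Pairwise shortest-path distances
#'
#' Binary connectomes use hop counts; weighted connectomes use edge
#' lengths `1 / weight` (stronger connections are shorter). Unreachable
#' pairs have infinite distance. All-pairs distances are computed by a
#' vectorized Floyd-Warshall sweep.
#'
#' @param x a `connectome`.
#' @return symmetric distance matrix with zero diagonal.
#' @examples
#' w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1
#' shortest_paths(connectome(w, letters[1:3], "struct_binary"))[1, 3]  # 2
#' @export
shortest_paths <- function(x) {
  stopifnot(inherits(x, "connectome"))
  edge_lengths <- length_matrix(x$weights, is_binary_kind(x$kind))
  D <- floyd_warshall(edge_lengths)
  dimnames(D) <- list(x$nodes, x$nodes)
  D
}

length_matrix <- function(w, binary) {
  L <- matrix(Inf, nrow(w), ncol(w))
  nz <- w != 0
  L[nz] <- if (binary) 1 else 1 / w[nz]
  diag(L) <- 0
  L
}

floyd_warshall <- function(L) {
  n <- nrow(L)
  D <- L
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    upd <- Dk < D
    if (any(upd)) D[upd] <- Dk[upd]
  }
  D
}

# efficiency of a raw weight matrix: mean over ordered pairs of 1/d.
efficiency_matrix <- function(w, binary) {
  n <- nrow(w)
  if (n < 2) return(0)
  D <- floyd_warshall(length_matrix(w, binary))
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path distance
#' (`1 / Inf = 0` for disconnected pairs) — the integration measure.
#'
#' @param x a `connectome`.
#' @return scalar efficiency.
#' @examples
#' w <- matrix(1, 4, 4); diag(w) <- 0
#' global_efficiency(connectome(w, letters[1:4], "struct_binary"))  # 1
#' @export
global_efficiency <- function(x) {
  stopifnot(inherits(x, "connectome"))
  efficiency_matrix(x$weights, is_binary_kind(x$kind))
}

#' Local efficiency
#'
#' Nodal value: the global efficiency of the subgraph induced by the
#' node's neighbors (same induced-subgraph rule for weighted kinds, on
#' the weights). Nodes with fewer than 2 neighbors score 0. The network
#' value is the mean over all nodes — the segregation measure.
#'
#' @param x a `connectome`.
#' @return list with `nodal` and `network`.
#' @examples
#' w <- matrix(1, 4, 4); diag(w) <- 0
#' local_efficiency(connectome(w, letters[1:4], "struct_binary"))$network
#' @export
local_efficiency <- function(x) {
  stopifnot(inherits(x, "connectome"))
  w <- x$weights
  binary <- is_binary_kind(x$kind)
  nodal <- vapply(seq_len(nrow(w)), function(i) {
    nb <- which(w[i, ] != 0)
    if (length(nb) < 2) return(0)
    efficiency_matrix(w[nb, nb, drop = FALSE], binary)
  }, numeric(1))
  names(nodal) <- x$nodes
  list(nodal = nodal, network = mean(nodal))
}

#' Network-level metric summary
#'
#' Emits the global (node-averaged) measures appropriate to the
#' connectome kind: strength, global efficiency, local efficiency and
#' clustering for weighted kinds; degree in place of strength for binary
#' kinds.
#'
#' @param x a `connectome`.
#' @return long-format `data.frame`: `subject_id`, `timepoint_index`,
#'   `kind`, `metric`, `value`.
#' @examples
#' w <- matrix(1, 4, 4); diag(w) <- 0
#' network_summary(connectome(w, letters[1:4], "struct_binary"))
#' @export
network_summary <- function(x) {
  stopifnot(inherits(x, "connectome"))
  ds <- nodal_degree_strength(x)
  vals <- c(
    if (is_binary_kind(x$kind)) c(degree = ds$network_degree)
    else c(strength = ds$network_strength),
    global_efficiency = global_efficiency(x),
    local_efficiency = local_efficiency(x)$network,
    clustering = clustering_coef(x)$network
  )
  data.frame(
    subject_id = x$subject_id,
    timepoint_index = x$timepoint_index,
    kind = x$kind,
    metric = names(vals),
    value = unname(vals),
    stringsAsFactors = FALSE
  )
}

#' Assemble a metric table from a list of connectomes
#'
#' Applies [network_summary()] to each connectome and joins the cohort's
#' group labels — the long-format table consumed by the statistics
#' modules.
#'
#' @param connectomes list of `connectome` objects (tagged with subject
#'   and timepoint).
#' @param cohort a `cohort_table`.
#' @return `data.frame`: `subject_id`, `group`, `timepoint_index`,
#'   `kind`, `metric`, `value`.
#' @export
compute_metric_table <- function(connectomes, cohort) {
  tab <- do.call(rbind, lapply(connectomes, network_summary))
  grp <- unique(cohort[, c("subject_id", "group")])
  out <- merge(tab, grp, by = "subject_id", sort = FALSE)
  out <- out[, c("subject_id", "group", "timepoint_index", "kind",
                 "metric", "value")]
  out[order(out$subject_id, out$timepoint_index, out$kind, out$metric), ,
      drop = FALSE]
}
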