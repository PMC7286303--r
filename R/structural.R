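#' Build the three structural connectomes from a streamline table
#'
#' An edge joins regions i and j iff at least one streamline starts in
#' one and ends in the other. Three weightings are returned over the
#' identical support set:
#' \describe{
#'   \item{`fa_w`}{mean of the streamlines' mean fractional anisotropy.}
#'   \item{`fd_w`}{fiber density: streamline count normalized by region
#'     volumes and streamline length, computed as
#'     `sum_s (1 / length_s) / (vol_i + vol_j)` (see
#'     `volume_normalization`).}
#'   \item{`struct_binary`}{1 where connected, 0 otherwise.}
#' }
#' Streamlines with both endpoints in the same region are ignored.
#'
#' @param streamlines data frame with columns `region_a`, `region_b`,
#'   `length_mm` (> 0) and `mean_fa` (in (0, 1)); unordered endpoint
#'   pairs, i.e. (a, b) and (b, a) are the same connection.
#' @param atlas a `region_atlas`; all endpoint labels must appear in
#'   `atlas$name`.
#' @param volume_normalization `"sum"` divides the inverse-length sum by
#'   `vol_i + vol_j` (default); `"mean"` divides by `(vol_i + vol_j)/2`.
#'   Only the fact of normalization by volumes and length is canonical;
#'   the constant is exposed because conventions differ.
#' @return Named list of three `connectome` objects: `fa_w`, `fd_w`,
#'   `struct_binary`.
#' @examples
#' atl <- generate_atlas(4, 3, seed = 1)
#' st <- data.frame(region_a = atl$name[1], region_b = atl$name[2],
#'                  length_mm = c(2, 4), mean_fa = c(0.4, 0.6))
#' cs <- build_structural(st, atl)
#' cs$fa_w$weights[1, 2]  # 0.5
#' @export
build_structural <- function(streamlines, atlas,
                             volume_normalization = c("sum", "mean")) {
  volume_normalization <- match.arg(volume_normalization)
  n <- nrow(atlas)
  if (n < 1) stop("atlas must be non-empty")
  nodes <- atlas$name
  sid <- if (nrow(streamlines) > 0 && "subject_id" %in% names(streamlines))
    streamlines$subject_id[1] else NA_character_
  tp <- if (nrow(streamlines) > 0 && "timepoint_index" %in% names(streamlines))
    streamlines$timepoint_index[1] else NA_integer_

  zero <- matrix(0, n, n, dimnames = list(nodes, nodes))
  make <- function(w, kind) connectome(w, nodes, kind, sid, tp)

  if (nrow(streamlines) == 0) {
    return(list(fa_w = make(zero, "fa_w"), fd_w = make(zero, "fd_w"),
                struct_binary = make(zero, "struct_binary")))
  }

  ia <- match(streamlines$region_a, nodes)
  ib <- match(streamlines$region_b, nodes)
  if (anyNA(ia) || anyNA(ib)) {
    bad <- unique(c(streamlines$region_a[is.na(ia)],
                    streamlines$region_b[is.na(ib)]))
    stop("unknown region label(s): ", paste(head(bad, 5), collapse = ", "))
  }
  if (any(streamlines$length_mm <= 0)) stop("streamline lengths must be > 0")
  if (any(streamlines$mean_fa <= 0 | streamlines$mean_fa >= 1))
    stop("streamline mean_fa must lie in (0, 1)")

  keep <- ia != ib                       # self-loop rule
  ia <- ia[keep]; ib <- ib[keep]
  if (!length(ia)) {
    return(list(fa_w = make(zero, "fa_w"), fd_w = make(zero, "fd_w"),
                struct_binary = make(zero, "struct_binary")))
  }
  fa <- streamlines$mean_fa[keep]
  invlen <- 1 / streamlines$length_mm[keep]
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  key <- (lo - 1) * n + hi

  agg <- rowsum(cbind(count = 1, fa = fa, invlen = invlen), group = key)
  ukey <- as.numeric(rownames(agg))
  ulo <- (ukey - 1) %/% n + 1
  uhi <- ukey - (ulo - 1) * n

  vol_norm <- atlas$volume[ulo] + atlas$volume[uhi]
  if (volume_normalization == "mean") vol_norm <- vol_norm / 2

  fa_m <- zero; fd_m <- zero; bin_m <- zero
  idx <- cbind(ulo, uhi)
  fa_m[idx] <- agg[, "fa"] / agg[, "count"]
  fd_m[idx] <- agg[, "invlen"] / vol_norm
  bin_m[idx] <- 1
  fa_m <- fa_m + t(fa_m); fd_m <- fd_m + t(fd_m); bin_m <- bin_m + t(bin_m)

  list(fa_w = make(fa_m, "fa_w"), fd_w = make(fd_m, "fd_w"),
       struct_binary = make(bin_m, "struct_binary"))
}
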