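# Connected-component labeling with selectable 4/8 connectivity.
# Implemented over the pixel-adjacency graph (igraph components) because
# spot counting conventionally uses 8-connectivity and the EBImage labeler
# is 4-connected only. Labels are assigned 1..n in row-major order of each
# component's first pixel, which makes outputs reproducible and easy to
# compare against an independent labeler.

#' Label connected components of a binary mask
#'
#' @param mask logical or 0/1 numeric matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal).
#' @return integer matrix of the same shape; 0 = background, k = component
#'   k in row-major order of first occurrence.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  fg <- mask > 0
  out <- matrix(0L, nrow(mask), ncol(mask))
  nfg <- sum(fg)
  if (nfg == 0L) return(out)

  # rank of each foreground pixel (column-major positions -> 1..nfg)
  rank <- matrix(0L, nrow(mask), ncol(mask))
  rank[fg] <- seq_len(nfg)
  nr <- nrow(mask); nc <- ncol(mask)

  edge_pairs <- function(dr, dc) {
    r1 <- seq_len(nr - abs(dr)); c1 <- seq_len(nc - abs(dc))
    if (dr < 0) r1 <- r1 - dr          # source rows shifted down
    if (dc < 0) c1 <- c1 - dc
    a <- rank[r1, c1, drop = FALSE]
    b <- rank[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    cbind(a[keep], b[keep])
  }
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- do.call(rbind, lapply(offs, function(o) edge_pairs(o[1], o[2])))

  g <- igraph::make_empty_graph(n = nfg, directed = FALSE)
  if (!is.null(edges) && nrow(edges))
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership

  # relabel components by row-major order of their first pixel
  idx <- which(fg)                       # column-major linear indices
  rows <- (idx - 1L) %% nr; cols <- (idx - 1L) %/% nr
  rowmajor <- rows * nc + cols
  o <- order(memb, rowmajor)
  firsts <- rowmajor[o][!duplicated(memb[o])]   # per component, in memb order
  relab <- integer(length(firsts))
  relab[order(firsts)] <- seq_along(firsts)
  out[fg] <- relab[memb]
  out
}

# Areas and 0-based centroids of every label in a label mask.
component_stats <- function(label_mask) {
  labs <- as.integer(label_mask[label_mask > 0])
  if (!length(labs))
    return(data.frame(id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), area_px = integer()))
  nr <- nrow(label_mask)
  idx <- which(label_mask > 0)
  rows <- (idx - 1L) %% nr; cols <- (idx - 1L) %/% nr
  area <- tabulate(labs)
  ids <- which(area > 0L)
  sums <- rowsum(cbind(rows, cols), labs)        # ordered by label
  data.frame(id = ids,
             centroid_row = sums[, 1] / area[ids],
             centroid_col = sums[, 2] / area[ids],
             area_px = area[ids])
}
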