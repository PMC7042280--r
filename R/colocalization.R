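# Bipartite synapse counting: a colocalized punctum pair is a
# presynaptic and a postsynaptic detected component that overlap (or
# whose centroids are close), matched one-to-one. The headline count is
# the maximum one-to-one matching; a many-to-one overlap statistic is
# also provided for antibody-validation style comparisons, where values
# above 100% are meaningful.

# Overlap table between two label masks: data.frame(pre_id, post_id,
# overlap_px) for every pair of components sharing at least one pixel.
overlap_table <- function(pre_mask, post_mask) {
  both <- pre_mask > 0L & post_mask > 0L
  if (!any(both))
    return(data.frame(pre_id = integer(), post_id = integer(),
                      overlap_px = integer()))
  tab <- table(pre = pre_mask[both], post = post_mask[both])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, ]
  data.frame(pre_id = as.integer(df$pre), post_id = as.integer(df$post),
             overlap_px = as.integer(df$Freq))
}

greedy_one_to_one <- function(cand) {
  pairs <- cand[0, c("pre_id", "post_id"), drop = FALSE]
  used_pre <- integer(); used_post <- integer()
  for (i in seq_len(nrow(cand))) {
    if (cand$pre_id[i] %in% used_pre || cand$post_id[i] %in% used_post)
      next
    pairs <- rbind(pairs, cand[i, c("pre_id", "post_id")])
    used_pre <- c(used_pre, cand$pre_id[i])
    used_post <- c(used_post, cand$post_id[i])
  }
  rownames(pairs) <- NULL
  pairs
}

#' Colocalize presynaptic and postsynaptic puncta
#'
#' Candidate pairs are components sharing at least `param` pixels
#' (`"PIXEL_OVERLAP"`, default) or whose centroids lie within `param`
#' pixels (`"CENTROID_DISTANCE"`). A one-to-one matching is built
#' greedily by descending overlap (resp. ascending distance), ties by
#' smaller pre id then post id.
#'
#' @param pre,post `puncta_set`s from the same field geometry (equal
#'   mask shapes).
#' @param criterion `"PIXEL_OVERLAP"` or `"CENTROID_DISTANCE"`.
#' @param param minimum shared pixels (overlap) or maximum centroid
#'   separation in px (distance).
#' @return object of class `coloc_result`: counts `n_pre`, `n_post`,
#'   `n_coloc`, the matched `pairs`, and the criterion used.
#' @export
colocalize <- function(pre, post,
                       criterion = c("PIXEL_OVERLAP", "CENTROID_DISTANCE"),
                       param = 1) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(pre, "puncta_set"), inherits(post, "puncta_set"))
  if (!all(dim(pre$label_mask) == dim(post$label_mask)))
    stop("pre and post masks must have the same shape")
  if (criterion == "PIXEL_OVERLAP") {
    cand <- overlap_table(pre$label_mask, post$label_mask)
    cand <- cand[cand$overlap_px >= param, , drop = FALSE]
    cand <- cand[order(-cand$overlap_px, cand$pre_id, cand$post_id), ,
                 drop = FALSE]
  } else {
    if (pre$n && post$n) {
      d <- outer(pre$puncta$centroid_row, post$puncta$centroid_row, `-`)^2 +
           outer(pre$puncta$centroid_col, post$puncta$centroid_col, `-`)^2
      hit <- which(d <= param^2, arr.ind = TRUE)
      cand <- data.frame(pre_id = pre$puncta$id[hit[, 1]],
                         post_id = post$puncta$id[hit[, 2]],
                         dist = sqrt(d[hit]))
      cand <- cand[order(cand$dist, cand$pre_id, cand$post_id), ,
                   drop = FALSE]
    } else {
      cand <- data.frame(pre_id = integer(), post_id = integer(),
                         dist = numeric())
    }
  }
  pairs <- greedy_one_to_one(cand)
  structure(list(n_pre = pre$n, n_post = post$n, n_coloc = nrow(pairs),
                 pairs = pairs, criterion = criterion, param = param),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d pre, %d post, %d colocalized (%s >= %g)\n",
              x$n_pre, x$n_post, x$n_coloc, x$criterion, x$param))
  invisible(x)
}

#' Many-to-one colocalization percentage against a reference set
#'
#' Returns `100 * (number of stained puncta overlapping any endogenous
#' punctum) / n_endogenous`. Because several stained puncta may map onto
#' one endogenous punctum, the statistic can exceed 100% - the behavior
#' seen when validating antibody staining against endogenous labels.
#'
#' @param stained,endogenous `puncta_set`s with equal mask shapes.
#' @return percentage (>= 0, possibly above 100).
#' @export
coloc_fraction_against_reference <- function(stained, endogenous) {
  stopifnot(inherits(stained, "puncta_set"),
            inherits(endogenous, "puncta_set"))
  if (!all(dim(stained$label_mask) == dim(endogenous$label_mask)))
    stop("masks must have the same shape")
  if (endogenous$n == 0L)
    stop("reference set is empty")
  ov <- overlap_table(stained$label_mask, endogenous$label_mask)
  100 * length(unique(ov$pre_id)) / endogenous$n
}
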