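#' Demultiplex hashtag counts into singlet / doublet / negative calls
#'
#' For each hash, log1p counts across cells are split by 2-means clustering;
#' the positivity threshold is the midpoint of the two cluster centers. If
#' clustering degenerates (fewer than two distinct values, or an all-zero
#' hash), the hash falls back to the 99th percentile of the lower half of its
#' log1p counts; an all-zero hash is never positive and triggers a warning.
#' A cell positive for exactly one hash is a singlet assigned to that hash's
#' sample; positive for two or more, a doublet; for none, a negative.
#'
#' @param hash_counts hashes x cells count matrix with dimnames (rownames are
#'   sample labels).
#' @return tibble: `barcode`, `call` (singlet/doublet/negative),
#'   `assigned_sample` (`NA` unless singlet), `n_positive`,
#'   `positive_hashes` (list-column). Per-hash thresholds (log1p scale) are
#'   attached as `attr(, "thresholds")`.
#' @export
demultiplex_hashes <- function(hash_counts) {
  if (is.null(rownames(hash_counts)) || is.null(colnames(hash_counts)))
    abort("`hash_counts` must have hash rownames and cell colnames")
  if (nrow(hash_counts) < 1 || ncol(hash_counts) < 2)
    abort("need at least 1 hash and 2 cells")
  lh <- log1p(as.matrix(hash_counts))
  thresholds <- vapply(seq_len(nrow(lh)), function(i) {
    x <- lh[i, ]
    if (all(x == 0)) {
      warn(sprintf("hash %s has all-zero counts; never positive",
                   rownames(lh)[i]))
      return(Inf)
    }
    ux <- unique(x)
    if (length(ux) < 2) return(Inf)  # constant nonzero: cannot split
    km <- tryCatch(kmeans(x, centers = 2, nstart = 5),
                   error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 2) {
      lower <- x[x <= median(x)]
      return(as.numeric(quantile(lower, 0.99)))
    }
    mean(sort(km$centers[, 1]))
  }, numeric(1))
  names(thresholds) <- rownames(lh)

  pos <- lh > thresholds  # hash x cell logical
  n_pos <- colSums(pos)
  call <- ifelse(n_pos == 0, "negative", ifelse(n_pos == 1, "singlet",
                                                "doublet"))
  assigned <- rep(NA_character_, ncol(lh))
  sing <- which(n_pos == 1)
  if (length(sing))
    assigned[sing] <- rownames(lh)[apply(pos[, sing, drop = FALSE], 2, which)]
  out <- tibble(barcode = colnames(hash_counts), call = unname(call),
                assigned_sample = assigned, n_positive = as.integer(n_pos),
                positive_hashes = lapply(seq_len(ncol(lh)), function(j)
                  rownames(lh)[pos[, j]]))
  attr(out, "thresholds") <- thresholds
  out
}
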