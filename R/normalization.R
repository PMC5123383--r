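#' Median-of-ratios size factors
#'
#' Per-sample scaling factors from the median-of-ratios model: each
#' sample's factor is the median, over genes with a positive geometric
#' mean across samples, of the ratio of the gene's count in that sample to
#' its geometric mean. Genes with a zero count in any sample are excluded
#' from the reference geometric means, matching the reference method; the
#' median of an even number of ratios is the arithmetic mean of the two
#' middle values (the `stats::median()` convention).
#'
#' @param counts Punctual counts: either a numeric matrix (genes x
#'   samples, sample names as column names) or a data frame with a `gene`
#'   column and one numeric column per sample.
#' @return A tibble with columns `sample_id`, `size_factor` (all positive;
#'   identical samples receive identical factors).
#' @examples
#' size_factors(tibble::tibble(gene = c("g1", "g2"),
#'                             s1 = c(10, 100), s2 = c(20, 200)))
#' @export
size_factors <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot("gene" %in% names(counts))
    m <- as.matrix(counts[setdiff(names(counts), "gene")])
    rownames(m) <- counts$gene
  } else {
    m <- as.matrix(counts)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("sample_", seq_len(ncol(m)))
  if (any(m < 0) || anyNA(m)) stop("counts must be nonnegative", call. = FALSE)
  log_geo <- rowMeans(log(m))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("no gene has a positive count in every sample; ",
         "compute factors from rescue-like centroids or total counts instead",
         call. = FALSE)
  }
  sf <- apply(m[use, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - log_geo[use]))
  })
  tibble::tibble(sample_id = colnames(m), size_factor = unname(sf))
}

#' Rescale fuzzy counts by a size factor
#'
#' Divides the four trapezoid parameters (and the centroid, when present)
#' of every gene by the sample's scaling factor; the ordering invariant
#' `A <= B <= C <= D` is preserved. The one-count support extension
#' (`A - 1`, `D + 1`) is applied at membership-evaluation time, not
#' stored, so it is unaffected by scaling.
#'
#' @param counts A fuzzy count table (see [fuzzy_counts()]).
#' @param size_factor A single positive scaling factor.
#' @return The rescaled fuzzy count table.
#' @export
normalize_counts <- function(counts, size_factor) {
  counts <- check_count_table(counts)
  if (!is.numeric(size_factor) || length(size_factor) != 1 ||
      !is.finite(size_factor) || size_factor <= 0) {
    stop("`size_factor` must be a single positive number", call. = FALSE)
  }
  dplyr::mutate(counts, dplyr::across(dplyr::any_of(c("A", "B", "C", "D", "centroid")),
                                      ~ .x / size_factor))
}
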