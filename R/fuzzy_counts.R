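# Per-read statistics needed by both the trapezoid construction and the
# rescue-like centroid, computed with base vectorized operations so large
# tables (hundreds of thousands of reads) stay fast.
#
# Adds to the table: n_refs (records for the read), best (read's top
# possibility), others_max (top possibility among the read's *other*
# records, -Inf for unique reads), w (centroid weight pi / sum pi).
read_stats <- function(mappings) {
  ord <- order(mappings$read_id, -mappings$possibility)
  m <- mappings[ord, ]
  first <- !duplicated(m$read_id)
  grp <- cumsum(first)
  starts <- which(first)
  sizes <- diff(c(starts, nrow(m) + 1L))

  best_g <- m$possibility[starts]
  second_g <- rep(-Inf, length(starts))
  has2 <- sizes >= 2L
  second_g[has2] <- m$possibility[starts[has2] + 1L]

  best <- best_g[grp]
  eq_best <- m$possibility == best
  n_at_best <- rowsum(as.numeric(eq_best), grp)[, 1][grp]
  others_max <- ifelse(eq_best & n_at_best == 1, second_g[grp], best)

  tot <- rowsum(m$possibility, grp)[, 1][grp]

  m$n_refs <- sizes[grp]
  m$best <- best
  m$others_max <- others_max
  m$w <- m$possibility / tot
  m
}

#' Trapezoidal fuzzy read counts for every gene of a sample
#'
#' Builds, for each gene, the four parameters of the trapezoidal fuzzy
#' read count `Tr[A, B, C, D]`:
#'
#' * `A` -- reads mapping uniquely to the gene (lowest possible count),
#' * `B` -- reads having the gene as *strict* best match,
#' * `C` -- reads having the gene as best match, ties included,
#' * `D` -- all reads with any record on the gene (highest possible count),
#'
#' so `A <= B <= C <= D`, membership is 1 on `[B, C]` and the support is
#' `(A - 1, D + 1)` (see [trapezoid_membership()]). The rescue-like
#' `centroid` assigns each read fractionally to its genes in proportion to
#' mapping possibility, so centroids sum to the number of mapped reads.
#'
#' @param mappings A mapping table (`read_id`, `reference_id`,
#'   `possibility`), e.g. from [read_blast_mappings()].
#' @param tie_tol Tolerance for best-match ties on the possibility scale:
#'   strict best means larger than every other record by more than
#'   `tie_tol`; ties count records within `tie_tol` of the read's best.
#' @param genes Optional character vector of genes the output must cover;
#'   genes without records get the zero trapezoid `Tr[0,0,0,0]`.
#' @return A tibble with columns `gene`, `A`, `B`, `C`, `D`, `centroid`,
#'   one row per gene, sorted by gene.
#' @examples
#' tab <- tibble::tibble(
#'   read_id = c("r1", "r2", "r2"),
#'   reference_id = c("g1", "g1", "g2"),
#'   possibility = c(1, 1, 0.8)
#' )
#' fuzzy_counts(tab)
#' @export
fuzzy_counts <- function(mappings, tie_tol = 1e-9, genes = NULL) {
  mappings <- as_mapping_table(mappings)
  if (nrow(mappings) == 0) {
    out <- tibble::tibble(gene = character(), A = double(), B = double(),
                          C = double(), D = double(), centroid = double())
  } else {
    st <- read_stats(mappings)
    out <- st |>
      dplyr::summarise(
        A = sum(.data$n_refs == 1),
        B = sum(.data$possibility > .data$others_max + tie_tol),
        C = sum(.data$possibility >= .data$best - tie_tol),
        D = dplyr::n(),
        centroid = sum(.data$w),
        .by = "reference_id"
      ) |>
      dplyr::rename(gene = "reference_id") |>
      dplyr::mutate(dplyr::across(c("A", "B", "C", "D"), as.double))
  }
  if (!is.null(genes)) {
    out <- tibble::tibble(gene = as.character(genes)) |>
      dplyr::left_join(out, by = "gene") |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ tidyr::replace_na(.x, 0)))
  }
  dplyr::arrange(out, .data$gene)
}

#' Fuzzy count of one gene
#'
#' Convenience wrapper around [fuzzy_counts()] returning the single row
#' for `gene`; a gene without records yields the zero trapezoid.
#'
#' @inheritParams fuzzy_counts
#' @param gene Gene identifier.
#' @return A one-row tibble `gene, A, B, C, D, centroid`.
#' @export
compute_abcd <- function(mappings, gene, tie_tol = 1e-9) {
  fuzzy_counts(mappings, tie_tol = tie_tol, genes = gene)
}

#' Exact discrete possibility distribution of a gene's read count
#'
#' The possibility that the gene's true read count equals `k` is the best
#' way of choosing `k` of the reads touching the gene as true matches and
#' all the others as false matches:
#' `max over |S| = k of min( min_{r in S} pi(r -> gene),
#' min_{r not in S} falsematch(r) )`, where `falsematch(r)` is the read's
#' best possibility on any *other* gene (0 for reads mapping only to this
#' gene). Computed by exact enumeration of all subsets, so it serves as
#' the independent oracle for the trapezoid construction: its support is
#' `[A, D]` and -- whenever each read's best alignment has possibility 1 --
#' its plateau is `[B, C]`.
#'
#' @inheritParams compute_abcd
#' @param max_reads Enumeration cap; genes touched by more reads than this
#'   raise an error directing the caller to the trapezoid approximation.
#' @return A tibble with columns `count` (0..n) and `possibility`.
#' @export
count_possibility <- function(mappings, gene, max_reads = 20) {
  mappings <- as_mapping_table(mappings)
  on_gene <- mappings[mappings$reference_id == gene, ]
  if (nrow(on_gene) == 0) {
    return(tibble::tibble(count = 0L, possibility = 1))
  }
  reads <- on_gene$read_id
  n <- length(reads)
  if (n > max_reads) {
    stop("gene `", gene, "` is touched by ", n, " reads (cap ", max_reads,
         "); use the trapezoid approximation from fuzzy_counts()", call. = FALSE)
  }
  pi_g <- on_gene$possibility
  elsewhere <- mappings[mappings$read_id %in% reads & mappings$reference_id != gene, ]
  fm <- rep(0, n)
  if (nrow(elsewhere) > 0) {
    fm_map <- dplyr::summarise(elsewhere, fm = max(.data$possibility), .by = "read_id")
    hit <- match(reads, fm_map$read_id)
    fm[!is.na(hit)] <- fm_map$fm[hit[!is.na(hit)]]
  }

  # enumerate every subset of the n reads as rows of a logical matrix
  masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  min_in <- do.call(pmin, c(lapply(seq_len(n), function(j) ifelse(masks[, j], pi_g[j], Inf)), list(1)))
  min_out <- do.call(pmin, c(lapply(seq_len(n), function(j) ifelse(masks[, j], Inf, fm[j])), list(1)))
  val <- pmin(min_in, min_out)
  k <- rowSums(masks)
  poss <- vapply(0:n, function(kk) max(val[k == kk]), numeric(1))
  tibble::tibble(count = 0:n, possibility = poss)
}

#' Rescue-like centroid counts
#'
#' Punctual count estimate distributing each read over its genes in
#' proportion to mapping possibility (a score-weighted variant of the
#' rescue method). Centroids sum to the total number of mapped reads and
#' each gene's centroid lies inside its trapezoid support `[A, D]`.
#'
#' @inheritParams fuzzy_counts
#' @return A tibble with columns `gene`, `centroid`.
#' @export
centroid_counts <- function(mappings, genes = NULL) {
  fuzzy_counts(mappings, genes = genes)[c("gene", "centroid")]
}
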