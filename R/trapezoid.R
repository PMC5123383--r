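#' Trapezoidal fuzzy-count membership
#'
#' Membership of count `x` in the trapezoidal fuzzy read count
#' `Tr[A', B, C, D']` with `A' = A - 1` and `D' = D + 1`: zero at or below
#' `A'` and at or above `D'`, one on `[B, C]`, linear on the shoulders.
#' The one-count extension gives counts `A` and `D` themselves non-null
#' possibility. Parameters may be non-integer (normalized counts);
#' membership at negative counts is always 0.
#'
#' @param x Count value(s) at which to evaluate the membership.
#' @param A,B,C,D Trapezoid parameters, `A <= B <= C <= D` (scalars or
#'   vectors recycled against `x`).
#' @return Membership degrees in \[0, 1\].
#' @export
trapezoid_membership <- function(x, A, B, C, D) {
  stopifnot(all(A <= B + 1e-12), all(B <= C + 1e-12), all(C <= D + 1e-12))
  Ap <- A - 1
  Dp <- D + 1
  y <- ifelse(x <= Ap | x >= Dp, 0,
       ifelse(x <= B, (x - Ap) / (B - Ap),
       ifelse(x < C, 1, (x - Dp) / (C - Dp))))
  y[x < 0] <- 0
  pmax(0, pmin(1, y))
}

# zero-filled full grid of count tables for merging
stack_counts <- function(tbls) {
  tbls <- purrr::map(tbls, check_count_table)
  genes <- sort(unique(unlist(purrr::map(tbls, "gene"))))
  purrr::map(tbls, function(tb) {
    tibble::tibble(gene = genes) |>
      dplyr::left_join(tb, by = "gene") |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ tidyr::replace_na(.x, 0)))
  }) |>
    dplyr::bind_rows()
}

check_count_table <- function(x) {
  need <- c("gene", "A", "B", "C", "D")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("a fuzzy count table needs columns gene, A, B, C, D", call. = FALSE)
  }
  bad <- with(x, A > B + 1e-9 | B > C + 1e-9 | C > D + 1e-9 | A < 0)
  if (any(bad)) stop("invalid trapezoid(s): need 0 <= A <= B <= C <= D", call. = FALSE)
  tibble::as_tibble(x)
}

#' Merge fuzzy counts across technical replicates
#'
#' Technical replicates are repeated sequencing runs of the same library;
#' as with crisp counts they merge by summation, here componentwise on the
#' four trapezoid parameters (and on the centroid when present). Genes
#' absent from a replicate contribute the zero trapezoid.
#'
#' @param ... Two or more fuzzy count tables (see [fuzzy_counts()]), or a
#'   single list of them.
#' @return A merged fuzzy count table over the union of genes.
#' @seealso [merge_biological()]
#' @export
merge_technical <- function(...) {
  tbls <- collect_tables(...)
  stack_counts(tbls) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of(c("A", "B", "C", "D", "centroid")), sum),
      .by = "gene"
    )
}

#' Merge fuzzy counts across biological replicates
#'
#' Biological replicates are different samples of the same condition. The
#' merged fuzzy count is the envelope trapezoid
#' `Tr[min A, min B, max C, max D]`: every count observed as fully
#' possible in any replicate stays fully possible, and -- because gene
#' expression varies continuously in time across non-independent cells --
#' intermediate values between disjoint replicate counts also receive full
#' possibility. The centroid of the merged count (when present) is the
#' mean of the replicate centroids. Idempotent, commutative, associative
#' on the trapezoid parameters.
#'
#' @inheritParams merge_technical
#' @return A merged fuzzy count table over the union of genes.
#' @export
merge_biological <- function(...) {
  tbls <- collect_tables(...)
  stack_counts(tbls) |>
    dplyr::summarise(
      A = min(.data$A), B = min(.data$B), C = max(.data$C), D = max(.data$D),
      dplyr::across(dplyr::any_of("centroid"), mean),
      .by = "gene"
    )
}

collect_tables <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.list(dots[[1]]) && !is.data.frame(dots[[1]])) {
    dots <- dots[[1]]
  }
  if (length(dots) < 1) stop("no count tables supplied", call. = FALSE)
  dots
}
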