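# Vectorized fuzzy fold-change endpoints. Subscript 1 = case, 2 = control.
# The support extension uses A' = max(A - 1, 0) and D' = D + 1; a zero A'
# yields an infinite endpoint (log2 of 0 or of Inf), which is a legal
# value reported as "-Inf"/"Inf". log2(0/0) is resolved to 0 (no evidence
# of change).
fc_endpoints <- function(A1, B1, C1, D1, A2, B2, C2, D2) {
  ap1 <- pmax(A1 - 1, 0)
  ap2 <- pmax(A2 - 1, 0)
  dp1 <- D1 + 1
  dp2 <- D2 + 1
  f1 <- log2(ap1 / dp2)
  f2 <- log2(B1 / C2)
  f3 <- log2(C1 / B2)
  f4 <- log2(dp1 / ap2)
  f2[B1 == 0 & C2 == 0] <- 0
  f3[C1 == 0 & B2 == 0] <- 0
  tibble::tibble(fc_f1 = f1, fc_f2 = f2, fc_f3 = f3, fc_f4 = f4)
}

#' Fuzzy fold change between two fuzzy read counts
#'
#' Extends the log2 fold change to trapezoidal fuzzy counts through the
#' extension principle, approximated by the trapezoid
#' `Tr[log2(A'1/D'2), log2(B1/C2), log2(C1/B2), log2(D'1/A'2)]`
#' (1 = case, 2 = control, primes the one-count support extension). The
#' wider the resulting fuzzy set, the more uncertain the fold change; the
#' farther from 0, the stronger the expression change. Zero counts
#' produce infinite endpoints, serialized as `"Inf"`/`"-Inf"`; the
#' possibility engine ([de_possibility()]) works on the two-dimensional
#' count relation and never consumes these values, so infinities affect
#' reporting only. Antisymmetric: swapping case and control negates and
#' reverses the four endpoints.
#'
#' @param case,control Fuzzy count tables of the two conditions (ideally
#'   normalized, see [normalize_counts()]). Genes missing from one side
#'   get the zero trapezoid.
#' @return A tibble `gene, fc_f1, fc_f2, fc_f3, fc_f4` with
#'   `fc_f1 <= fc_f2 <= fc_f3 <= fc_f4`.
#' @export
fuzzy_fold_change <- function(case, control) {
  case <- check_count_table(case)
  control <- check_count_table(control)
  both <- stack_pair(case, control)
  dplyr::bind_cols(
    both["gene"],
    fc_endpoints(both$A1, both$B1, both$C1, both$D1,
                 both$A2, both$B2, both$C2, both$D2)
  )
}

# full join of two count tables with zero fill, suffixing 1 = case, 2 = control
stack_pair <- function(case, control) {
  keep <- c("gene", "A", "B", "C", "D", intersect("centroid", intersect(names(case), names(control))))
  j <- dplyr::full_join(case[intersect(keep, names(case))],
                        control[intersect(keep, names(control))],
                        by = "gene", suffix = c("1", "2"))
  dplyr::mutate(j, dplyr::across(dplyr::where(is.numeric), ~ tidyr::replace_na(.x, 0))) |>
    dplyr::arrange(.data$gene)
}

#' Punctual log2 fold change on centroid counts
#'
#' `log2((case + pseudocount) / (control + pseudocount))`. With the
#' default pseudocount of 0 a zero on one side gives an infinite fold
#' change; a zero on both sides is returned as 0 (no evidence of change).
#'
#' @param case,control Nonnegative punctual (centroid) counts, recycled
#'   against each other.
#' @param pseudocount Nonnegative value added to both counts.
#' @return A numeric vector of log2 fold changes (may contain `Inf`).
#' @examples
#' punctual_fold_change(8, 2)  # 2
#' punctual_fold_change(43, 1) # log2(43)
#' @export
punctual_fold_change <- function(case, control, pseudocount = 0) {
  stopifnot(all(case >= 0), all(control >= 0), pseudocount >= 0)
  fc <- log2((case + pseudocount) / (control + pseudocount))
  fc[is.nan(fc)] <- 0
  fc
}
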