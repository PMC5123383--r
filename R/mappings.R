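#' Possibility degree of a single alignment from identity and coverage
#'
#' Scales BLAST-style percent identity and query coverage into a mapping
#' possibility in \[0, 1\]: the degree to which the read can actually
#' originate from the hit gene. The default score is the product
#' `identity/100 * coverage/100`, which is 1 exactly for a full-length
#' perfect match; `identity_only = TRUE` uses identity alone.
#'
#' @param identity_pct Percent identity of the alignment, in \[0, 100\].
#' @param coverage_pct Percent query coverage, in \[0, 100\]. Ignored when
#'   `identity_only = TRUE`.
#' @param identity_only Use identity alone instead of the
#'   identity-times-coverage product.
#' @return A numeric vector of possibility degrees in \[0, 1\].
#' @examples
#' mapping_possibility(99, 80)   # 0.792
#' mapping_possibility(100, 100) # 1
#' @export
mapping_possibility <- function(identity_pct, coverage_pct, identity_only = FALSE) {
  check_pct(identity_pct, "identity_pct")
  if (!identity_only) check_pct(coverage_pct, "coverage_pct")
  if (identity_only) identity_pct / 100 else (identity_pct / 100) * (coverage_pct / 100)
}

check_pct <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0) || any(x > 100)) {
    stop("`", name, "` must be finite and within [0, 100]", call. = FALSE)
  }
  invisible(x)
}

# Validate and canonicalize a mapping table: one row per (read, gene),
# possibility in (0, 1], duplicates collapsed to the best possibility.
as_mapping_table <- function(x, collapse = TRUE) {
  need <- c("read_id", "reference_id", "possibility")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop("a mapping table needs columns read_id, reference_id, possibility", call. = FALSE)
  }
  x <- tibble::as_tibble(x)[need]
  if (anyNA(x$possibility) || any(x$possibility > 1)) {
    stop("mapping possibilities must lie in (0, 1]", call. = FALSE)
  }
  if (any(x$possibility <= 0)) {
    n0 <- sum(x$possibility <= 0)
    warning(n0, " alignment(s) with possibility <= 0 dropped", call. = FALSE)
    x <- x[x$possibility > 0, ]
  }
  if (collapse && anyDuplicated(x[c("read_id", "reference_id")])) {
    x <- dplyr::summarise(x, possibility = max(.data$possibility),
                          .by = c("read_id", "reference_id"))
  }
  x
}

#' Read BLAST-style tabular alignments into a possibility table
#'
#' Parses a tab-separated alignment file (BLAST `outfmt 6` dialect, no
#' header) and converts each hit into a mapping possibility via
#' [mapping_possibility()]. Duplicate (read, gene) pairs are collapsed to
#' their best possibility; per-read possibilities are *not* renormalized,
#' so a read's best hit need not reach 1.
#'
#' @param path Path to the tabular file.
#' @param read_col,ref_col,identity_col,coverage_col 1-based column indices
#'   of the read identifier, subject identifier, percent identity and
#'   percent query coverage.
#' @param identity_only Passed to [mapping_possibility()].
#' @return A tibble with columns `read_id`, `reference_id`, `possibility`.
#' @seealso [read_sam_mappings()], [write_mappings()]
#' @export
read_blast_mappings <- function(path, read_col = 1, ref_col = 2,
                                identity_col = 3, coverage_col = 4,
                                identity_only = FALSE) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    warning("no alignments in ", path, call. = FALSE)
    return(tibble::tibble(read_id = character(), reference_id = character(),
                          possibility = double()))
  }
  need <- max(read_col, ref_col, identity_col, if (identity_only) 0 else coverage_col)
  if (ncol(raw) < need) {
    stop(path, ": expected at least ", need, " columns, found ", ncol(raw), call. = FALSE)
  }
  ident <- suppressWarnings(as.numeric(raw[[identity_col]]))
  cov <- if (identity_only) rep(100, nrow(raw)) else suppressWarnings(as.numeric(raw[[coverage_col]]))
  bad <- which(is.na(ident) | is.na(cov))
  if (length(bad) > 0) {
    stop(path, ": malformed row(s) at line ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  as_mapping_table(tibble::tibble(
    read_id = raw[[read_col]],
    reference_id = raw[[ref_col]],
    possibility = mapping_possibility(ident, cov, identity_only = identity_only)
  ))
}

#' Read SAM/BAM alignments into a possibility table
#'
#' Reads all mapped records (secondary alignments included) through
#' Rsamtools and converts per-alignment scores into mapping possibilities.
#' Two conventions are available:
#'
#' * `"mapq"` (default): possibility = MAPQ / 255, clamped to (0, 1];
#'   records with MAPQ 0 receive the floor `mapq_floor`. Note that most
#'   aligners assign MAPQ 0 to multireads, which flattens precisely the
#'   graded scores this representation wants -- kept as the default for the
#'   direct MAPQ-scaling convention, with `"tag"` as the recommended
#'   alternative.
#' * `"tag"`: the per-alignment score tag (default `AS`) is divided by the
#'   read's best score, so every read's best alignment has possibility 1.
#'   Requires nonnegative scores.
#'
#' @param path Path to a SAM or BAM file with secondary alignments kept.
#' @param score_mode `"mapq"` or `"tag"`.
#' @param tag Name of the alignment-score tag used in `"tag"` mode.
#' @param mapq_floor Possibility assigned to MAPQ-0 records in `"mapq"`
#'   mode (default 1/255).
#' @return A tibble with columns `read_id`, `reference_id`, `possibility`.
#' @export
read_sam_mappings <- function(path, score_mode = c("mapq", "tag"),
                              tag = "AS", mapq_floor = 1 / 255) {
  score_mode <- match.arg(score_mode)
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "mapq"),
    tag = if (score_mode == "tag") tag else character(),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(rec$qname) == 0) {
    warning("no mapped records in ", path, call. = FALSE)
    return(tibble::tibble(read_id = character(), reference_id = character(),
                          possibility = double()))
  }
  if (score_mode == "mapq") {
    q <- as.numeric(rec$mapq)
    q[is.na(q)] <- 0
    poss <- pmin(q / 255, 1)
    poss[poss <= 0] <- mapq_floor
  } else {
    s <- rec$tag[[tag]]
    if (is.null(s) || all(is.na(s))) {
      stop("score tag `", tag, "` absent from ", path, call. = FALSE)
    }
    if (anyNA(s)) stop("score tag `", tag, "` missing on some records in ", path, call. = FALSE)
    if (any(s < 0)) {
      stop("negative `", tag, "` scores cannot be scaled by the best score; ",
           "use an aligner scoring scheme with nonnegative scores", call. = FALSE)
    }
    best <- stats::ave(as.numeric(s), rec$qname, FUN = max)
    poss <- ifelse(best > 0, as.numeric(s) / best, 0)
  }
  as_mapping_table(tibble::tibble(
    read_id = as.character(rec$qname),
    reference_id = as.character(rec$rname),
    possibility = poss
  ))
}

#' Write / read the internal possibility-table TSV
#'
#' The internal dialect is a tab-separated file with a single header line
#' `read_id  reference_id  possibility`, `.` as decimal separator. Writing
#' then reading a table reproduces it exactly.
#'
#' @param mappings A mapping table (see [read_blast_mappings()]).
#' @param path File path.
#' @return `write_mappings()` returns `path` invisibly; `read_mappings()`
#'   returns the mapping tibble.
#' @export
write_mappings <- function(mappings, path) {
  mappings <- as_mapping_table(mappings, collapse = FALSE)
  readr::write_tsv(mappings, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_mappings
#' @export
read_mappings <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    read_id = readr::col_character(),
    reference_id = readr::col_character(),
    possibility = readr::col_double()
  ), progress = FALSE)
  if (nrow(tab) == 0) warning("empty possibility table: ", path, call. = FALSE)
  as_mapping_table(tab)
}

#' Write a mapping table as a minimal SAM file
#'
#' Emits one SAM record per mapping: the best record of each read is
#' primary, the others secondary (flag 0x100). MAPQ is the possibility
#' scaled to 0..255 and the `AS` tag carries the possibility scaled by
#' `score_scale`, so the file round-trips through [read_sam_mappings()] in
#' either mode (up to integer rounding). Intended for fixtures and
#' interoperability tests, not as a general-purpose SAM writer.
#'
#' @param mappings A mapping table.
#' @param path Output path (conventionally `.sam`).
#' @param score_scale Integer scale for the `AS` tag.
#' @return `path`, invisibly.
#' @export
write_sam_mappings <- function(mappings, path, score_scale = 60L) {
  mappings <- as_mapping_table(mappings)
  refs <- sort(unique(mappings$reference_id))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", refs, "\tLN:1000"))
  ord <- order(mappings$read_id, -mappings$possibility)
  m <- mappings[ord, ]
  primary <- !duplicated(m$read_id)
  rec <- paste(m$read_id,
               ifelse(primary, 0L, 256L),
               m$reference_id,
               1L, round(m$possibility * 255), "50M", "*", 0L, 0L, "*", "*",
               paste0("AS:i:", round(m$possibility * score_scale)),
               sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Summarize multiread content of a mapping table
#'
#' @param mappings A mapping table.
#' @return A one-row tibble: number of reads, number of genes, fraction of
#'   reads mapping to more than one gene, and fraction of genes touched by
#'   at least one multiread.
#' @export
multiread_stats <- function(mappings) {
  mappings <- as_mapping_table(mappings)
  nref <- dplyr::summarise(mappings, n = dplyr::n(), .by = "read_id")
  multi <- nref$read_id[nref$n > 1]
  genes_multi <- unique(mappings$reference_id[mappings$read_id %in% multi])
  tibble::tibble(
    n_reads = nrow(nref),
    n_genes = length(unique(mappings$reference_id)),
    multiread_read_frac = if (nrow(nref) > 0) length(multi) / nrow(nref) else 0,
    multiread_gene_frac = if (length(unique(mappings$reference_id)) > 0) {
      length(genes_multi) / length(unique(mappings$reference_id))
    } else 0
  )
}
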