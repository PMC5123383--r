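#' Read and validate a sample sheet
#'
#' The sample sheet is a TSV with one row per input alignment file and
#' columns `file`, `sample_id`, `condition` (`case` or `control`),
#' `replicate_kind` (`technical` or `biological`) and `format` (`blast`,
#' `sam` or `table`, the package's internal possibility-table TSV).
#' Technical replicates of the same library share a `sample_id` and are
#' merged by summation; distinct `sample_id`s within a condition are
#' biological replicates and are merged by the envelope rule.
#'
#' @param path Path to the sample sheet TSV.
#' @param base_dir Directory against which relative `file` paths are
#'   resolved (defaults to the sheet's directory).
#' @return A validated tibble.
#' @export
read_sample_sheet <- function(path, base_dir = dirname(path)) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  need <- c("file", "sample_id", "condition", "replicate_kind", "format")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", sheet$file)
  sheet$file[rel] <- file.path(base_dir, sheet$file[rel])
  validate_sheet(sheet)
}

validate_sheet <- function(sheet) {
  if (!all(sheet$condition %in% c("case", "control"))) {
    stop("`condition` must be 'case' or 'control'", call. = FALSE)
  }
  if (!all(sheet$replicate_kind %in% c("technical", "biological"))) {
    stop("`replicate_kind` must be 'technical' or 'biological'", call. = FALSE)
  }
  if (length(unique(sheet$condition)) < 2) {
    stop("both a case and a control condition are required", call. = FALSE)
  }
  cond_by_sample <- dplyr::summarise(sheet, n = dplyr::n_distinct(.data$condition),
                                     .by = "sample_id")
  if (any(cond_by_sample$n > 1)) {
    stop("a sample_id cannot span two conditions", call. = FALSE)
  }
  dup <- dplyr::summarise(sheet, n = dplyr::n(),
                          kinds = paste(sort(unique(.data$replicate_kind)), collapse = ","),
                          .by = "sample_id")
  if (any(dup$n > 1 & dup$kinds != "technical")) {
    stop("only technical replicates may share a sample_id", call. = FALSE)
  }
  tibble::as_tibble(sheet)
}

load_mapping_file <- function(file, format) {
  switch(format,
         blast = read_blast_mappings(file),
         sam = read_sam_mappings(file),
         table = read_mappings(file),
         stop("unknown mapping format `", format, "`", call. = FALSE))
}

#' Run the fuzzy differential-expression pipeline
#'
#' End-to-end analysis of a two-condition experiment: parse each sample
#' into a possibility table, build trapezoidal fuzzy counts and
#' rescue-like centroids, merge technical replicates by summation,
#' compute median-of-ratios size factors and rescale, merge biological
#' replicates by the envelope rule, fit the fold-change significance
#' envelope on the centroid MA cloud, and compute per gene the fuzzy fold
#' change plus the three DE possibilities by sup-min intersection.
#'
#' Rows are sorted by ascending same-expression possibility (most
#' reliable DE events first), ties broken by decreasing |centroid log2
#' FC| then by gene. Genes observed in only one condition carry the zero
#' trapezoid on the other side rather than being dropped. The run is
#' deterministic given inputs and parameters.
#'
#' @param samples One of: a path to a sample-sheet TSV
#'   ([read_sample_sheet()]), a sample-sheet data frame with a `file`
#'   column, or a named list of mapping tables (then `sheet` must
#'   describe them).
#' @param sheet When `samples` is a list of mapping tables: a data frame
#'   with columns `sample_id`, `condition`, `replicate_kind`, one row per
#'   list element (matched by name through an optional `sample` column,
#'   else by position).
#' @param q Quantile for the envelope fit ([fit_fc_threshold()]).
#' @param grid_n Grid resolution of the sup-min intersection.
#' @param tie_tol Best-match tie tolerance ([fuzzy_counts()]).
#' @param norm_source Counts feeding the size factors: `"centroid"`
#'   (rescue-like centroids), `"unique"` (genes untouched by multireads),
#'   or `"auto"` (unique when multireads are sporadic, i.e. fewer than
#'   `sporadic_threshold` of reads, centroid otherwise).
#' @param sporadic_threshold Multiread fraction below which `"auto"` uses
#'   unique counts.
#' @param pseudocount Pseudocount for the punctual centroid fold change.
#' @param min_possibility Optional filter: keep genes whose
#'   over- or under-expression possibility reaches this value.
#' @param min_abs_fc Optional filter: keep genes with |centroid log2 FC|
#'   above this value.
#' @param direction `"case-over-control"` (default: over-expression means
#'   case above control) or `"control-over-case"` (swaps the two sigmoid
#'   labels).
#' @return An object of class `fuzzy_de`: a list with `results` (the
#'   ranked gene table), `model` (the fitted `fc_threshold`),
#'   `size_factors`, `stats` (multiread diagnostics) and `params`.
#'   `tidy()` returns the result table, `glance()` a one-row summary,
#'   `autoplot()` an annotated MA plot.
#' @export
fuzzy_de <- function(samples, sheet = NULL, q = 0.99, grid_n = 64,
                     tie_tol = 1e-9,
                     norm_source = c("auto", "centroid", "unique"),
                     sporadic_threshold = 0.01, pseudocount = 0,
                     min_possibility = NULL, min_abs_fc = NULL,
                     direction = c("case-over-control", "control-over-case")) {
  norm_source <- match.arg(norm_source)
  direction <- match.arg(direction)

  # --- resolve inputs into mapping tables + metadata -----------------
  if (is.character(samples) && length(samples) == 1) {
    samples <- read_sample_sheet(samples)
  }
  if (is.data.frame(samples)) {
    sheet <- validate_sheet(samples)
    tables <- purrr::map2(sheet$file, sheet$format, load_mapping_file)
  } else if (is.list(samples)) {
    if (is.null(sheet)) stop("`sheet` is required when `samples` is a list of tables", call. = FALSE)
    sheet <- tibble::as_tibble(sheet)
    if (!"sample" %in% names(sheet)) sheet$sample <- names(samples) %||% as.character(seq_along(samples))
    idx <- match(sheet$sample, names(samples) %||% as.character(seq_along(samples)))
    if (anyNA(idx)) stop("`sheet$sample` does not match the names of `samples`", call. = FALSE)
    sheet$condition <- as.character(sheet$condition)
    sheet$replicate_kind <- as.character(sheet$replicate_kind)
    if (length(unique(sheet$condition)) < 2) {
      stop("both a case and a control condition are required", call. = FALSE)
    }
    tables <- purrr::map(samples[idx], as_mapping_table)
  } else {
    stop("`samples` must be a sheet path, a sample sheet, or a list of mapping tables",
         call. = FALSE)
  }

  genes_per_table <- purrr::map(tables, ~ unique(.x$reference_id))
  genes <- sort(unique(unlist(genes_per_table)))
  if (length(genes) == 0) stop("no genes found in any sample", call. = FALSE)
  if (length(purrr::reduce(genes_per_table, intersect)) == 0) {
    stop("no gene is shared across all samples", call. = FALSE)
  }

  # --- multiread diagnostics ----------------------------------------
  mstats <- purrr::map(tables, multiread_stats) |> dplyr::bind_rows()
  total_reads <- sum(mstats$n_reads)
  stats <- list(
    n_genes = length(genes),
    n_inputs = length(tables),
    total_reads = total_reads,
    multiread_read_frac = sum(mstats$multiread_read_frac * mstats$n_reads) / total_reads,
    multiread_gene_frac = length(unique(unlist(purrr::map(
      tables, ~ unique(.x$reference_id[.x$read_id %in%
        .x$read_id[duplicated(.x$read_id)]]))))) / length(genes)
  )

  # --- fuzzy counts, technical merge --------------------------------
  counts <- purrr::map(tables, fuzzy_counts, tie_tol = tie_tol, genes = genes)
  by_sample <- split(seq_along(counts), sheet$sample_id)
  sample_counts <- purrr::map(by_sample, function(ix) {
    if (length(ix) == 1) counts[[ix]] else merge_technical(counts[ix])
  })
  sample_cond <- purrr::map_chr(by_sample, ~ sheet$condition[.x[1]])

  # --- normalization ------------------------------------------------
  if (norm_source == "auto") {
    norm_source <- if (stats$multiread_read_frac < sporadic_threshold) "unique" else "centroid"
  }
  mat <- purrr::map(sample_counts, "centroid") |> do.call(what = cbind)
  dimnames(mat) <- list(sample_counts[[1]]$gene, names(sample_counts))
  if (norm_source == "unique") {
    a_mat <- purrr::map(sample_counts, "A") |> do.call(what = cbind)
    d_mat <- purrr::map(sample_counts, "D") |> do.call(what = cbind)
    pure <- rowSums(a_mat == d_mat) == ncol(a_mat)
    if (!any(pure & rowSums(a_mat > 0) == ncol(a_mat))) {
      stop("no multiread-free gene is positive in every sample; ",
           "use norm_source = \"centroid\"", call. = FALSE)
    }
    mat <- a_mat[pure, , drop = FALSE]
    dimnames(mat) <- list(sample_counts[[1]]$gene[pure], names(sample_counts))
  }
  sf <- size_factors(mat)
  stats$norm_source <- norm_source
  normed <- purrr::map2(sample_counts, sf$size_factor, normalize_counts)

  # --- biological merge per condition -------------------------------
  case_counts <- merge_biological(normed[sample_cond == "case"])
  control_counts <- merge_biological(normed[sample_cond == "control"])

  # --- envelope model ------------------------------------------------
  # With replicates the fold-change variability envelope is estimated
  # from within-condition replicate comparisons, which carry no induced
  # expression change by construction; without replicates it falls back
  # to the case-control cloud, whose DE minority the fit trims as
  # outliers.
  env_pts <- list()
  for (cond in c("case", "control")) {
    ix <- which(sample_cond == cond)
    if (length(ix) >= 2) {
      cents <- purrr::map(normed[ix], "centroid")
      pairs <- utils::combn(length(ix), 2, simplify = FALSE)
      env_pts <- c(env_pts, purrr::map(pairs, function(p) {
        tibble::tibble(
          mean_expr = (cents[[p[1]]] + cents[[p[2]]]) / 2,
          log2fc = punctual_fold_change(cents[[p[1]]], cents[[p[2]]],
                                        pseudocount = pseudocount)
        )
      }))
    }
  }
  env_pts <- dplyr::bind_rows(env_pts)
  cent <- dplyr::inner_join(case_counts[c("gene", "centroid")],
                            control_counts[c("gene", "centroid")],
                            by = "gene", suffix = c("_case", "_control"))
  cent$log2fc <- punctual_fold_change(cent$centroid_case, cent$centroid_control,
                                      pseudocount = pseudocount)
  cent$mean_expr <- (cent$centroid_case + cent$centroid_control) / 2
  model <- tryCatch({
    if (nrow(env_pts) >= 50) {
      stats$envelope_source <- "replicates"
      fit_fc_threshold(env_pts, q = q)
    } else {
      stats$envelope_source <- "case-control"
      fit_fc_threshold(cent, q = q)
    }
  }, error = function(e) {
    warning("envelope fit failed (", conditionMessage(e),
            "); using the default conservative envelope", call. = FALSE)
    stats$envelope_source <<- "default"
    default_fc_threshold()
  })

  # --- possibilities, fuzzy fold change, assembly -------------------
  poss <- de_possibility(case_counts, control_counts, model, grid_n = grid_n)
  if (direction == "control-over-case") {
    poss <- dplyr::rename(poss, p_under = "p_over", p_over = "p_under")
  }
  ffc <- fuzzy_fold_change(case_counts, control_counts)

  results <- case_counts |>
    dplyr::select("gene", case_A = "A", case_B = "B", case_C = "C", case_D = "D",
                  case_centroid = "centroid") |>
    dplyr::inner_join(
      dplyr::select(control_counts, "gene", control_A = "A", control_B = "B",
                    control_C = "C", control_D = "D", control_centroid = "centroid"),
      by = "gene") |>
    dplyr::inner_join(ffc, by = "gene") |>
    dplyr::inner_join(poss, by = "gene") |>
    dplyr::mutate(log2fc_centroid = punctual_fold_change(
      .data$case_centroid, .data$control_centroid, pseudocount = pseudocount)) |>
    dplyr::relocate("case_centroid", "control_centroid", "log2fc_centroid",
                    .after = "p_over") |>
    dplyr::arrange(.data$p_same, dplyr::desc(abs(.data$log2fc_centroid)), .data$gene)

  if (!is.null(min_possibility)) {
    results <- dplyr::filter(results, pmax(.data$p_over, .data$p_under) >= min_possibility)
  }
  if (!is.null(min_abs_fc)) {
    results <- dplyr::filter(results, abs(.data$log2fc_centroid) > min_abs_fc)
  }

  structure(list(results = results, model = model, size_factors = sf,
                 stats = stats,
                 params = list(q = q, grid_n = grid_n, tie_tol = tie_tol,
                               sporadic_threshold = sporadic_threshold,
                               pseudocount = pseudocount,
                               min_possibility = min_possibility,
                               min_abs_fc = min_abs_fc, direction = direction)),
            class = "fuzzy_de")
}

#' @export
print.fuzzy_de <- function(x, ...) {
  cat("<fuzzy_de> possibilistic differential expression\n")
  cat(sprintf("  %d genes, %d input samples; %.1f%% multireads touching %.1f%% of genes\n",
              x$stats$n_genes, x$stats$n_inputs,
              100 * x$stats$multiread_read_frac, 100 * x$stats$multiread_gene_frac))
  cat("  size factors:",
      paste(sprintf("%s=%.3f", x$size_factors$sample_id, x$size_factors$size_factor),
            collapse = ", "), "\n")
  cat("  top of ranking (lowest same-expression possibility):\n")
  print(utils::head(x$results[c("gene", "p_under", "p_same", "p_over", "log2fc_centroid")], 5))
  invisible(x)
}

#' Tidy a fuzzy differential-expression run
#'
#' @param x A `fuzzy_de` object.
#' @param ... Unused.
#' @return `tidy()`: the ranked per-gene result table; `glance()`: a
#'   one-row run summary.
#' @method tidy fuzzy_de
#' @export
tidy.fuzzy_de <- function(x, ...) x$results

#' @rdname tidy.fuzzy_de
#' @method glance fuzzy_de
#' @export
glance.fuzzy_de <- function(x, ...) {
  tibble::tibble(
    n_genes = x$stats$n_genes,
    n_inputs = x$stats$n_inputs,
    total_reads = x$stats$total_reads,
    multiread_read_frac = x$stats$multiread_read_frac,
    multiread_gene_frac = x$stats$multiread_gene_frac,
    norm_source = x$stats$norm_source,
    envelope = x$model$type
  )
}

#' Write the ranked result table
#'
#' One row per gene in the fixed column order (gene, the four normalized
#' case trapezoid values, the four control values, the four fuzzy
#' fold-change values, the three DE possibilities, the two centroids and
#' the centroid log2 FC), 6 significant digits, `Inf`/`-Inf` literals,
#' tab-separated, preceded by comment lines recording the size factors.
#' Byte-identical across runs on identical input.
#'
#' @param x A `fuzzy_de` object or a result tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  res <- if (inherits(x, "fuzzy_de")) x$results else tibble::as_tibble(x)
  hdr <- character()
  if (inherits(x, "fuzzy_de")) {
    hdr <- c(sprintf("# size_factor\t%s\t%s", x$size_factors$sample_id,
                     format(signif(x$size_factors$size_factor, 6))),
             sprintf("# norm_source\t%s", x$stats$norm_source))
  }
  out <- dplyr::mutate(res, dplyr::across(dplyr::where(is.numeric),
                                          ~ as.character(signif(.x, 6))))
  body <- c(paste(names(out), collapse = "\t"),
            if (nrow(out) > 0) do.call(paste, c(unclass(out), sep = "\t")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, comment = "#",
                  col_types = readr::cols(gene = readr::col_character(),
                                          .default = readr::col_double()),
                  progress = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
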