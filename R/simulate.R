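#' Simulate a two-condition experiment with known ground truth
#'
#' Generates per-sample possibility tables emulating a case-control
#' RNA-Seq experiment with paralog-driven multireads: reads are abstract
#' records (no sequences, no aligner), emitted directly at the
#' possibility-table stage. Each gene draws a baseline expression level;
#' a chosen set of genes receives an induced log2 fold change, split
#' symmetrically across conditions (case scaled by `2^(fc/2)`, control by
#' `2^(-fc/2)`), and per-replicate counts are Poisson. Genes in paralog
#' families share reads: a `multiread_fraction` of each family gene's
#' reads gains a decoy record on another family member, with possibility
#' `1 - |N(0, score_noise)|` clamped to (0.5, 1); the true record always
#' has possibility 1, mimicking near-perfect decoy alignments.
#'
#' Defaults mirror a small-scale version of a 2-replicate, 10-over /
#' 10-under (log2 FC of +1 / -1) simulation, with DE baselines large
#' enough that two-replicate Poisson noise on the induced fold change is
#' well below the induced size.
#'
#' @param n_genes Number of genes.
#' @param n_families Number of paralog families (reads shared within).
#' @param family_size Genes per family.
#' @param mu_null Median baseline reads per null gene (lognormal).
#' @param mu_sdlog Lognormal spread of the null baselines.
#' @param mu_de Range (length 2) of the uniform DE-gene baselines.
#' @param n_de_over,n_de_under Numbers of over-/under-expressed genes.
#' @param induced_log2fc Magnitude of the induced log2 fold change.
#' @param multiread_fraction Fraction of family-gene reads gaining a
#'   decoy record.
#' @param score_noise Standard deviation of the decoy possibility jitter.
#' @param n_replicates Biological replicates per condition.
#' @param seed Integer seed; fixed seed, identical output.
#' @return A list with `samples` (named list of mapping tibbles, one per
#'   replicate), `sheet` (metadata tibble for [fuzzy_de()]), `truth`
#'   (gene, condition, replicate, true_count, induced_log2fc) and
#'   `de_genes` (gene, induced_log2fc).
#' @examples
#' sim <- simulate_experiment(n_genes = 30, n_families = 5, mu_null = 30,
#'                            mu_de = c(100, 150), n_de_over = 2,
#'                            n_de_under = 2, seed = 7)
#' names(sim$samples)
#' @export
simulate_experiment <- function(n_genes = 250, n_families = 50, family_size = 2,
                                mu_null = 120, mu_sdlog = 0.7,
                                mu_de = c(1500, 2500),
                                n_de_over = 10, n_de_under = 10,
                                induced_log2fc = 1,
                                multiread_fraction = 0.2, score_noise = 0.15,
                                n_replicates = 2, seed = 1) {
  if (n_families * family_size > n_genes) {
    stop("n_families * family_size exceeds n_genes", call. = FALSE)
  }
  if (n_de_over + n_de_under > n_genes) stop("more DE genes than genes", call. = FALSE)
  stopifnot(induced_log2fc > 0, multiread_fraction >= 0, multiread_fraction <= 1)

  withr::with_seed(seed, {
    genes <- sprintf("gene-%04d", seq_len(n_genes))

    fam_members <- sample(genes, n_families * family_size)
    family_of <- stats::setNames(rep(NA_integer_, n_genes), genes)
    family_of[fam_members] <- rep(seq_len(max(n_families, 1)), each = family_size)[
      seq_along(fam_members)]
    partners <- lapply(stats::setNames(fam_members, fam_members), function(g) {
      setdiff(fam_members[family_of[fam_members] == family_of[g]], g)
    })

    de <- sample(genes, n_de_over + n_de_under)
    fc_of <- stats::setNames(rep(0, n_genes), genes)
    fc_of[de] <- rep(c(induced_log2fc, -induced_log2fc),
                     c(n_de_over, n_de_under))

    mu <- stats::setNames(stats::rlnorm(n_genes, log(mu_null), mu_sdlog), genes)
    mu[de] <- stats::runif(length(de), mu_de[1], mu_de[2])

    conds <- c("case", "control")
    samples <- list()
    truth <- list()
    for (cond in conds) {
      sign_ <- if (cond == "case") 0.5 else -0.5
      for (r in seq_len(n_replicates)) {
        sname <- paste0(cond, "_", r)
        lambda <- mu * 2^(sign_ * fc_of)
        n_r <- stats::rpois(n_genes, lambda)
        true_gene <- rep(genes, n_r)
        n_reads <- length(true_gene)
        read_id <- sprintf("%s_r%07d", sname, seq_len(n_reads))

        in_fam <- true_gene %in% fam_members
        decoy_sel <- in_fam & stats::runif(n_reads) < multiread_fraction
        di <- which(decoy_sel)
        decoy_gene <- vapply(true_gene[di], function(g) {
          p <- partners[[g]]
          if (length(p) == 1) p else sample(p, 1)
        }, character(1))
        decoy_poss <- pmin(pmax(1 - abs(stats::rnorm(length(di), 0, score_noise)),
                                0.5 + 1e-6), 1 - 1e-6)

        samples[[sname]] <- tibble::tibble(
          read_id = c(read_id, read_id[di]),
          reference_id = c(true_gene, decoy_gene),
          possibility = c(rep(1, n_reads), decoy_poss)
        )
        truth[[sname]] <- tibble::tibble(
          gene = genes, condition = cond, replicate = r,
          true_count = as.integer(table(factor(true_gene, levels = genes))),
          induced_log2fc = unname(fc_of)
        )
      }
    }

    list(
      samples = samples,
      sheet = tibble::tibble(
        sample = names(samples),
        sample_id = names(samples),
        condition = sub("_[0-9]+$", "", names(samples)),
        replicate_kind = "biological"
      ),
      truth = dplyr::bind_rows(truth),
      de_genes = tibble::tibble(gene = de, induced_log2fc = unname(fc_of[de]))
    )
  })
}

#' Write a simulated experiment to disk
#'
#' Materializes a [simulate_experiment()] result as one possibility-table
#' TSV per sample plus `sheet.tsv` (ready for [fuzzy_de()] or the
#' `fuzzydea` command-line script) and `truth.tsv`.
#'
#' @param sim A list from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return The path of the written sample sheet, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::imap_chr(sim$samples, function(tab, name) {
    f <- file.path(dir, paste0(name, ".tsv"))
    write_mappings(tab, f)
    paste0(name, ".tsv")
  })
  sheet <- dplyr::mutate(sim$sheet, file = unname(files[.data$sample]),
                         format = "table") |>
    dplyr::select("file", "sample_id", "condition", "replicate_kind", "format")
  readr::write_tsv(sheet, file.path(dir, "sheet.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(file.path(dir, "sheet.tsv"))
}
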