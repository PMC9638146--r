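#' Two-group comparison of label-free EV proteomes
#'
#' The package's central estimator. Takes an identification table holding the
#' replicate runs of two groups, quantifies each group with emPAI-based molar
#' percentages ([quantify_group()]), partitions the detected proteins into
#' unique and shared sets, and, for every shared protein, computes the fold
#' change of group mean M%, its absolute value and abundance class at the
#' cutoff, and an unpaired t-test over the detected-run M% values with
#' optional multiplicity adjustment.
#'
#' @param id_table Identification table (data frame or path readable by
#'   [read_id_table()]) with the runs of both groups.
#' @param database Protein database from [read_fasta_db()] (or a FASTA path).
#' @param groups Character vector of length 2 naming group A and group B, in
#'   that order. Default: the two group labels in order of appearance.
#' @param digest [digest_params()] for the observable-peptide counts.
#' @param cutoff Absolute fold-change cutoff for biological significance
#'   (default 1.3).
#' @param alpha Significance threshold for the t-tests (default 0.05).
#' @param test `"pooled"` (default) or `"welch"` t-test variant.
#' @param adjust `"none"` (default), `"holm_sidak"`, or `"BH"`.
#' @param normalize M% normalization mode passed to [quantify_group()].
#'
#' @return An object of class `ev_compare`: a list with components
#'   `quant_a`, `quant_b` (per-group [quantify_group()] results),
#'   `partition` (an `ev_partition`), `comparison` (one row per shared
#'   protein: means, `n_a`/`n_b`, `ratio`, `log2_ratio`, `abs_fc`, `klass`,
#'   `p_value`, `p_adjusted`, `significant`), `groups`, `cutoff`, `alpha`,
#'   `test`, `adjust`, and the matched `call`.
#' @seealso [summary.ev_compare()], [plot.ev_compare()], [volcano_table()]
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 40, seed = 1))
#' fit <- ev_compare(sim$tables, sim$proteome)
#' fit
#' @export
ev_compare <- function(id_table, database, groups = NULL,
                       digest = digest_params(), cutoff = 1.3, alpha = 0.05,
                       test = c("pooled", "welch"),
                       adjust = c("none", "holm_sidak", "BH"),
                       normalize = "per_run") {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (is.character(id_table)) id_table <- read_id_table(id_table)
  if (is.character(database)) database <- read_fasta_db(database)
  found <- unique(id_table$group)
  if (is.null(groups)) groups <- found
  if (length(groups) != 2L || !all(groups %in% found)) {
    stop("expected exactly two group labels present in the table; got: ",
         paste(found, collapse = ", "), call. = FALSE)
  }
  quant_a <- quantify_group(id_table[id_table$group == groups[1L], ],
                            database, digest, normalize)
  quant_b <- quantify_group(id_table[id_table$group == groups[2L], ],
                            database, digest, normalize)
  part <- partition_detected(quant_a$accession, quant_b$accession)

  shared <- part$shared
  ia <- match(shared, quant_a$accession)
  ib <- match(shared, quant_b$accession)
  fc <- fold_change(quant_a$mean_molar_pct[ia], quant_b$mean_molar_pct[ib],
                    cutoff)
  pr_a <- attr(quant_a, "per_run")
  pr_b <- attr(quant_b, "per_run")
  vals_a <- split(pr_a$molar_pct, factor(pr_a$accession, levels = shared))
  vals_b <- split(pr_b$molar_pct, factor(pr_b$accession, levels = shared))
  tests <- protein_tests(vals_a, vals_b, method = test, adjust = adjust)
  p_used <- if (adjust == "none") tests$p_value else tests$p_adjusted
  comparison <- data.frame(
    accession = shared,
    gene_symbol = quant_a$gene_symbol[ia],
    mean_a = quant_a$mean_molar_pct[ia],
    mean_b = quant_b$mean_molar_pct[ib],
    n_a = quant_a$n[ia], n_b = quant_b$n[ib],
    fc,
    p_value = tests$p_value, p_adjusted = tests$p_adjusted,
    significant = !is.na(p_used) & p_used < alpha & fc$abs_fc >= cutoff,
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(quant_a = quant_a, quant_b = quant_b, partition = part,
                 comparison = comparison, groups = groups, cutoff = cutoff,
                 alpha = alpha, test = test, adjust = adjust,
                 call = match.call()),
            class = "ev_compare")
}

#' @export
print.ev_compare <- function(x, ...) {
  cat("Two-group emPAI comparison:", x$groups[1L], "(A) vs", x$groups[2L],
      "(B)\n")
  k <- x$partition$counts
  cat(sprintf("  detected: %d in A, %d in B (union %d)\n",
              k[1L] + k[2L], k[2L] + k[3L], sum(k)))
  cat(sprintf("  partition: %d unique to A, %d shared, %d unique to B\n",
              k[1L], k[2L], k[3L]))
  kl <- table(x$comparison$klass)
  cat(sprintf("  abs FC >= %.2g: %d increased in A, %d increased in B; %d below cutoff\n",
              x$cutoff, kl[["increased_in_A"]], kl[["increased_in_B"]],
              kl[["below_cutoff"]]))
  cat(sprintf("  significant (p < %.3g & abs FC >= %.2g, %s t-test, adjust = %s): %d\n",
              x$alpha, x$cutoff, x$test, x$adjust,
              sum(x$comparison$significant)))
  invisible(x)
}

#' Summarize a two-group comparison
#'
#' @param object An `ev_compare` object.
#' @param ... Unused.
#' @return An object of class `summary.ev_compare` with the partition, class
#'   counts, test counts, and the significant proteins ordered by p-value.
#' @export
summary.ev_compare <- function(object, ...) {
  comp <- object$comparison
  sig <- comp[comp$significant, , drop = FALSE]
  sig <- sig[order(sig$p_value), , drop = FALSE]
  structure(list(groups = object$groups, partition = object$partition,
                 klass_counts = table(comp$klass),
                 n_tested = sum(!is.na(comp$p_value)),
                 n_not_testable = sum(is.na(comp$p_value)),
                 n_significant = sum(comp$significant),
                 significant = sig, cutoff = object$cutoff,
                 alpha = object$alpha, test = object$test,
                 adjust = object$adjust),
            class = "summary.ev_compare")
}

#' @export
print.summary.ev_compare <- function(x, ...) {
  cat("Two-group emPAI comparison:", x$groups[1L], "(A) vs", x$groups[2L],
      "(B)\n\n")
  print(x$partition)
  cat("\nAbundance classes at abs FC cutoff", x$cutoff, "\n")
  print(x$klass_counts)
  cat("\n", x$n_tested, " shared proteins testable (>= 2 runs/group), ",
      x$n_not_testable, " not testable\n", sep = "")
  cat(x$n_significant, " significant at alpha = ", x$alpha, " (", x$test,
      " t-test, adjust = ", x$adjust, ")\n", sep = "")
  if (nrow(x$significant)) {
    cat("\nTop significant proteins:\n")
    cols <- c("accession", "gene_symbol", "mean_a", "mean_b", "abs_fc",
              "klass", "p_value", "p_adjusted")
    print(utils::head(x$significant[cols], 10L), row.names = FALSE,
          digits = 4)
  }
  invisible(x)
}

#' @export
coef.ev_compare <- function(object, ...) {
  stats::setNames(object$comparison$log2_ratio, object$comparison$accession)
}

#' Volcano plot of a two-group comparison
#'
#' log2 fold change against -log10 p-value for the tested shared proteins,
#' with dashed guides at the fold-change cutoff and the significance
#' threshold; significant proteins drawn filled.
#'
#' @param x An `ev_compare` object.
#' @param use_adjusted Plot adjusted p-values (default follows the fit's
#'   `adjust` setting).
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.ev_compare <- function(x, use_adjusted = x$adjust != "none", ...) {
  volc <- volcano_table(x$comparison, alpha = x$alpha, cutoff = x$cutoff,
                        use_adjusted = use_adjusted)
  plot(volc$log2_ratio, volc$neg_log10_p,
       pch = ifelse(volc$significant, 19, 1),
       col = ifelse(volc$significant, "firebrick", "grey40"),
       xlab = expression(log[2] ~ "fold change (A / B)"),
       ylab = expression(-log[10] ~ italic(p)), ...)
  abline(v = c(-1, 1) * log2(x$cutoff), lty = 2, col = "grey60")
  abline(h = -log10(x$alpha), lty = 2, col = "grey60")
  invisible(x)
}

#' Write the comparison report
#'
#' TSV with one row per shared protein: means, per-group sample sizes, ratio,
#' log2 ratio, absolute fold change, abundance class, p-values, and the
#' significance flag.
#'
#' @param fit An `ev_compare` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(fit, path) {
  .write_tsv(fit$comparison, path)
}
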