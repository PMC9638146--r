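#' Partition detected proteins of two groups
#'
#' Venn-style partition of the detected proteins (detected = identified in at
#' least one run of a group) into unique-to-A, shared, and unique-to-B cells,
#' with counts and percentages of the union.
#'
#' @param detected_a,detected_b Character vectors of accessions detected in
#'   each group.
#' @return An object of class `ev_partition`: list with `unique_a`, `shared`,
#'   `unique_b` (sorted accession vectors), `counts`, and `pct` (percentages
#'   of the union, unrounded).
#' @examples
#' partition_detected(c("p1", "p2", "p3"), c("p2", "p3", "p4"))
#' @export
partition_detected <- function(detected_a, detected_b) {
  a <- unique(as.character(detected_a))
  b <- unique(as.character(detected_b))
  res <- list(unique_a = sort(setdiff(a, b)),
              shared = sort(intersect(a, b)),
              unique_b = sort(setdiff(b, a)))
  counts <- lengths(res)
  total <- sum(counts)
  pct <- if (total > 0) 100 * counts / total else counts * NA_real_
  structure(c(res, list(counts = counts, pct = pct)), class = "ev_partition")
}

#' @export
print.ev_partition <- function(x, ...) {
  cat("Protein partition (union = ", sum(x$counts), " proteins)\n", sep = "")
  cells <- data.frame(cell = c("unique to A", "shared", "unique to B"),
                      n = as.integer(x$counts),
                      pct_of_union = round(x$pct, 1))
  print(cells, row.names = FALSE)
  invisible(x)
}

#' Fold change and abundance classification
#'
#' For shared proteins, the fold change is the ratio of the group mean M%
#' values, A over B. The absolute fold change removes direction:
#' `abs_fc = 2^|log2(ratio)| = max(ratio, 1/ratio) >= 1`. Proteins with
#' `abs_fc >= cutoff` (inclusive) are classified as increased in A or
#' increased in B by the sign of the log2 ratio; the rest fall below the
#' cutoff. The default cutoff of 1.3 reflects the smallest fold difference
#' that emPAI-based quantification classifies reliably.
#'
#' @param mean_a,mean_b Positive group mean M% vectors (same length).
#' @param cutoff Biological-significance cutoff on `abs_fc` (default 1.3).
#' @return Data frame with `ratio`, `log2_ratio`, `abs_fc`, and `klass`
#'   (factor: `increased_in_A`, `increased_in_B`, `below_cutoff`).
#' @examples
#' fold_change(2, 1)   # abs_fc 2, increased_in_A
#' @export
fold_change <- function(mean_a, mean_b, cutoff = 1.3) {
  stopifnot(length(mean_a) == length(mean_b), cutoff >= 1)
  if (any(mean_a <= 0) || any(mean_b <= 0)) {
    stop("fold change requires positive mean abundances in both groups",
         call. = FALSE)
  }
  ratio <- mean_a / mean_b
  abs_fc <- pmax(ratio, 1 / ratio)
  # exact ties (ratio == 1) have no direction and stay below the cutoff even
  # at cutoff = 1
  klass <- ifelse(abs_fc < cutoff | ratio == 1, "below_cutoff",
                  ifelse(ratio > 1, "increased_in_A", "increased_in_B"))
  data.frame(ratio = ratio, log2_ratio = log2(ratio), abs_fc = abs_fc,
             klass = factor(klass, levels = c("increased_in_A",
                                              "increased_in_B",
                                              "below_cutoff")))
}

#' Per-protein two-sample t-tests
#'
#' Unpaired t-test on the detected-run M% values of each protein, with
#' pooled-variance (default, matching the row-wise multiple-t-test default of
#' common spreadsheet statistics tools) or Welch variants, and optional
#' family-wise (Holm-Sidak) or FDR (Benjamini-Hochberg) adjustment across all
#' tested proteins. A protein needs at least two detected runs per group to
#' be testable; otherwise its p-value is `NA`.
#'
#' @param values_a,values_b Lists of numeric vectors (per-run M% of each
#'   protein, detected runs only), parallel to each other.
#' @param method `"pooled"` or `"welch"`.
#' @param adjust `"none"`, `"holm_sidak"`, or `"BH"`.
#' @return Data frame with `p_value`, `p_adjusted`, `testable`.
#' @export
protein_tests <- function(values_a, values_b,
                          method = c("pooled", "welch"),
                          adjust = c("none", "holm_sidak", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  stopifnot(length(values_a) == length(values_b))
  p <- mapply(function(x, y) {
    if (length(x) < 2L || length(y) < 2L) return(NA_real_)
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) {
        message("zero variance in both groups with equal means; p = 1")
        return(1)
      }
      return(0)
    }
    stats::t.test(x, y, var.equal = (method == "pooled"))$p.value
  }, values_a, values_b)
  padj <- switch(adjust,
                 none = p,
                 holm_sidak = holm_sidak(p),
                 BH = stats::p.adjust(p, method = "BH"))
  data.frame(p_value = unname(p), p_adjusted = unname(padj),
             testable = !is.na(p))
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak procedure: with p-values sorted ascending,
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, followed by enforcement of
#' monotonicity (running maximum) and capping at 1. `NA` values are left
#' untouched and do not count towards `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (may contain `NA`).
#' @return Adjusted p-values in the input order.
#' @examples
#' holm_sidak(c(0.01, 0.04))
#' @export
holm_sidak <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- p
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv)
  adj <- 1 - (1 - pv[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out[ok][o] <- adj
  out
}

#' Volcano table
#'
#' One row per tested shared protein, pairing the log2 fold change with
#' `-log10(p)` and a significance flag combining both thresholds:
#' `significant = (p < alpha) AND (abs_fc >= cutoff)` -- the classic volcano
#' quadrant rule. When an adjustment method was applied, the flag uses the
#' adjusted p-values.
#'
#' @param comparison A comparison data frame (see [ev_compare()]) with
#'   columns `gene_symbol`, `log2_ratio`, `abs_fc`, `p_value`, `p_adjusted`.
#' @param alpha Significance threshold (default 0.05).
#' @param cutoff Absolute fold-change cutoff (default 1.3).
#' @param use_adjusted Flag significance on `p_adjusted` instead of raw
#'   `p_value` (default `FALSE`: unadjusted per-comparison alpha).
#' @return Data frame with `gene_symbol`, `log2_ratio`, `neg_log10_p`,
#'   `significant`.
#' @export
volcano_table <- function(comparison, alpha = 0.05, cutoff = 1.3,
                          use_adjusted = FALSE) {
  tab <- comparison[!is.na(comparison$p_value), , drop = FALSE]
  p <- if (use_adjusted) tab$p_adjusted else tab$p_value
  data.frame(accession = tab$accession, gene_symbol = tab$gene_symbol,
             log2_ratio = tab$log2_ratio,
             neg_log10_p = -log10(p),
             significant = p < alpha & tab$abs_fc >= cutoff,
             stringsAsFactors = FALSE)
}

#' Match a protein signature against abundance classes
#'
#' Counts how many members of a signature (e.g. a neutrophil-associated
#' protein list) fall into the increased- and decreased-abundance classes of
#' a comparison, with percentages of the signature size. Matching is by gene
#' symbol, case-insensitive after whitespace stripping.
#'
#' @param signature Character vector of gene symbols (the signature).
#' @param increased,decreased Character vectors of gene symbols in the
#'   increased- and decreased-abundance classes.
#' @param name Optional signature name for printing.
#' @return An object of class `signature_match` with counts
#'   `n_in_increased`, `n_in_decreased`, `n_neither` and unrounded
#'   percentages `pct_increased`, `pct_decreased` of the signature size.
#' @examples
#' match_signature(c("Mpo", "Elane", "Ltf"), increased = c("MPO", "ELANE"),
#'                 decreased = "LTF")
#' @export
match_signature <- function(signature, increased, decreased,
                            name = "signature") {
  sig <- unique(.norm_symbol(signature))
  sig <- sig[nzchar(sig)]
  if (length(sig) == 0L) stop("empty signature", call. = FALSE)
  inc <- .norm_symbol(increased)
  dec <- .norm_symbol(decreased)
  n_inc <- sum(sig %in% inc)
  n_dec <- sum(sig %in% dec & !sig %in% inc)
  structure(list(signature_name = name, signature_genes = sig,
                 n_in_increased = n_inc, n_in_decreased = n_dec,
                 n_neither = length(sig) - n_inc - n_dec,
                 pct_increased = 100 * n_inc / length(sig),
                 pct_decreased = 100 * n_dec / length(sig)),
            class = "signature_match")
}

.norm_symbol <- function(x) toupper(trimws(as.character(x)))

#' @export
print.signature_match <- function(x, ...) {
  n <- length(x$signature_genes)
  cat("Signature '", x$signature_name, "' (", n, " genes)\n", sep = "")
  cat(sprintf("  in increased class: %d of %d (%.2f%%)\n",
              x$n_in_increased, n, x$pct_increased))
  cat(sprintf("  in decreased class: %d of %d (%.2f%%)\n",
              x$n_in_decreased, n, x$pct_decreased))
  cat("  in neither class:  ", x$n_neither, "\n")
  invisible(x)
}

#' Read a signature file
#'
#' Plain text, one gene symbol per line; `#` starts a comment.
#'
#' @param path Path to the signature file.
#' @return Character vector of symbols.
#' @export
read_signature <- function(path) {
  lines <- trimws(readLines(path))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Within-family composition profile
#'
#' Relative abundance of a protein subset (e.g. the apolipoproteins detected
#' in one fraction pool) as percentages of the subset's total mean M%.
#'
#' @param subset Character vector of accessions.
#' @param quantified A `quantified_group` from [quantify_group()].
#' @return Data frame with `accession`, `gene_symbol`, `mean_molar_pct`, and
#'   `pct_of_subset` (sums to 100).
#' @export
composition_profile <- function(subset, quantified) {
  subset <- unique(as.character(subset))
  if (length(subset) == 0L) stop("empty subset", call. = FALSE)
  idx <- match(subset, quantified$accession)
  if (anyNA(idx)) {
    stop("subset accession(s) not quantified in this group: ",
         paste(subset[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  mm <- quantified$mean_molar_pct[idx]
  total <- sum(mm)
  if (total <= 0) stop("subset has zero total mean M%", call. = FALSE)
  data.frame(accession = subset,
             gene_symbol = quantified$gene_symbol[idx],
             mean_molar_pct = mm,
             pct_of_subset = 100 * mm / total,
             stringsAsFactors = FALSE)
}
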