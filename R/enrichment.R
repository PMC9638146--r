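#' Read a GMT gene-set collection
#'
#' Tab-separated, one term per line: term id, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @param name Collection name (default: file base name).
#' @return An object of class `gene_set_collection`: list with `name`,
#'   `term_id`, `term_name`, and `genes` (a list of character vectors,
#'   case-folded to upper case).
#' @export
read_gmt <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    stop("malformed GMT line (need term id, description, >= 1 gene): ", path,
         call. = FALSE)
  }
  term_id <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(term_id)) {
    stop("duplicate term id(s) in GMT: ",
         paste(unique(term_id[duplicated(term_id)]), collapse = ", "),
         call. = FALSE)
  }
  genes <- lapply(fields, function(f) unique(.norm_symbol(f[-(1:2)])))
  if (any(lengths(genes) == 0L)) stop("empty gene set in GMT", call. = FALSE)
  structure(list(name = if (is.null(name))
                   sub("\\.gmt$", "", basename(path)) else name,
                 term_id = term_id,
                 term_name = vapply(fields, `[`, character(1), 2L),
                 genes = genes),
            class = "gene_set_collection")
}

#' Build a gene-set collection in code
#' @param terms Named list of character gene vectors (names = term ids).
#' @param term_names Optional descriptions (default: the ids).
#' @param name Collection name.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(terms, term_names = names(terms),
                                name = "collection") {
  stopifnot(length(terms) > 0L, !is.null(names(terms)),
            !anyDuplicated(names(terms)), all(lengths(terms) > 0L))
  structure(list(name = name, term_id = names(terms),
                 term_name = unname(term_names),
                 genes = lapply(unname(terms), .norm_symbol)),
            class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- mapply(function(id, nm, g) paste(c(id, nm, g), collapse = "\t"),
                  collection$term_id, collection$term_name, collection$genes)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Gene-set over-representation analysis
#'
#' One-sided Fisher / hypergeometric test per term: the p-value is the upper
#' tail probability of drawing at least the observed overlap when
#' `|query|` genes are sampled without replacement from the background.
#' Each term is intersected with the background before testing; terms with an
#' empty intersection are skipped. FDR is controlled by Benjamini-Hochberg
#' (default) across all tested terms of the collection.
#'
#' @param query Character vector of gene symbols (e.g. a differential
#'   protein class). Must be contained in `background`; members outside it
#'   are dropped with a warning.
#' @param collection A `gene_set_collection`.
#' @param background Character vector: the gene universe. The recommended
#'   default in this pipeline is every gene quantified in the experiment,
#'   not a whole-genome list.
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return An object of classes `enrichment_result`/`data.frame`, sorted by
#'   p ascending: `term_id`, `term_name`, `n_query`, `n_term`, `n_overlap`,
#'   `n_background`, `p_value`, `fdr`, `neg_log10_fdr`, `overlap_genes`
#'   (";"-collapsed), plus `kappa_group_id`/`is_group_representative` once
#'   [kappa_grouping()] has run.
#' @export
enrich <- function(query, collection, background,
                   adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(collection, "gene_set_collection"))
  background <- unique(.norm_symbol(background))
  background <- background[nzchar(background)]
  query <- unique(.norm_symbol(query))
  query <- query[nzchar(query)]
  if (length(query) == 0L || length(background) == 0L) {
    stop("empty query or background", call. = FALSE)
  }
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the background dropped",
            call. = FALSE)
    query <- intersect(query, background)
    if (length(query) == 0L) stop("no query gene in background", call. = FALSE)
  }
  N <- length(background)
  k <- length(query)
  rows <- lapply(seq_along(collection$term_id), function(i) {
    term_bg <- intersect(collection$genes[[i]], background)
    if (length(term_bg) == 0L) return(NULL)
    ov <- intersect(query, term_bg)
    m <- length(term_bg)
    p <- stats::phyper(length(ov) - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(term_id = collection$term_id[i],
               term_name = collection$term_name[i],
               n_query = k, n_term = m, n_overlap = length(ov),
               n_background = N, p_value = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) {
    message(skipped, " term(s) with empty background intersection skipped")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable term in collection", call. = FALSE)
  out$fdr <- stats::p.adjust(out$p_value,
                             method = if (adjust == "BH") "BH" else
                               "bonferroni")
  out$neg_log10_fdr <- -log10(out$fdr)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out$kappa_group_id <- NA_integer_
  out$is_group_representative <- NA
  attr(out, "collection") <- collection$name
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Cohen's kappa between two gene memberships
#'
#' Agreement of two binary membership vectors over a gene universe:
#' `kappa = (Po - Pe) / (1 - Pe)` from the 2x2 contingency table of joint
#' membership, where `Po` is observed and `Pe` chance agreement.
#'
#' @param x,y Logical vectors of equal length (membership over the universe).
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_score <- function(x, y) {
  stopifnot(is.logical(x), is.logical(y), length(x) == length(y),
            length(x) > 0L)
  n <- length(x)
  a <- sum(x & y); b <- sum(x & !y); c_ <- sum(!x & y); d <- n - a - b - c_
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    return(if (po >= 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Group enriched terms by kappa score
#'
#' Functionally groups significant terms that share genes: pairwise Cohen's
#' kappa is computed between term-membership vectors over the union of genes
#' annotated to any significant term, terms with `kappa >= kappa_threshold`
#' are linked, groups are the connected components of that graph, and the
#' most significant (lowest-p) term of each group is flagged as its
#' representative (the term that names the group). Grouping by connected
#' components is a deliberate simplification of iterative leading-term
#' merging heuristics.
#'
#' @param result An `enrichment_result` from [enrich()].
#' @param collection The `gene_set_collection` the result came from.
#' @param kappa_threshold Minimum kappa for an edge (default 0.4, the
#'   conventional default of kappa-grouping enrichment tools).
#' @param max_fdr Terms with `fdr <= max_fdr` are grouped (default 0.05);
#'   the rest keep `NA` group ids.
#' @return `result` with `kappa_group_id` and `is_group_representative`
#'   filled in for the significant terms.
#' @export
kappa_grouping <- function(result, collection, kappa_threshold = 0.4,
                           max_fdr = 0.05) {
  stopifnot(inherits(result, "enrichment_result"),
            inherits(collection, "gene_set_collection"))
  sig <- which(result$fdr <= max_fdr)
  if (length(sig) == 0L) stop("no significant term to group", call. = FALSE)
  ids <- result$term_id[sig]
  genes <- collection$genes[match(ids, collection$term_id)]
  universe <- sort(unique(unlist(genes)))
  memb <- vapply(genes, function(g) universe %in% g,
                 logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe))
  m <- length(ids)
  edges <- NULL
  if (m > 1L) {
    pairs <- utils::combn(m, 2L)
    keep <- apply(pairs, 2L, function(ij) {
      kappa_score(memb[, ij[1L]], memb[, ij[2L]]) >= kappa_threshold
    })
    edges <- pairs[, keep, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  if (!is.null(edges) && ncol(edges)) g <- igraph::add_edges(g, as.vector(edges))
  comp <- igraph::components(g)$membership
  # stable ids: number groups by their most significant member's rank
  best_rank <- vapply(seq_len(max(comp)), function(cid) min(sig[comp == cid]),
                      numeric(1))
  relabel <- rank(best_rank)[comp]
  result$kappa_group_id[sig] <- as.integer(relabel)
  rep_flag <- logical(m)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    rep_flag[members[which.min(result$p_value[sig][members])]] <- TRUE
  }
  result$is_group_representative[sig] <- rep_flag
  result
}

#' Label enriched terms by cluster specificity
#'
#' A term is specific to one of two gene clusters when more than
#' `specificity_fraction` of its genes overlapping the clusters' union come
#' from that cluster; otherwise it is common. Terms with zero overlap are
#' skipped (`NA`).
#'
#' @param result An `enrichment_result`.
#' @param collection Its `gene_set_collection`.
#' @param cluster_a,cluster_b Character gene-symbol vectors (two disjoint
#'   clusters, e.g. increased-in-A and increased-in-B proteins).
#' @param specificity_fraction Strict threshold (default 0.60).
#' @return `result` with a `specificity` column:
#'   `"specific_A"`, `"specific_B"`, `"common"`, or `NA`.
#' @export
cluster_specificity <- function(result, collection, cluster_a, cluster_b,
                                specificity_fraction = 0.60) {
  stopifnot(inherits(result, "enrichment_result"))
  ca <- unique(.norm_symbol(cluster_a))
  cb <- unique(.norm_symbol(cluster_b))
  genes <- collection$genes[match(result$term_id, collection$term_id)]
  result$specificity <- vapply(genes, function(g) {
    na <- length(intersect(g, ca))
    nb <- length(intersect(g, cb))
    tot <- length(intersect(g, union(ca, cb)))
    if (tot == 0L) return(NA_character_)
    if (na / tot > specificity_fraction) "specific_A"
    else if (nb / tot > specificity_fraction) "specific_B"
    else "common"
  }, character(1))
  result
}

#' Top enriched terms
#'
#' Convenience selector for report figures that display the `n` most
#' significant terms of a collection.
#'
#' @param result An `enrichment_result` (already sorted by p).
#' @param n Number of terms (default 4).
#' @return The first `n` rows.
#' @export
top_terms <- function(result, n = 4L) {
  utils::head(result, n)
}

#' Bar chart of enrichment significance
#'
#' Horizontal bars of `-log10(FDR)` for the top terms.
#'
#' @param x An `enrichment_result`.
#' @param n Number of top terms to show (default 10).
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.enrichment_result <- function(x, n = 10L, ...) {
  top <- utils::head(x, n)
  graphics::barplot(rev(top$neg_log10_fdr), names.arg = rev(top$term_name),
                    horiz = TRUE, las = 1,
                    xlab = expression(-log[10] ~ "FDR"), ...)
  invisible(x)
}

#' Write an enrichment report
#' @param result An `enrichment_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(result, path) {
  .write_tsv(as.data.frame(result), path)
}
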