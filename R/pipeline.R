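#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full pipeline run. A YAML
#' file with the same keys can be loaded with `pipeline_config("conf.yml")`;
#' arguments given here override values from the file.
#'
#' @param path Optional YAML config file.
#' @param ... Overriding key-value pairs. Recognized keys: `fasta`, `tables`
#'   (identification TSV), `out_dir`; optional `gmt` (character vector of
#'   collection paths), `signatures` (character vector of signature paths),
#'   `composition_subset` (path to an accession list, one per line, for the
#'   composition profile); `group_a`, `group_b`; analysis constants `cutoff`
#'   (default 1.3), `alpha` (default 0.05), `test`, `adjust`,
#'   `kappa_threshold` (default 0.4), `max_fdr` (default 0.05),
#'   `specificity_fraction` (default 0.6), `normalize`, `seed` (default 1);
#'   digestion settings `protease`, `max_missed_cleavages`, `mass_min_da`,
#'   `mass_max_da`, `mass_type`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  conf <- if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file not found: ", path, call. = FALSE)
    }
    yaml::read_yaml(path)
  } else list()
  dots <- list(...)
  conf[names(dots)] <- dots
  defaults <- list(gmt = character(0), signatures = character(0),
                   composition_subset = NULL, group_a = NULL, group_b = NULL,
                   cutoff = 1.3, alpha = 0.05, test = "pooled",
                   adjust = "none", kappa_threshold = 0.4, max_fdr = 0.05,
                   specificity_fraction = 0.6, normalize = "per_run",
                   seed = 1L,
                   protease = "trypsin", max_missed_cleavages = 1L,
                   mass_min_da = 500, mass_max_da = 3000,
                   mass_type = "monoisotopic")
  for (k in names(defaults)) {
    if (is.null(conf[[k]])) conf[k] <- list(defaults[[k]])
  }
  for (k in c("fasta", "tables", "out_dir")) {
    if (is.null(conf[[k]])) stop("config lacks required key: ", k,
                                 call. = FALSE)
  }
  for (p in c(conf$fasta, conf$tables, conf$gmt, conf$signatures,
              conf$composition_subset)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p,
                              call. = FALSE)
  }
  stopifnot(conf$cutoff >= 1, conf$alpha > 0, conf$alpha < 1,
            conf$kappa_threshold >= -1, conf$kappa_threshold <= 1,
            conf$specificity_fraction > 0, conf$specificity_fraction < 1)
  conf$digest <- digest_params(conf$protease, conf$max_missed_cleavages,
                               conf$mass_min_da, conf$mass_max_da,
                               conf$mass_type)
  structure(conf, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full comparison pipeline
#'
#' Orchestrates quantification, partition, fold-change classification and
#' tests, signature matching, composition profiling, and enrichment, and
#' writes one TSV report per stage plus a run manifest into
#' `config$out_dir`. Reruns with an identical configuration produce
#' byte-identical reports.
#'
#' @param config A [pipeline_config()] (or a YAML path).
#' @return Invisibly, a list with the `ev_compare` fit, the report paths,
#'   and the manifest lines.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  database <- .stage("read_fasta", read_fasta_db(config$fasta))
  id_table <- .stage("read_tables", read_id_table(config$tables))
  groups <- if (!is.null(config$group_a)) c(config$group_a, config$group_b)
  fit <- .stage("compare",
                ev_compare(id_table, database, groups = groups,
                           digest = config$digest, cutoff = config$cutoff,
                           alpha = config$alpha, test = config$test,
                           adjust = config$adjust,
                           normalize = config$normalize))

  out <- function(f) file.path(config$out_dir, f)
  paths <- c(quant_a = out(paste0("quantification_", fit$groups[1L], ".tsv")),
             quant_b = out(paste0("quantification_", fit$groups[2L], ".tsv")),
             partition = out("partition.tsv"),
             comparison = out("comparison.tsv"),
             volcano = out("volcano.tsv"))
  write_quant_report(fit$quant_a, paths[["quant_a"]])
  write_quant_report(fit$quant_b, paths[["quant_b"]])
  part <- fit$partition
  part_tab <- data.frame(
    accession = c(part$unique_a, part$shared, part$unique_b),
    cell = rep(c("unique_a", "shared", "unique_b"), part$counts),
    stringsAsFactors = FALSE)
  .write_tsv(part_tab, paths[["partition"]])
  write_comparison_report(fit, paths[["comparison"]])
  volc <- volcano_table(fit$comparison, alpha = config$alpha,
                        cutoff = config$cutoff,
                        use_adjusted = config$adjust != "none")
  .write_tsv(volc, paths[["volcano"]])

  comp <- fit$comparison
  inc <- comp$gene_symbol[comp$klass == "increased_in_A"]
  dec <- comp$gene_symbol[comp$klass == "increased_in_B"]
  for (sg in config$signatures) {
    nm <- sub("\\.[^.]*$", "", basename(sg))
    m <- .stage(paste0("signature:", nm),
                match_signature(read_signature(sg), inc, dec, name = nm))
    sig_tab <- data.frame(signature = nm,
                          n_signature = length(m$signature_genes),
                          n_in_increased = m$n_in_increased,
                          n_in_decreased = m$n_in_decreased,
                          n_neither = m$n_neither,
                          pct_increased = round(m$pct_increased, 2),
                          pct_decreased = round(m$pct_decreased, 2))
    p <- out(paste0("signature_", nm, ".tsv"))
    .write_tsv(sig_tab, p)
    paths[paste0("signature_", nm)] <- p
  }

  if (!is.null(config$composition_subset)) {
    subset <- read_signature(config$composition_subset)
    prof_a <- .stage("composition",
                     composition_profile(subset, fit$quant_a))
    prof_b <- .stage("composition",
                     composition_profile(subset, fit$quant_b))
    prof <- rbind(cbind(group = fit$groups[1L], prof_a),
                  cbind(group = fit$groups[2L], prof_b))
    paths["composition"] <- out("composition.tsv")
    .write_tsv(prof, paths[["composition"]])
  }

  background <- unique(c(fit$quant_a$gene_symbol, fit$quant_b$gene_symbol))
  background <- background[nzchar(background)]
  query <- unique(c(inc, dec))
  query <- query[nzchar(query)]
  for (g in config$gmt) {
    coll <- .stage("read_gmt", read_gmt(g))
    res <- .stage(paste0("enrich:", coll$name),
                  enrich(query, coll, background))
    if (any(res$fdr <= config$max_fdr)) {
      res <- kappa_grouping(res, coll, config$kappa_threshold,
                            config$max_fdr)
    }
    res <- cluster_specificity(res, coll, inc, dec,
                               config$specificity_fraction)
    p <- out(paste0("enrichment_", coll$name, ".tsv"))
    write_enrichment_report(res, p)
    paths[paste0("enrichment_", coll$name)] <- p
  }

  manifest <- c(
    paste0("evquant_version: ",
           as.character(utils::packageVersion("evquant"))),
    paste0("fasta: ", config$fasta),
    paste0("tables: ", config$tables),
    paste0("group_a: ", fit$groups[1L]),
    paste0("group_b: ", fit$groups[2L]),
    paste0("cutoff: ", config$cutoff),
    paste0("alpha: ", config$alpha),
    paste0("test: ", config$test),
    paste0("adjust: ", config$adjust),
    paste0("normalize: ", config$normalize),
    paste0("protease: ", config$digest$protease),
    paste0("max_missed_cleavages: ", config$digest$max_missed_cleavages),
    paste0("mass_window_da: ", config$digest$mass_min_da, "-",
           config$digest$mass_max_da, " (", config$digest$mass_type, ")"),
    paste0("kappa_threshold: ", config$kappa_threshold),
    paste0("max_fdr: ", config$max_fdr),
    paste0("seed: ", config$seed),
    vapply(names(paths), function(k) {
      paste0("rows_", k, ": ",
             length(readLines(paths[[k]])) - 1L)
    }, character(1)))
  manifest_path <- out("manifest.txt")
  writeLines(manifest, manifest_path)
  paths["manifest"] <- manifest_path

  invisible(list(fit = fit, paths = paths, manifest = manifest))
}
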