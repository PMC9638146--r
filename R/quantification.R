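#' Exponentially modified protein abundance index
#'
#' `emPAI = 10^(N_observed / N_observable) - 1`, where `N_observed` is the
#' number of distinct peptides of the protein identified in one MS/MS run and
#' `N_observable` the number of distinct in-silico digestion peptides in the
#' instrument's mass window (see [count_observable()]). The ratio
#' `N_observed / N_observable` is the protein abundance index (PAI); the
#' exponential form makes emPAI approximately proportional to molar amount.
#'
#' @param n_observed Integer vector, distinct identified peptides (>= 0).
#' @param n_observable Integer vector, observable peptides (>= 1).
#' @return Numeric vector of emPAI values (>= 0).
#' @examples
#' empai(10, 10)  # PAI = 1 -> emPAI = 9
#' @export
empai <- function(n_observed, n_observable) {
  stopifnot(is.numeric(n_observed), is.numeric(n_observable),
            all(n_observed >= 0))
  if (any(n_observable < 1)) {
    stop("emPAI undefined: protein(s) with no observable peptides ",
         "(n_observable < 1)", call. = FALSE)
  }
  10^(n_observed / n_observable) - 1
}

#' Normalize emPAI values to molar percentages
#'
#' Protein content as molar percentage:
#' `M%(p) = 100 * emPAI(p) / sum(emPAI)`, the sum running over all proteins
#' identified in the same run. Output sums to 100.
#'
#' @param empai_values Named numeric vector of emPAI values for one run.
#' @return Named numeric vector of M% values summing to 100.
#' @examples
#' molar_percent(c(A = 1, B = 1, C = 2))  # 25, 25, 50
#' @export
molar_percent <- function(empai_values) {
  stopifnot(is.numeric(empai_values), all(empai_values >= 0))
  total <- sum(empai_values)
  if (length(empai_values) == 0L || total <= 0) {
    stop("cannot normalize: no protein with positive emPAI in this run",
         call. = FALSE)
  }
  100 * empai_values / total
}

#' Read a peptide-identification table
#'
#' Tab-separated with header columns `run_id`, `group`, `accession`,
#' `n_observed_peptides`; one row per (run, protein) pair. A protein absent
#' from a run is simply not listed (missing, not zero).
#'
#' @param path Path to a TSV file.
#' @return A validated data frame.
#' @export
read_id_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("run_id", "group", "accession", "n_observed_peptides")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("identification table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  .validate_id_table(tab[required])
}

.validate_id_table <- function(tab) {
  if (any(tab$n_observed_peptides < 1)) {
    stop("n_observed_peptides must be >= 1 (absent proteins are not listed)",
         call. = FALSE)
  }
  key <- paste(tab$run_id, tab$accession, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (run_id, accession) pair(s) in identification table",
         call. = FALSE)
  }
  tab
}

#' Write a peptide-identification table
#' @param tab Data frame with columns `run_id`, `group`, `accession`,
#'   `n_observed_peptides`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_id_table <- function(tab, path) {
  .write_tsv(tab[c("run_id", "group", "accession", "n_observed_peptides")],
             path)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Quantify one group of replicate runs
#'
#' Computes emPAI and M% per protein within each run where it was identified,
#' then aggregates across a group's replicate runs: `n` = number of runs with
#' an identification, mean and SEM of M% over those runs only. Undetected
#' runs are excluded from the mean -- missing is not zero, and no value is
#' imputed, so each protein carries its own sample size `n` bounded by the
#' group's run count.
#'
#' @param id_table Identification table (see [read_id_table()]) for a single
#'   group.
#' @param database Protein database data frame from [read_fasta_db()].
#' @param params [digest_params()] controlling the observable-peptide count.
#' @param normalize `"per_run"` (default): M% normalized within each run over
#'   that run's identified proteins, so every run sums to 100.
#'   `"pooled"`: emPAI normalized to the grand total over all the group's
#'   runs, a sensitivity-analysis mode in which per-run values no longer sum
#'   to 100.
#'
#' @return A data frame of class `quantified_group`, one row per protein ever
#'   detected: `accession`, `gene_symbol`, `group`, `n`, `mean_molar_pct`,
#'   `sem_molar_pct` (NA when `n` = 1), plus one `M%` column per run
#'   (`NA` = not detected). The long per-run emPAI/M% table is in
#'   `attr(, "per_run")`.
#' @export
quantify_group <- function(id_table, database, params = digest_params(),
                           normalize = c("per_run", "pooled")) {
  normalize <- match.arg(normalize)
  id_table <- .validate_id_table(id_table)
  groups <- unique(id_table$group)
  if (length(groups) != 1L) {
    stop("quantify_group() expects runs from a single group, got: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  accs <- unique(id_table$accession)
  unknown <- setdiff(accs, database$accession)
  if (length(unknown)) {
    stop("accession(s) not in the FASTA database: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  n_obs_able <- vapply(accs, function(a) {
    count_observable(database$sequence[match(a, database$accession)], params)
  }, numeric(1))
  dropped <- accs[n_obs_able == 0]
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " protein(s) with no observable peptides under current ",
            "digestion parameters: ",
            paste(utils::head(dropped, 5L), collapse = ", "), call. = FALSE)
    id_table <- id_table[!id_table$accession %in% dropped, , drop = FALSE]
    if (nrow(id_table) == 0L) {
      stop("no quantifiable proteins left in group '", groups, "'",
           call. = FALSE)
    }
  }
  id_table$empai <- empai(id_table$n_observed_peptides,
                          n_obs_able[id_table$accession])
  run_ids <- unique(id_table$run_id)
  per_run <- do.call(rbind, lapply(run_ids, function(r) {
    rows <- id_table[id_table$run_id == r, , drop = FALSE]
    if (nrow(rows) == 0L) {
      warning("run ", r, " has no observations; skipped", call. = FALSE)
      return(NULL)
    }
    mp <- if (normalize == "per_run") {
      molar_percent(stats::setNames(rows$empai, rows$accession))
    } else {
      100 * rows$empai / sum(id_table$empai)
    }
    data.frame(run_id = r, accession = rows$accession, empai = rows$empai,
               molar_pct = unname(mp), stringsAsFactors = FALSE)
  }))
  accs <- accs[!accs %in% dropped]
  mpw <- matrix(NA_real_, nrow = length(accs), ncol = length(run_ids),
                dimnames = list(accs, run_ids))
  mpw[cbind(per_run$accession, per_run$run_id)] <- per_run$molar_pct
  n <- rowSums(!is.na(mpw))
  mean_mp <- rowMeans(mpw, na.rm = TRUE)
  sem_mp <- apply(mpw, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  out <- data.frame(accession = accs,
                    gene_symbol =
                      database$gene_symbol[match(accs, database$accession)],
                    group = groups, n = as.integer(n),
                    mean_molar_pct = mean_mp, sem_molar_pct = sem_mp,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- cbind(out, as.data.frame(mpw, optional = TRUE))
  rownames(out) <- NULL
  attr(out, "per_run") <- per_run
  attr(out, "run_ids") <- run_ids
  attr(out, "normalize") <- normalize
  class(out) <- c("quantified_group", "data.frame")
  out
}

#' Write a quantification report
#'
#' TSV with accession, gene symbol, group, per-protein sample size `n`, mean
#' and SEM of M%, and one M% column per run.
#'
#' @param quant A `quantified_group` from [quantify_group()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_report <- function(quant, path) {
  .write_tsv(as.data.frame(quant), path)
}
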