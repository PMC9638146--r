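# Approximate natural amino-acid frequencies (vertebrate proteomes); K + R
# together ~11%, so random sequences carry realistic tryptic site density.
.AA_FREQ <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.8,
              G = 7.1, H = 2.3, I = 6.0, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
              P = 4.7, S = 6.6, T = 5.3, W = 1.1, Y = 2.9, V = 6.9)

#' Simulation configuration
#'
#' Parameters of the synthetic-proteome generator and the replicate-run
#' detection model, chosen to mirror the replicate design the pipeline is
#' meant for: two groups of label-free MS/MS runs (9 and 13 replicates by
#' default), per-protein molar fractions spanning orders of magnitude, and
#' abundance-dependent detection so each protein carries its own per-group
#' sample size `n`.
#'
#' @param n_proteins Number of database proteins (default 500).
#' @param protein_length_range Min/max residues per protein (default
#'   150--600).
#' @param n_runs_a,n_runs_b Replicate runs per group (defaults 9 and 13).
#' @param group_names Labels of groups A and B (default `c("KO", "WT")`).
#' @param base_meanlog,base_sdlog Log-normal law of the raw abundances that
#'   are renormalized into true molar fractions (defaults 0 and 1).
#' @param frac_differential Fraction of proteins with a planted fold change
#'   (default 0.1), split evenly between the two directions.
#' @param true_abs_fc Planted absolute fold change (default 3).
#' @param detection_rate_k Scaling constant `k` of the per-peptide detection
#'   law `P(detect) = 1 - exp(-k * c)` at true molar fraction `c`. The
#'   default 18 puts the median protein of a 500-protein lognormal(0,1)
#'   proteome in roughly 60--80% of runs (protein-level detection
#'   probability `1 - exp(-k * c * N_observable)`).
#' @param min_peptides Peptides required to call a protein identified in a
#'   run (default 1).
#' @param symbol_fraction Fraction of proteins carrying a gene symbol
#'   (default 1).
#' @param gene_symbol_pool Optional symbol vector to draw from (default:
#'   generated `GS0001...`).
#' @param seed RNG seed (integer).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 500L, protein_length_range = c(150L, 600L),
                       n_runs_a = 9L, n_runs_b = 13L,
                       group_names = c("KO", "WT"),
                       base_meanlog = 0, base_sdlog = 1,
                       frac_differential = 0.1, true_abs_fc = 3,
                       detection_rate_k = 18, min_peptides = 1L,
                       symbol_fraction = 1, gene_symbol_pool = NULL,
                       seed = 1L) {
  stopifnot(n_proteins >= 2L, length(protein_length_range) == 2L,
            protein_length_range[1L] >= 10L,
            protein_length_range[1L] <= protein_length_range[2L],
            n_runs_a >= 1L, n_runs_b >= 1L, length(group_names) == 2L,
            frac_differential >= 0, frac_differential <= 1,
            true_abs_fc >= 1, detection_rate_k >= 0,
            min_peptides >= 1L, symbol_fraction >= 0, symbol_fraction <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 protein_length_range = as.integer(protein_length_range),
                 n_runs_a = as.integer(n_runs_a),
                 n_runs_b = as.integer(n_runs_b),
                 group_names = as.character(group_names),
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 frac_differential = frac_differential,
                 true_abs_fc = true_abs_fc,
                 detection_rate_k = detection_rate_k,
                 min_peptides = as.integer(min_peptides),
                 symbol_fraction = symbol_fraction,
                 gene_symbol_pool = gene_symbol_pool,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic protein database
#'
#' Random sequences drawn from natural amino-acid frequencies (K/R together
#' about 11%, so tryptic peptides exist), with accessions `SYN0001...` and a
#' configurable fraction of gene symbols. Deterministic for a fixed
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A database data frame (`accession`, `gene_symbol`, `sequence`),
#'   the same shape as [read_fasta_db()] returns.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .generate_proteome_impl(config)
}

.generate_proteome_impl <- function(config) {
  n <- config$n_proteins
  len_choices <- seq(config$protein_length_range[1L],
                     config$protein_length_range[2L])
  lens <- len_choices[sample.int(length(len_choices), n, replace = TRUE)]
  prob <- .AA_FREQ / sum(.AA_FREQ)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(.AA_FREQ), L, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
  pool <- config$gene_symbol_pool
  if (is.null(pool)) pool <- sprintf("GS%04d", seq_len(n))
  symbols <- rep("", n)
  n_sym <- round(config$symbol_fraction * n)
  if (n_sym > 0L) {
    symbols[sample.int(n, n_sym)] <- sample(pool, n_sym,
                                            replace = length(pool) < n_sym)
  }
  data.frame(accession = sprintf("SYN%04d", seq_len(n)),
             gene_symbol = symbols, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Simulate replicate identification runs
#'
#' For each protein with true molar fraction `c` in a group, every observable
#' peptide is detected independently in each run with probability
#' `1 - exp(-k * c)` -- the simplest saturating abundance-detection link
#' consistent with emPAI's premise that more abundant proteins yield more of
#' their observable peptides. A protein is listed in a run when at least
#' `min_peptides` of its peptides were detected, which reproduces the
#' structure of real replicate tables: abundance-dependent detection,
#' per-run missingness, and a per-protein sample size `n` varying between 1
#' and the group's run count. Differential proteins have their fraction
#' multiplied (first half) or divided (second half) by `true_abs_fc` in
#' group A before renormalization.
#'
#' @param proteome Database data frame (see [generate_proteome()]).
#' @param config A [sim_config()].
#' @param digest [digest_params()] used for observable-peptide counts.
#' @return An object of class `ev_simulation`: list with `tables` (the
#'   identification table for both groups), `truth` (per-protein true molar
#'   fractions per group, planted class, and `n_observable`), `proteome`,
#'   and `config`.
#' @export
simulate_runs <- function(proteome, config, digest = digest_params()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_obs_able <- vapply(proteome$sequence, count_observable, numeric(1),
                       params = digest, USE.NAMES = FALSE)
  usable <- n_obs_able >= 1L
  if (!all(usable)) {
    message(sum(!usable), " protein(s) without observable peptides excluded ",
            "from simulation")
  }
  prot <- proteome[usable, , drop = FALSE]
  n_obs_able <- n_obs_able[usable]
  n <- nrow(prot)

  base <- stats::rlnorm(n, config$base_meanlog, config$base_sdlog)
  n_diff <- round(config$frac_differential * n)
  planted <- if (n_diff > 0L) sample.int(n, n_diff) else integer(0)
  up_in_a <- planted[seq_len(ceiling(n_diff / 2))]
  down_in_a <- setdiff(planted, up_in_a)
  frac_a <- frac_b <- base
  frac_a[up_in_a] <- frac_a[up_in_a] * config$true_abs_fc
  frac_a[down_in_a] <- frac_a[down_in_a] / config$true_abs_fc
  frac_a <- frac_a / sum(frac_a)
  frac_b <- frac_b / sum(frac_b)
  true_class <- rep("null", n)
  true_class[up_in_a] <- "increased_in_A"
  true_class[down_in_a] <- "increased_in_B"

  sim_group <- function(fracs, group, n_runs) {
    p_det <- 1 - exp(-config$detection_rate_k * fracs)
    do.call(rbind, lapply(seq_len(n_runs), function(r) {
      n_obs <- stats::rbinom(n, n_obs_able, p_det)
      keep <- n_obs >= config$min_peptides
      if (!any(keep)) return(NULL)
      data.frame(run_id = sprintf("%s_r%02d", group, r), group = group,
                 accession = prot$accession[keep],
                 n_observed_peptides = n_obs[keep],
                 stringsAsFactors = FALSE)
    }))
  }
  tab_a <- sim_group(frac_a, config$group_names[1L], config$n_runs_a)
  tab_b <- sim_group(frac_b, config$group_names[2L], config$n_runs_b)
  tables <- rbind(tab_a, tab_b)
  if (is.null(tables) || nrow(tables) == 0L) {
    warning("no protein identified in any run (detection probabilities ",
            "all ~0); observed identification rate = 0", call. = FALSE)
    tables <- data.frame(run_id = character(0), group = character(0),
                         accession = character(0),
                         n_observed_peptides = integer(0))
  }
  truth <- data.frame(accession = prot$accession,
                      gene_symbol = prot$gene_symbol,
                      n_observable = n_obs_able,
                      true_frac_a = frac_a, true_frac_b = frac_b,
                      true_class = true_class, stringsAsFactors = FALSE)
  structure(list(tables = tables, truth = truth, proteome = prot,
                 config = config),
            class = "ev_simulation")
}

#' Generate a full synthetic dataset
#'
#' Convenience wrapper: [generate_proteome()] then [simulate_runs()] under
#' one seed, so the whole simulate-quantify-compare chain is reproducible.
#'
#' @param config A [sim_config()].
#' @param digest [digest_params()].
#' @return An `ev_simulation` (see [simulate_runs()]).
#' @export
simulate_dataset <- function(config = sim_config(),
                             digest = digest_params()) {
  simulate_runs(generate_proteome(config), config, digest)
}

#' @export
print.ev_simulation <- function(x, ...) {
  cat("Synthetic EV proteomics dataset\n")
  cat("  proteins:", nrow(x$truth), " runs:",
      x$config$n_runs_a, "(", x$config$group_names[1L], ") +",
      x$config$n_runs_b, "(", x$config$group_names[2L], ")\n")
  cat("  planted differential:", sum(x$truth$true_class != "null"),
      "at abs FC", x$config$true_abs_fc, "\n")
  cat("  identification rows:", nrow(x$tables), "\n")
  invisible(x)
}

#' Recovery report against simulation ground truth
#'
#' Confronts an [ev_compare()] fit obtained on simulated tables with the
#' planted truth: a confusion matrix of estimated abundance class against
#' true class (over the shared, compared proteins), direction accuracy among
#' flagged (significant) planted proteins, and the median relative error of
#' the estimated absolute fold change among planted differential proteins
#' present in the comparison.
#'
#' @param truth The `truth` data frame of an `ev_simulation`.
#' @param fit An `ev_compare` object fitted on the simulated tables (group A
#'   of the fit must be group A of the simulation).
#' @return An object of class `recovery_report`: list with `confusion`
#'   (table), `n_flagged`, `n_flagged_planted`, `direction_accuracy`
#'   (among flagged planted; `NaN` when none), `fdr_observed` (fraction of
#'   flagged proteins that are truly null), and `median_rel_fc_error`.
#' @export
recovery_report <- function(truth, fit) {
  stopifnot(inherits(fit, "ev_compare"))
  truth$true_abs_fc <- pmax(truth$true_frac_a / truth$true_frac_b,
                            truth$true_frac_b / truth$true_frac_a)
  comp <- merge(fit$comparison,
                truth[c("accession", "true_class", "true_abs_fc")],
                by = "accession")
  comp$true_class <- factor(comp$true_class,
                            levels = c("increased_in_A", "increased_in_B",
                                       "null"))
  confusion <- table(estimated = comp$klass, truth = comp$true_class)
  flagged <- comp[comp$significant, , drop = FALSE]
  fp <- flagged$true_class == "null"
  planted_flagged <- flagged[!fp, , drop = FALSE]
  dir_acc <- mean(as.character(planted_flagged$klass) ==
                    as.character(planted_flagged$true_class))
  diff <- comp[comp$true_class != "null", , drop = FALSE]
  rel_err <- if (nrow(diff)) {
    abs(diff$abs_fc - diff$true_abs_fc) / diff$true_abs_fc
  } else numeric(0)
  structure(list(confusion = confusion,
                 n_compared = nrow(comp),
                 n_flagged = nrow(flagged),
                 n_flagged_planted = nrow(planted_flagged),
                 direction_accuracy = dir_acc,
                 fdr_observed = if (nrow(flagged)) mean(fp) else NaN,
                 median_rel_fc_error = if (length(rel_err))
                   stats::median(rel_err) else NaN),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery against simulation ground truth\n")
  print(x$confusion)
  cat(sprintf("\nflagged significant: %d (%d planted, %d null)\n",
              x$n_flagged, x$n_flagged_planted,
              x$n_flagged - x$n_flagged_planted))
  cat(sprintf("direction accuracy among flagged planted: %.3f\n",
              x$direction_accuracy))
  cat(sprintf("median relative abs-FC error (planted): %.3f\n",
              x$median_rel_fc_error))
  invisible(x)
}
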