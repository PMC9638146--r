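# Independent oracles, deliberately implemented by different routes than the
# package: substring enumeration instead of segment stitching, atomic
# composition instead of residue-mass tables, closed forms instead of stats::
# wrappers.

# Residue elemental composition (C, H, N, O, S) and monoisotopic element
# masses; peptide mass = sum of residue formulas + H2O.
.ORACLE_FORMULA <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))
.ORACLE_ELEMENT <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                     O = 15.9949146196, S = 31.97207100)

oracle_peptide_mass <- function(sequence) {
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% names(.ORACLE_FORMULA))) return(NA_real_)
  counts <- Reduce(`+`, .ORACLE_FORMULA[res]) + c(0, 2, 0, 1, 0)  # + H2O
  sum(counts * .ORACLE_ELEMENT[c("C", "H", "N", "O", "S")])
}

# Brute-force digestion: enumerate every substring and keep the ones whose
# boundaries are valid cleavage boundaries with at most max_missed internal
# cleavage sites.
oracle_digest <- function(sequence, max_missed = 1, protease = "trypsin") {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  is_site <- function(i) {                     # cut after residue i?
    if (i < 1 || i >= n) return(FALSE)
    if (!res[i] %in% c("K", "R")) return(FALSE)
    if (protease == "trypsin" && res[i + 1] == "P") return(FALSE)
    TRUE
  }
  boundary <- function(i) i == 0 || i == n || is_site(i)
  out <- NULL
  for (s in 0:(n - 1)) {
    for (e in (s + 1):n) {
      if (!boundary(s) || !boundary(e)) next
      internal <- if (e - s > 1) sum(vapply((s + 1):(e - 1), is_site,
                                            logical(1))) else 0
      if (internal > max_missed) next
      out <- rbind(out, data.frame(
        sequence = substr(sequence, s + 1, e), start = s, end = e,
        missed_cleavages = internal, stringsAsFactors = FALSE))
    }
  }
  out[order(out$start, out$end), , drop = FALSE]
}

oracle_count_observable <- function(sequence, max_missed = 1,
                                    mass_min = 500, mass_max = 3000,
                                    protease = "trypsin") {
  pep <- oracle_digest(sequence, max_missed, protease)
  masses <- vapply(pep$sequence, oracle_peptide_mass, numeric(1))
  sum(!is.na(masses) & masses >= mass_min & masses <= mass_max)
}

# Pooled two-sample t-test p-value from the closed-form statistic and the
# incomplete-beta tail P(|T| >= t) = I_{df/(df+t^2)}(df/2, 1/2).
oracle_pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  pbeta(df / (df + t^2), df / 2, 1 / 2)
}

# Hypergeometric upper tail by direct enumeration of point masses with
# choose(); background N, term size m, query size k, observed overlap x.
oracle_hyper_tail <- function(x, m, N, k) {
  hi <- min(m, k)
  if (x > hi) return(0)
  sum(vapply(x:hi, function(i) {
    choose(m, i) * choose(N - m, k - i) / choose(N, k)
  }, numeric(1)))
}

# Random protein sequence over the 20 standard residues.
random_protein <- function(len, kr_boost = TRUE) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  prob <- rep(1 / 20, 20)
  paste(sample(aa, len, replace = TRUE, prob = prob), collapse = "")
}

# Tiny two-group identification fixture built in code.
make_tiny_db <- function() {
  data.frame(
    accession = c("P1", "P2", "P3", "P4"),
    gene_symbol = c("Mpo", "Elane", "Ltf", ""),
    sequence = c(
      "MKWVTFISLLKFLCLVFPAYSRGVFRRDAHKSEVAHRFKDLGEEHFK",
      "GLSDGEWQLVLNVWGKVEADIPGHGQEVLIRLFKGHPETLEKFDKFK",
      "AEFVEVTKLVTDLTKVHTECCHGDLLECADDRADLAKYICDNQDTISSK",
      "VLSPADKTNVKAAWGKVGAHAGEYGAEALERMFLSFPTTKTYFPHF"),
    stringsAsFactors = FALSE)
}
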