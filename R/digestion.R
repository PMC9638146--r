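# Residue masses in Da. Peptide mass = sum of residue masses + one water.
# Ambiguity codes (B, Z, X) and the rare translated residues U, O carry no
# mass here; peptides containing them are excluded from observable counts.
.RESIDUE_MASS <- list(
  monoisotopic = c(
    G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
    V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
    I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
    K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
    F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313),
  average = c(
    G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
    V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
    I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
    K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
    F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
)
.WATER_MASS <- c(monoisotopic = 18.010565, average = 18.01528)

#' Digestion parameters
#'
#' Bundles the protease rule and observability filter used to count the
#' peptides of a protein that a mass spectrometer could in principle detect
#' (the denominator of emPAI).
#'
#' @param protease Cleavage rule. `"trypsin"` cleaves C-terminal of K or R
#'   except when the next residue is P (the Keil rule); `"trypsin/P"` ignores
#'   the proline suppression. Both rules are offered because search engines
#'   support either and published searches rarely state which was used.
#' @param max_missed_cleavages Maximum number of uncut internal sites retained
#'   in a peptide (0--5). Default 1, a common database-search setting.
#' @param mass_min_da,mass_max_da Peptide mass window in Da defining
#'   "observable". Default 500--3000 Da, a typical LC-MS/MS precursor range.
#' @param mass_type `"monoisotopic"` (default) or `"average"`.
#'
#' @return An object of class `digest_params`.
#' @examples
#' digest_params()
#' digest_params(protease = "trypsin/P", max_missed_cleavages = 2)
#' @export
digest_params <- function(protease = c("trypsin", "trypsin/P"),
                          max_missed_cleavages = 1L,
                          mass_min_da = 500, mass_max_da = 3000,
                          mass_type = c("monoisotopic", "average")) {
  if (is.character(protease) && length(protease) == 1L &&
      !protease %in% c("trypsin", "trypsin/P")) {
    stop("unknown protease rule: '", protease, "'", call. = FALSE)
  }
  protease <- match.arg(protease)
  mass_type <- match.arg(mass_type)
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  stopifnot(length(max_missed_cleavages) == 1L, max_missed_cleavages >= 0L,
            max_missed_cleavages <= 5L,
            is.numeric(mass_min_da), is.numeric(mass_max_da),
            mass_min_da < mass_max_da)
  structure(list(protease = protease,
                 max_missed_cleavages = max_missed_cleavages,
                 mass_min_da = mass_min_da, mass_max_da = mass_max_da,
                 mass_type = mass_type),
            class = "digest_params")
}

#' @export
print.digest_params <- function(x, ...) {
  cat("Digestion parameters\n")
  cat("  protease:            ", x$protease, "\n")
  cat("  max missed cleavages:", x$max_missed_cleavages, "\n")
  cat("  observable window:   ", x$mass_min_da, "-", x$mass_max_da, "Da (",
      x$mass_type, ")\n", sep = "")
  invisible(x)
}

# 1-based residue positions after which the protease cuts.
.cleavage_sites <- function(residues, protease) {
  n <- length(residues)
  if (n < 2L) return(integer(0))
  cut <- residues[-n] %in% c("K", "R")
  if (protease == "trypsin") cut <- cut & residues[-1L] != "P"
  which(cut)
}

#' In-silico protease digestion
#'
#' Enumerates every peptide producible from a protein sequence under the
#' cleavage rule with up to `max_missed_cleavages` uncut internal sites.
#' No mass filtering is applied here; see [count_observable()].
#'
#' @param sequence A single protein sequence (character scalar, amino-acid
#'   one-letter codes; ambiguity codes B/Z/X/U/O are tolerated but yield
#'   `NA` masses).
#' @param params A [digest_params()] object.
#'
#' @return A data frame with one row per peptide, unique by coordinate:
#'   `sequence`, `start`, `end` (0-based half-open coordinates in the parent),
#'   `missed_cleavages`, and `mass_da` (`NA` when a residue has no defined
#'   mass).
#' @examples
#' digest("AKRPGK", digest_params(max_missed_cleavages = 0))
#' @export
digest <- function(sequence, params = digest_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            !is.na(sequence), nchar(sequence) >= 1L)
  stopifnot(inherits(params, "digest_params"))
  residues <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(residues)
  bounds <- c(0L, .cleavage_sites(residues, params$protease), n)
  nseg <- length(bounds) - 1L
  starts <- ends <- mc <- integer(0)
  for (i in seq_len(nseg)) {
    jmax <- min(nseg, i + params$max_missed_cleavages)
    j <- i:jmax
    starts <- c(starts, rep.int(bounds[i], length(j)))
    ends <- c(ends, bounds[j + 1L])
    mc <- c(mc, j - i)
  }
  seqs <- substring(sequence, starts + 1L, ends)
  data.frame(sequence = seqs, start = starts, end = ends,
             missed_cleavages = mc,
             mass_da = .peptide_mass_or_na(seqs, params$mass_type),
             stringsAsFactors = FALSE)
}

# Vectorized mass; NA where any residue lacks a defined mass.
.peptide_mass_or_na <- function(sequences, mass_type = "monoisotopic") {
  tab <- .RESIDUE_MASS[[mass_type]]
  vapply(strsplit(toupper(sequences), "", fixed = TRUE), function(res) {
    m <- tab[res]
    if (anyNA(m)) NA_real_ else sum(m) + .WATER_MASS[[mass_type]]
  }, numeric(1))
}

#' Peptide mass
#'
#' Mass of a peptide as the sum of its residue masses plus one water
#' (18.010565 Da monoisotopic).
#'
#' @param sequence Peptide sequence(s), standard one-letter codes only.
#' @param mass_type `"monoisotopic"` (default) or `"average"`.
#' @return Numeric vector of masses in Da.
#' @examples
#' peptide_mass("G")   # 75.032029
#' @export
peptide_mass <- function(sequence, mass_type = c("monoisotopic", "average")) {
  mass_type <- match.arg(mass_type)
  m <- .peptide_mass_or_na(sequence, mass_type)
  if (anyNA(m)) {
    bad <- sequence[is.na(m)]
    stop("mass undefined for peptide(s) containing non-standard residues: ",
         paste(utils::head(bad, 3L), collapse = ", "), call. = FALSE)
  }
  m
}

#' Count observable peptides
#'
#' Number of distinct digestion peptides of a protein whose mass falls in the
#' observable window -- the denominator of the protein abundance index.
#' Peptides containing residues without a defined mass (B/Z/X/U/O) are
#' excluded with a message.
#'
#' @inheritParams digest
#' @return A non-negative integer count.
#' @examples
#' count_observable("MKWVTFISLLLLFSSAYSRGVFRR")
#' @export
count_observable <- function(sequence, params = digest_params()) {
  pep <- digest(sequence, params)
  if (anyNA(pep$mass_da)) {
    message(sum(is.na(pep$mass_da)),
            " peptide(s) with undefined mass excluded from observable count")
    pep <- pep[!is.na(pep$mass_da), , drop = FALSE]
  }
  sum(pep$mass_da >= params$mass_min_da & pep$mass_da <= params$mass_max_da)
}

#' Read a protein database from FASTA
#'
#' Headers are parsed as `>accession[ |]description`; a gene symbol is taken
#' from a `GN=` token in the description when present. Wrapped and unwrapped
#' sequence lines are both accepted.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `accession`, `gene_symbol` (may be
#'   `""`), and `sequence`.
#' @export
read_fasta_db <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no records in FASTA file: ", path, call. = FALSE)
  headers <- names(aa)
  accession <- vapply(strsplit(headers, "[ |]"), `[`, character(1), 1L)
  if (anyDuplicated(accession)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(accession[duplicated(accession)]), collapse = ", "),
         call. = FALSE)
  }
  gn <- regmatches(headers, regexpr("GN=[^[:space:]]+", headers))
  gene_symbol <- character(length(headers))
  has_gn <- grepl("GN=", headers, fixed = TRUE)
  gene_symbol[has_gn] <- sub("^GN=", "", gn)
  seqs <- as.character(aa)
  if (any(nchar(seqs) < 1L)) stop("empty sequence in FASTA", call. = FALSE)
  data.frame(accession = accession, gene_symbol = gene_symbol,
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write a protein database to FASTA
#'
#' @param db Data frame as returned by [read_fasta_db()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_db <- function(db, path) {
  stopifnot(all(c("accession", "gene_symbol", "sequence") %in% names(db)))
  aa <- Biostrings::AAStringSet(db$sequence)
  names(aa) <- ifelse(nzchar(db$gene_symbol),
                      paste0(db$accession, " GN=", db$gene_symbol),
                      db$accession)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
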