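# Sequence feature extraction: FASTA IO, physicochemical descriptors,
# amino-acid composition, and data-driven k-mer fraction features.

#' Read a protein FASTA file into a named sequence vector
#'
#' Parses a (possibly line-wrapped) multi-record protein FASTA and returns
#' the proteome as a named character vector, one canonical-alphabet sequence
#' per accession. The accession is the first whitespace-delimited token of
#' the header; UniProt-style `sp|ACC|NAME` (or `tr|...`) headers yield the
#' central accession.
#'
#' Residues outside the 20-letter alphabet are handled according to
#' `sanitize_policy`:
#' \describe{
#'   \item{`"map"`}{(default) U is mapped to C, B to D, Z to E; anything else
#'     (X, J, O, `*`, gaps) is removed. A warning lists affected records.}
#'   \item{`"drop-residue"`}{every nonstandard letter is removed.}
#'   \item{`"drop-protein"`}{records containing any nonstandard letter are
#'     discarded with a warning.}
#' }
#' Records whose sequence is empty after sanitization are dropped with a
#' warning; duplicate accessions are an error.
#'
#' @param path Path to a FASTA file.
#' @param sanitize_policy One of `"map"`, `"drop-residue"`, `"drop-protein"`.
#' @return Named character vector: `names` are accessions, values sequences.
#' @export
read_fasta <- function(path, sanitize_policy = c("map", "drop-residue", "drop-protein")) {
  sanitize_policy <- match.arg(sanitize_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  acc <- vapply(strsplit(headers, "[ \t]+"), `[`, "", 1L)
  pipey <- grepl("^(sp|tr)\\|", acc)
  acc[pipey] <- vapply(strsplit(acc[pipey], "\\|"), `[`, "", 2L)
  if (anyDuplicated(acc))
    stop("duplicate accession(s): ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- acc
  sanitize_sequences(seqs, sanitize_policy)
}

# Apply a sanitization policy to a named sequence vector.
sanitize_sequences <- function(seqs, policy) {
  clean_pat <- paste0("[^", paste(AA_ALPHA, collapse = ""), "]")
  dirty <- grepl(clean_pat, seqs)
  if (any(dirty)) {
    if (policy == "drop-protein") {
      warning("dropping ", sum(dirty), " record(s) with nonstandard residues: ",
              paste(utils::head(names(seqs)[dirty], 5L), collapse = ", "))
      seqs <- seqs[!dirty]
    } else {
      if (policy == "map")
        seqs <- chartr("UBZ", "CDE", seqs)
      seqs <- gsub(clean_pat, "", seqs)
      warning("sanitized nonstandard residues in ", sum(dirty), " record(s) (policy: ",
              policy, ")")
    }
  }
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " record(s) empty after sanitization: ",
            paste(names(seqs)[empty], collapse = ", "))
    seqs <- seqs[!empty]
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over all residues.
#'
#' @param sequence Canonical-alphabet protein sequence.
#' @return A single number (dimensionless; negative = hydrophilic end of the
#'   scale).
#' @export
compute_gravy <- function(sequence) {
  check_sequence(sequence)
  mean(KD_SCALE[aa_index(sequence)])
}

# Net charge of a sequence at a given pH under the Henderson-Hasselbalch
# model with the EMBOSS pKa set; counts are precomputed by the caller.
net_charge_at <- function(pH, counts) {
  pos <- counts[c("Nterm", "K", "R", "H")]
  neg <- counts[c("Cterm", "D", "E", "C", "Y")]
  sum(pos / (1 + 10^(pH - PKA_POS))) - sum(neg / (1 + 10^(PKA_NEG - pH)))
}

charge_counts <- function(sequence) {
  idx <- aa_index(sequence)
  tab <- tabulate(idx, nbins = 20L)
  names(tab) <- AA_ALPHA
  c(Nterm = 1, Cterm = 1, tab[c("K", "R", "H", "D", "E", "C", "Y")])
}

#' Net charge at a given pH
#'
#' Modeled net charge (Henderson-Hasselbalch, EMBOSS pKa values, free N- and
#' C-termini included).
#'
#' @param sequence Protein sequence.
#' @param pH pH at which to evaluate the charge.
#' @return Net charge in elementary-charge units.
#' @export
compute_net_charge <- function(sequence, pH = 7.0) {
  check_sequence(sequence)
  net_charge_at(pH, charge_counts(sequence))
}

#' Isoelectric point
#'
#' pH at which the modeled net charge is zero, found by bisection on
#' \[0, 14\] to a charge tolerance of 1e-6. Uses the EMBOSS pKa set
#' (N-terminus 8.6, C-terminus 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1,
#' C 8.5, Y 10.1).
#'
#' @param sequence Protein sequence.
#' @return pI in pH units.
#' @export
compute_pi <- function(sequence) {
  check_sequence(sequence)
  counts <- charge_counts(sequence)
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- net_charge_at(mid, counts)
    if (abs(q) < 1e-6) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

# Shannon entropies (bits) of all sliding windows of length w over the
# integer-coded sequence. Sequences shorter than w yield the single
# whole-sequence window.
window_entropies <- function(idx, w) {
  L <- length(idx)
  if (L <= w) {
    p <- tabulate(idx, nbins = 20L)
    p <- p[p > 0] / L
    return(-sum(p * log2(p)))
  }
  onehot <- matrix(0L, nrow = L, ncol = 20L)
  onehot[cbind(seq_len(L), idx)] <- 1L
  cs <- rbind(0L, apply(onehot, 2L, cumsum))
  counts <- cs[(w + 1L):(L + 1L), , drop = FALSE] - cs[1L:(L - w + 1L), , drop = FALSE]
  p <- counts / w
  plp <- p * log2(p)
  plp[p == 0] <- 0
  -rowSums(plp)
}

#' Low-complexity-region fraction
#'
#' Slides a window along the sequence; a window is low-complexity when its
#' Shannon entropy (base-2, over residue frequencies) falls below
#' `entropy_threshold`. A residue is inside an LCR if at least one
#' low-complexity window covers it. Sequences shorter than the window are
#' scored with a single whole-sequence window. Defaults follow SEG-like
#' trigger settings (window 12, threshold 2.2 bits).
#'
#' @param sequence Protein sequence.
#' @param window Window length in residues (>= 2).
#' @param entropy_threshold Entropy threshold in bits.
#' @return Fraction of residues inside low-complexity regions, in \[0, 1\].
#' @export
compute_lcr_fraction <- function(sequence, window = 12L, entropy_threshold = 2.2) {
  check_sequence(sequence)
  if (window < 2L) stop("`window` must be >= 2")
  idx <- aa_index(sequence)
  L <- length(idx)
  ent <- window_entropies(idx, window)
  low <- ent < entropy_threshold
  if (L <= window) return(if (low) 1 else 0)
  starts <- which(low)
  if (length(starts) == 0L) return(0)
  ends <- pmin(starts + window, L + 1L)
  cover <- cumsum(tabulate(starts, nbins = L + 1L) - tabulate(ends, nbins = L + 1L)) > 0
  sum(cover[seq_len(L)]) / L
}

#' Names of the 19 physicochemical descriptors, in canonical order
#' @return Character vector of length 19.
#' @export
physchem_feature_names <- function() {
  c("length", "mol_weight", "pI", "gravy", "lcr_fraction",
    "aromaticity", "net_charge_pH7", "frac_positive", "frac_negative",
    "frac_charged", "charge_asymmetry", "frac_polar", "frac_tiny",
    "frac_proline", "frac_glycine", "frac_cysteine", "frac_serine",
    "mean_flexibility", "max_run_fraction")
}

#' Physicochemical descriptor vector (n = 19)
#'
#' Computes the full physicochemical block for one sequence: length,
#' molecular weight (Da), isoelectric point, GRAVY, LCR fraction,
#' aromaticity (F+W+Y fraction), net charge at pH 7, fractions of positive
#' (K+R), negative (D+E), and all charged residues, charge asymmetry
#' (positive minus negative fraction), polar fraction (S,T,N,Q,C,Y), tiny
#' fraction (A,G,S), proline/glycine/cysteine/serine fractions, mean Vihinen
#' flexibility, and the longest homopolymer run divided by length.
#'
#' @param sequence Protein sequence.
#' @param lcr_window,lcr_threshold LCR detection parameters
#'   (see [compute_lcr_fraction()]).
#' @return Named numeric vector with exactly 19 entries.
#' @export
compute_physchem <- function(sequence, lcr_window = 12L, lcr_threshold = 2.2) {
  check_sequence(sequence)
  idx <- aa_index(sequence)
  L <- length(idx)
  comp <- tabulate(idx, nbins = 20L) / L
  names(comp) <- AA_ALPHA
  frac <- function(letters) sum(comp[letters])
  runs <- rle(idx)
  out <- c(
    length           = L,
    mol_weight       = sum(AA_MASS[idx]) + WATER_MASS,
    pI               = compute_pi(sequence),
    gravy            = mean(KD_SCALE[idx]),
    lcr_fraction     = compute_lcr_fraction(sequence, lcr_window, lcr_threshold),
    aromaticity      = frac(c("F", "W", "Y")),
    net_charge_pH7   = compute_net_charge(sequence, 7.0),
    frac_positive    = frac(c("K", "R")),
    frac_negative    = frac(c("D", "E")),
    frac_charged     = frac(c("K", "R", "D", "E")),
    charge_asymmetry = frac(c("K", "R")) - frac(c("D", "E")),
    frac_polar       = frac(c("S", "T", "N", "Q", "C", "Y")),
    frac_tiny        = frac(c("A", "G", "S")),
    frac_proline     = frac("P"),
    frac_glycine     = frac("G"),
    frac_cysteine    = frac("C"),
    frac_serine      = frac("S"),
    mean_flexibility = mean(AA_FLEX[idx]),
    max_run_fraction = max(runs$lengths) / L
  )
  names(out) <- physchem_feature_names()
  out
}

#' Amino-acid composition fractions
#'
#' @param sequence Protein sequence.
#' @return Named numeric vector of 20 fractions (names `aa_A` .. `aa_Y`)
#'   summing to 1.
#' @export
aa_composition <- function(sequence) {
  check_sequence(sequence)
  comp <- tabulate(aa_index(sequence), nbins = 20L) / nchar(sequence)
  names(comp) <- paste0("aa_", AA_ALPHA)
  comp
}

# All overlapping k-mers of a sequence, in order of occurrence.
kmer_windows <- function(sequence, k) {
  L <- nchar(sequence)
  if (L < k) return(character(0))
  substring(sequence, 1L:(L - k + 1L), k:L)
}

#' Select the most abundant k-mers from a positive set
#'
#' Counts overlapping k-mer occurrences summed over all supplied sequences
#' and returns the `top_n` k-mers by total count, ties broken
#' alphabetically. When fewer than `top_n` distinct k-mers exist, all
#' observed k-mers are returned and the result carries attribute
#' `short = TRUE` (with a warning).
#'
#' @param positives Named character vector of positive-class sequences.
#' @param k k-mer length (2 or 3).
#' @param top_n Number of k-mers to keep.
#' @return Character vector of k-mers, ordered by decreasing total count;
#'   attribute `counts` holds the totals.
#' @export
select_kmer_vocabulary <- function(positives, k, top_n = 50L) {
  if (!k %in% c(2L, 3L)) stop("`k` must be 2 or 3")
  if (length(positives) == 0L) stop("no positive sequences supplied")
  all_kmers <- unlist(lapply(positives, kmer_windows, k = k), use.names = FALSE)
  if (length(all_kmers) == 0L)
    stop("no sequence of length >= ", k, " among positives")
  counts <- table(all_kmers)
  ord <- order(-as.integer(counts), names(counts))
  counts <- counts[ord]
  n_take <- min(top_n, length(counts))
  vocab <- names(counts)[seq_len(n_take)]
  attr(vocab, "counts") <- as.integer(counts)[seq_len(n_take)]
  if (n_take < top_n) {
    attr(vocab, "short") <- TRUE
    warning("only ", n_take, " distinct ", k, "-mers observed (requested ", top_n, ")")
  }
  vocab
}

#' Build the 2-mer/3-mer vocabulary from training positives
#'
#' @param positives Named character vector of positive-class sequences.
#' @param top_n Vocabulary size per k.
#' @return List with components `k2` and `k3` (see
#'   [select_kmer_vocabulary()]).
#' @export
build_vocabulary <- function(positives, top_n = 50L) {
  list(k2 = select_kmer_vocabulary(positives, 2L, top_n),
       k3 = select_kmer_vocabulary(positives, 3L, top_n))
}

#' Overlapping k-mer fractions over a fixed vocabulary
#'
#' For each vocabulary k-mer, the overlapping occurrence count divided by
#' the number of length-k windows (L - k + 1). Sequences shorter than k
#' yield all-zero fractions.
#'
#' @param sequence Protein sequence.
#' @param vocabulary Character vector of k-mers of uniform length.
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
kmer_fractions <- function(sequence, vocabulary) {
  if (length(vocabulary) == 0L) stop("empty vocabulary")
  k <- unique(nchar(vocabulary))
  if (length(k) != 1L) stop("vocabulary must have uniform k-mer length")
  L <- nchar(sequence)
  out <- numeric(length(vocabulary))
  names(out) <- vocabulary
  if (L < k) return(out)
  counts <- table(kmer_windows(sequence, k))
  hit <- match(vocabulary, names(counts))
  out[!is.na(hit)] <- as.integer(counts)[hit[!is.na(hit)]]
  out / (L - k + 1L)
}

#' Build the full feature table for a set of proteins
#'
#' Assembles the canonical 139-column representation: 19 physicochemical
#' descriptors, 20 amino-acid composition fractions, and the fractions of
#' the vocabulary's 50 2-mers and 50 3-mers (column names prefixed `k2_` /
#' `k3_`). The vocabulary must be selected from training positives before
#' the call; column order is fixed by the vocabulary and persists with any
#' model trained on the table.
#'
#' @param records Named character vector of sequences (names = accessions).
#' @param vocabulary List with `k2` and `k3` components
#'   (see [build_vocabulary()]).
#' @param lcr_window,lcr_threshold LCR detection parameters.
#' @return Numeric matrix, one row per record (rownames = accessions).
#' @export
build_feature_table <- function(records, vocabulary,
                                lcr_window = 12L, lcr_threshold = 2.2) {
  if (length(records) == 0L) stop("no records supplied")
  if (is.null(names(records)) || anyDuplicated(names(records)))
    stop("records must be uniquely named by accession")
  rows <- lapply(records, function(s) {
    c(compute_physchem(s, lcr_window, lcr_threshold),
      aa_composition(s),
      stats::setNames(kmer_fractions(s, vocabulary$k2),
                      paste0("k2_", vocabulary$k2)),
      stats::setNames(kmer_fractions(s, vocabulary$k3),
                      paste0("k3_", vocabulary$k3)))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- names(records)
  if (!all(is.finite(tab)))
    stop("non-finite feature value(s) in rows: ",
         paste(utils::head(rownames(tab)[!stats::complete.cases(tab) |
                                           rowSums(!is.finite(tab)) > 0], 5L),
               collapse = ", "))
  tab
}
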