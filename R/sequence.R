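#' @title Peptide sequences and the hairpin interaction census
#' @description Parsing of capped one-letter sequences, the four-group
#'   polarity classification, the positional facing-pair register of an
#'   antiparallel hairpin, the eight inter-strand backbone hydrogen bonds,
#'   and the census of stabilizing non-covalent pairs.
#' @name sequence-analysis
NULL

# Four-group polarity classification. Side chains are grouped by charge
# state at neutral pH and polarity; histidine is counted as positively
# charged, tyrosine and cysteine as uncharged polar, proline and glycine
# as non-polar.
POLARITY_TABLE <- c(
  R = "positive-polar", K = "positive-polar", H = "positive-polar",
  D = "negative-polar", E = "negative-polar",
  S = "uncharged-polar", T = "uncharged-polar", N = "uncharged-polar",
  Q = "uncharged-polar", Y = "uncharged-polar", C = "uncharged-polar",
  W = "uncharged-polar",
  A = "non-polar", V = "non-polar", L = "non-polar", I = "non-polar",
  M = "non-polar", F = "non-polar", P = "non-polar", G = "non-polar"
)

AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Classify a residue into one of four polarity groups
#'
#' Groups: positively charged polar (R, K, H), negatively charged polar
#' (D, E), uncharged polar (S, T, N, Q, Y, C, W) and non-polar /
#' hydrophobic (A, V, L, I, M, F, P, G).
#'
#' @param code One-letter amino-acid code (vectorized).
#' @return Character vector of polarity classes.
#' @export
#' @examples
#' classify_residue(c("R", "L", "Q"))
classify_residue <- function(code) {
  code <- toupper(as.character(code))
  bad <- !code %in% names(POLARITY_TABLE)
  if (any(bad)) {
    stop("invalid residue code(s): ", paste(unique(code[bad]), collapse = ", "))
  }
  unname(POLARITY_TABLE[code])
}

#' Parse a one-letter peptide sequence
#'
#' Residues are numbered 1..L; terminal capping groups (acetyl at the
#' N-terminus, N-methyl amide at the C-terminus) are recorded as flags and
#' never carry a residue index, so numbering matches the uncapped sequence.
#'
#' @param one_letter Character scalar of standard one-letter codes.
#' @param label Free-text label (e.g. `"EF1"`).
#' @param capped Logical; if `TRUE`, record Ace/Nme caps.
#' @return A `peptide_sequence` object: data frame of residues
#'   (`index`, `code`, `code3`, `polarity`) plus cap and label attributes.
#' @export
#' @examples
#' ef1 <- parse_sequence("DYATLQLQEGRLHFMFDLG", label = "EF1", capped = TRUE)
#' ef1
parse_sequence <- function(one_letter, label = "", capped = FALSE) {
  stopifnot(is.character(one_letter), length(one_letter) == 1L,
            nzchar(one_letter))
  codes <- strsplit(toupper(one_letter), "")[[1]]
  bad <- which(!codes %in% names(POLARITY_TABLE))
  if (length(bad)) {
    stop(sprintf("invalid sequence: unknown letter '%s' at position %d",
                 codes[bad[1]], bad[1]))
  }
  res <- data.frame(
    index = seq_along(codes),
    code = codes,
    code3 = unname(AA_THREE[codes]),
    polarity = classify_residue(codes),
    stringsAsFactors = FALSE
  )
  structure(
    list(residues = res,
         n_term_cap = if (capped) "ACE" else NA_character_,
         c_term_cap = if (capped) "NME" else NA_character_,
         label = label),
    class = "peptide_sequence"
  )
}

#' @export
print.peptide_sequence <- function(x, ...) {
  caps <- if (!is.na(x$n_term_cap)) {
    sprintf("%s-...-%s", x$n_term_cap, x$c_term_cap)
  } else "uncapped"
  cat(sprintf("<peptide_sequence> %s: %s (%d residues, %s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              paste(x$residues$code, collapse = ""),
              nrow(x$residues), caps))
  invisible(x)
}

#' @export
length.peptide_sequence <- function(x) nrow(x$residues)

#' Positional facing pairs of an antiparallel hairpin
#'
#' In a two-strand antiparallel hairpin of length L with a central turn,
#' residue i on the N-strand faces residue L - i on the C-strand. All pairs
#' (i, L - i) with i < L - i and (L - i) - i >= 2 are returned; for L = 19
#' that is (1,18)..(8,11), leaving the turn (9,10) and the last residue
#' unpaired. Even-index pairs carry the inter-strand backbone hydrogen
#' bonds; each pair is annotated with the interaction kind its residues
#' support.
#'
#' @param seq A `peptide_sequence`.
#' @return Data frame with columns `i`, `j`, `kind`, `residue_i`,
#'   `residue_j`. `kind` is one of `hbond-register`, `hydrophobic`, `none`.
#' @export
facing_pairs <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  L <- length(seq)
  if (L < 5L) stop("no register: need at least 5 residues")
  i <- seq_len(floor((L - 1) / 2))
  j <- L - i
  keep <- (j - i) >= 2L
  i <- i[keep]; j <- j[keep]
  codes <- seq$residues$code
  pol <- seq$residues$polarity
  kind <- ifelse(i %% 2L == 0L, "hbond-register",
                 ifelse(pol[i] == "non-polar" & pol[j] == "non-polar",
                        "hydrophobic", "none"))
  data.frame(i = i, j = j, kind = kind,
             residue_i = codes[i], residue_j = codes[j],
             stringsAsFactors = FALSE)
}

#' Register hydrogen bonds of the hairpin (HB1..HB8)
#'
#' Each even-index facing pair (i, j = L - i) contributes two backbone
#' hydrogen bonds between the strands: the amide of residue i donating to
#' the carbonyl of residue j, and the carbonyl of residue i accepting from
#' the amide of residue j. For a 19-residue hairpin this yields the eight
#' bonds HB1..HB8 on pairs (2,17), (4,15), (6,13), (8,11), ordered outermost
#' first.
#'
#' @param seq A `peptide_sequence`.
#' @return Data frame with columns `label`, `donor_residue`, `donor_atom`,
#'   `acceptor_residue`, `acceptor_atom`, plus three-letter residue names.
#' @export
#' @examples
#' hbond_register(parse_sequence("DYATLQLQEGRLHFMFDLG", "EF1", capped = TRUE))
hbond_register <- function(seq) {
  fp <- facing_pairs(seq)
  reg <- fp[fp$kind == "hbond-register", , drop = FALSE]
  if (nrow(reg) == 0L) stop("no even-index register pairs for this length")
  code3 <- seq$residues$code3
  out <- do.call(rbind, lapply(seq_len(nrow(reg)), function(k) {
    i <- reg$i[k]; j <- reg$j[k]
    data.frame(
      label = sprintf("HB%d", 2L * k - c(1L, 0L)),
      donor_residue = c(i, j), donor_atom = "N",
      acceptor_residue = c(j, i), acceptor_atom = "O",
      donor_name = code3[c(i, j)], acceptor_name = code3[c(j, i)],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Facing hydrophobic pairs
#'
#' Non-register (odd-index) facing pairs where both residues are non-polar;
#' these are the inter-strand hydrophobic contacts that alternate with the
#' hydrogen-bonded pairs along the hairpin.
#'
#' @param seq A `peptide_sequence`.
#' @return Data frame subset of [facing_pairs()].
#' @export
hydrophobic_pairs <- function(seq) {
  fp <- facing_pairs(seq)
  fp[fp$kind == "hydrophobic", , drop = FALSE]
}

#' Possible ionic pairs in the turn region
#'
#' A deterministic positional heuristic for salt bridges near the turn:
#' pairs of oppositely charged residues with sequence separation at most 2,
#' both inside the central region (positions 8..12 of a 19-residue
#' hairpin, scaled as the middle five positions).
#'
#' @param seq A `peptide_sequence`.
#' @return Data frame with columns `i`, `j`, `kind`, `residue_i`, `residue_j`.
#' @export
ionic_pairs <- function(seq) {
  stopifnot(inherits(seq, "peptide_sequence"))
  L <- length(seq)
  mid <- (L + 1) / 2
  lo <- max(1L, floor(mid - 2)); hi <- min(L, ceiling(mid + 2))
  pol <- seq$residues$polarity
  codes <- seq$residues$code
  out <- data.frame(i = integer(), j = integer(), kind = character(),
                    residue_i = character(), residue_j = character(),
                    stringsAsFactors = FALSE)
  idx <- lo:hi
  for (a in idx) {
    for (b in idx) {
      if (b <= a || (b - a) > 2L) next
      opp <- (pol[a] == "positive-polar" && pol[b] == "negative-polar") ||
             (pol[a] == "negative-polar" && pol[b] == "positive-polar")
      if (opp) {
        out <- rbind(out, data.frame(
          i = a, j = b, kind = "ionic",
          residue_i = codes[a], residue_j = codes[b],
          stringsAsFactors = FALSE))
      }
    }
  }
  out
}

#' Census of stabilizing non-covalent pairs
#'
#' Counts the hydrogen-bonded register pairs (always 4 for a 19-residue
#' hairpin), the facing hydrophobic pairs, and the turn-region ionic pairs,
#' and their total. The total separates a stable hairpin (8 pairs for the
#' EF1 sequence) from a marginal one (6 pairs for EF2).
#'
#' @param seq A `peptide_sequence`.
#' @return List of class `noncovalent_census` with counts and the underlying
#'   pair tables.
#' @export
#' @examples
#' noncovalent_census(parse_sequence("DYATLQLQEGRLHFMFDLG", "EF1", TRUE))
noncovalent_census <- function(seq) {
  fp <- facing_pairs(seq)
  reg <- fp[fp$kind == "hbond-register", , drop = FALSE]
  phob <- fp[fp$kind == "hydrophobic", , drop = FALSE]
  ion <- ionic_pairs(seq)
  structure(
    list(label = seq$label,
         n_hbond_registers = nrow(reg),
         n_hydrophobic = nrow(phob),
         n_ionic = nrow(ion),
         total = nrow(reg) + nrow(phob) + nrow(ion),
         register_pairs = reg, hydrophobic_pairs = phob, ionic_pairs = ion),
    class = "noncovalent_census"
  )
}

#' @export
print.noncovalent_census <- function(x, ...) {
  cat(sprintf(
    "<noncovalent_census> %s: %d H-bond register + %d hydrophobic + %d ionic = %d pairs\n",
    if (nzchar(x$label)) x$label else "(unlabelled)",
    x$n_hbond_registers, x$n_hydrophobic, x$n_ionic, x$total))
  invisible(x)
}

#' Census as a flat pair table
#'
#' @param census A `noncovalent_census`.
#' @return Data frame with columns `pair_i`, `pair_j`, `kind`, `residue_i`,
#'   `residue_j`, suitable for TSV export.
#' @export
census_table <- function(census) {
  stopifnot(inherits(census, "noncovalent_census"))
  parts <- rbind(census$register_pairs, census$hydrophobic_pairs,
                 census$ionic_pairs)
  data.frame(pair_i = parts$i, pair_j = parts$j, kind = parts$kind,
             residue_i = parts$residue_i, residue_j = parts$residue_j,
             stringsAsFactors = FALSE)
}

#' Bundled hairpin peptide sequences
#'
#' The two laminin LG4-module loop peptides studied throughout the package:
#' EF1 (`DYATLQLQEGRLHFMFDLG`), which folds into a stable antiparallel
#' hairpin, and the homologous EF2 (`DFATVQLRNGFPYFSYDLG`), which does not.
#' Both are acetyl/N-methyl capped.
#'
#' @param name `"EF1"` or `"EF2"`.
#' @return A `peptide_sequence`.
#' @export
hairpin_peptide <- function(name = c("EF1", "EF2")) {
  name <- match.arg(name)
  seqs <- c(EF1 = "DYATLQLQEGRLHFMFDLG", EF2 = "DFATVQLRNGFPYFSYDLG")
  parse_sequence(seqs[[name]], label = name, capped = TRUE)
}
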