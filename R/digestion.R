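#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence after every lysine (K) or arginine (R) that is
#' not immediately followed by proline (P), with no missed cleavages: every
#' fragment contains zero internal cut sites. Fragments shorter than
#' `min_length` residues are discarded; the survivors are the protein's
#' theoretical tryptic peptides.
#'
#' Ambiguous residues (B, J, O, U, X, Z) are accepted and treated as
#' non-cleaving; a warning is emitted once per call. A trailing stop codon
#' `*` is stripped with a warning. Input case is ignored.
#'
#' @param sequence Single amino-acid string.
#' @param min_length Minimum peptide length in residues (default 6).
#' @return Character vector of peptides, N- to C-terminal order.
#' @seealso [tryptic_fragments()] for the unfiltered fragments,
#'   [theoretical_counts()] for per-protein counts over a collection.
#' @examples
#' tryptic_peptides("MKAAAAAAR")  # "AAAAAAR"; the fragment "MK" is too short
#' tryptic_peptides("MKPAAAAR")   # KP is a non-cut site
#' @export
tryptic_peptides <- function(sequence, min_length = 6L) {
  frags <- tryptic_fragments(sequence)
  frags[nchar(frags) >= min_length]
}

#' All tryptic fragments of a sequence
#'
#' Like [tryptic_peptides()] but without the length filter, so that
#' concatenating the fragments in order reconstructs the input sequence.
#'
#' @inheritParams tryptic_peptides
#' @return Character vector of fragments covering the whole sequence.
#' @export
tryptic_fragments <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    stop("`sequence` must be a single character string", call. = FALSE)
  }
  seq <- toupper(sequence)
  if (endsWith(seq, "*")) {
    warning("trailing stop character '*' stripped from sequence", call. = FALSE)
    seq <- sub("\\*+$", "", seq)
  }
  if (!nzchar(seq)) {
    stop("empty protein sequence", call. = FALSE)
  }
  if (grepl("[^A-Z]", seq)) {
    stop("sequence contains non-alphabetic characters", call. = FALSE)
  }
  if (grepl("[BJOUXZ]", seq)) {
    warning("ambiguous residues (B/J/O/U/X/Z) treated as non-cleaving",
            call. = FALSE)
  }
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(res)
  # cut after position i when res[i] is K/R and the next residue is not P;
  # a terminal K/R coincides with the sequence end and adds no empty fragment
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  substring(seq, starts, ends)
}

#' Theoretical peptide counts for a protein collection
#'
#' Counts each protein's theoretical tryptic peptides (see
#' [tryptic_peptides()]) and the collection total. Counting is of peptide
#' occurrences, not distinct sequences: a peptide produced twice by one
#' protein counts twice. Proteins yielding zero peptides are retained and
#' flagged `quantifiable = FALSE`; they cannot enter spectral-counting
#' normalization.
#'
#' @param proteome Named character vector of sequences, a
#'   [Biostrings::AAStringSet], or a data frame with columns `protein_id`
#'   and `sequence`. Identifiers must be unique and are matched as given
#'   (isoform-level, no collapsing).
#' @param min_length Minimum peptide length (default 6).
#' @return Object of class `theoretical_digest`: a list with
#'   `counts` (data frame: `protein_id`, `n_peptides`, `quantifiable`) and
#'   `total` (sum of `n_peptides`).
#' @export
theoretical_counts <- function(proteome, min_length = 6L) {
  proteome <- as_protein_vector(proteome)
  if (length(proteome) == 0L) {
    stop("empty protein collection", call. = FALSE)
  }
  if (anyDuplicated(names(proteome))) {
    stop("duplicate protein identifiers in collection", call. = FALSE)
  }
  n_pep <- vapply(proteome, function(s) length(tryptic_peptides(s, min_length)),
                  integer(1), USE.NAMES = FALSE)
  counts <- data.frame(
    protein_id = names(proteome),
    n_peptides = n_pep,
    quantifiable = n_pep > 0L,
    stringsAsFactors = FALSE
  )
  structure(list(counts = counts, total = sum(n_pep)),
            class = "theoretical_digest")
}

#' @export
print.theoretical_digest <- function(x, ...) {
  cat(sprintf("Theoretical digest: %d proteins, %d peptides total (%d unquantifiable)\n",
              nrow(x$counts), x$total, sum(!x$counts$quantifiable)))
  invisible(x)
}

# Accept AAStringSet, named character, or data.frame(protein_id, sequence)
as_protein_vector <- function(proteome) {
  if (methods::is(proteome, "XStringSet")) {
    out <- as.character(proteome)
    # FASTA descriptions: identifier is the first whitespace-delimited token
    names(out) <- sub("\\s.*$", "", names(proteome))
    return(out)
  }
  if (is.data.frame(proteome)) {
    stopifnot(all(c("protein_id", "sequence") %in% names(proteome)))
    out <- proteome$sequence
    names(out) <- proteome$protein_id
    return(out)
  }
  if (is.character(proteome)) {
    if (length(proteome) > 0L && is.null(names(proteome))) {
      stop("character proteome must be named by protein id", call. = FALSE)
    }
    return(proteome)
  }
  stop("unsupported proteome representation", call. = FALSE)
}
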