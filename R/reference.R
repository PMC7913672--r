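#' Reference amplicon with annotated m6A positions
#'
#' Constructs the reference object used throughout the pipeline: a single
#' amplicon sequence plus the 1-based positions annotated as (candidate)
#' m6A sites. RNA input is normalized to the DNA alphabet (U -> T) at this
#' boundary; all downstream logic works on A/C/G/T, matching what the
#' sequencer reports. Coordinates are 1-based and fully closed everywhere
#' user-facing.
#'
#' @param sequence Character scalar, the amplicon sequence (DNA or RNA
#'   alphabet; lower case accepted).
#' @param modified_positions Integer vector of 1-based positions annotated as
#'   m6A. May be empty. Every position must fall inside the sequence and sit
#'   on an A.
#' @param name Text identifier for the amplicon.
#' @return An object of class \code{noseq_reference}: a list with elements
#'   \code{name}, \code{sequence} (normalized DNA string) and
#'   \code{modified_positions} (sorted integer vector).
#' @examples
#' ref <- reference_amplicon("AUGGCA", modified_positions = 6, name = "toy")
#' ref$sequence  # "ATGGCA"
#' @export
reference_amplicon <- function(sequence, modified_positions = integer(),
                               name = "amplicon") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq <- normalize_sequence(sequence)
  if (nchar(seq) == 0L) {
    stop("reference sequence is empty", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), c("A", "C", "G", "T"))
  if (length(bad) > 0L) {
    stop("reference contains characters outside A/C/G/T(/U): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mp <- as.integer(modified_positions)
  if (anyNA(mp)) stop("modified positions must be integers", call. = FALSE)
  if (any(mp < 1L | mp > nchar(seq))) {
    stop("modified position out of range 1..", nchar(seq), call. = FALSE)
  }
  base_at <- if (length(mp) > 0L) substring(seq, mp, mp) else character()
  if (any(base_at != "A")) {
    off <- mp[base_at != "A"][1L]
    stop("modified position ", off, " is not an A (found ",
         substring(seq, off, off), ")", call. = FALSE)
  }
  structure(
    list(name = as.character(name), sequence = seq,
         modified_positions = sort(unique(mp))),
    class = "noseq_reference"
  )
}

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Upper-cases and maps U to T. Idempotent.
#' @param x Character vector of sequences.
#' @return Character vector of normalized sequences.
#' @export
normalize_sequence <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' Read a reference amplicon from a FASTA file
#'
#' The first record of the file is used. U is normalized to T and the
#' annotated modified positions are validated against the sequence (each must
#' be an A).
#'
#' @param path Path to a FASTA file with at least one record.
#' @param modified_positions Integer vector of annotated 1-based m6A positions.
#' @return A \code{\link{reference_amplicon}} object.
#' @export
read_reference <- function(path, modified_positions = integer()) {
  path <- as.character(path)
  recs <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                   error = function(e) {
                     stop("FASTA format error in '", path, "': ",
                          conditionMessage(e), call. = FALSE)
                   })
  if (length(recs) == 0L) {
    stop("FASTA format error: no records in '", path, "'", call. = FALSE)
  }
  reference_amplicon(as.character(recs[[1L]]),
                     modified_positions = modified_positions,
                     name = names(recs)[1L])
}

#' The synthetic 53-mer calibration oligo
#'
#' The synthetic 53-nt RNA oligonucleotide used for deamination condition
#' screening and stoichiometry calibration, carrying a single m6A at position
#' 33 (or plain A in the unmethylated control version). This is the standard
#' in-package fixture for demonstrations and tests.
#'
#' @param methylated If TRUE (default), position 33 is annotated as m6A; if
#'   FALSE the unmodified control oligo (no annotation) is returned.
#' @return A \code{\link{reference_amplicon}} of length 53.
#' @examples
#' ref <- oligo_53mer()
#' nchar(ref$sequence)        # 53
#' ref$modified_positions     # 33
#' @export
oligo_53mer <- function(methylated = TRUE) {
  seq <- "AUAGGGGAAUGGGCCGUUCAUCUGCUAAAAGGACUGCUUUUGGGGCUUGUAGU"
  reference_amplicon(seq,
                     modified_positions = if (methylated) 33L else integer(),
                     name = if (methylated) "53mer_m6A33" else "53mer_A33")
}

#' @export
print.noseq_reference <- function(x, ...) {
  cat("Reference amplicon '", x$name, "' (", nchar(x$sequence), " nt)\n",
      sep = "")
  cat("  sequence: ", abbreviate_seq(x$sequence), "\n", sep = "")
  if (length(x$modified_positions) > 0L) {
    cat("  annotated m6A position(s): ",
        paste(x$modified_positions, collapse = ", "), "\n", sep = "")
  } else {
    cat("  no annotated m6A positions\n")
  }
  invisible(x)
}

abbreviate_seq <- function(s, width = 50L) {
  if (nchar(s) <= width) s else paste0(substr(s, 1L, width - 3L), "...")
}

# positions of a given base in a reference (1-based)
base_positions <- function(reference, base) {
  which(strsplit(reference$sequence, "")[[1L]] == base)
}
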