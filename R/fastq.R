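#' Describe the read layout (insert + optional UMI)
#'
#' Amplicon libraries built with a targeted RT primer carry a 7-nt unique
#' molecular identifier (UMI) downstream of the insert; ligation-based
#' libraries carry none. The layout descriptor states where the UMI sits in
#' each sequenced read so that \code{\link{read_structured_fastq}} can split
#' it off.
#'
#' @param placement One of \code{"none"} (whole read is the insert) or
#'   \code{"trailing"} (the last \code{umi_length} bases are the UMI).
#' @param umi_length UMI length in nt (default 7; ignored for
#'   \code{"none"}).
#' @return A list of class \code{noseq_umi_spec}.
#' @examples
#' umi_spec("trailing")          # amplicon preset: trailing 7-nt UMI
#' umi_spec("none")              # ligation-based library, no UMI
#' @export
umi_spec <- function(placement = c("none", "trailing"), umi_length = 7L) {
  placement <- match.arg(placement)
  umi_length <- as.integer(umi_length)
  if (placement == "trailing" && (is.na(umi_length) || umi_length < 1L)) {
    stop("umi_length must be a positive integer for trailing UMIs",
         call. = FALSE)
  }
  structure(list(placement = placement,
                 umi_length = if (placement == "none") 0L else umi_length),
            class = "noseq_umi_spec")
}

#' Construct a structured-read table
#'
#' Internal-facing constructor for the container used between the simulator,
#' the FASTQ layer and the aligner: one row per read with the insert and UMI
#' already split. Qualities are carried verbatim, never interpreted.
#'
#' @param read_id Character vector of read identifiers.
#' @param insert Character vector of insert sequences (alphabet A/C/G/T/N).
#' @param umi Character vector of UMIs, or NA where absent.
#' @param qual Character vector of Phred+33 quality strings for the insert
#'   (same length as insert), or NA.
#' @return A data.frame of class \code{noseq_reads}.
#' @export
structured_reads <- function(read_id, insert, umi = NA_character_,
                             qual = NA_character_) {
  df <- data.frame(read_id = as.character(read_id),
                   insert = toupper(as.character(insert)),
                   umi = as.character(umi),
                   qual = as.character(qual),
                   stringsAsFactors = FALSE)
  bad <- grepl("[^ACGTN]", df$insert)
  if (any(bad)) {
    stop("insert alphabet outside A/C/G/T/N in read ",
         df$read_id[bad][1L], call. = FALSE)
  }
  class(df) <- c("noseq_reads", "data.frame")
  df
}

#' Read a FASTQ file into structured reads
#'
#' Parses a Phred+33 FASTQ file and splits each read into insert and UMI
#' according to the read-layout descriptor. Reads are returned in file order.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @param spec A \code{\link{umi_spec}}; default: no UMI.
#' @return A \code{\link{structured_reads}} table.
#' @export
read_structured_fastq <- function(path, spec = umi_spec("none")) {
  stopifnot(inherits(spec, "noseq_umi_spec"))
  validate_fastq_structure(path)
  parsed <- tryCatch({
    recs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
    list(ids = names(recs), seqs = as.character(recs),
         quals = as.character(S4Vectors::mcols(recs)$qualities))
  }, error = function(e) {
    stop("FASTQ format error in '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (length(parsed$seqs) == 0L) {
    return(structured_reads(character(), character(), character(), character()))
  }
  seqs <- parsed$seqs
  quals <- parsed$quals
  ids <- sub("\\s.*$", "", parsed$ids)
  if (spec$placement == "none") {
    return(structured_reads(ids, seqs, NA_character_, quals))
  }
  n <- nchar(seqs)
  too_short <- which(n <= spec$umi_length)
  if (length(too_short) > 0L) {
    stop("read ", ids[too_short[1L]], " is not longer than the ",
         spec$umi_length, "-nt trailing UMI", call. = FALSE)
  }
  ins_end <- n - spec$umi_length
  structured_reads(ids,
                   substr(seqs, 1L, ins_end),
                   substr(seqs, ins_end + 1L, n),
                   substr(quals, 1L, ins_end))
}

#' Write structured reads to a FASTQ file
#'
#' Inverse of \code{\link{read_structured_fastq}}: re-joins insert and UMI
#' per the layout descriptor and writes Phred+33 FASTQ. Reads whose quality
#' string is absent get a constant high quality ('I').
#'
#' @param reads A \code{\link{structured_reads}} table.
#' @param path Output path.
#' @param spec A \code{\link{umi_spec}} describing where the UMI goes.
#' @return Invisibly, \code{path}.
#' @export
write_structured_fastq <- function(reads, path, spec = umi_spec("none")) {
  stopifnot(inherits(reads, "noseq_reads"), inherits(spec, "noseq_umi_spec"))
  seqs <- reads$insert
  quals <- reads$qual
  quals[is.na(quals)] <- strrep("I", nchar(seqs[is.na(quals)]))
  if (spec$placement == "trailing") {
    if (anyNA(reads$umi)) {
      stop("trailing-UMI layout requested but some reads have no UMI",
           call. = FALSE)
    }
    if (any(nchar(reads$umi) != spec$umi_length)) {
      stop("UMI length differs from the configured ", spec$umi_length, " nt",
           call. = FALSE)
    }
    seqs <- paste0(seqs, reads$umi)
    quals <- paste0(quals, strrep("I", spec$umi_length))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

# Structural pre-check of a 4-line-record FASTQ file so that malformed
# input fails with a record index instead of depending on parser internals.
# Validation only; parsing stays with Biostrings.
validate_fastq_structure <- function(path) {
  con <- gzfile(path, "r")   # reads plain and gzipped files alike
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("FASTQ format error in '", path, "': truncated record ",
         n %/% 4L + 1L, call. = FALSE)
  }
  if (n == 0L) return(invisible(TRUE))
  rec <- matrix(lines, nrow = 4L)
  bad_head <- which(!startsWith(rec[1L, ], "@") | !startsWith(rec[3L, ], "+"))
  if (length(bad_head) > 0L) {
    stop("FASTQ format error in '", path, "': malformed record ",
         bad_head[1L], call. = FALSE)
  }
  bad_len <- which(nchar(rec[2L, ]) != nchar(rec[4L, ]))
  if (length(bad_len) > 0L) {
    stop("FASTQ format error in '", path, "': quality length differs from ",
         "sequence length at record ", bad_len[1L], call. = FALSE)
  }
  invisible(TRUE)
}

#' Length of the longest run of N's in a primer sequence
#'
#' Targeted RT primers embed the UMI as a run of N's between the sequencing
#' adapter and the gene-specific binding sequence; the longest N run gives
#' the UMI length the primer encodes (7 nt in the amplicon designs shipped
#' with the method).
#'
#' @param primer_sequence Base string, possibly containing N's.
#' @return Integer: length of the longest run of consecutive N characters
#'   (0 if none).
#' @examples
#' count_umi_run("AGACGTGTGCTCTTCCGATCTNNNNNNNTGCTAGTCCTCAGGA")  # 7
#' @export
count_umi_run <- function(primer_sequence) {
  stopifnot(is.character(primer_sequence), length(primer_sequence) == 1L)
  runs <- regmatches(primer_sequence,
                     gregexpr("N+", toupper(primer_sequence)))[[1L]]
  if (length(runs) == 0L) 0L else max(nchar(runs))
}

#' @export
print.noseq_reads <- function(x, ...) {
  cat("Structured reads: ", nrow(x), " read(s)",
      if (all(is.na(x$umi))) ", no UMI" else
        paste0(", UMI length ", nchar(x$umi[!is.na(x$umi)][1L])),
      "\n", sep = "")
  if (nrow(x) > 0L) {
    utils::str(utils::head(as.data.frame(x), 3L), vec.len = 1)
  }
  invisible(x)
}
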