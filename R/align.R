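#' The asymmetric deamination substitution matrix
#'
#' Scoring table for read base (rows) against reference base (columns) under
#' the +1/-1 reward system. Beyond the identity pairings, +1 is granted to
#' the deamination-compatible pairings: read G on reference A (A-to-inosine
#' signal), read T on reference C (C-to-uridine signal), and read A on
#' reference G (the minor adenosine signal observed at guanosine positions
#' after xanthosine read-through). The matrix is asymmetric: read T on
#' reference C scores +1 while read C on reference T scores -1, because no
#' chemistry converts U back to C.
#'
#' @return A 4x4 integer matrix with dimnames
#'   \code{list(read = c("A","C","G","T"), ref = c("A","C","G","T"))}.
#' @examples
#' m <- substitution_matrix()
#' m["G", "A"]  # +1 : deaminated A reads as G
#' m["C", "T"]  # -1 : nothing converts U back to C
#' @export
substitution_matrix <- function() {
  b <- c("A", "C", "G", "T")
  m <- matrix(-1L, 4L, 4L, dimnames = list(read = b, ref = b))
  diag(m) <- 1L
  m["G", "A"] <- 1L
  m["A", "G"] <- 1L
  m["T", "C"] <- 1L
  m
}

#' Read a custom 4x4 substitution matrix from a TSV file
#'
#' Expects a tab-separated table with row and column names over A/C/G/T
#' (rows = read base, columns = reference base), so an externally published
#' matrix can be swapped in verbatim.
#'
#' @param path Path to the TSV file.
#' @return A 4x4 integer matrix in A/C/G/T order.
#' @export
read_substitution_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
  validate_matrix(m)
}

validate_matrix <- function(m) {
  b <- c("A", "C", "G", "T")
  if (!is.matrix(m) || !all(dim(m) == 4L) ||
      !all(b %in% rownames(m)) || !all(b %in% colnames(m))) {
    stop("substitution matrix must be 4x4 with A/C/G/T row and column names",
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m <- m[b, b]
  names(dimnames(m)) <- c("read", "ref")
  m
}

#' Build the k-mer index of a reference amplicon
#'
#' The reference is divided into all overlapping k-mers (k = 11 by default),
#' each recorded with its 1-based start position(s); entries are kept in
#' lexicographic k-mer order.
#'
#' @param reference A \code{\link{reference_amplicon}}.
#' @param k Seed length (default 11); must satisfy 1 <= k <= reference length.
#' @return An object of class \code{noseq_kmer_index} with elements \code{k},
#'   \code{kmers} (sorted unique k-mer strings), \code{positions} (list of
#'   1-based start positions parallel to \code{kmers}), and the reference.
#' @examples
#' idx <- build_index(oligo_53mer(), k = 11)
#' sum(lengths(idx$positions))  # 43 indexed start positions
#' @export
build_index <- function(reference, k = 11L) {
  stopifnot(inherits(reference, "noseq_reference"))
  k <- as.integer(k)
  L <- nchar(reference$sequence)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > L) {
    stop("k (", k, ") exceeds the reference length (", L, ")", call. = FALSE)
  }
  starts <- seq_len(L - k + 1L)
  kmers <- substring(reference$sequence, starts, starts + k - 1L)
  pos_by_kmer <- split(starts, kmers)              # split() sorts keys
  structure(list(k = k,
                 kmers = names(pos_by_kmer),
                 positions = unname(pos_by_kmer),
                 reference = reference),
            class = "noseq_kmer_index")
}

#' @export
print.noseq_kmer_index <- function(x, ...) {
  cat("k-mer index: k = ", x$k, ", ",
      length(x$kmers), " distinct k-mers over a ",
      nchar(x$reference$sequence), "-nt reference\n", sep = "")
  invisible(x)
}

#' Find deamination-compatible seed matches of a read
#'
#' Segments the read into its overlapping k-mers and reports every pairing
#' with a reference k-mer whose k positions all score +1 under the
#' substitution matrix (deamination-compatible seeding; a fully deaminated
#' k-mer still seeds). With \code{mode = "literal"} only exact string
#' matches seed, as in conventional mappers.
#'
#' @param read Read sequence (character scalar) or a single row of a
#'   \code{\link{structured_reads}} table.
#' @param index A \code{\link{build_index}} result.
#' @param matrix Substitution matrix (default \code{\link{substitution_matrix}}).
#' @param mode \code{"matrix"} (default) or \code{"literal"}.
#' @return A data.frame with columns \code{read_offset} and
#'   \code{reference_offset} (both 1-based), sorted lexicographically.
#' @export
seed_matches <- function(read, index, matrix = substitution_matrix(),
                         mode = c("matrix", "literal")) {
  mode <- match.arg(mode)
  read <- as_read_string(read)
  stopifnot(inherits(index, "noseq_kmer_index"))
  matrix <- validate_matrix(matrix)
  k <- index$k
  Lr <- nchar(read)
  out <- list()
  if (Lr >= k) {
    refc <- strsplit(index$reference$sequence, "")[[1L]]
    rc <- strsplit(read, "")[[1L]]
    ref_starts <- seq_len(length(refc) - k + 1L)
    for (i in seq_len(Lr - k + 1L)) {
      if (mode == "literal") {
        km <- substr(read, i, i + k - 1L)
        hit <- match(km, index$kmers)
        js <- if (is.na(hit)) integer() else sort(index$positions[[hit]])
      } else {
        js <- ref_starts[vapply(ref_starts, function(j) {
          all(matrix[cbind(rc[i:(i + k - 1L)], refc[j:(j + k - 1L)])] == 1L)
        }, logical(1L))]
      }
      if (length(js) > 0L) {
        out[[length(out) + 1L]] <- data.frame(read_offset = i,
                                              reference_offset = js)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(read_offset = integer(), reference_offset = integer()))
  }
  do.call(rbind, out)
}

#' Gapless extension and retention verdict for one seed
#'
#' Extends a seed to the full read (no gaps: the perfect-score retention
#' filter makes any gap or -1 pairing fatal, so ungapped extension is
#' exhaustive) and applies the three retention filters: total score must
#' equal the read length, the implied reference start must be 1, and the
#' read must cover the evaluation window (default: the entire reference).
#'
#' @param read Read sequence or a single structured-read row.
#' @param seed Length-2 integer vector or list \code{(read_offset,
#'   reference_offset)}, 1-based, as produced by \code{\link{seed_matches}}.
#' @param reference A \code{\link{reference_amplicon}}.
#' @param matrix Substitution matrix.
#' @param window Integer pair \code{c(start, end)} of the evaluation window;
#'   default the full reference.
#' @return A list with \code{accepted} (logical), \code{reference_start},
#'   \code{score} (NA when the placement runs off the reference) and
#'   \code{reason} (\code{"accepted"}, \code{"score"}, \code{"anchor"} or
#'   \code{"coverage"}).
#' @export
extend_and_score <- function(read, seed, reference,
                             matrix = substitution_matrix(), window = NULL) {
  read <- as_read_string(read)
  stopifnot(inherits(reference, "noseq_reference"))
  matrix <- validate_matrix(matrix)
  seed <- as.integer(unlist(seed)[1:2])
  Lr <- nchar(read)
  Lref <- nchar(reference$sequence)
  if (is.null(window)) window <- c(1L, Lref)
  start <- seed[2L] - seed[1L] + 1L
  if (start < 1L || start + Lr - 1L > Lref) {
    return(list(accepted = FALSE, reference_start = start, score = NA_integer_,
                reason = "coverage"))
  }
  rc <- strsplit(read, "")[[1L]]
  refc <- strsplit(reference$sequence, "")[[1L]]
  sc <- sum(matrix[cbind(rc, refc[start:(start + Lr - 1L)])])
  reason <- if (sc != Lr) "score"
            else if (start != 1L) "anchor"
            else if (start > window[1L] || start + Lr - 1L < window[2L])
              "coverage"
            else "accepted"
  list(accepted = reason == "accepted", reference_start = start,
       score = sc, reason = reason)
}

#' Align a read set with the deamination-aware seed-and-extend mapper
#'
#' Maps every read against the reference amplicon and applies the strict
#' retention filters: a read is kept only if some seed's gapless extension
#' scores exactly its length (every pairing a +1), starts at reference
#' position 1, and covers the evaluation window. Reads whose insert
#' contains N are set aside before alignment (the perfect-score filter is
#' unattainable with N). Rejected reads carry the verdict of their
#' lexicographically first seed, or \code{no_seed}/\code{n_base}.
#'
#' @param reads A \code{\link{structured_reads}} table (or character vector
#'   of read sequences).
#' @param reference A \code{\link{reference_amplicon}}.
#' @param k Seed length (default 11).
#' @param matrix Substitution matrix (default the asymmetric deamination
#'   matrix).
#' @param window Evaluation window \code{c(start, end)}; default the full
#'   reference.
#' @param seed_mode \code{"matrix"} (deamination-compatible seeding,
#'   default) or \code{"literal"} (exact k-mer equality).
#' @return An object of class \code{noseq_alignment}: list with
#'   \code{reference}, \code{decisions} (per-read data.frame: read_id, umi,
#'   reference_start, score, accepted, reason), \code{accepted} (the
#'   surviving reads with their aligned bases in reference coordinates) and
#'   \code{stats} (the filtering funnel).
#' @export
align_all <- function(reads, reference, k = 11L,
                      matrix = substitution_matrix(), window = NULL,
                      seed_mode = c("matrix", "literal")) {
  seed_mode <- match.arg(seed_mode)
  stopifnot(inherits(reference, "noseq_reference"))
  matrix <- validate_matrix(matrix)
  if (is.character(reads)) {
    reads <- structured_reads(sprintf("read%06d", seq_along(reads)), reads)
  }
  stopifnot(inherits(reads, "noseq_reads"))
  k <- as.integer(k)
  L <- nchar(reference$sequence)
  if (k < 1L || k > L) {
    stop("k must satisfy 1 <= k <= reference length", call. = FALSE)
  }
  if (is.null(window)) window <- c(1L, L)
  window <- as.integer(window)
  if (window[1L] < 1L || window[2L] > L || window[1L] > window[2L]) {
    stop("evaluation window must lie within the reference", call. = FALSE)
  }

  n <- nrow(reads)
  reason <- rep(NA_character_, n)
  start <- rep(NA_integer_, n)
  score <- rep(NA_integer_, n)
  seeded <- rep(FALSE, n)

  has_n <- grepl("N", reads$insert, fixed = TRUE)
  reason[has_n] <- "n_base"
  todo <- which(!has_n)
  if (length(todo) > 0L) {
    res <- .cpp_align_batch(reads$insert[todo], reference$sequence, k,
                            unname(matrix), window[1L], window[2L],
                            seed_mode == "literal")
    reason[todo] <- c("accepted", "score", "anchor", "coverage",
                      "no_seed")[res$reason + 1L]
    start[todo] <- res$reference_start
    score[todo] <- res$score
    seeded[todo] <- res$seeded
  }

  decisions <- data.frame(read_id = reads$read_id, umi = reads$umi,
                          reference_start = start, score = score,
                          length = nchar(reads$insert),
                          accepted = reason == "accepted", reason = reason,
                          stringsAsFactors = FALSE)
  acc <- which(decisions$accepted)
  accepted <- data.frame(read_id = reads$read_id[acc], umi = reads$umi[acc],
                         reference_start = decisions$reference_start[acc],
                         score = decisions$score[acc],
                         aligned_bases = reads$insert[acc],
                         stringsAsFactors = FALSE)
  stats <- c(input = n,
             usable = sum(!has_n),
             seeded = sum(seeded),
             accepted = length(acc),
             rejected_score = sum(reason == "score"),
             rejected_anchor = sum(reason == "anchor"),
             rejected_coverage = sum(reason == "coverage"),
             rejected_no_seed = sum(reason == "no_seed"),
             rejected_n_base = sum(has_n))
  structure(list(reference = reference, decisions = decisions,
                 accepted = accepted, stats = stats, k = k,
                 matrix = matrix, window = window, seed_mode = seed_mode),
            class = "noseq_alignment")
}

#' @export
print.noseq_alignment <- function(x, ...) {
  s <- x$stats
  cat("Deamination-aware alignment against '", x$reference$name, "' (k = ",
      x$k, ")\n", sep = "")
  cat(sprintf("  input %d -> usable %d -> seeded %d -> accepted %d (%.1f%%)\n",
              s["input"], s["usable"], s["seeded"], s["accepted"],
              100 * s["accepted"] / max(1L, s["input"])))
  rej <- s[grep("^rejected_", names(s))]
  rej <- rej[rej > 0L]
  if (length(rej) > 0L) {
    cat("  rejected:", paste(sub("rejected_", "", names(rej)), rej,
                             sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
#' @method summary noseq_alignment
summary.noseq_alignment <- function(object, ...) {
  print(object)
  invisible(object$stats)
}

#' Render accepted alignments as SAM for inspection
#'
#' Writes the accepted (ungapped, anchored) reads as a minimal SAM file so
#' they can be viewed in standard tools. This is a rendering of the
#' package's own alignment decisions, not an alternative aligner.
#'
#' @param alignment A \code{\link{align_all}} result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_sam <- function(alignment, path) {
  stopifnot(inherits(alignment, "noseq_alignment"))
  ref <- alignment$reference
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref$name, nchar(ref$sequence)),
               "@PG\tID:noseq\tPN:noseq"), con)
  a <- alignment$accepted
  if (nrow(a) > 0L) {
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                       a$read_id, ref$name, a$reference_start,
                       nchar(a$aligned_bases), a$aligned_bases,
                       strrep("I", nchar(a$aligned_bases))), con)
  }
  invisible(path)
}

as_read_string <- function(read) {
  if (is.list(read) || is.data.frame(read)) read <- read$insert
  stopifnot(is.character(read), length(read) == 1L)
  toupper(read)
}
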