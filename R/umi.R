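#' Read redundancy from unique molecular identifiers
#'
#' Quantifies PCR redundancy in an aligned read set: duplicates are reads
#' sharing an identical UMI string (exact equality by default). Reports the
#' duplicate fraction and the UMI multiplicity histogram. Because UMIs are
#' finite random tags (4^length distinct), chance collisions impose a
#' baseline redundancy floor; the report carries a birthday-bound estimate
#' of that floor and flags when the read count approaches UMI diversity.
#' UMIs containing N are excluded from the tally and counted separately.
#'
#' @param alignment A \code{\link{align_all}} result whose accepted reads all
#'   carry a UMI, or a \code{\link{structured_reads}} table.
#' @param cluster_1mm If TRUE, UMIs within edit distance 1 (Hamming, equal
#'   length) are merged into one molecule before counting. Default FALSE:
#'   plain string identity defines a duplicate.
#' @return A list of class \code{noseq_redundancy}: \code{total_reads},
#'   \code{distinct_umis}, \code{duplicate_reads},
#'   \code{redundancy_fraction}, \code{umi_count_histogram} (table of
#'   multiplicities), \code{n_umi_with_N}, \code{collision_floor} (expected
#'   baseline redundancy from random-tag collisions alone) and
#'   \code{saturation_warning}.
#' @export
assess_redundancy <- function(alignment, cluster_1mm = FALSE) {
  umis <- if (inherits(alignment, "noseq_alignment")) {
    alignment$accepted$umi
  } else if (inherits(alignment, "noseq_reads")) {
    alignment$umi
  } else {
    stop("expected a noseq_alignment or noseq_reads object", call. = FALSE)
  }
  if (length(umis) == 0L) stop("no reads to assess", call. = FALSE)
  if (anyNA(umis)) {
    stop("some reads carry no UMI; redundancy is undefined", call. = FALSE)
  }
  len <- unique(nchar(umis))
  if (length(len) != 1L) {
    stop("UMIs have mixed lengths: ", paste(len, collapse = ", "),
         call. = FALSE)
  }
  with_n <- grepl("N", umis, fixed = TRUE)
  n_umi_with_N <- sum(with_n)
  umis <- umis[!with_n]
  total <- length(umis)
  if (total == 0L) stop("all UMIs contain N", call. = FALSE)

  if (cluster_1mm) umis <- cluster_umis_1mm(umis)
  counts <- table(umis)
  distinct <- length(counts)
  dup <- total - distinct

  diversity <- 4^len
  # expected distinct tags if all reads were distinct molecules
  exp_distinct <- diversity * (1 - (1 - 1 / diversity)^total)
  structure(list(total_reads = total,
                 distinct_umis = distinct,
                 duplicate_reads = dup,
                 redundancy_fraction = dup / total,
                 umi_count_histogram = table(as.integer(counts)),
                 n_umi_with_N = n_umi_with_N,
                 umi_length = len,
                 collision_floor = (total - exp_distinct) / total,
                 saturation_warning = total > 0.1 * diversity),
            class = "noseq_redundancy")
}

# Greedy Hamming-distance-1 merge: each UMI is absorbed into the most
# frequent UMI within distance 1, if any.
cluster_umis_1mm <- function(umis) {
  counts <- sort(table(umis), decreasing = TRUE)
  tags <- names(counts)
  parent <- setNames(tags, tags)
  for (i in seq_along(tags)[-1L]) {
    ti <- strsplit(tags[i], "")[[1L]]
    for (j in seq_len(i - 1L)) {
      if (sum(ti != strsplit(tags[j], "")[[1L]]) == 1L) {
        parent[tags[i]] <- parent[tags[j]]
        break
      }
    }
  }
  unname(parent[umis])
}

#' @export
print.noseq_redundancy <- function(x, ...) {
  cat(sprintf(paste0("UMI redundancy: %d reads, %d distinct UMIs, ",
                     "%d duplicates (%.1f%%)\n"),
              x$total_reads, x$distinct_umis, x$duplicate_reads,
              100 * x$redundancy_fraction))
  cat(sprintf("  collision floor for random %d-nt UMIs at this depth: %.2f%%\n",
              x$umi_length, 100 * x$collision_floor))
  if (x$n_umi_with_N > 0L) {
    cat("  UMIs with N excluded:", x$n_umi_with_N, "\n")
  }
  if (x$saturation_warning) {
    cat("  WARNING: read count approaches UMI diversity (4^",
        x$umi_length, "); redundancy is collision-dominated\n", sep = "")
  }
  invisible(x)
}
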