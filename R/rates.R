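#' Per-position base composition and conversion rates
#'
#' Tabulates, over all accepted reads (which by construction cover the full
#' evaluation window and start at reference position 1), the number of
#' A/C/G/T read-outs at every reference position, and derives the
#' deamination read-out rates: at reference A positions the A rate
#' (fraction of reads still showing A; high at m6A sites) and G rate
#' (fraction showing G, the A-to-inosine conversion signal); at reference C
#' positions the T rate (C-to-uridine signal). Denominators are the total
#' number of accepted reads, so rates are "fraction of reads" in the plotted
#' sense; bases other than the expected pair (sequencing error) still count
#' toward the composition but dilute both rates.
#'
#' @param alignment A \code{\link{align_all}} result with at least one
#'   accepted read.
#' @return A data.frame of class \code{noseq_rates}: one row per window
#'   position with columns \code{position}, \code{ref_base}, \code{n_A},
#'   \code{n_C}, \code{n_G}, \code{n_T}, \code{coverage}, \code{a_rate},
#'   \code{g_rate}, \code{t_rate} (rates are NA off their base class).
#' @export
tabulate_rates <- function(alignment) {
  stopifnot(inherits(alignment, "noseq_alignment"))
  acc <- alignment$accepted
  if (nrow(acc) == 0L) {
    stop("no accepted reads: rate table would be empty", call. = FALSE)
  }
  w <- alignment$window
  positions <- seq.int(w[1L], w[2L])
  # accepted reads are anchored at 1, so read coordinate == ref coordinate
  m <- matrix(unlist(strsplit(acc$aligned_bases, ""), use.names = FALSE),
              nrow = nrow(acc), byrow = TRUE)[, positions, drop = FALSE]
  count_base <- function(b) colSums(m == b)
  nA <- count_base("A"); nC <- count_base("C")
  nG <- count_base("G"); nT <- count_base("T")
  nreads <- nrow(acc)
  refc <- strsplit(alignment$reference$sequence, "")[[1L]][positions]
  tab <- data.frame(position = positions, ref_base = refc,
                    n_A = nA, n_C = nC, n_G = nG, n_T = nT,
                    coverage = nreads,
                    a_rate = ifelse(refc == "A", nA / nreads, NA_real_),
                    g_rate = ifelse(refc == "A", nG / nreads, NA_real_),
                    t_rate = ifelse(refc == "C", nT / nreads, NA_real_),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(tab, class = c("noseq_rates", "data.frame"),
            n_reads = nreads,
            modified_positions = alignment$reference$modified_positions)
}

#' @export
print.noseq_rates <- function(x, ...) {
  cat("Per-position rate table over ", nrow(x), " positions, ",
      attr(x, "n_reads"), " accepted reads\n", sep = "")
  aidx <- x$ref_base == "A"
  cat(sprintf("  A positions: %d; mean A rate %.3f, mean G rate %.3f\n",
              sum(aidx), mean(x$a_rate[aidx]), mean(x$g_rate[aidx])))
  cidx <- x$ref_base == "C"
  if (any(cidx)) {
    cat(sprintf("  C positions: %d; mean T rate %.3f\n",
                sum(cidx), mean(x$t_rate[cidx])))
  }
  invisible(x)
}

#' Stacked base-composition plot of a rate table
#'
#' Per-position stacked fractions of A (green), G (orange), C (blue) and
#' T (red) read-outs over the amplicon, the standard rendering of a
#' partially deaminated alignment.
#'
#' @param x A \code{\link{tabulate_rates}} result.
#' @param ... Passed to \code{\link[graphics]{barplot}}.
#' @export
#' @method plot noseq_rates
plot.noseq_rates <- function(x, ...) {
  frac <- t(as.matrix(x[, c("n_A", "n_G", "n_C", "n_T")])) / attr(x, "n_reads")
  graphics::barplot(frac, names.arg = x$position, border = NA,
                    col = c("forestgreen", "orange", "steelblue", "firebrick"),
                    xlab = "reference position", ylab = "fraction of reads",
                    legend.text = c("A", "G", "C", "T"),
                    args.legend = list(x = "topright", bg = "white"), ...)
  invisible(x)
}

#' Uniformity of deamination along the amplicon
#'
#' Summarizes the dispersion of conversion read-out rates across positions
#' (G rate over A positions, T rate over C positions), excluding candidate
#' m6A sites, to verify that deamination events are uniformly distributed
#' along the amplicon -- i.e. that targeted priming did not bias conversion
#' near the site of interest.
#'
#' @param rate_table A \code{\link{tabulate_rates}} result.
#' @param exclude Positions to exclude (typically the candidate/annotated
#'   m6A sites; default: the annotated sites carried by the table).
#' @return A data.frame with one row per signal (\code{g_rate},
#'   \code{t_rate}): number of positions, mean, SD and coefficient of
#'   variation.
#' @export
deamination_uniformity <- function(rate_table,
                                   exclude = attr(rate_table,
                                                  "modified_positions")) {
  stopifnot(inherits(rate_table, "noseq_rates"))
  keep <- !(rate_table$position %in% exclude)
  g <- rate_table$g_rate[keep & rate_table$ref_base == "A"]
  t <- rate_table$t_rate[keep & rate_table$ref_base == "C"]
  if (length(g) + length(t) < 3L) {
    stop("fewer than 3 assessable positions after exclusion", call. = FALSE)
  }
  one <- function(v, what) {
    data.frame(signal = what, n_positions = length(v),
               mean = mean(v), sd = stats::sd(v),
               cv = stats::sd(v) / mean(v))
  }
  rbind(one(g, "g_rate"), one(t, "t_rate"))
}
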