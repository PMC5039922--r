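#' Genome-wide RAF threshold
#'
#' The cut point separating the "excess" allele from the other at each
#' marker. By default it is the median RAF over all retained heterozygous
#' sites across the genome, which absorbs a global reference bias; it should
#' land close to 0.5.
#'
#' @param sites A `het_sites` or `marker_table` data frame (needs a `raf`
#'   column), or a numeric vector of RAFs.
#' @param override Optional fixed threshold in (0, 1); when given it is
#'   returned unchanged.
#' @return A single numeric threshold.
#' @export
compute_threshold <- function(sites, override = NULL) {
  if (!is.null(override)) {
    stopifnot(is.numeric(override), length(override) == 1L,
              override > 0, override < 1)
    return(as.numeric(override))
  }
  raf <- if (is.data.frame(sites)) sites$raf else as.numeric(sites)
  raf <- raf[!is.na(raf)]
  if (length(raf) == 0L) {
    stop("compute_threshold: no sites with defined RAF", call. = FALSE)
  }
  stats::median(raf)
}

#' Frequency-based phasing: assign the excess allele at each marker
#'
#' At each heterozygous marker independently, the allele whose read
#' frequency exceeds the threshold is declared the "excess" allele; the
#' excess alleles across markers form a putative haplotype. The concordance
#' indicator `z` records whether that excess allele sits on estimated
#' haplotype 1 (`z = 1`) or haplotype 2 (`z = 0`). Under no imbalance the
#' excess allele is noise and `z` is a fair coin; under allelic imbalance
#' the `z` track aligns with one haplotype over long stretches. A marker
#' whose RAF equals the threshold exactly is uninformative and set missing
#' (deterministic tie rule).
#'
#' @param table A `marker_table` from [read_phased_haplotypes()].
#' @param t Threshold from [compute_threshold()].
#' @return The table with added columns `excess_allele` (0 = REF, 1 = ALT,
#'   NA at ties) and `z` (1, 0 or NA).
#' @export
frequency_based_phase <- function(table, t) {
  stopifnot(is.numeric(t), length(t) == 1L)
  excess <- ifelse(table$raf > t, 0L, ifelse(table$raf < t, 1L, NA_integer_))
  table$excess_allele <- excess
  table$z <- ifelse(is.na(excess), NA_integer_,
                    as.integer(excess == table$hap1))
  table
}

#' Phase concordance of a concordance-indicator track
#'
#' The fraction of consecutive non-missing marker pairs whose indicators
#' agree (`z_i == z_j`). Adjacent pairing makes the statistic robust to
#' switch errors in the statistical haplotypes: a single long-range switch
#' corrupts only the one pair that straddles it. Expectation is 0.5 under
#' the no-imbalance null. Missing markers are skipped, joining their
#' neighbours into a pair; chromosome boundaries break pairing.
#'
#' @param z Integer vector of indicators (1/0/NA), or a table carrying a `z`
#'   column (and optionally `chrom`).
#' @param chrom Optional chromosome labels, same length as `z`.
#' @param window Optional inclusive 1-based index range `c(from, to)`
#'   restricting the computation.
#' @return Concordance in \[0, 1\], or `NA_real_` when fewer than 2
#'   non-missing markers are available (undefined, distinct from 0).
#' @export
phase_concordance <- function(z, chrom = NULL, window = NULL) {
  if (is.data.frame(z)) {
    if (is.null(chrom) && "chrom" %in% names(z)) chrom <- z$chrom
    z <- z$z
  }
  z <- as.integer(z)
  if (is.null(chrom)) chrom <- rep("*", length(z))
  if (!is.null(window)) {
    idx <- seq(window[1L], window[2L])
    z <- z[idx]
    chrom <- chrom[idx]
  }
  n_pairs <- 0L
  n_agree <- 0L
  for (ch in unique(chrom)) {
    zi <- z[chrom == ch]
    zi <- zi[!is.na(zi)]
    if (length(zi) < 2L) next
    a <- zi[-length(zi)]
    b <- zi[-1L]
    n_pairs <- n_pairs + length(a)
    n_agree <- n_agree + sum(a == b)
  }
  if (n_pairs == 0L) return(NA_real_)
  n_agree / n_pairs
}

#' Sliding-window phase concordance scan
#'
#' A descriptive companion to the HMM: concordance computed in windows of a
#' fixed number of markers along each chromosome. Windows with fewer than 2
#' non-missing markers report `NA`. A chromosome shorter than the window
#' yields a single truncated window.
#'
#' @param table A phased `marker_table` (with `z`), or a list with `z`,
#'   `chrom`, `pos` components.
#' @param window_size Window size in markers (>= 2).
#' @param step Step between window starts, in markers.
#' @return A data frame: `chrom`, `start`, `end` (genomic span of the
#'   window's markers), `n_markers`, `n_informative`, `concordance`.
#' @export
windowed_concordance_scan <- function(table, window_size = 50L, step = 25L) {
  stopifnot(window_size >= 2L, step >= 1L)
  res <- list()
  for (ch in unique(table$chrom)) {
    sel <- table$chrom == ch
    z <- table$z[sel]
    pos <- table$pos[sel]
    n <- length(z)
    starts <- seq(1L, max(1L, n - window_size + 1L), by = step)
    if (n <= window_size) starts <- 1L
    for (s in starts) {
      e <- min(s + window_size - 1L, n)
      zi <- z[s:e]
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = pos[s], end = pos[e],
        n_markers = e - s + 1L,
        n_informative = sum(!is.na(zi)),
        concordance = phase_concordance(zi),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, res)
}
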