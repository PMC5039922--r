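#' @useDynLib haploscan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rbinom rbeta rpois rnbinom runif setNames
#' @importFrom utils head write.table
NULL

# Numeric-aware chromosome ordering: header contig order when available,
# otherwise "chr2" sorts before "chr10".
chrom_levels <- function(chroms, contigs = NULL) {
  u <- unique(as.character(chroms))
  if (!is.null(contigs) && length(contigs) && all(u %in% contigs)) {
    return(contigs[contigs %in% u])
  }
  num <- suppressWarnings(as.numeric(sub("^chr", "", u)))
  u[order(is.na(num), num, u)]
}

#' Read heterozygous sites with allelic depths from a VCF
#'
#' Extracts biallelic heterozygous SNVs with their reference/alternate read
#' depths (the `AD` FORMAT field) from a VCF v4.x file and derives the
#' reference allele frequency (RAF) at each site. Homozygous calls,
#' multi-allelic records, indels and sites below the depth cutoff are
#' dropped. This is the entire evidence the downstream model consumes: no
#' paired normal sample is used anywhere.
#'
#' @param path Path to a VCF file with `GT` and `AD` FORMAT fields.
#' @param min_depth Minimum total read depth (ref + alt) for a site to be
#'   retained. The depth filter is a pre-processing decision, not part of the
#'   statistical model; 10 keeps RAF estimates meaningful at WES coverage.
#' @param sample_name Sample to extract; required when the VCF is
#'   multi-sample.
#' @return A `data.frame` of class `het_sites` with columns `chrom`, `pos`,
#'   `ref_depth`, `alt_depth`, `raf`, sorted by (chrom, pos). Attribute
#'   `n_skipped_ad` counts sites skipped for malformed AD; attribute
#'   `contigs` records the header contig order used for sorting.
#' @export
read_sample_vcf <- function(path, min_depth = 10L, sample_name = NULL) {
  if (!file.exists(path)) {
    stop("read_sample_vcf: file not found: ", path, call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  hdr <- VariantAnnotation::header(vcf)
  fmt <- rownames(VariantAnnotation::geno(hdr))
  if (!"AD" %in% fmt) {
    stop("read_sample_vcf: VCF has no 'AD' FORMAT field (allelic depths are required)",
         call. = FALSE)
  }
  if (!"GT" %in% fmt) {
    stop("read_sample_vcf: VCF has no 'GT' FORMAT field", call. = FALSE)
  }
  samples <- colnames(vcf)
  if (is.null(sample_name)) {
    if (length(samples) > 1L) {
      stop("read_sample_vcf: multi-sample VCF; 'sample_name' must be given",
           call. = FALSE)
    }
    sample_name <- samples[1L]
  } else if (!sample_name %in% samples) {
    stop("read_sample_vcf: sample '", sample_name, "' not present in VCF",
         call. = FALSE)
  }

  gt <- as.character(VariantAnnotation::geno(vcf)$GT[, sample_name])
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  snv <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
  keep <- het & snv

  ad <- VariantAnnotation::geno(vcf)$AD
  ad_col <- if (length(dim(ad)) == 3L) {
    lapply(seq_len(nrow(ad)), function(i) ad[i, sample_name, ])
  } else {
    ad[, sample_name]
  }
  ok_ad <- vapply(ad_col, function(x) length(x) >= 2L && !anyNA(x[1:2]),
                  logical(1))
  n_skipped <- sum(keep & !ok_ad)
  if (n_skipped > 0L) {
    message("read_sample_vcf: skipped ", n_skipped,
            " het site(s) with malformed AD")
  }
  keep <- keep & ok_ad

  rr <- SummarizedExperiment::rowRanges(vcf)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = BiocGenerics::start(rr)[keep],
    ref_depth = vapply(ad_col[keep], function(x) as.integer(x[1L]), integer(1)),
    alt_depth = vapply(ad_col[keep], function(x) as.integer(x[2L]), integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[out$ref_depth + out$alt_depth >= min_depth, , drop = FALSE]

  contigs <- rownames(VariantAnnotation::meta(hdr)$contig)
  if (is.null(contigs)) contigs <- GenomeInfoDb_seqlevels(vcf)
  lev <- chrom_levels(out$chrom, contigs)
  out <- out[order(match(out$chrom, lev), out$pos), , drop = FALSE]

  dup <- duplicated(out[, c("chrom", "pos")])
  if (any(dup)) {
    warning("read_sample_vcf: dropped ", sum(dup),
            " duplicated position(s), keeping first")
    out <- out[!dup, , drop = FALSE]
  }
  tot <- out$ref_depth + out$alt_depth
  out$raf <- ifelse(tot > 0L, out$ref_depth / tot, NA_real_)
  rownames(out) <- NULL
  structure(out, n_skipped_ad = n_skipped, contigs = contigs,
            class = c("het_sites", "data.frame"))
}

GenomeInfoDb_seqlevels <- function(vcf) {
  as.character(unique(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(vcf))))
}

#' Attach statistically estimated germline haplotypes to heterozygous sites
#'
#' Joins a phased VCF (pipe-separated `GT`, e.g. `0|1`) to the sites read by
#' [read_sample_vcf()], producing the marker table the detector operates on.
#' Sites absent from the phase file, and phase records that are unphased or
#' not `0|1`/`1|0`, are dropped (a count is reported). The phasing is a
#' statistical estimate and may contain switch errors; downstream components
#' are designed to tolerate them.
#'
#' @param path Path to a phased VCF.
#' @param sites A `het_sites` data frame from [read_sample_vcf()].
#' @param sample_name Sample in the phased VCF to use (defaults to the first).
#' @return A `marker_table` data frame: the inner join of `sites` with
#'   columns `hap1` and `hap2` (0 = REF allele, 1 = ALT allele on that
#'   haplotype), ordered like `sites`.
#' @export
read_phased_haplotypes <- function(path, sites, sample_name = NULL) {
  if (!file.exists(path)) {
    stop("read_phased_haplotypes: file not found: ", path, call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  if (is.null(sample_name)) sample_name <- samples[1L]
  if (!sample_name %in% samples) {
    stop("read_phased_haplotypes: sample '", sample_name, "' not in phase VCF",
         call. = FALSE)
  }
  gt <- as.character(VariantAnnotation::geno(vcf)$GT[, sample_name])
  phased <- gt %in% c("0|1", "1|0")
  n_unphased <- sum(!phased & grepl("^[01][/|][01]$", gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ph <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr))[phased],
    pos = BiocGenerics::start(rr)[phased],
    hap1 = as.integer(substr(gt[phased], 1L, 1L)),
    hap2 = as.integer(substr(gt[phased], 3L, 3L)),
    stringsAsFactors = FALSE
  )
  ph <- ph[!duplicated(ph[, c("chrom", "pos")]), , drop = FALSE]

  key_s <- paste(sites$chrom, sites$pos)
  key_p <- paste(ph$chrom, ph$pos)
  idx <- match(key_s, key_p)
  hit <- !is.na(idx)
  if (!any(hit)) {
    stop("read_phased_haplotypes: zero sites overlap between sample VCF and phase file",
         call. = FALSE)
  }
  n_dropped <- sum(!hit)
  if (n_dropped > 0L || n_unphased > 0L) {
    message("read_phased_haplotypes: dropped ", n_dropped,
            " site(s) absent from phase file; ", n_unphased,
            " unphased phase record(s) ignored")
  }
  out <- sites[hit, , drop = FALSE]
  out$hap1 <- ph$hap1[idx[hit]]
  out$hap2 <- ph$hap2[idx[hit]]
  rownames(out) <- NULL
  structure(as.data.frame(out), n_dropped = n_dropped,
            class = c("marker_table", "data.frame"))
}

#' Write the per-site posterior report
#'
#' One row per heterozygous marker: position, allelic depths, RAF, the
#' excess allele chosen by frequency-based phasing, the haplotype
#' concordance indicator, and the posterior probability that the marker lies
#' in a region of allelic imbalance.
#'
#' @param table A `marker_table` carrying `excess_allele` and `z` columns
#'   (see [frequency_based_phase()]).
#' @param posteriors Numeric vector, one AI posterior per marker.
#' @param path Output path (tab-separated, with header).
#' @export
write_site_report <- function(table, posteriors, path) {
  if (length(posteriors) != nrow(table)) {
    stop("write_site_report: ", length(posteriors), " posteriors for ",
         nrow(table), " markers", call. = FALSE)
  }
  out <- data.frame(
    chrom = table$chrom,
    pos = table$pos,
    ref_depth = table$ref_depth,
    alt_depth = table$alt_depth,
    raf = sprintf("%.6f", table$raf),
    excess_allele = ifelse(is.na(table$excess_allele), "NA",
                           ifelse(table$excess_allele == 0L, "REF", "ALT")),
    concordance_indicator = ifelse(is.na(table$z), "NA", table$z),
    posterior_AI = sprintf("%.6f", posteriors),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write called events as BED
#'
#' BED convention: 0-based half-open intervals, so a 1-based inclusive event
#' span `[start_pos, end_pos]` becomes `start_pos - 1, end_pos`. Columns are
#' BED5 (chrom, start, end, name, score = round(1000 * mean posterior)) plus
#' `n_markers` and the mean absolute RAF deviation from 0.5. An empty event
#' set yields an empty file.
#'
#' @param events An `ai_events` data frame from [call_events()].
#' @param path Output path.
#' @export
write_events_bed <- function(events, path) {
  if (is.null(events) || nrow(events) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = events$chrom,
    start = events$start_pos - 1L,
    end = events$end_pos,
    name = events$event_id,
    score = as.integer(round(1000 * events$mean_posterior)),
    n_markers = events$n_markers,
    mean_raf_dev = sprintf("%.6f", events$mean_raf_dev),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
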