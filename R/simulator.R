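#' Simulation configuration
#'
#' Describes a synthetic single-chromosome design with germline het sites,
#' sequencing depth, allele sampling noise, switch-error-corrupted
#' haplotype estimates, and a set of allelic-imbalance events at given
#' aberrant-cell fractions. Two presets capture the designs the detector
#' targets: exome-like (`"wes"`: ~1 het per 3 kb arranged in exon-like
#' 150 bp islands, mean depth 80) and whole-genome-like (`"wgs"`: ~1 het
#' per 1.5 kb uniform, mean depth 30).
#'
#' @param preset `"wes"` or `"wgs"`; fills `het_spacing` and `mean_depth`
#'   unless overridden.
#' @param region_length Simulated chromosome length in bp.
#' @param chrom Chromosome name used in the emitted VCFs.
#' @param het_spacing Mean bp per heterozygous site.
#' @param mean_depth Mean total read depth per site.
#' @param depth_model `"poisson"` or `"nbinom"` (negative binomial with
#'   `depth_dispersion` as the size parameter); depths floored at 1.
#' @param depth_dispersion Negative-binomial size (smaller = noisier).
#' @param rho Beta-binomial overdispersion of allele sampling in \[0, 1);
#'   0 gives pure binomial reads.
#' @param switch_error_rate Per-adjacent-pair probability that the
#'   estimated haplotypes switch orientation (flips persist until the next
#'   switch).
#' @param events A data frame with columns `start`, `end` (1-based bp,
#'   inclusive), `type` (`"cnloh"`, `"deletion"`, `"amplification"`) and
#'   `fraction` (aberrant-cell fraction in \[0, 1\]); events must be
#'   non-overlapping and inside the region. `NULL` means no imbalance.
#' @param seed Integer seed; every random draw in the simulation flows
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(preset = c("wes", "wgs"), region_length = 1e8,
                       chrom = "chr1", het_spacing = NULL, mean_depth = NULL,
                       depth_model = c("poisson", "nbinom"),
                       depth_dispersion = 10, rho = 0,
                       switch_error_rate = 0.02, events = NULL, seed = 1L) {
  preset <- match.arg(preset)
  depth_model <- match.arg(depth_model)
  if (is.null(het_spacing)) het_spacing <- if (preset == "wes") 3000 else 1500
  if (is.null(mean_depth)) mean_depth <- if (preset == "wes") 80 else 30
  stopifnot(region_length > 0, het_spacing > 0, mean_depth > 0,
            rho >= 0, rho < 1,
            switch_error_rate >= 0, switch_error_rate < 1)
  if (!is.null(events) && nrow(events) > 0L) {
    stopifnot(all(c("start", "end", "type", "fraction") %in% names(events)))
    if (any(events$start < 1 | events$end > region_length |
            events$start > events$end)) {
      stop("sim_config: event outside simulated region", call. = FALSE)
    }
    if (any(events$fraction < 0 | events$fraction > 1)) {
      stop("sim_config: event fraction must lie in [0, 1]", call. = FALSE)
    }
    if (!all(events$type %in% c("cnloh", "deletion", "amplification"))) {
      stop("sim_config: unknown event type", call. = FALSE)
    }
    ev <- events[order(events$start), , drop = FALSE]
    if (nrow(ev) > 1L && any(ev$start[-1L] <= ev$end[-nrow(ev)])) {
      stop("sim_config: events overlap", call. = FALSE)
    }
    events <- ev
  }
  structure(list(preset = preset, region_length = region_length,
                 chrom = chrom, het_spacing = het_spacing,
                 mean_depth = mean_depth, depth_model = depth_model,
                 depth_dispersion = depth_dispersion, rho = rho,
                 switch_error_rate = switch_error_rate, events = events,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected allele frequency under an imbalance mixture
#'
#' A sample in which a fraction `f` of cells carries the aberration while
#' the rest are diploid-balanced has an expected favored-haplotype allele
#' frequency of `(1 + f) / 2` for copy-neutral LOH (favored haplotype
#' duplicated, other lost), `1 / (2 - f)` for a single-copy deletion of the
#' other haplotype, and `(1 + f) / (2 + f)` for a single-copy amplification
#' of the favored haplotype. The balanced state gives 0.5.
#'
#' @param state_type `"N"`, `"cnloh"`, `"deletion"` or `"amplification"`.
#' @param f Aberrant-cell fraction in \[0, 1\].
#' @param ref_on_favored_hap Logical; orients the frequency onto the REF
#'   allele (`FALSE` returns the complement).
#' @return Expected reference-allele frequency.
#' @export
expected_raf <- function(state_type, f, ref_on_favored_hap = TRUE) {
  stopifnot(all(f >= 0), all(f <= 1))
  fav <- switch(state_type,
                N = rep(0.5, length(f)),
                cnloh = (1 + f) / 2,
                deletion = 1 / (2 - f),
                amplification = (1 + f) / (2 + f),
                stop("expected_raf: unknown state type '", state_type, "'",
                     call. = FALSE))
  ifelse(ref_on_favored_hap, fav, 1 - fav)
}

rbetabinom <- function(n, size, prob, rho) {
  if (rho <= 0) return(rbinom(n, size, prob))
  nu <- 1 / rho - 1
  p <- rbeta(n, prob * nu, (1 - prob) * nu)
  rbinom(n, size, p)
}

#' Simulate a sequenced sample with allelic imbalance
#'
#' Draws het-site positions per the preset, assigns true germline
#' haplotypes by fair coin, picks a favored (retained / duplicated /
#' amplified) haplotype per event, computes each marker's expected RAF from
#' the mixture algebra of [expected_raf()], and samples read depths and
#' reference read counts. Estimated haplotypes are the truth corrupted by a
#' persistent switch process. The genotype written to the sample VCF is
#' called from the simulated reads (`0/1` only when both alleles are
#' observed), so near-pure events lose markers to the downstream het filter
#' exactly as real data would. Fully deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional directory; when given, writes `sample.vcf`
#'   (GT + AD), `phased.vcf` (estimated haplotypes) and `truth.tsv`.
#' @return A list of class `sim_dataset`: `markers` (per-marker truth and
#'   reads), `events` (truth events with favored-haplotype flag), `config`,
#'   and the file `paths` when written.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$region_length

  if (config$preset == "wes") {
    # exon-like islands: one 150 bp target every ~3 kb het-spacing unit,
    # Poisson(1) markers per island -> sparse, bursty spacing
    island_every <- config$het_spacing
    n_isl <- floor(L / island_every)
    isl_start <- (seq_len(n_isl) - 1) * island_every +
      floor(runif(n_isl, 0, max(1, island_every - 150)))
    n_per <- rpois(n_isl, 1)
    pos <- unlist(mapply(function(s, k) {
      if (k == 0) integer(0) else s + sort(sample.int(150L, min(k, 150L)))
    }, isl_start, n_per, SIMPLIFY = FALSE))
  } else {
    n <- rpois(1, L / config$het_spacing)
    pos <- sort(sample.int(L, n))
  }
  pos <- unique(pmin(as.numeric(pos), L))
  n <- length(pos)
  if (n < 2L) stop("simulate_dataset: fewer than 2 markers simulated",
                   call. = FALSE)

  hap1 <- rbinom(n, 1L, 0.5)  # allele on haplotype 1: 0 = REF, 1 = ALT
  hap2 <- 1L - hap1

  state <- rep("N", n)
  event_id <- rep(NA_integer_, n)
  frac <- rep(0, n)
  fav_is_hap1 <- rep(NA, n)
  ev <- config$events
  if (!is.null(ev) && nrow(ev) > 0L) {
    ev$favored_hap1 <- as.logical(rbinom(nrow(ev), 1L, 0.5))
    for (k in seq_len(nrow(ev))) {
      in_ev <- pos >= ev$start[k] & pos <= ev$end[k]
      state[in_ev] <- ev$type[k]
      event_id[in_ev] <- k
      frac[in_ev] <- ev$fraction[k]
      fav_is_hap1[in_ev] <- ev$favored_hap1[k]
    }
  }

  fav_allele <- ifelse(is.na(fav_is_hap1), NA_integer_,
                       ifelse(fav_is_hap1, hap1, hap2))
  exp_raf <- rep(0.5, n)
  for (ty in unique(state[state != "N"])) {
    sel <- state == ty
    exp_raf[sel] <- expected_raf(ty, frac[sel],
                                 ref_on_favored_hap = fav_allele[sel] == 0L)
  }

  depth <- switch(config$depth_model,
                  poisson = rpois(n, config$mean_depth),
                  nbinom = rnbinom(n, size = config$depth_dispersion,
                                   mu = config$mean_depth))
  depth <- pmax(depth, 1L)
  ref_depth <- rbetabinom(n, depth, exp_raf, config$rho)
  alt_depth <- depth - ref_depth

  # persistent switch process on the estimated haplotypes
  flips <- rbinom(n - 1L, 1L, config$switch_error_rate)
  orient <- cumsum(c(0L, flips)) %% 2L
  est_hap1 <- ifelse(orient == 0L, hap1, hap2)
  est_hap2 <- 1L - est_hap1

  markers <- data.frame(
    chrom = config$chrom, pos = as.integer(pos),
    hap1 = hap1, hap2 = hap2, est_hap1 = est_hap1, est_hap2 = est_hap2,
    state = state, event_id = event_id, fraction = frac,
    exp_raf = exp_raf, depth = as.integer(depth),
    ref_depth = as.integer(ref_depth), alt_depth = as.integer(alt_depth),
    gt_called_het = ref_depth > 0L & alt_depth > 0L,
    stringsAsFactors = FALSE
  )
  out <- structure(list(markers = markers, events = ev, config = config,
                        paths = NULL),
                   class = "sim_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(sample_vcf = file.path(out_dir, "sample.vcf"),
                  phased_vcf = file.path(out_dir, "phased.vcf"),
                  truth = file.path(out_dir, "truth.tsv"))
    write_sim_vcfs(out, paths)
    out$paths <- paths
  }
  out
}

vcf_header <- function(config, fmt_lines, sample_id) {
  c("##fileformat=VCFv4.2",
    "##source=haploscan_simulator",
    sprintf("##contig=<ID=%s,length=%d>", config$chrom,
            as.integer(config$region_length)),
    fmt_lines,
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
}

write_sim_vcfs <- function(sim, paths) {
  m <- sim$markers
  cfg <- sim$config
  gt <- ifelse(m$gt_called_het, "0/1",
               ifelse(m$ref_depth > 0L, "0/0", "1/1"))
  body <- sprintf("%s\t%d\t.\tA\tC\t.\tPASS\t.\tGT:AD:DP\t%s:%d,%d:%d",
                  m$chrom, m$pos, gt, m$ref_depth, m$alt_depth, m$depth)
  writeLines(c(vcf_header(cfg, c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total depth">'),
    "SAMPLE"), body), paths$sample_vcf)

  phased <- sprintf("%s\t%d\t.\tA\tC\t.\tPASS\t.\tGT\t%d|%d",
                    m$chrom, m$pos, m$est_hap1, m$est_hap2)
  writeLines(c(vcf_header(cfg, c(
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype (estimated haplotypes)">'),
    "SAMPLE"), phased), paths$phased_vcf)

  data.table::fwrite(m, paths$truth, sep = "\t", quote = FALSE)
  invisible(paths)
}

# MarkerTable straight from a simulation, applying the same het + depth
# filters the VCF reading path applies.
sim_marker_table <- function(sim, min_depth = 10L) {
  m <- sim$markers
  keep <- m$gt_called_het & m$depth >= min_depth
  tab <- data.frame(
    chrom = m$chrom[keep], pos = m$pos[keep],
    ref_depth = m$ref_depth[keep], alt_depth = m$alt_depth[keep],
    raf = m$ref_depth[keep] / m$depth[keep],
    hap1 = m$est_hap1[keep], hap2 = m$est_hap2[keep],
    stringsAsFactors = FALSE
  )
  structure(tab, class = c("marker_table", "data.frame"))
}

#' Detection sensitivity across aberrant-cell fractions
#'
#' Replays the detector over a grid of aberrant-cell fractions: for each
#' fraction and replicate, the configured events are simulated at that
#' fraction, the full statistical pipeline (threshold, frequency-based
#' phasing, EM-calibrated HMM, event calling) is run with the supplied
#' settings, and each true event is scored as detected when a called
#' segment overlaps at least `overlap` of its span with mean posterior at
#' least `posterior_cut`. Called segments overlapping no true event are
#' counted as false events.
#'
#' @param base_config A [sim_config()] whose `events` define placement and
#'   type; their `fraction` column is overwritten by each grid value.
#' @param fractions Aberrant-cell fractions to scan, ascending.
#' @param replicates Replicates per fraction.
#' @param detect_args List of overrides passed to [detect_ai()].
#' @param overlap Minimum fraction of the true event span a called segment
#'   must cover.
#' @param seed Base seed; replicate seeds are derived from it.
#' @return A data frame with one row per fraction: `fraction`,
#'   `detection_rate`, `n_detected`, `n_events`, `mean_false_events`,
#'   `replicates`. Per-replicate detail in attribute `detail`.
#' @export
purity_grid_experiment <- function(base_config, fractions,
                                   replicates = 20L,
                                   detect_args = list(),
                                   overlap = 0.5, seed = 1L) {
  stopifnot(!is.null(base_config$events), nrow(base_config$events) >= 1L,
            !is.unsorted(fractions))
  detail <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    for (rep_i in seq_len(replicates)) {
      cfg <- base_config
      cfg$events$fraction <- f
      cfg$seed <- as.integer((as.numeric(seed) * 997 + fi * 211 + rep_i * 7) %%
                               2147483647)
      sim <- simulate_dataset(cfg)
      tab <- sim_marker_table(sim,
                              min_depth = detect_args$min_depth %||% 10L)
      fit <- do.call(detect_ai,
                     c(list(table = tab),
                       detect_args[setdiff(names(detect_args), "min_depth")]))
      sc <- score_detection(fit$events, sim$events, overlap,
                            fit$posterior_cut)
      detail[[length(detail) + 1L]] <- data.frame(
        fraction = f, replicate = rep_i,
        n_events = nrow(sim$events), n_detected = sc$n_detected,
        false_events = sc$false_events, stringsAsFactors = FALSE)
    }
  }
  detail <- do.call(rbind, detail)
  agg <- do.call(rbind, lapply(split(detail, detail$fraction), function(d) {
    data.frame(fraction = d$fraction[1L],
               detection_rate = sum(d$n_detected) / sum(d$n_events),
               n_detected = sum(d$n_detected), n_events = sum(d$n_events),
               mean_false_events = mean(d$false_events),
               replicates = nrow(d), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$fraction), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, detail = detail, class = c("power_table", "data.frame"))
}

score_detection <- function(called, truth, overlap, posterior_cut) {
  if (is.null(truth) || nrow(truth) == 0L) {
    return(list(n_detected = 0L, false_events = nrow(called)))
  }
  detected <- logical(nrow(truth))
  hit_any <- rep(FALSE, nrow(called))
  if (nrow(called)) {
    for (k in seq_len(nrow(truth))) {
      ov <- pmax(0, pmin(called$end_pos, truth$end[k]) -
                     pmax(called$start_pos, truth$start[k]) + 1)
      hit <- ov / (truth$end[k] - truth$start[k] + 1) >= overlap &
        called$mean_posterior >= posterior_cut
      cover <- ov > 0
      detected[k] <- any(hit)
      hit_any <- hit_any | cover
    }
  }
  list(n_detected = sum(detected), false_events = sum(!hit_any))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
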