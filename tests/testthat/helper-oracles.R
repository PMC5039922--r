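# Independent oracles used across the suite. These deliberately avoid the
# package's DP code paths: posteriors and path probabilities are obtained by
# exhaustive enumeration over all 3^n state paths.

oracle_emission <- function(s, z, gamma) {
  if (is.na(z)) return(1)
  if (s == 1L) return(0.5)
  if (s == 2L) return(if (z == 1) gamma else 1 - gamma)
  if (z == 0) gamma else 1 - gamma
}

oracle_path_prob <- function(path, z, params) {
  tr <- build_transition_matrix(params)
  init <- attr(tr, "stationary")
  v <- unname(init[path[1L]]) * oracle_emission(path[1L], z[1L], params$gamma)
  if (length(z) > 1L) {
    for (t in 2:length(z)) {
      v <- v * tr[path[t - 1L], path[t]] *
        oracle_emission(path[t], z[t], params$gamma)
    }
  }
  v
}

oracle_all_paths <- function(n) {
  as.matrix(expand.grid(rep(list(1:3), n), KEEP.OUT.ATTRS = FALSE))
}

# Exact marginal posteriors and log-likelihood by enumeration.
oracle_forward_backward <- function(z, params) {
  n <- length(z)
  paths <- oracle_all_paths(n)
  pr <- apply(paths, 1L, oracle_path_prob, z = z, params = params)
  tot <- sum(pr)
  post <- vapply(seq_len(n), function(t) {
    vapply(1:3, function(s) sum(pr[paths[, t] == s]), numeric(1))
  }, numeric(3))
  list(posterior = t(post) / tot, loglik = log(tot))
}

# Probability of the single best path (ties collapse: only the max matters).
oracle_best_path_prob <- function(z, params) {
  paths <- oracle_all_paths(length(z))
  max(apply(paths, 1L, oracle_path_prob, z = z, params = params))
}

random_params <- function() {
  hmm_params(prevalence = runif(1, 0.02, 0.4),
             mean_event_markers = runif(1, 2, 50),
             gamma = runif(1, 0.55, 0.95),
             switch_rate = runif(1, 0, 0.2))
}

random_track <- function(n, p_missing = 0.2) {
  z <- rbinom(n, 1L, 0.5)
  z[runif(n) < p_missing] <- NA_integer_
  z
}

# Sample (states, indicators) from the generative HMM itself; used for EM
# parameter-recovery checks.
sim_hmm_track <- function(n, params) {
  tr <- build_transition_matrix(params)
  init <- attr(tr, "stationary")
  states <- integer(n)
  states[1L] <- sample.int(3L, 1L, prob = init)
  for (t in 2:n) states[t] <- sample.int(3L, 1L, prob = tr[states[t - 1L], ])
  g <- params$gamma
  p1 <- c(0.5, g, 1 - g)[states]  # P(z = 1 | state)
  z <- rbinom(n, 1L, p1)
  list(states = states, z = z)
}

# Minimal VCF emitter for fixtures. `rows` needs chrom, pos, ref, alt, gt,
# ad (comma-joined string); phased files carry GT only.
write_toy_vcf <- function(path, rows, sample_names = "S1", phased = FALSE,
                          contigs = unique(rows$chrom), ad_format = TRUE) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=250000000>", contigs),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (ad_format && !phased) {
    hdr <- c(hdr, '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
  }
  hdr <- c(hdr, paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                       paste(sample_names, collapse = "\t")))
  fmt <- if (phased || !ad_format) "GT" else "GT:AD"
  smp <- if (phased || !ad_format) rows$gt else paste(rows$gt, rows$ad, sep = ":")
  if (length(sample_names) > 1L) {
    smp <- apply(matrix(smp, ncol = length(sample_names)), 1L, paste,
                 collapse = "\t")
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\t%s\t%s",
                  rows$chrom, rows$pos, rows$ref, rows$alt, fmt, smp)
  writeLines(c(hdr, body), path)
  path
}

toy_sites_df <- function(chrom, pos, ref_depth, alt_depth) {
  tot <- ref_depth + alt_depth
  structure(data.frame(chrom = chrom, pos = as.integer(pos),
                       ref_depth = as.integer(ref_depth),
                       alt_depth = as.integer(alt_depth),
                       raf = ifelse(tot > 0, ref_depth / tot, NA_real_),
                       stringsAsFactors = FALSE),
            class = c("het_sites", "data.frame"))
}
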