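#' HMM parameters for allelic-imbalance segmentation
#'
#' The hidden chain runs over heterozygous markers (marker index, not
#' genomic distance) with three states: `N` (balanced) and two imbalance
#' orientations `A1`/`A2`, one per haplotype in excess. The two-orientation
#' design lets a switch error in the statistical haplotype estimates flip
#' the favored haplotype mid-event without destroying the evidence for
#' imbalance.
#'
#' @param prevalence Prior fraction of markers in imbalance; the transition
#'   matrix is built so the stationary occupancy of `A1 + A2` equals it.
#' @param mean_event_markers Expected imbalance event length in markers;
#'   the per-step probability of leaving imbalance is its reciprocal.
#' @param gamma Emission probability that, inside an imbalance state, the
#'   excess allele lands on the favored haplotype. 0.5 means no signal; it
#'   is usually re-estimated from the data (see [estimate_gamma_em()]).
#' @param switch_rate Per-step probability of swapping the favored
#'   haplotype inside imbalance (absorbs statistical-phasing switch errors).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(prevalence = 0.05, mean_event_markers = 200,
                       gamma = 0.65, switch_rate = 0.02) {
  stopifnot(prevalence > 0, prevalence < 1,
            mean_event_markers > 1,
            gamma > 0.5, gamma < 1,
            switch_rate >= 0, switch_rate < 0.5)
  structure(list(prevalence = prevalence,
                 mean_event_markers = mean_event_markers,
                 gamma = gamma, switch_rate = switch_rate),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("HMM parameters (states N, A1, A2):\n",
      sprintf("  prevalence         %.4g\n", x$prevalence),
      sprintf("  mean_event_markers %.4g\n", x$mean_event_markers),
      sprintf("  gamma              %.4g\n", x$gamma),
      sprintf("  switch_rate        %.4g\n", x$switch_rate), sep = "")
  invisible(x)
}

#' Transition matrix over (N, A1, A2)
#'
#' Exit from imbalance carries mass `q = 1 / mean_event_markers` toward `N`;
#' within imbalance, mass `switch_rate * (1 - q)` crosses between the two
#' orientations. Entry into imbalance, split equally between `A1` and `A2`,
#' is solved so the stationary distribution places exactly `prevalence` on
#' the imbalance states: `r = prevalence * q / (1 - prevalence)`.
#'
#' @param params An [hmm_params()] object.
#' @return A 3x3 row-stochastic matrix with dimnames `N`, `A1`, `A2` and a
#'   `stationary` attribute.
#' @export
build_transition_matrix <- function(params) {
  p <- params$prevalence
  q <- 1 / params$mean_event_markers
  s <- params$switch_rate
  r <- p * q / (1 - p)
  if (r > 1) {
    stop("build_transition_matrix: no valid entry rate for prevalence = ", p,
         " with mean_event_markers = ", params$mean_event_markers,
         " (required N-exit mass exceeds 1)", call. = FALSE)
  }
  m <- matrix(c(1 - r,        r / 2,             r / 2,
                q,            (1 - q) * (1 - s), (1 - q) * s,
                q,            (1 - q) * s,       (1 - q) * (1 - s)),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("N", "A1", "A2"), c("N", "A1", "A2")))
  structure(m, stationary = c(N = 1 - p, A1 = p / 2, A2 = p / 2))
}

#' Emission probability of a concordance indicator
#'
#' `N` emits 1/0 as a fair coin; `A1` emits `z = 1` with probability
#' `gamma`; `A2` is its mirror. A missing indicator is uninformative and
#' emits 1 in every state.
#'
#' @param state One of `"N"`, `"A1"`, `"A2"`.
#' @param z 1, 0 or `NA`.
#' @param gamma Concordance emission probability in (0.5, 1).
#' @return The emission probability.
#' @export
emission_prob <- function(state, z, gamma) {
  state <- match.arg(state, c("N", "A1", "A2"))
  if (is.na(z)) return(1)
  switch(state,
         N = 0.5,
         A1 = if (z == 1) gamma else 1 - gamma,
         A2 = if (z == 0) gamma else 1 - gamma)
}

z_codes <- function(z) {
  z <- as.integer(z)
  z[is.na(z)] <- -1L
  z
}

run_codes <- function(chrom, n) {
  if (is.null(chrom)) return(rep.int(1L, n))
  as.integer(match(chrom, unique(chrom)))
}

#' Per-marker posterior probabilities of allelic imbalance
#'
#' Exact marginal state posteriors by the scaled forward-backward
#' algorithm; the per-step scaling keeps million-marker tracks
#' underflow-free. Chromosomes are independent chains, each starting from
#' the stationary distribution (no information before the first marker).
#' The reported `p_ai` at a marker is `P(A1) + P(A2)`.
#'
#' @param z Concordance indicators (1/0/NA) or a table with a `z` column.
#' @param params An [hmm_params()] object.
#' @param chrom Optional chromosome labels breaking the chain.
#' @return A list of class `posterior_track`: `posterior` (n x 3 matrix over
#'   N, A1, A2), `p_ai`, and the observed-data log-likelihood `loglik`.
#' @export
forward_backward <- function(z, params, chrom = NULL) {
  if (is.data.frame(z)) {
    if (is.null(chrom) && "chrom" %in% names(z)) chrom <- z$chrom
    z <- z$z
  }
  n <- length(z)
  stopifnot(n >= 1L)
  trans <- build_transition_matrix(params)
  init <- attr(trans, "stationary")
  res <- hmm_forward_backward_cpp(z_codes(z), run_codes(chrom, n),
                                  unclass(trans), init, params$gamma)
  post <- res$posterior
  colnames(post) <- c("N", "A1", "A2")
  structure(list(posterior = post,
                 p_ai = post[, "A1"] + post[, "A2"],
                 loglik = res$loglik,
                 gamma_num = res$gamma_num, gamma_den = res$gamma_den),
            class = "posterior_track")
}

#' Most probable state path
#'
#' Viterbi decoding of the same chain as [forward_backward()]; ties are
#' broken toward `N` (conservative calling).
#'
#' @inheritParams forward_backward
#' @return A character vector of states (`"N"`, `"A1"`, `"A2"`).
#' @export
viterbi_segments <- function(z, params, chrom = NULL) {
  if (is.data.frame(z)) {
    if (is.null(chrom) && "chrom" %in% names(z)) chrom <- z$chrom
    z <- z$z
  }
  n <- length(z)
  stopifnot(n >= 1L)
  trans <- build_transition_matrix(params)
  init <- attr(trans, "stationary")
  path <- hmm_viterbi_cpp(z_codes(z), run_codes(chrom, n),
                          unclass(trans), init, params$gamma)
  c("N", "A1", "A2")[path + 1L]
}

#' Estimate the concordance emission probability by EM
#'
#' Baum-Welch updates of `gamma` alone, transitions held fixed; this makes
#' the tool self-calibrating against unknown aberrant-cell fraction and
#' depth. Each iteration is one forward-backward pass; the constrained
#' M-step clamps `gamma` to `[0.5 + 1e-6, 1 - 1e-6]`, so the observed-data
#' log-likelihood is non-decreasing across iterations. On data with no
#' imbalance `gamma` drifts to the lower clamp and posteriors stay at the
#' prior.
#'
#' @inheritParams forward_backward
#' @param max_iter Maximum EM iterations.
#' @param tol Stop when `|delta gamma| < tol`.
#' @return A list: updated `params`, `gamma`, `loglik_trace`, `n_iter`,
#'   `converged`.
#' @export
estimate_gamma_em <- function(z, params, max_iter = 50L, tol = 1e-4,
                              chrom = NULL) {
  if (is.data.frame(z)) {
    if (is.null(chrom) && "chrom" %in% names(z)) chrom <- z$chrom
    z <- z$z
  }
  if (all(is.na(z))) {
    warning("estimate_gamma_em: all indicators missing; returning input gamma")
    return(list(params = params, gamma = params$gamma,
                loglik_trace = numeric(0), n_iter = 0L, converged = FALSE))
  }
  lo <- 0.5 + 1e-6
  hi <- 1 - 1e-6
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    fb <- forward_backward(z, params, chrom)
    trace <- c(trace, fb$loglik)
    gnew <- min(hi, max(lo, fb$gamma_num / fb$gamma_den))
    if (abs(gnew - params$gamma) < tol) {
      params$gamma <- gnew
      converged <- TRUE
      break
    }
    params$gamma <- gnew
  }
  list(params = params, gamma = params$gamma, loglik_trace = trace,
       n_iter = it, converged = converged)
}

#' Segment posterior tracks into called events
#'
#' Maximal runs of consecutive markers with `p_ai >= posterior_cut`,
#' trimmed of uninformative (missing-`z`) flanking markers, and retained
#' when at least `min_event_markers` long. Runs separated by even a single
#' sub-threshold marker are not merged. Each event records its genomic span
#' (positions of its first and last marker), the mean posterior, the mean
#' absolute RAF deviation from 0.5, and the aberrant-cell fraction that
#' deviation implies under a copy-neutral LOH model.
#'
#' @param posteriors A `posterior_track` from [forward_backward()], or a
#'   numeric vector of AI posteriors.
#' @param table The `marker_table` the posteriors were computed on (with
#'   `z`).
#' @param posterior_cut Posterior threshold defining event membership.
#' @param min_event_markers Minimum run length, in markers.
#' @return An `ai_events` data frame: `event_id`, `chrom`, `start_pos`,
#'   `end_pos`, `n_markers`, `mean_posterior`, `mean_raf_dev`,
#'   `est_fraction_cnloh`.
#' @export
call_events <- function(posteriors, table, posterior_cut = 0.90,
                        min_event_markers = 10L) {
  stopifnot(posterior_cut > 0, posterior_cut < 1)
  p_ai <- if (inherits(posteriors, "posterior_track")) posteriors$p_ai
          else as.numeric(posteriors)
  if (length(p_ai) != nrow(table)) {
    stop("call_events: posterior/table length mismatch", call. = FALSE)
  }
  events <- list()
  for (ch in unique(table$chrom)) {
    sel <- which(table$chrom == ch)
    above <- p_ai[sel] >= posterior_cut
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]
      i1 <- ends[k]
      zrun <- table$z[sel[i0:i1]]
      while (i0 <= i1 && is.na(table$z[sel[i0]])) i0 <- i0 + 1L
      while (i1 >= i0 && is.na(table$z[sel[i1]])) i1 <- i1 - 1L
      nm <- i1 - i0 + 1L
      if (nm < min_event_markers) next
      run <- sel[i0:i1]
      d <- mean(abs(table$raf[run] - 0.5))
      events[[length(events) + 1L]] <- data.frame(
        chrom = ch,
        start_pos = table$pos[run[1L]],
        end_pos = table$pos[run[length(run)]],
        n_markers = nm,
        mean_posterior = mean(p_ai[run]),
        mean_raf_dev = d,
        est_fraction_cnloh = estimate_fraction(d, "cnloh"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(events)) do.call(rbind, events) else data.frame(
    chrom = character(0), start_pos = integer(0), end_pos = integer(0),
    n_markers = integer(0), mean_posterior = numeric(0),
    mean_raf_dev = numeric(0), est_fraction_cnloh = numeric(0),
    stringsAsFactors = FALSE)
  out <- cbind(event_id = if (nrow(out)) sprintf("AI_%03d", seq_len(nrow(out)))
                          else character(0),
               out, stringsAsFactors = FALSE)
  structure(out, class = c("ai_events", "data.frame"))
}

#' Aberrant-cell fraction implied by a mean RAF deviation
#'
#' Inverts the mixture algebra for the expected favored-haplotype allele
#' frequency at aberrant-cell fraction `f` (see [expected_raf()]): with
#' `d` the deviation of that frequency from 0.5, copy-neutral LOH gives
#' `f = 2d`, single-copy deletion `f = 4d / (1 + 2d)` and single-copy
#' amplification `f = 4d / (1 - 2d)` (capped at 1). Distinguishing the
#' three mechanisms needs total-coverage information this model does not
#' use, so the caller chooses the model.
#'
#' @param mean_raf_dev Mean of `|RAF - 0.5|` over event markers, in
#'   \[0, 0.5).
#' @param model One of `"cnloh"`, `"deletion"`, `"amplification"`.
#' @return Estimated aberrant-cell fraction in \[0, 1\].
#' @export
estimate_fraction <- function(mean_raf_dev,
                              model = c("cnloh", "deletion", "amplification")) {
  model <- match.arg(model)
  d <- mean_raf_dev
  stopifnot(all(d >= 0), all(d < 0.5))
  f <- switch(model,
              cnloh = 2 * d,
              deletion = 4 * d / (1 + 2 * d),
              amplification = 4 * d / (1 - 2 * d))
  if (model == "amplification" && any(f > 1)) {
    warning("estimate_fraction: deviation exceeds the amplification model range; capping at 1")
    f <- pmin(f, 1)
  }
  pmin(f, 1)
}
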