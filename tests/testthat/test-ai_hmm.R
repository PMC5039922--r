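test_that("transition matrix structure and stationary distribution", {
  set.seed(101)
  for (i in 1:20) {
    p <- random_params()
    tr <- build_transition_matrix(p)
    expect_equal(unname(rowSums(tr)), rep(1, 3), tolerance = 1e-12)
    # exit mass toward N is 1 / mean_event_markers
    expect_equal(tr["A1", "N"], 1 / p$mean_event_markers)
    # eigen-solve oracle: left eigenvector for eigenvalue 1
    e <- eigen(t(unclass(tr)))
    v <- Re(e$vectors[, which.min(abs(e$values - 1))])
    v <- v / sum(v)
    expect_equal(v[2] + v[3], p$prevalence, tolerance = 1e-9)
    expect_equal(v, unname(attr(tr, "stationary")), tolerance = 1e-9)
  }

  # prevalence -> 0 limit: entry mass vanishes
  tiny <- build_transition_matrix(hmm_params(prevalence = 1e-9,
                                             mean_event_markers = 100))
  expect_lt(tiny["N", "A1"] + tiny["N", "A2"], 1e-10)

  # infeasible combination names both parameters
  expect_error(
    build_transition_matrix(hmm_params(prevalence = 0.99,
                                       mean_event_markers = 1.01)),
    "prevalence.*mean_event_markers")
})

test_that("emission probabilities", {
  expect_equal(emission_prob("N", 1, 0.8), 0.5)
  expect_equal(emission_prob("N", 0, 0.8), 0.5)
  expect_equal(emission_prob("A1", 1, 0.8), 0.8)
  expect_equal(emission_prob("A1", 0, 0.8), 0.2)
  expect_equal(emission_prob("A2", 0, 0.8), 0.8)
  expect_equal(emission_prob("A2", 1, 0.8), 0.2)
  for (s in c("N", "A1", "A2")) {
    expect_equal(emission_prob(s, 1, 0.77) + emission_prob(s, 0, 0.77), 1)
    expect_equal(emission_prob(s, NA, 0.77), 1)  # missing is uninformative
  }
})

test_that("forward_backward matches exhaustive enumeration", {
  set.seed(202)
  for (i in 1:30) {
    n <- sample(1:10, 1)
    p <- random_params()
    z <- random_track(n)
    fb <- forward_backward(z, p)
    o <- oracle_forward_backward(z, p)
    expect_lt(max(abs(unname(fb$posterior) - o$posterior)), 1e-10)
    expect_equal(fb$loglik, o$loglik, tolerance = 1e-10)
    expect_equal(unname(rowSums(fb$posterior)), rep(1, n), tolerance = 1e-9)
  }
})

test_that("forward_backward limits and symmetries", {
  p <- hmm_params(prevalence = 0.05, mean_event_markers = 200, gamma = 0.8)
  # all-missing track: posterior equals the prior exactly
  fb <- forward_backward(rep(NA_integer_, 50), p)
  expect_equal(unname(fb$p_ai), rep(0.05, 50), tolerance = 1e-12)

  # constant z = 1 over 200 markers: overwhelming evidence at the interior
  fb2 <- forward_backward(rep(1L, 200), p)
  expect_true(all(fb2$p_ai[50:150] > 0.99))

  # monotone in run length and in gamma (interior marker)
  mid_p <- function(n, g) {
    pp <- hmm_params(prevalence = 0.05, mean_event_markers = 200, gamma = g)
    forward_backward(rep(1L, n), pp)$p_ai[ceiling(n / 2)]
  }
  lens <- c(5, 10, 20, 40, 80)
  expect_true(all(diff(vapply(lens, mid_p, numeric(1), g = 0.7)) > -1e-12))
  gs <- c(0.55, 0.6, 0.7, 0.8, 0.9)
  expect_true(all(diff(vapply(gs, mid_p, numeric(1), n = 20)) > -1e-12))

  # haplotype relabelling: z -> 1 - z leaves p_ai unchanged
  set.seed(9)
  z <- random_track(300, p_missing = 0.1)
  expect_equal(forward_backward(z, p)$p_ai,
               forward_backward(1L - z, p)$p_ai, tolerance = 1e-12)

  # chromosomes are independent chains
  z2 <- c(rep(1L, 30), rep(0L, 30))
  chrom <- rep(c("chr1", "chr2"), each = 30)
  joint <- forward_backward(z2, p, chrom = chrom)
  solo <- forward_backward(rep(1L, 30), p)
  expect_equal(unname(joint$p_ai[1:30]), unname(solo$p_ai), tolerance = 1e-12)
})

test_that("viterbi path attains the enumerated maximum probability", {
  set.seed(303)
  for (i in 1:30) {
    n <- sample(2:10, 1)
    p <- random_params()
    z <- random_track(n)
    path <- viterbi_segments(z, p)
    lp <- oracle_path_prob(match(path, c("N", "A1", "A2")), z, p)
    expect_equal(lp, oracle_best_path_prob(z, p), tolerance = 1e-10)
  }
  # all-missing, prevalence < 0.5: ties resolve to all-N
  p <- hmm_params(prevalence = 0.05, mean_event_markers = 50)
  expect_true(all(viterbi_segments(rep(NA_integer_, 20), p) == "N"))
  # relabelling swaps A1 and A2, leaves N in place
  z <- c(rep(1L, 20), rep(0L, 20))
  p2 <- hmm_params(prevalence = 0.2, mean_event_markers = 10, gamma = 0.9)
  v1 <- viterbi_segments(z, p2)
  v2 <- viterbi_segments(1L - z, p2)
  expect_equal(v1 == "N", v2 == "N")
  expect_equal(v1[v1 != "N"] == "A1", v2[v2 != "N"] == "A2")
  # inside a missing-data gap the switch point is ambiguous (ties broken
  # deterministically), but the two decodings are equally probable
  zg <- c(rep(1L, 20), rep(NA_integer_, 5), rep(0L, 20))
  lp1 <- oracle_path_prob(match(viterbi_segments(zg, p2), c("N", "A1", "A2")),
                          zg, p2)
  lp2 <- oracle_path_prob(match(viterbi_segments(1L - zg, p2),
                                c("N", "A1", "A2")), 1L - zg, p2)
  expect_equal(lp1, lp2, tolerance = 1e-12)
})

test_that("call_events segments posterior runs as specified", {
  mk_tab <- function(n, z = rep(1L, n), chrom = "chr1") {
    data.frame(chrom = chrom, pos = seq_len(n) * 1000L,
               raf = ifelse(is.na(z), 0.5, 0.6), z = z,
               stringsAsFactors = FALSE)
  }
  # nothing above the cut
  tab <- mk_tab(20)
  expect_equal(nrow(call_events(rep(0.5, 20), tab, 0.9, 10)), 0L)

  # a single 30-marker run
  tab <- mk_tab(50)
  p <- c(rep(0.1, 10), rep(0.95, 30), rep(0.1, 10))
  ev <- call_events(p, tab, 0.9, 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_markers, 30L)
  expect_equal(ev$start_pos, 11000L)
  expect_equal(ev$end_pos, 40000L)
  expect_equal(ev$mean_posterior, 0.95)
  expect_equal(ev$mean_raf_dev, 0.1)
  expect_equal(ev$est_fraction_cnloh, 0.2)

  # two runs separated by one sub-cut marker are not merged
  p2 <- c(rep(0.95, 15), 0.5, rep(0.95, 15))
  ev2 <- call_events(p2, mk_tab(31), 0.9, 10)
  expect_equal(nrow(ev2), 2L)

  # missing-z flanks are trimmed before the length check
  z3 <- c(NA, NA, rep(1L, 9), NA)
  p3 <- rep(0.95, 12)
  ev3 <- call_events(p3, mk_tab(12, z = z3), 0.9, 10)
  expect_equal(nrow(ev3), 0L)  # 9 informative-flanked markers < 10
  ev4 <- call_events(p3, mk_tab(12, z = z3), 0.9, 9)
  expect_equal(ev4$start_pos, 3000L)
  expect_equal(ev4$end_pos, 11000L)
  expect_equal(ev4$n_markers, 9L)
})

test_that("EM on gamma increases likelihood and recovers the truth", {
  set.seed(404)
  truth <- hmm_params(prevalence = 0.2, mean_event_markers = 500,
                      gamma = 0.8, switch_rate = 0.02)
  tr <- sim_hmm_track(10000, truth)
  init <- hmm_params(prevalence = 0.2, mean_event_markers = 500,
                     gamma = 0.65, switch_rate = 0.02)
  em <- estimate_gamma_em(tr$z, init, max_iter = 100, tol = 1e-5)
  expect_true(all(diff(em$loglik_trace) > -1e-8))  # EM monotonicity
  expect_gt(em$gamma, 0.75)
  expect_lt(em$gamma, 0.85)

  # degenerate all-missing track returns the input gamma with a warning
  expect_warning(em0 <- estimate_gamma_em(rep(NA_integer_, 200), init),
                 "missing")
  expect_equal(em0$gamma, 0.65)
})

test_that("EM on null data drifts toward the 0.5 clamp and calls nothing", {
  set.seed(505)
  z <- rbinom(5000, 1, 0.5)
  init <- hmm_params(prevalence = 0.05, mean_event_markers = 200,
                     gamma = 0.65)
  em <- estimate_gamma_em(z, init, max_iter = 100)
  expect_lt(em$gamma, 0.60)
  fb <- forward_backward(z, em$params)
  tab <- data.frame(chrom = "chr1", pos = seq_along(z) * 1000L,
                    raf = 0.5, z = z)
  expect_equal(nrow(call_events(fb, tab, 0.9, 10)), 0L)
})

test_that("estimate_fraction inverts the mixture algebra", {
  for (m in c("cnloh", "deletion", "amplification")) {
    expect_equal(estimate_fraction(0, m), 0)
  }
  expect_equal(estimate_fraction(0.08, "cnloh"), 0.16)
  # round trips through the forward mixture model
  expect_equal(estimate_fraction(1 / (2 - 0.5) - 0.5, "deletion"), 0.5)
  f <- 0.3
  d_amp <- (1 + f) / (2 + f) - 0.5
  expect_equal(estimate_fraction(d_amp, "amplification"), f)
  d_cn <- (1 + f) / 2 - 0.5
  expect_equal(estimate_fraction(d_cn, "cnloh"), f)
  # deviations beyond the amplification range cap at 1 with a warning
  expect_warning(f1 <- estimate_fraction(0.3, "amplification"), "capping")
  expect_equal(f1, 1)
  expect_error(estimate_fraction(0.5, "cnloh"))
})
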