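# Three-step caller: ploidy fit, prevalence detection, assignment, and
# the exhaustive oracle.

test_that("noise-free prevalences are recovered exactly from branch coordinates", {
  b <- rbind(exact_bubbles(1, 1, 1, length_mb = c(200, 180, 150)),
             exact_bubbles(c(0, 0, 0), c(1, 1, 2), c(0.88, 0.60, 0.30),
                           length_mb = c(60, 50, 40), chrom = c("4", "5", "6")))
  b$r_adj <- b$r_raw
  expect_equal(detect_prevalences(b), c(0.88, 0.60, 0.30))
})

test_that("a genome with all bubbles at (1, 0) has no informative SCNA", {
  b <- exact_bubbles(1, 1, 1, length_mb = rep(100, 6))
  b$r_adj <- b$r_raw
  expect_error(detect_prevalences(b), "no informative SCNA")
  pf <- fit_ploidy(b)
  expect_equal(pf$tau_t, 2)
  expect_equal(pf$phi, 1)
  expect_match(pf$warnings, "unidentifiable", all = FALSE)
})

test_that("prevalence clustering merges nearby values at the cutoff", {
  # brute-force agglomeration by hand: {0.89, 0.88} {0.61, 0.60} {0.30}
  # at cutoff 0.2 gives medians 0.885, 0.605, 0.30
  b <- rbind(exact_bubbles(1, 1, 1, length_mb = c(200, 200)),
             exact_bubbles(0, 1, c(0.89, 0.88, 0.61, 0.60),
                           length_mb = 40, chrom = c("3", "4", "5", "6")),
             exact_bubbles(0, 2, 0.30, length_mb = 40, chrom = "7"))
  b$r_adj <- b$r_raw
  expect_equal(detect_prevalences(b), c(0.885, 0.605, 0.30))
})

test_that("assignment inverts the worked example and ties break to parsimony", {
  b <- exact_bubbles(c(1, 0), c(1, 1), c(1, 0.75), length_mb = c(150, 50))
  b$r_adj <- b$r_raw
  cs <- assign_ascn(b, prevalences = 0.75)
  expect_equal(cs$assignments$genotype, c("AB", "B"))
  expect_equal(cs$assignments$x, c(1, 0))
  expect_equal(cs$assignments$y, c(1, 1))
  expect_equal(cs$assignments$p[2], 0.75)
  expect_equal(cs$fit_residual, 0)
  # expected BAF pair of the B segment
  expect_equal(cs$assignments$baf_exp_hi[2], 0.8)
  expect_equal(cs$assignments$baf_exp_lo[2], 0.2)
})

test_that("noisy assignment recovers known states at fixed prevalences", {
  set.seed(101)
  states <- data.frame(x = sample(0:1, 40, TRUE))
  states$y <- states$x + sample(1:2, 40, TRUE)
  states$p <- sample(c(0.9, 0.5), 40, TRUE)
  b <- exact_bubbles(states$x, states$y, states$p, length_mb = 30)
  b$r_adj <- b$r_raw + rnorm(40, 0, 0.02)
  b$hds_median <- pmin(pmax(b$hds_median + rnorm(40, 0, 0.01), 0), 0.5)
  cs <- assign_ascn(b, prevalences = c(0.9, 0.5))
  hit <- cs$assignments$x == states$x & cs$assignments$y == states$y &
    cs$assignments$p == states$p
  expect_gte(mean(hit), 0.95)
})

test_that("the exhaustive oracle refuses large instances and nails exact ones", {
  b <- exact_bubbles(0, 1, 0.6, length_mb = rep(10, 13))
  b$r_adj <- b$r_raw
  expect_error(brute_force_fit(b), "refusing")
  b1 <- exact_bubbles(1, 2, 0.4)
  b1$r_adj <- b1$r_raw
  bf <- brute_force_fit(b1)
  expect_equal(bf$assignments[, c("x", "y", "p")],
               data.frame(x = 1, y = 2, p = 0.4))
  expect_equal(bf$fit_residual, 0)
})

test_that("the three-step heuristic matches the exhaustive oracle on noise-free instances", {
  mismatches <- 0
  for (seed in 1:100) {
    inst <- random_instance(seed)
    cs <- call_clones(inst$bubbles)
    b2 <- inst$bubbles
    b2$r_adj <- b2$r_raw
    bf <- brute_force_fit(b2, max_bubbles = nrow(b2))
    same <- isTRUE(all.equal(cs$assignments[, c("x", "y", "p")],
                             bf$assignments[, c("x", "y", "p")],
                             tolerance = 1e-9))
    if (!same) mismatches <- mismatches + 1
    expect_equal(sort(cs$subclone_prevalences), sort(inst$prevalences),
                 tolerance = 1e-9)
  }
  expect_equal(mismatches, 0)
})

test_that("fitting already-adjusted diploid data is idempotent (Phi = 1)", {
  inst <- random_instance(2024)
  pf <- fit_ploidy(inst$bubbles)
  expect_equal(pf$phi, 1, tolerance = 1e-4)
  expect_equal(pf$class, 2)
  expect_equal(pf$bubbles$r_adj, pf$bubbles$r_raw, tolerance = 1e-4)
})

test_that("polyploid ratio compression is undone by the scale profile", {
  # tri- and tetraploid genomes compress the raw ratio by their own
  # Phi; the fitted scale must restore the branch coordinates
  for (name in c("sam14", "sam15")) {
    cfg <- sam_config(name, het_density = 1 / 1e6)
    sim <- simulate_segments(cfg, seed = 19, noise_free = TRUE)
    loci <- select_het_loci(sim$variants)
    hz <- homogenize(sim$segments, loci)
    pf <- fit_ploidy(hz$bubbles)
    expect_equal(pf$phi, sim$truth$phi, tolerance = 0.02)
    st <- sim$truth$segment_states
    key <- paste(hz$bubbles$chrom, hz$bubbles$start)
    r_exp <- (st$r_true * sim$truth$phi)[match(key, paste(st$chrom, st$start))]
    expect_equal(pf$bubbles$r_adj, r_exp, tolerance = 0.03)
  }
})

test_that("prevalence ordering and separation invariants hold on sim output", {
  for (seed in c(3, 4)) {
    fit <- fit_sam("sam8", seed = seed)
    prevs <- fit$callset$subclone_prevalences
    expect_true(all(diff(prevs) < 0))
    if (length(prevs) > 1) expect_true(all(-diff(prevs) >= 0.2 - 1e-9))
    expect_true(all(fit$callset$assignments$p %in% c(prevs, 1)))
    expect_lte(fit$callset$purity, 1)
  }
})

test_that("report_tracks is genome-ordered and conserves segments", {
  fit <- fit_sam("sam3", seed = 5)
  tr <- report_tracks(fit$callset, loci = fit$loci)
  expect_equal(nrow(tr), nrow(fit$callset$assignments))
  expect_true(all(diff(order(clonecall:::chrom_rank(tr$chrom), tr$start)) == 1))
  ab <- tr[tr$genotype == "AB", ]
  expect_equal(ab$baf_exp_hi, rep(0.5, nrow(ab)))
  expect_equal(ab$r_exp, rep(1, nrow(ab)))
  l <- attr(tr, "loci")
  expect_false(is.null(l))
  expect_true(all(!is.na(l$baf_exp_hi[1:10])))
})
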