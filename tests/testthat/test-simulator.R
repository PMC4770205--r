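# Clone-tree simulator: mixture arithmetic, expectation correctness,
# determinism, inheritance.

test_that("cell fractions reproduce the benchmark mixture arithmetic", {
  m11 <- data.frame(component = c("normal", "T1", "T1a", "T1b"),
                    coverage = c(2, 5, 5, 5))
  cf <- cell_fractions(m11)
  expect_equal(cf$purity, 15 / 17)          # 88.2%
  expect_equal(cf$purity_reads, 30 / 34)    # same: all diploid
  m7 <- data.frame(component = c("normal", "T1", "T1a"), coverage = c(2, 8, 8))
  expect_equal(cell_fractions(m7)$purity, 16 / 18)  # 88.9%
  m1 <- data.frame(component = "normal", coverage = 15)
  expect_equal(cell_fractions(m1)$purity, 0)
  expect_error(cell_fractions(data.frame(component = "normal", coverage = 0)),
               "zero total coverage")
  # ploidy-weighted read share differs from the cell share
  m14 <- data.frame(component = c("normal", "T3"), coverage = c(3, 8),
                    ploidy = c(2, 3))
  cf14 <- cell_fractions(m14)
  expect_equal(cf14$purity, 8 / 11)
  expect_equal(cf14$purity_reads, 24 / 30)
})

test_that("nested clones inherit ancestral SCNAs and ground truth aggregates them", {
  cfg <- sam_config("sam11")
  sim <- simulate_segments(cfg, seed = 1)
  expect_equal(sim$truth$prevalences, c(15, 10, 5) / 17)
  st <- sim$truth$segment_states
  chr19 <- st[st$chrom == "19", ]            # T1 loss, shared by T1a/T1b
  expect_equal(chr19$x, 0); expect_equal(chr19$y, 1)
  expect_equal(chr19$p, 15 / 17)
  chr14 <- st[st$chrom == "14", ]            # subclone-common marker
  expect_equal(chr14$p, 10 / 17)
  chr12 <- st[st$chrom == "12" & st$start == 3e7 + 1, ]  # T1b-unique gain
  expect_equal(c(chr12$x, chr12$y), c(1, 2))
  expect_equal(chr12$p, 5 / 17)
})

test_that("noise-free expectations sit exactly on the branch lattice", {
  cfg <- sam_config("sam11", het_density = 1 / 2e6)
  sim <- simulate_segments(cfg, seed = 3, noise_free = TRUE)
  st <- sim$truth$segment_states
  phi <- sim$truth$phi
  expect_equal(st$r_true * phi, r_score(st$x, st$y, st$p), tolerance = 1e-12)
  ok <- !(st$x == 0 & st$y == 0)
  expect_equal(st$hds_true[ok], hds(st$x[ok], st$y[ok], st$p[ok]),
               tolerance = 1e-12)
  # normal-only genome: flat ratios, balanced BAFs
  sim1 <- simulate_segments(sam_config("sam1", het_density = 1 / 2e6),
                            seed = 3, noise_free = TRUE)
  expect_equal(sim1$truth$segment_states$r_true,
               rep(1, nrow(sim1$truth$segment_states)))
  expect_equal(sim1$truth$segment_states$hds_true,
               rep(0, nrow(sim1$truth$segment_states)))
})

test_that("the full pipeline on noise-free data recovers the ground truth", {
  cfg <- sam_config("sam11", het_density = 1 / 5e5)
  sim <- simulate_segments(cfg, seed = 9, noise_free = TRUE)
  loci <- select_het_loci(sim$variants)
  cs <- call_clones(homogenize(sim$segments, loci)$bubbles)
  expect_equal(cs$purity, sim$truth$purity, tolerance = 0.01)
  expect_equal(length(cs$subclone_prevalences), 3)
  expect_equal(cs$subclone_prevalences, sim$truth$prevalences,
               tolerance = 0.02)
})

test_that("tetraploid and diploid-twin observables coincide in simulation", {
  # the tetraploid design presents raw observables identical to a
  # diploid tumor at p' = p/(1+p), up to Monte-Carlo error
  cfg <- sam_config("sam15", het_density = 1 / 2e6)
  sim <- simulate_segments(cfg, seed = 5, noise_free = TRUE)
  st <- sim$truth$segment_states
  p_twin <- diploid_equivalent_purity(st$p)
  raw_twin <- r_score(pmax(st$x - 1, 0), pmax(st$y - 1, 0), p_twin)
  ok <- st$x >= 1
  expect_equal(st$r_true[ok], raw_twin[ok], tolerance = 0.02)
})

test_that("simulation is deterministic given seed and config", {
  cfg <- sam_config("sam3", het_density = 1 / 1e6)
  s1 <- simulate_segments(cfg, seed = 123)
  s2 <- simulate_segments(cfg, seed = 123)
  expect_identical(s1$segments, s2$segments)
  expect_identical(s1$variants, s2$variants)
  s3 <- simulate_segments(cfg, seed = 124)
  expect_false(identical(s1$variants, s3$variants))
})

test_that("sampling noise shrinks with marker density (Monte-Carlo consistency)", {
  err <- vapply(c(4e5, 1e5, 2.5e4), function(sp) {
    cfg <- sam_config("sam2", het_density = 1 / 2e6, marker_spacing = sp)
    sim <- simulate_segments(cfg, seed = 11)
    mean(abs(sim$segments$r_raw - sim$truth$segment_states$r_true))
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("config validation rejects inconsistent clone trees", {
  clones <- data.frame(name = "T1", parent = NA, ploidy = 2)
  ev <- data.frame(clone = "T1", chrom = "1", start = c(1, 50), end = c(100, 80),
                   x = 0, y = 1)
  mix <- data.frame(component = c("normal", "T1"), coverage = c(1, 1))
  expect_error(clone_tree_config(clones, ev, mix), "overlapping events")
  ev2 <- data.frame(clone = "T9", chrom = "1", start = 1, end = 100, x = 0, y = 1)
  expect_error(clone_tree_config(clones, ev2, mix), "unknown clone")
  mix2 <- data.frame(component = c("normal", "T2"), coverage = c(1, 1))
  expect_error(clone_tree_config(clones, NULL, mix2), "unknown component")
})

test_that("somatic scenarios inconsistent with the host state are rejected", {
  cfg <- sam_config("sam3", het_density = 1 / 1e6)
  sim <- simulate_segments(cfg, seed = 2)
  st <- sim$truth$segment_states
  loss <- which(st$x == 0 & st$y == 1)[1]
  bad <- data.frame(segment = loss, multiplicity = 2,
                    carrier_prevalence = st$p[loss])
  expect_error(simulate_somatics(sim, scenarios = bad, seed = 1),
               "exceeds the allele copy number")
  good <- data.frame(segment = loss, multiplicity = 1,
                     carrier_prevalence = st$p[loss])
  sv <- simulate_somatics(sim, scenarios = good, seed = 1, depth = 500)
  expect_equal(sv$true_vaf,
               expected_vaf(0, 1, st$p[loss], 1, st$p[loss]))
})

test_that("clone-config YAML round-trips", {
  cfg <- sam_config("sam7")
  path <- tempfile(fileext = ".yaml")
  write_clone_config(cfg, path)
  cfg2 <- read_clone_config(path)
  expect_equal(cfg2$mixture$coverage, cfg$mixture$coverage)
  expect_equal(cfg2$events$x, cfg$events$x)
  expect_equal(unname(cfg2$genome), unname(cfg$genome))
  sim1 <- simulate_segments(cfg, seed = 5)
  sim2 <- simulate_segments(cfg2, seed = 5)
  expect_equal(sim1$segments, sim2$segments)
})
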