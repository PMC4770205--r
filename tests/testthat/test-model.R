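# Forward model: expected copy number, copy ratio, BAF, HDS, branch
# lattice and the ploidy-adjustment algebra.

test_that("forward model reproduces the one-copy-loss worked example", {
  # (0, 1, 0.75): direct arithmetic oracle
  # CN = 2*0.25 + 1*0.75 = 1.25; R = CN/2; BAF = (0.75+0.25)/(0.75+0.5)
  expect_equal(expected_copy_number(0, 1, 0.75), 1.25)
  expect_equal(r_score(0, 1, 0.75), 0.625)
  expect_equal(baf(0, 1, 0.75), 0.8)
  expect_equal(hds(0, 1, 0.75), 0.3)
})

test_that("trivial states behave as expected", {
  expect_equal(r_score(1, 1, c(0, 0.3, 1)), c(1, 1, 1))
  expect_equal(expected_copy_number(1, 1, 0.3), 2)
  expect_equal(expected_copy_number(0, 0, 1), 0)
  expect_equal(r_score(2, 2, 1), 2)
  expect_equal(baf(0, 2, 1), 1)
  expect_equal(baf(1, 1, 0.4), 0.5)
  expect_equal(hds(3, 3, 0.7), 0)
  expect_equal(hds(1, 2, 1), 1 / 6)
})

test_that("invalid states are rejected", {
  expect_error(r_score(2, 1, 0.5), "x <= y")
  expect_error(hds(0, 1, 1.2), "prevalence")
  expect_error(r_score(0.5, 1, 0.5), "integers")
  expect_error(baf(0, 0, 1), "no DNA")
  expect_error(hds(0, 0, 1), "no DNA")
  expect_equal(r_score(0, 0, 1), 0)  # ratio is still measurable
})

test_that("hds equals |baf - 0.5| across the state space", {
  g <- expand.grid(x = 0:5, y = 0:5, p = seq(0, 0.99, by = 0.01))
  g <- g[g$x <= g$y, ]
  expect_equal(hds(g$x, g$y, g$p), abs(baf(g$x, g$y, g$p) - 0.5))
})

test_that("hds is monotone in prevalence, r in total copy number", {
  p <- seq(0.05, 1, by = 0.05)
  for (st in list(c(0, 1), c(0, 2), c(1, 2), c(1, 3))) {
    h <- hds(st[1], st[2], p)
    expect_true(all(diff(h) > 0))
  }
  for (pp in c(0.2, 0.6, 1)) {
    states <- data.frame(x = c(0, 0, 1, 1, 2), y = c(0, 1, 1, 2, 2))
    r <- r_score(states$x, states$y, pp)
    expect_true(all(diff(r[order(states$x + states$y)]) > 0))
  }
  expect_true(all(hds(0:4, 1:5, 0.5) <= 0.5))
  expect_true(all(hds(1, 2, seq(0.01, 1, 0.01)) <= 1 / 6 + 1e-12))
})

test_that("branch lattice enumerates genotypes and collapses to (1,0) at p -> 0", {
  # independent enumeration oracle
  count_states <- function(m) {
    n <- 0L
    for (x in 0:m) for (y in x:m) if (x + y <= m) n <- n + 1L
    n
  }
  expect_equal(nrow(ascn_genotypes(2)), count_states(2))
  expect_equal(nrow(ascn_genotypes(2)), 4L)  # {0, B, AB, BB}
  expect_equal(nrow(ascn_genotypes(10)), count_states(10))
  expect_equal(count_states(10), 36L)  # frozen from the oracle above

  b <- build_branches(2, prevalence_ticks = 1)
  expect_setequal(b$genotype, c("Ø", "B", "AB", "BB"))
  expect_equal(nrow(b), 4)

  b0 <- build_branches(5, prevalence_ticks = 1e-9)
  expect_equal(b0$r, rep(1, nrow(b0)), tolerance = 1e-6)
  expect_equal(b0$hds, rep(0, nrow(b0)), tolerance = 1e-6)

  b2 <- build_branches(4, prevalence_ticks = seq(0.1, 1, 0.1))
  expect_true(all(diff(order(b2$x + b2$y, b2$y - b2$x, b2$p)) == 1))
  expect_true(all(b2$hds <= 0.5 & b2$hds >= 0) && all(b2$r >= 0))
})

test_that("genotype labels follow the A/B convention", {
  expect_equal(genotype_label(c(0, 0, 1, 0, 1), c(0, 1, 1, 2, 2)),
               c("Ø", "B", "AB", "BB", "ABB"))
  expect_equal(genotype_label(0, 0, ascii = TRUE), "0")
})

test_that("ploidy adjustment factor matches its closed form", {
  expect_equal(ploidy_phi(2, 0.9)$phi, 1)
  expect_equal(ploidy_phi(2, 0.1)$phi, 1)
  expect_equal(ploidy_phi(4, 1)$phi, 2)
  expect_equal(ploidy_phi(3, 0.723)$phi, (3 * 0.723 + 2 * 0.277) / 2)
  expect_equal(ploidy_phi(3, 0.723)$phi, 1.3615, tolerance = 1e-4)
  pa <- ploidy_phi(3, 0.5)
  expect_equal(pa$adjust_r(c(1, 0.8)), c(1, 0.8) * pa$phi)
})

test_that("diploid-equivalent purity of a tetraploid solution", {
  expect_equal(diploid_equivalent_purity(0.70), 0.7 / 1.7)
  expect_equal(round(diploid_equivalent_purity(0.70), 2), 0.41)
  expect_equal(diploid_equivalent_purity(0), 0)
  expect_equal(diploid_equivalent_purity(1), 0.5)
  expect_true(all(diploid_equivalent_purity(seq(0, 1, 0.01)) <= 0.5))
})

test_that("whole-genome-doubling twin states are indistinguishable in raw scores", {
  # a tetraploid tumor at purity p carrying (x+1, y+1) shows the same
  # raw (R', HDS) as a diploid tumor at p' = p/(1+p) carrying (x, y);
  # the doubled state (2x, 2y) is the twin of diploid (2x-1, 2y-1)
  g <- expand.grid(x = 0:3, y = 0:3, p = seq(0.05, 0.95, by = 0.05))
  g <- g[g$x <= g$y, ]
  p_dip <- diploid_equivalent_purity(g$p)
  r_tet_raw <- r_score(g$x + 1, g$y + 1, g$p) / ploidy_phi(4, g$p)$phi
  r_dip_raw <- r_score(g$x, g$y, p_dip)  # Phi = 1 for the diploid twin
  expect_equal(r_tet_raw, r_dip_raw, tolerance = 1e-12)
  expect_equal(hds(g$x + 1, g$y + 1, g$p), hds(g$x, g$y, p_dip),
               tolerance = 1e-12)
})
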