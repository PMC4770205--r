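# Fixture builders shared across the suite.  Everything is generated in
# code; no data files.

# Bubbles placed at exact branch coordinates (already ploidy-adjusted,
# i.e. a diploid-scale genome with Phi = 1).
exact_bubbles <- function(x, y, p, length_mb = 50, chrom = NULL) {
  n <- max(length(x), length(y), length(p), length(length_mb))
  x <- rep_len(x, n); y <- rep_len(y, n); p <- rep_len(p, n)
  length_mb <- rep_len(length_mb, n)
  if (is.null(chrom)) chrom <- as.character(seq_len(n))
  start <- rep(1, n)
  data.frame(chrom = chrom, start = start,
             end = start + length_mb * 1e6 - 1,
             length_bp = length_mb * 1e6,
             n_het = 1000L,
             r_raw = r_score(x, y, p),
             hds_median = clonecall:::hds_branch(x, y, p),
             hds_sd = 0, hds_floor = 0,
             r_adj = NA_real_)
}

# A random noise-free diploid instance for the heuristic-vs-oracle
# equivalence check: at most `max_seg` segments, up to three prevalence
# levels separated by >= 0.25 on the 0.05 grid, states drawn from
# unambiguous branch families, a large disomic background, and an
# implied tumor ploidy near 2 (rejection-sampled) so the instance is a
# coherent diploid genome.
random_instance <- function(seed, max_seg = 12) {
  set.seed(seed)
  pool <- list(c(0, 1), c(0, 2), c(0, 3), c(1, 2), c(2, 2), c(0, 0))
  repeat {
    p1 <- sample(seq(0.55, 0.95, by = 0.05), 1)
    k <- sample(1:3, 1)
    prevs <- p1
    grid_below <- function(top) {
      if (top - 0.25 < 0.15 - 1e-9) numeric(0) else
        seq(0.15, top - 0.25, by = 0.05)
    }
    if (k >= 2) {
      lo <- grid_below(p1)
      if (length(lo) == 0) next
      prevs <- c(prevs, sample(rep(lo, 2), 1))
    }
    if (k >= 3) {
      lo <- grid_below(min(prevs))
      if (length(lo) == 0) next
      prevs <- c(prevs, sample(rep(lo, 2), 1))
    }
    n_ab <- sample(3:5, 1)
    n_scna <- sample(length(prevs):(max_seg - n_ab), 1)
    st <- pool[sample(length(pool), n_scna, replace = TRUE)]
    sx <- vapply(st, `[`, 0, 1)
    sy <- vapply(st, `[`, 0, 2)
    # every prevalence level needs at least one unbalanced witness
    sp <- numeric(n_scna)
    sp[seq_along(prevs)] <- prevs
    if (n_scna > length(prevs))
      sp[(length(prevs) + 1):n_scna] <- sample(prevs, n_scna - length(prevs),
                                               replace = TRUE)
    for (j in seq_along(prevs)) {
      # every level needs a witness on a branch that can seed a
      # prevalence: unbalanced and outside the ambiguous ABB-family
      lev <- which(sp == prevs[j])
      seedable <- sx[lev] == 0 & sy[lev] >= 1
      if (!any(seedable)) {
        swap <- pool[[sample(3, 1)]]  # (0,1), (0,2) or (0,3)
        sx[lev[1]] <- swap[1]; sy[lev[1]] <- swap[2]
      }
    }
    x <- c(rep(1, n_ab), sx)
    y <- c(rep(1, n_ab), sy)
    p <- c(rep(1, n_ab), sp)
    len <- c(stats::runif(n_ab, 120, 240), stats::runif(n_scna, 15, 60))
    # implied tumor ploidy over the clonal mass (AB counts as 2)
    clonal <- (x == 1 & y == 1) | p >= p1 - 0.1
    tau_hat <- sum(len[clonal] * (x + y)[clonal]) / sum(len[clonal])
    if (tau_hat < 1.85 || tau_hat > 2.15) next
    # the dominant clone needs real mass among informative segments
    inf_mass <- sum(len[!(x == 1 & y == 1)])
    cl_mass <- sum(len[!(x == 1 & y == 1) & p == p1])
    if (cl_mass < 0.15 * inf_mass) next
    return(list(bubbles = exact_bubbles(x, y, p, length_mb = len),
                x = x, y = y, p = p, prevalences = sort(prevs,
                                                        decreasing = TRUE)))
  }
}

# Heterozygous loci with prescribed folded BAF values for one segment.
loci_with_fold <- function(chrom, pos, folded, depth = 100) {
  data.frame(chrom = chrom, pos = pos,
             ref_count = round(depth * (0.5 - folded)),
             alt_count = round(depth * (0.5 + folded)),
             baf_obs = 0.5 + folded)
}

# A simulated dataset + fitted callset reused across tests; the default
# locus density matches the shipped configs (~50k loci genome-wide).
fit_sam <- function(name, seed, het_density = 1 / 6e4, ...) {
  cfg <- sam_config(name, het_density = het_density)
  sim <- simulate_segments(cfg, seed = seed)
  loci <- select_het_loci(sim$variants)
  hz <- homogenize(sim$segments, loci)
  cs <- call_clones(hz$bubbles, ...)
  list(sim = sim, loci = loci, bubbles = hz$bubbles, callset = cs)
}
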