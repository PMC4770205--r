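# Segment-level simulator of tumor/normal mixtures with known clone
# trees.  Read-level simulation is deliberately avoided: the caller
# consumes only the sufficient statistics (per-segment copy ratio,
# per-locus allele counts), so those are generated directly from the
# mixture model, with configurable noise.

#' Reference chromosome lengths used by the simulator
#'
#' The 22 autosomes with lengths rounded to the megabase.
#'
#' @return Named numeric vector of lengths in bp.
#' @export
default_genome <- function() {
  mb <- c(`1` = 249, `2` = 243, `3` = 198, `4` = 191, `5` = 181, `6` = 171,
          `7` = 159, `8` = 146, `9` = 141, `10` = 136, `11` = 135,
          `12` = 134, `13` = 115, `14` = 107, `15` = 102, `16` = 90,
          `17` = 81, `18` = 78, `19` = 59, `20` = 63, `21` = 48, `22` = 51)
  mb * 1e6
}

# Internal: the baseline ASCN of a clone given its ploidy.
baseline_state <- function(ploidy) {
  switch(as.character(ploidy),
         `2` = c(1, 1), `3` = c(1, 2), `4` = c(2, 2),
         stop("unsupported clone ploidy: ", ploidy))
}

#' Assemble a clone-tree configuration
#'
#' @param clones data.frame with `name`, `parent` (`NA` for a founder)
#'   and `ploidy` (2, 3 or 4; sets the baseline genotype AB, ABB or
#'   AABB).  Children inherit ancestral SCNAs unless they define an
#'   overlapping event of their own.
#' @param events data.frame of SCNA events: `clone`, `chrom`, `start`,
#'   `end`, `x`, `y`.  Events of one clone must not overlap.
#' @param mixture data.frame with `component` (a clone name or
#'   `"normal"`) and `coverage`, the per-haploid-copy depth of that
#'   component; a component of ploidy tau contributes `coverage * tau`
#'   to the total depth, and cell fractions are proportional to
#'   `coverage`.
#' @param genome Named vector of chromosome lengths (default
#'   [default_genome()]).
#' @param het_density Germline heterozygous loci per bp (default
#'   1/60000, about 50k loci genome-wide).
#' @param sd_r Per-marker standard deviation of the copy-ratio noise;
#'   a segment with n markers gets ratio noise `sd_r / sqrt(n)`
#'   (default 0.25).
#' @param marker_spacing Copy-ratio marker spacing in bp (default 5e4).
#' @param normal_depth Depth of the matched normal sample at het loci
#'   (default 30).
#' @return An object of class `clone_tree_config`.
#' @export
clone_tree_config <- function(clones, events, mixture,
                              genome = default_genome(),
                              het_density = 1 / 60000,
                              sd_r = 0.25, marker_spacing = 5e4,
                              normal_depth = 30) {
  stopifnot(is.data.frame(clones),
            all(c("name", "parent", "ploidy") %in% names(clones)),
            is.data.frame(mixture),
            all(c("component", "coverage") %in% names(mixture)))
  if (is.null(events) || nrow(events) == 0)
    events <- data.frame(clone = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         x = integer(0), y = integer(0))
  stopifnot(all(c("clone", "chrom", "start", "end", "x", "y") %in% names(events)))
  events$chrom <- normalize_chrom(events$chrom)
  clones$name <- as.character(clones$name)
  bad_parent <- !is.na(clones$parent) & !(clones$parent %in% clones$name)
  if (any(bad_parent)) stop("clone_tree_config: unknown parent clone")
  if (!all(events$clone %in% clones$name))
    stop("clone_tree_config: event references unknown clone")
  if (!all(mixture$component %in% c("normal", clones$name)))
    stop("clone_tree_config: mixture references unknown component")
  if (any(mixture$coverage <= 0))
    stop("clone_tree_config: coverages must be positive")
  if (nrow(events) > 0) ascn_state(events$x, events$y, 0)
  # events of one clone must not overlap
  for (cl in unique(events$clone)) for (ch in unique(events$chrom)) {
    e <- events[events$clone == cl & events$chrom == ch, , drop = FALSE]
    if (nrow(e) > 1) {
      e <- e[order(e$start), , drop = FALSE]
      if (any(e$start[-1] <= e$end[-nrow(e)]))
        stop(sprintf("clone_tree_config: overlapping events for clone %s on chr %s",
                     cl, ch))
    }
  }
  mixture$ploidy <- ifelse(mixture$component == "normal", 2,
                           clones$ploidy[match(mixture$component, clones$name)])
  structure(list(clones = clones, events = events, mixture = mixture,
                 genome = genome, het_density = het_density, sd_r = sd_r,
                 marker_spacing = marker_spacing,
                 normal_depth = normal_depth),
            class = "clone_tree_config")
}

#' @export
print.clone_tree_config <- function(x, ...) {
  cat(sprintf("clone tree: %d clone(s), %d SCNA event(s)\n",
              nrow(x$clones), nrow(x$events)))
  cf <- cell_fractions(x$mixture)
  cat(sprintf("  mixture: %s (purity %.3f)\n",
              paste(sprintf("%s:%g", x$mixture$component, x$mixture$coverage),
                    collapse = ", "),
              cf$purity))
  invisible(x)
}

#' Cell and read fractions of a mixture
#'
#' Cell counts are proportional to the per-haploid coverage (a cell of
#' ploidy tau yields tau-fold the reads), so the purity -- the tumor
#' *cell* fraction -- is the tumor share of the coverages, while the
#' read share weights coverage by ploidy.  For all-diploid mixtures the
#' two coincide.
#'
#' @param mixture data.frame with `component`, `coverage` and optionally
#'   `ploidy` (default 2).
#' @return List with `fractions` (per-component `cell_fraction` and
#'   `read_share`), `purity` (tumor cell fraction) and `purity_reads`
#'   (tumor read share).
#' @examples
#' m <- data.frame(component = c("normal", "T1", "T1a", "T1b"),
#'                 coverage = c(2, 5, 5, 5))
#' cell_fractions(m)$purity  # 15/17 = 0.882
#' @export
cell_fractions <- function(mixture) {
  stopifnot(is.data.frame(mixture), nrow(mixture) >= 1,
            all(c("component", "coverage") %in% names(mixture)))
  if (sum(mixture$coverage) <= 0) stop("cell_fractions: zero total coverage")
  pl <- if ("ploidy" %in% names(mixture)) mixture$ploidy else rep(2, nrow(mixture))
  f <- data.frame(component = mixture$component,
                  coverage = mixture$coverage,
                  ploidy = pl,
                  cell_fraction = mixture$coverage / sum(mixture$coverage),
                  read_share = mixture$coverage * pl / sum(mixture$coverage * pl))
  tum <- f$component != "normal"
  list(fractions = f,
       purity = sum(f$cell_fraction[tum]),
       purity_reads = sum(f$read_share[tum]))
}

# Internal: ancestors-first lineage of a clone (self first).
clone_lineage <- function(clones, name) {
  line <- character(0)
  while (!is.na(name)) {
    line <- c(line, name)
    name <- clones$parent[match(name, clones$name)]
  }
  line
}

# Internal: per-clone (x, y) state of an atomic segment [s, e] on chrom
# ch.  The nearest ancestor (self first) with a covering event wins;
# otherwise the clone's ploidy baseline.
segment_clone_state <- function(config, clone, ch, s, e) {
  for (cl in clone_lineage(config$clones, clone)) {
    ev <- config$events
    hit <- ev$clone == cl & ev$chrom == ch & ev$start <= s & ev$end >= e
    if (any(hit)) {
      i <- which(hit)[1]
      return(c(ev$x[i], ev$y[i]))
    }
  }
  baseline_state(config$clones$ploidy[match(clone, config$clones$name)])
}

#' Simulate segment-level observables from a clone tree
#'
#' Partitions the genome at all SCNA breakpoints, computes the exact
#' mixture expectations per atomic segment -- copy ratio
#' `R' = sum_c f_c n_c / sum_c f_c tau_c` and B-allele frequency
#' `sum_c f_c b_c / sum_c f_c n_c`, summed over *all* mixture components
#' -- then draws the observables: per-segment ratio
#' `Normal(R'_true, sd_r / sqrt(n_markers))` and per-locus allele counts
#' `Binomial(depth, BAF)` with `depth ~ Poisson(total_depth * R'_true)`
#' and random phase (the amplified parental allele is equally likely to
#' be the alt allele).
#'
#' @param config A [clone_tree_config()].
#' @param seed RNG seed; the same seed and config give identical output.
#' @param noise_free Emit exact expectations instead of draws (loci at
#'   depth 10000 with counts rounded).
#' @return List with `segments` (raw segment table for [homogenize()]),
#'   `variants` (paired allele depths for [select_het_loci()]) and
#'   `truth` (list: `purity`, `prevalences` (descending), `tau_t`
#'   (length-weighted mean tumor ploidy), `phi`, `cell_fractions`, and
#'   `segment_states` with the true `(x, y, p)` and expected scores per
#'   segment).
#' @export
simulate_segments <- function(config, seed = NULL, noise_free = FALSE) {
  stopifnot(inherits(config, "clone_tree_config"))
  if (!is.null(seed)) set.seed(seed)
  cf <- cell_fractions(config$mixture)
  fr <- cf$fractions
  tumor_clones <- fr$component[fr$component != "normal"]
  total_depth <- sum(fr$coverage * fr$ploidy)

  # atomic partition per chromosome
  segs <- list()
  for (ch in names(config$genome)) {
    len <- config$genome[[ch]]
    ev <- config$events[config$events$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(1, len + 1, ev$start, ev$end + 1)))
    bp <- bp[bp >= 1 & bp <= len + 1]
    segs[[ch]] <- data.frame(chrom = ch, start = bp[-length(bp)],
                             end = bp[-1] - 1)
  }
  segs <- do.call(rbind, segs)
  rownames(segs) <- NULL

  n <- nrow(segs)
  ncomp <- nrow(fr)
  cn <- matrix(0, n, ncomp)   # total copies per component
  bc <- matrix(0, n, ncomp)   # copies of the tracked parental allele B
  for (j in seq_len(ncomp)) {
    comp <- fr$component[j]
    for (i in seq_len(n)) {
      st <- if (comp == "normal") c(1, 1) else
        segment_clone_state(config, comp, segs$chrom[i], segs$start[i],
                            segs$end[i])
      cn[i, j] <- st[1] + st[2]
      bc[i, j] <- st[2]
    }
  }
  w <- segs$end - segs$start + 1
  f <- fr$cell_fraction
  n_mix <- as.vector(cn %*% f)
  b_mix <- as.vector(bc %*% f)
  tau_mix <- sum(w * n_mix) / sum(w)
  r_true <- n_mix / tau_mix
  baf_true <- ifelse(n_mix > 0, b_mix / n_mix, NA_real_)

  # ground-truth per-segment state: clones sharing an identical non-AB
  # state are one carrier group; p is their summed cell fraction
  tj <- which(fr$component != "normal")
  truth_rows <- lapply(seq_len(n), function(i) {
    key <- paste(cn[i, tj] - bc[i, tj], bc[i, tj])
    alt <- which(!(cn[i, tj] == 2 & bc[i, tj] == 1))
    if (length(alt) == 0)
      return(data.frame(segment = i, x = 1, y = 1, p = cf$purity))
    g <- split(alt, key[alt])
    do.call(rbind, lapply(g, function(k) {
      data.frame(segment = i, x = cn[i, tj[k[1]]] - bc[i, tj[k[1]]],
                 y = bc[i, tj[k[1]]], p = sum(f[tj[k]]))
    }))
  })
  truth_states <- do.call(rbind, truth_rows)
  rownames(truth_states) <- NULL
  # primary state per segment: the carrier group of largest prevalence
  prim <- truth_states[order(truth_states$segment, -truth_states$p), ]
  prim <- prim[!duplicated(prim$segment), ]
  seg_states <- cbind(segs, prim[match(seq_len(n), prim$segment),
                                 c("x", "y", "p")],
                      r_true = r_true, baf_true = baf_true,
                      hds_true = abs(baf_true - 0.5))
  rownames(seg_states) <- NULL

  tau_t <- sum(vapply(tj, function(j) f[j] * sum(w * cn[, j]) / sum(w), 0)) /
    sum(f[tj])
  prevalences <- sort(unique(round(
    truth_states$p[!(truth_states$x == 1 & truth_states$y == 1)], 10)),
    decreasing = TRUE)

  # observed copy-ratio segments
  segs$n_markers <- pmax(1L, as.integer(round(w / config$marker_spacing)))
  if (noise_free) {
    segs$r_raw <- r_true
  } else {
    segs$r_raw <- pmax(0, stats::rnorm(n, r_true,
                                       config$sd_r / sqrt(segs$n_markers)))
  }

  # germline het loci
  loci <- list()
  for (i in seq_len(n)) {
    k <- round(w[i] * config$het_density)
    if (k < 1) next
    pos <- sort(sample.int(w[i], min(k, w[i]))) + segs$start[i] - 1
    k <- length(pos)
    if (is.na(baf_true[i])) next  # no DNA: no readable loci
    if (noise_free) {
      dp <- rep(10000L, k)
      alt <- round(dp * baf_true[i])
    } else {
      dp <- stats::rpois(k, total_depth * r_true[i])
      flip <- stats::runif(k) < 0.5
      q <- ifelse(flip, 1 - baf_true[i], baf_true[i])
      alt <- stats::rbinom(k, dp, q)
    }
    ndp <- if (noise_free) rep(10000L, k) else
      stats::rpois(k, config$normal_depth)
    nalt <- if (noise_free) as.integer(ndp / 2) else
      stats::rbinom(k, ndp, 0.5)
    keep <- dp > 0 & ndp > 0
    loci[[length(loci) + 1]] <- data.frame(
      chrom = segs$chrom[i], pos = pos, tumor_ref = (dp - alt),
      tumor_alt = alt, normal_ref = ndp - nalt, normal_alt = nalt)[keep, ,
                                                                   drop = FALSE]
  }
  variants <- do.call(rbind, loci)
  rownames(variants) <- NULL

  list(segments = segs[, c("chrom", "start", "end", "n_markers", "r_raw")],
       variants = variants,
       truth = list(purity = cf$purity, purity_reads = cf$purity_reads,
                    prevalences = prevalences, tau_t = tau_t,
                    phi = tau_mix / 2, total_depth = total_depth,
                    cell_fractions = fr, segment_states = seg_states,
                    all_states = truth_states))
}

#' Simulate somatic variants with known chronology
#'
#' Draws somatic point mutations inside simulated segments: each variant
#' is placed on a scenario band of its host segment's true state (see
#' [scenario_bands()]) and its alt count is `Binomial(depth,
#' vaf_expected)`.
#'
#' @param sim Output of [simulate_segments()].
#' @param n Number of variants (default 200).
#' @param depth Mean tumor depth; per-variant depth is
#'   `Poisson(depth * R'_true)` of the host segment (min 1).
#' @param seed RNG seed.
#' @param scenarios Optional explicit scenarios: data.frame with
#'   `segment` (row in `sim$truth$segment_states`), `multiplicity`,
#'   `carrier_prevalence`; validated against the segment states
#'   (a multiplicity above the allele copy number is an error).
#' @return data.frame with `chrom`, `pos`, `ref_count`, `alt_count`,
#'   `vaf_obs`, `true_label`, `true_vaf`, `segment`.
#' @export
simulate_somatics <- function(sim, n = 200, depth = 100, seed = NULL,
                              scenarios = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ss <- sim$truth$segment_states
  prevs <- sim$truth$prevalences
  if (!is.null(scenarios)) {
    stopifnot(all(c("segment", "multiplicity", "carrier_prevalence")
                  %in% names(scenarios)))
    out <- lapply(seq_len(nrow(scenarios)), function(i) {
      s <- ss[scenarios$segment[i], ]
      vaf <- expected_vaf(s$x, s$y, s$p, scenarios$multiplicity[i],
                          scenarios$carrier_prevalence[i])
      dp <- max(1, stats::rpois(1, depth * s$r_true))
      alt <- stats::rbinom(1, dp, vaf)
      data.frame(chrom = s$chrom,
                 pos = round(stats::runif(1, s$start, s$end)),
                 ref_count = dp - alt, alt_count = alt,
                 true_label = NA_character_, true_vaf = vaf,
                 segment = scenarios$segment[i])
    })
    out <- do.call(rbind, out)
    out$vaf_obs <- out$alt_count / (out$ref_count + out$alt_count)
    return(out)
  }
  usable <- which(!is.na(ss$baf_true) & ss$p > 0 & pmax(ss$x, ss$y) >= 1)
  w <- (ss$end - ss$start + 1)[usable]
  host <- sample(usable, n, replace = TRUE, prob = w)
  rows <- lapply(host, function(i) {
    s <- ss[i, ]
    bands <- scenario_bands(s$x, s$y, s$p, prevs[prevs < s$p - 1e-9])
    bands <- bands[bands$vaf_expected > 0, , drop = FALSE]
    if (nrow(bands) == 0) return(NULL)
    j <- sample.int(nrow(bands), 1)
    dp <- max(1, stats::rpois(1, depth * s$r_true))
    alt <- stats::rbinom(1, dp, bands$vaf_expected[j])
    data.frame(chrom = s$chrom, pos = round(stats::runif(1, s$start, s$end)),
               ref_count = dp - alt, alt_count = alt,
               true_label = bands$label[j], true_vaf = bands$vaf_expected[j],
               segment = i)
  })
  out <- do.call(rbind, rows)
  out$vaf_obs <- out$alt_count / (out$ref_count + out$alt_count)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------
# Ready-made designs: the sam1..sam15 mixture scheme

# Internal: the shared clone library (T1 with nested subclones T1a/T1b,
# an independent clone T2, a triploid T3 and a tetraploid T4).
sam_clone_library <- function() {
  clones <- data.frame(
    name = c("T1", "T1a", "T1b", "T2", "T3", "T4"),
    parent = c(NA, "T1", "T1", NA, NA, NA),
    ploidy = c(2, 2, 2, 2, 3, 4))
  ev <- function(clone, chrom, s_mb, e_mb, x, y)
    data.frame(clone = clone, chrom = as.character(chrom),
               start = as.integer(s_mb * 1e6 + 1), end = as.integer(e_mb * 1e6),
               x = x, y = y)
  events <- rbind(
    # T1: homozygous deletions on 1 and 2p, one-copy losses on 2q/17p/19,
    # copy-neutral LOH on 7q and 15 (shared by T1a and T1b)
    ev("T1", 1, 50, 80, 0, 0),
    ev("T1", 2, 20, 50, 0, 0),
    ev("T1", 2, 120, 200, 0, 1),
    ev("T1", 17, 0, 22, 0, 1),
    ev("T1", 19, 0, 59, 0, 1),
    ev("T1", 7, 60, 159, 0, 2),
    ev("T1", 15, 0, 102, 0, 2),
    # common marker of the subclones: one-copy loss of 14
    ev("T1a", 14, 0, 107, 0, 1),
    ev("T1b", 14, 0, 107, 0, 1),
    # unique T1b marker: a 20 Mb one-copy gain on 12
    ev("T1b", 12, 30, 50, 1, 2),
    # independent clone T2
    ev("T2", 3, 0, 198, 0, 1),
    ev("T2", 8, 0, 146, 0, 2),
    ev("T2", 9, 10, 30, 0, 0),
    ev("T2", 5, 50, 90, 1, 2),
    # triploid T3 (baseline ABB): relative losses and gains
    ev("T3", 4, 0, 191, 1, 1),
    ev("T3", 17, 0, 81, 0, 1),
    ev("T3", 8, 0, 146, 1, 3),
    ev("T3", 13, 0, 115, 0, 2),
    # tetraploid T4 (baseline AABB): modest post-doubling SCNAs, all of
    # which mirror a diploid state one copy down -- the whole-genome
    # doubling degeneracy is left intact by design
    ev("T4", 13, 0, 115, 1, 2),
    ev("T4", 9, 40, 141, 1, 3),
    ev("T4", 5, 0, 46, 2, 3),
    ev("T4", 17, 0, 81, 2, 4))
  list(clones = clones, events = events)
}

#' Mixture designs of the simulated samples
#'
#' The fifteen coverage mixtures (component x per-haploid coverage) of
#' the benchmark designs: normal-only, pure tumor, purity ladders,
#' nested and independent subclones, and tri-/tetraploid clones.
#'
#' @return Named list of mixture data.frames.
#' @export
sam_mixtures <- function() {
  mx <- function(...) {
    v <- c(...)
    data.frame(component = names(v), coverage = unname(v))
  }
  list(sam1 = mx(normal = 15),
       sam2 = mx(T1 = 15),
       sam3 = mx(normal = 3, T1 = 12),
       sam4 = mx(normal = 6, T1 = 9),
       sam5 = mx(normal = 9, T1 = 6),
       sam6 = mx(normal = 12, T1 = 3),
       sam7 = mx(normal = 2, T1 = 8, T1a = 8),
       sam8 = mx(normal = 2, T1 = 8, T1a = 4, T1b = 4),
       sam9 = mx(normal = 2, T1 = 8, T2 = 8),
       sam10 = mx(normal = 2, T1 = 11, T2 = 5),
       sam11 = mx(normal = 2, T1 = 5, T1a = 5, T1b = 5),
       sam12 = mx(normal = 2, T1 = 8, T1a = 4, T2 = 4),
       sam13 = mx(normal = 2, T1 = 8, T1a = 5, T1b = 3),
       sam14 = mx(normal = 3, T3 = 8),
       sam15 = mx(normal = 3, T4 = 6))
}

#' Ready-made simulation configs sam1..sam15
#'
#' @param name One of `"sam1"` .. `"sam15"`.
#' @param ... Overrides passed to [clone_tree_config()] (e.g.
#'   `het_density`, `sd_r`).
#' @return A `clone_tree_config`.
#' @examples
#' cfg <- sam_config("sam11")
#' cell_fractions(cfg$mixture)$purity  # 15/17
#' @export
sam_config <- function(name, ...) {
  mixes <- sam_mixtures()
  if (!name %in% names(mixes))
    stop("sam_config: unknown design ", name)
  lib <- sam_clone_library()
  mix <- mixes[[name]]
  used <- mix$component[mix$component != "normal"]
  keep_clone <- lib$clones$name %in% c(used, lib$clones$parent[
    lib$clones$name %in% used])
  clones <- lib$clones[lib$clones$name %in%
                         unique(unlist(lapply(used, clone_lineage,
                                              clones = lib$clones))), ,
                       drop = FALSE]
  if (nrow(clones) == 0)
    clones <- lib$clones[0, , drop = FALSE]
  events <- lib$events[lib$events$clone %in% clones$name, , drop = FALSE]
  clone_tree_config(clones = clones, events = events, mixture = mix, ...)
}

#' Write / read a clone-tree config as YAML
#'
#' @param config A `clone_tree_config`.
#' @param path File path.
#' @return `path` (write) or the config (read).
#' @export
write_clone_config <- function(config, path) {
  stopifnot(inherits(config, "clone_tree_config"))
  obj <- list(clones = config$clones, events = config$events,
              mixture = config$mixture[, c("component", "coverage")],
              genome = as.list(config$genome),
              het_density = config$het_density, sd_r = config$sd_r,
              marker_spacing = config$marker_spacing,
              normal_depth = config$normal_depth)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_clone_config
#' @param path Path to a YAML config.
#' @export
read_clone_config <- function(path) {
  obj <- yaml::read_yaml(path)
  to_df <- function(x) as.data.frame(lapply(x, unlist),
                                     stringsAsFactors = FALSE)
  clones <- to_df(obj$clones)
  clones$parent <- as.character(clones$parent)
  clones$parent[clones$parent %in% c("NA", "")] <- NA_character_
  clone_tree_config(clones = clones,
                    events = to_df(obj$events),
                    mixture = to_df(obj$mixture),
                    genome = unlist(obj$genome),
                    het_density = obj$het_density, sd_r = obj$sd_r,
                    marker_spacing = obj$marker_spacing,
                    normal_depth = obj$normal_depth)
}
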