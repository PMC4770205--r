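# Three-step interpretation of the R-HDS plane:
#   (i)   fit tumor ploidy, adjust copy ratios (R = R' * Phi)
#   (ii)  detect purity and subclone prevalences from large segments
#   (iii) assign an ASCN state to every segment under the fixed prevalences

# Internal: lattice of branch points used for grid search.
# `(1, 1)` is collapsed to a single row at p = 1 (its coordinates do not
# depend on p).
branch_lattice <- function(max_total_copy = 10,
                           p_grid = seq(0.02, 1, by = 0.005)) {
  g <- ascn_genotypes(max_total_copy)
  balanced_ab <- g$x == 1 & g$y == 1
  lat <- merge(g[!balanced_ab, , drop = FALSE], data.frame(p = p_grid))
  lat <- rbind(lat, data.frame(x = 1, y = 1, p = 1))
  lat$r <- r_score(lat$x, lat$y, lat$p)
  lat$hds <- hds_branch(lat$x, lat$y, lat$p)
  lat$tot <- lat$x + lat$y
  lat <- lat[order(lat$tot, lat$y - lat$x, lat$p), , drop = FALSE]
  rownames(lat) <- NULL
  lat
}

# Internal: nearest lattice point per observation with the deterministic
# tie-break (smaller x + y, then larger p).  Returns indices + distances.
nearest_state <- function(r, h, lat, tie_eps = 1e-9, margin_frac = 0.1) {
  n <- length(r)
  idx <- integer(n)
  dist <- numeric(n)
  dist2_alt <- numeric(n)  # best distance on a different (x, y) branch
  near_p <- vector("list", n)  # prevalences of all near-tied branch points
  for (i in seq_len(n)) {
    d <- sqrt((lat$r - r[i])^2 + (lat$hds - h[i])^2)
    dmin <- min(d)
    cand <- which(d - dmin <= tie_eps)
    pick <- cand[order(lat$tot[cand], -lat$p[cand])][1]
    idx[i] <- pick
    dist[i] <- d[pick]
    other <- lat$x != lat$x[pick] | lat$y != lat$y[pick]
    dist2_alt[i] <- if (any(other)) min(d[other]) else Inf
    near_p[[i]] <- unique(lat$p[d <= dmin / (1 - margin_frac) + tie_eps])
  }
  list(idx = idx, dist = dist, dist_alt = dist2_alt, near_p = near_p)
}

# Internal: is a bubble consistent with normal disomy AB at (1, 0)?
# The folded-BAF median has a depth-dependent sampling floor even when the
# true HDS is zero, so the HDS test is relative to that floor.
disomy_consistent <- function(r_adj, hds_median, hds_floor = 0,
                              hds_tol = 0.02, r_tol = 0.08) {
  hds_median <= hds_floor + hds_tol & abs(r_adj - 1) <= r_tol
}

bubble_weights <- function(bubbles) {
  w <- bubbles$length_bp
  if (is.null(w)) w <- rep(1, nrow(bubbles))
  w[!is.finite(w) | w <= 0] <- 1
  w
}

# Internal: the segment HDS the engine fits against -- the debiased MLE
# when available (see homogenize), else the folded median -- together
# with the matching noise floor for the disomy test.  Values within the
# estimator's own sampling floor of zero are shrunk to exactly zero:
# near h = 0 the phase-symmetric mixture is only weakly identified
# (both estimators have a positive floor there), and leaving the floor
# in place lets low-prevalence branches absorb balanced segments at any
# scale.
bubble_hds <- function(bubbles, shrink = TRUE) {
  n <- nrow(bubbles)
  h <- bubbles$hds_median
  fl <- if (is.null(bubbles$hds_floor)) rep(0, n) else bubbles$hds_floor
  tol <- rep(0.02, n)
  if (!is.null(bubbles$hds_fit)) {
    use <- !is.na(bubbles$hds_fit)
    h[use] <- bubbles$hds_fit[use]
    fl[use] <- 0
    # the mixture MLE has an n^(-1/4)-rate sampling floor at h = 0
    # (the symmetric mixture is weakly identified there); the shrink
    # threshold tracks it per segment via the locus count and depth
    if (!is.null(bubbles$n_het) && !is.null(bubbles$depth_median)) {
      sigma <- sqrt(0.25 / pmax(bubbles$depth_median[use], 1))
      tol[use] <- pmax(0.02, 2.5 * sigma / pmax(bubbles$n_het[use], 1)^0.25)
    } else {
      tol[use] <- 0.03
    }
  }
  if (shrink) h[h <= fl + tol] <- 0
  list(h = h, floor = fl)
}

# Internal: profile the scale factor Phi over a grid against the raw
# observables.  For each Phi the lattice is mapped into raw space
# (r / Phi) so that measurement noise is weighted identically across
# candidate scales, each bubble takes its nearest branch point, and the
# candidate is summarized by its length-weighted mean distance plus the
# self-consistency quantities: the implied tumor ploidy tau_hat
# (weighted mean assigned total copy number over the clonal mass, AB
# counting as 2) and the top assigned prevalence.  A scale is valid only
# if Phi reproduces (tau_hat p + 2(1 - p)) / 2 -- otherwise it is a
# spurious re-interpretation at the wrong scale.
profile_phi <- function(bubbles, lat, phi_grid,
                        clonal_tol = 0.05, phi_tol = 0.1,
                        min_clonal_share = 0.1) {
  r <- bubbles$r_raw
  h <- bubble_hds(bubbles)$h
  w <- bubble_weights(bubbles)
  H2 <- outer(lat$hds, h, "-")^2           # Phi-independent part
  # infinitesimal tie-break toward smaller total copy and larger p, so
  # exactly coincident branch points (e.g. the ABB/ABBB family) resolve
  # as the deterministic nearest_state would
  tb <- 1e-7 * lat$tot + 1e-9 * (1 - lat$p)
  res <- vector("list", length(phi_grid))
  for (k in seq_along(phi_grid)) {
    phi <- phi_grid[k]
    D2 <- outer(lat$r / phi, r, "-")^2 + H2 + tb
    idx <- max.col(-t(D2), ties.method = "first")
    d <- sqrt(pmax(D2[cbind(idx, seq_along(r))] - tb[idx], 0))
    ax <- lat$x[idx]; ay <- lat$y[idx]; ap <- lat$p[idx]
    is_ab <- ax == 1 & ay == 1
    inf <- !is_ab
    if (!any(inf)) { res[[k]] <- NULL; next }
    p_top <- max(ap[inf])
    clonal <- is_ab | ap >= p_top - 2 * clonal_tol
    tau_hat <- sum(w[clonal] * (ax + ay)[clonal]) / sum(w[clonal])
    phi_implied <- (tau_hat * p_top + 2 * (1 - p_top)) / 2
    cl_mass <- sum(w[inf & abs(ap - p_top) <= clonal_tol]) / sum(w[inf])
    res[[k]] <- data.frame(
      phi = phi, score = sum(w * d) / sum(w), tau_hat = tau_hat,
      p_top = p_top, class = round(tau_hat),
      valid = abs(phi - phi_implied) <= phi_tol &
        cl_mass >= min_clonal_share)
  }
  do.call(rbind, res)
}

#' Fit tumor ploidy and adjust copy ratios
#'
#' Step (i) of the interpretation.  The multiplicative correction
#' `Phi = (tau_t p + 2(1 - p)) / 2` is profiled over a grid of scale
#' factors; at each scale the raw `(R', HDS)` cloud of the large
#' segments is matched to the branch lattice and scored by the
#' length-weighted mean distance.  A scale is admissible only when it is
#' self-consistent: the tumor ploidy implied by the resulting
#' assignments must reproduce the scale (this rejects spurious
#' re-interpretations at the wrong ploidy).  Admissible scales are
#' grouped by integer ploidy class (default 2, 3, 4) and the
#' best-scoring class wins.  Near-ties -- the diploid/tetraploid
#' degeneracy, where a doubled genome at purity `p` fits exactly as a
#' diploid at `p/(1+p)` -- are resolved by parsimony (fewer prevalence
#' clusters) and then, when `prefer_high_purity` is set, by the
#' higher-purity solution; the runner-up is kept as `alternative`.
#'
#' @param bubbles Bubble table from [homogenize()] (needs `r_raw`,
#'   `hds_median`, `length_bp`; `hds_floor` used when present).
#' @param candidate_ploidies Integer ploidy classes considered; default
#'   `c(2, 3, 4)`.  Monoploid and >= pentaploid fits are not searched by
#'   default.
#' @param prefer_high_purity On a tie, return the higher-purity
#'   (higher-ploidy) solution as primary.  Default `TRUE`.
#' @param large_threshold_bp Segments at least this long drive the fit
#'   (default 5 Mb).
#' @param max_total_copy Lattice bound on `x + y` (default 10).
#' @param phi_grid Scale factors profiled (default
#'   `seq(0.6, 2.6, by = 0.005)`).
#' @return An object of class `ploidy_fit`: list with `tau_t` (implied
#'   tumor ploidy, a real number near the winning class), `class`,
#'   `phi`, `purity` (prevalence-cluster estimate), `score`, `bubbles`
#'   (input with `r_adj = r_raw * phi` filled in), `alternative`
#'   (runner-up solution or `NULL`), `candidates` (per-class score
#'   table) and `warnings`.
#' @export
fit_ploidy <- function(bubbles, candidate_ploidies = c(2, 3, 4),
                       prefer_high_purity = TRUE,
                       large_threshold_bp = 5e6,
                       max_total_copy = 10,
                       phi_grid = seq(0.6, 2.6, by = 0.005)) {
  stopifnot(is.data.frame(bubbles), nrow(bubbles) >= 1,
            all(c("r_raw", "hds_median") %in% names(bubbles)))
  if (is.null(bubbles$hds_floor)) bubbles$hds_floor <- 0
  big <- bubbles[is.na(bubbles$length_bp) |
                   bubbles$length_bp >= large_threshold_bp, , drop = FALSE]
  if (nrow(big) == 0) big <- bubbles
  warnings <- character(0)
  bh <- bubble_hds(big)

  # no HDS/R signal at all: ploidy unidentifiable
  if (all(disomy_consistent(big$r_raw, bh$h, bh$floor))) {
    warnings <- c(warnings,
                  "no informative SCNA signal; ploidy unidentifiable, defaulting to diploid")
    bubbles$r_adj <- bubbles$r_raw
    return(structure(list(tau_t = 2, class = 2, phi = 1, purity = NA_real_,
                          score = 0, bubbles = bubbles, alternative = NULL,
                          candidates = data.frame(class = 2, phi = 1,
                                                  tau_t = 2, score = 0),
                          warnings = warnings),
                     class = "ploidy_fit"))
  }

  # scale-profile lattice: prevalences below 10% are indistinguishable
  # from noise at this step and would let any scale fit the balanced
  # mass
  lat <- branch_lattice(max_total_copy, p_grid = seq(0.1, 1, by = 0.01))
  prof <- profile_phi(big, lat, phi_grid)
  prof <- prof[prof$valid & prof$class %in% candidate_ploidies, , drop = FALSE]
  if (nrow(prof) == 0)
    stop("fit_ploidy: no candidate ploidy admits a self-consistent fit")
  # short-list scales per ploidy class by the free-lattice score (the
  # final comparison below re-scores them under the clonal constraint)
  prof <- prof[order(prof$class, prof$score), , drop = FALSE]
  shortlist <- list()
  for (cl in unique(prof$class)) {
    rows <- prof[prof$class == cl, , drop = FALSE]
    pick <- integer(0)
    for (i in seq_len(nrow(rows))) {
      if (length(pick) >= 6) break
      if (all(abs(rows$phi[i] - rows$phi[pick]) >= 0.02) || length(pick) == 0)
        pick <- c(pick, i)
    }
    shortlist[[as.character(cl)]] <- rows[pick, , drop = FALSE]
  }
  cand <- do.call(rbind, shortlist)

  # Re-score every class under the clonal constraint: detect shared
  # prevalences at the class's best scale and measure the residual of
  # the constrained assignment.  The unconstrained nearest-branch score
  # overfits at high ploidy (dense lattices give each balanced segment a
  # free prevalence), so classes are compared on the physically
  # meaningful fit, where all segments share the detected clone
  # structure.
  # weighted raw-space distance at one scale, for local refinement
  raw_score <- function(phi, l) {
    ns <- nearest_state(big$r_raw, bh$h, transform(l, r = r / phi))
    w <- bubble_weights(big)
    sum(w * ns$dist) / sum(w)
  }
  pick_summary <- function(row) {
    # refine the scale within its own grid cell (the 0.005 grid step
    # otherwise leaves a visible residual on near-exact data)
    row$phi <- stats::optimize(raw_score, c(row$phi - 0.005, row$phi + 0.005),
                               l = lat, tol = 1e-5)$minimum
    b <- bubbles
    b$r_adj <- b$r_raw * row$phi
    # parsimony: while classes compete, a class may only invoke states
    # up to two copies above its own baseline -- otherwise the dense
    # high-copy lattice can quantize pure measurement noise
    mtc <- min(max_total_copy, row$class + 2)
    prev <- tryCatch(
      detect_prevalences(b, large_threshold_bp = large_threshold_bp,
                         max_total_copy = mtc),
      error = function(e) numeric(0))
    constrained <- if (length(prev)) {
      big2 <- b[is.na(b$length_bp) | b$length_bp >= large_threshold_bp, ,
                drop = FALSE]
      cs <- assign_ascn(big2, prev, max_total_copy = mtc)
      # residual in raw-observable space, so that the same measurement
      # noise costs every ploidy class equally
      a <- cs$assignments
      w2 <- bubble_weights(big2)
      d <- sqrt(((a$r_adj - a$r_exp) / row$phi)^2 +
                  (bubble_hds(big2)$h - a$hds_exp)^2)
      sum(w2 * d) / sum(w2)
    } else Inf
    list(tau_t = row$tau_hat, class = row$class, phi = row$phi,
         score = constrained, score_free = row$score,
         purity = if (length(prev)) prev[1] else NA_real_,
         prevalences = prev, k = length(prev))
  }
  sols_try <- lapply(seq_len(nrow(cand)), function(i) pick_summary(cand[i, ]))
  sc_try <- vapply(sols_try, `[[`, 0, "score")
  if (all(!is.finite(sc_try)))
    stop("fit_ploidy: no candidate ploidy admits a consistent fit")
  # best constrained fit per class
  cls_try <- vapply(sols_try, `[[`, 0, "class")
  ord <- order(cls_try, sc_try)
  keep_best <- ord[!duplicated(cls_try[ord])]
  sols_all <- sols_try[keep_best]
  sc <- vapply(sols_all, `[[`, 0, "score")
  sols_all <- sols_all[order(sc)]
  sc <- sort(sc)

  # Near-ties between ploidy classes are genuine degeneracies of the
  # observables.  A doubled genome at purity p matches a diploid one at
  # p' = p/(1+p); when a tied pair satisfies that relation the
  # high-purity preference picks the polyploid reading (the runner-up is
  # kept as `alternative`).  Any other tie resolves to the lowest class:
  # without the twin signature the parsimonious karyotype is preferred.
  # a residual difference below ~25% of the residual itself is within
  # the sampling error of the weighted mean over this many segments
  tie_tol <- max(0.25 * sc[1], 5e-4)
  sols <- sols_all[is.finite(sc) & sc - sc[1] <= tie_tol]
  primary <- NULL
  alternative <- NULL
  if (length(sols) > 1) {
    cls <- vapply(sols, `[[`, 0, "class")
    pur <- vapply(sols, function(s) ifelse(is.na(s$purity), -1, s$purity), 0)
    if (prefer_high_purity) {
      pairs <- expand.grid(a = seq_along(sols), b = seq_along(sols))
      pairs <- pairs[cls[pairs$b] > cls[pairs$a] &
                       pur[pairs$a] > 0 & pur[pairs$b] > 0, , drop = FALSE]
      twin <- abs(pur[pairs$a] - pur[pairs$b] / (1 + pur[pairs$b])) <= 0.05
      if (any(twin)) {
        hit <- pairs[twin, , drop = FALSE][1, ]
        primary <- sols[[hit$b]]
        alternative <- sols[[hit$a]]
        warnings <- c(warnings, sprintf(
          paste0("ploidy degeneracy: class %g at purity %.3f and class %g at ",
                 "purity %.3f fit equally well; high-purity solution chosen"),
          cls[hit$a], pur[hit$a], cls[hit$b], pur[hit$b]))
      }
    }
    if (is.null(primary)) {
      ord <- order(cls)
      primary <- sols[[ord[1]]]
      alternative <- sols[[ord[2]]]
      if (cls[ord[1]] != cls[ord[2]])
        warnings <- c(warnings, sprintf(
          "ploidy classes %g and %g fit comparably; the lower class is primary",
          cls[ord[1]], cls[ord[2]]))
    }
  } else {
    primary <- sols[[1]]
    # report the best other-class reading when it is at least plausible
    cls_all <- vapply(sols_all, `[[`, 0, "class")
    others <- which(cls_all != primary$class &
                      sc <= max(3 * sc[1], sc[1] + 0.01))
    if (length(others) > 0)
      alternative <- sols_all[[others[1]]]
  }
  if (!is.null(alternative)) {
    alternative <- list(tau_t = alternative$tau_t, class = alternative$class,
                        phi = alternative$phi, purity = alternative$purity,
                        subclone_prevalences = alternative$prevalences,
                        score = alternative$score)
  }

  bubbles$r_adj <- bubbles$r_raw * primary$phi
  structure(list(tau_t = primary$tau_t, class = primary$class,
                 phi = primary$phi, purity = primary$purity,
                 score = primary$score, bubbles = bubbles,
                 alternative = alternative, candidates = cand,
                 warnings = warnings),
            class = "ploidy_fit")
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat(sprintf("ploidy fit: tau_t = %.3g (class %g, Phi = %.4g), score = %.4g\n",
              x$tau_t, x$class, x$phi, x$score))
  if (!is.null(x$alternative))
    cat(sprintf("  alternative: tau_t = %g, purity = %.3g\n",
                x$alternative$tau_t, x$alternative$purity))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Detect tumor purity and subclone prevalences
#'
#' Step (ii).  Every large, ploidy-adjusted segment that is not
#' disomy-consistent is matched to its nearest branch point `(x, y, p)`
#' with `p` on a fine grid; the matched prevalences are clustered by
#' average-linkage hierarchical clustering cut at `cluster_cutoff`, and
#' the cluster medians are returned in descending order.  The largest is
#' the purity (prevalence of the dominant clone).  Segments whose two
#' nearest branches are nearly equidistant (ambiguous) are left out of
#' the clustering when unambiguous ones exist.
#'
#' @param bubbles Adjusted bubbles (column `r_adj` filled, e.g. by
#'   [fit_ploidy()]).
#' @param large_threshold_bp Minimum segment length considered (default
#'   5 Mb).
#' @param p_grid_step Prevalence grid step for the branch search (default
#'   0.005; the grid spans `[min_prevalence, 1]`).
#' @param cluster_cutoff Cut height of the prevalence clustering; also
#'   the minimum separation between reported prevalences (default 0.2).
#' @param max_total_copy Lattice bound on `x + y`.
#' @param ambiguity_frac Two branches within this relative distance of
#'   each other make a segment ambiguous (default 0.1).
#' @param min_prevalence Matched prevalences below this carry no usable
#'   signal (they are within measurement noise of normal disomy) and are
#'   dropped before clustering (default 0.1).
#' @return Numeric vector of prevalences, descending; first element is
#'   the purity.
#' @export
detect_prevalences <- function(bubbles, large_threshold_bp = 5e6,
                               p_grid_step = 0.005, cluster_cutoff = 0.2,
                               max_total_copy = 10, ambiguity_frac = 0.1,
                               min_prevalence = 0.1) {
  stopifnot(is.data.frame(bubbles), "r_adj" %in% names(bubbles))
  big <- bubbles[is.na(bubbles$length_bp) |
                   bubbles$length_bp >= large_threshold_bp, , drop = FALSE]
  bh <- bubble_hds(big)
  informative <- !disomy_consistent(big$r_adj, bh$h, bh$floor)
  big <- big[informative, , drop = FALSE]
  h <- bh$h[informative]
  if (nrow(big) == 0)
    stop("no informative SCNA: purity is unidentifiable from these segments")
  # below min_prevalence every branch crowds into the normal point and
  # matches are meaningless, so that region is excluded from the search
  lat <- branch_lattice(max_total_copy,
                        p_grid = seq(max(0.02, min_prevalence), 1,
                                     by = p_grid_step))
  ns <- nearest_state(big$r_adj, h, lat)
  ax <- lat$x[ns$idx]; ay <- lat$y[ns$idx]; ap <- lat$p[ns$idx]
  keep <- !(ax == 1 & ay == 1) & ap >= min_prevalence
  if (!any(keep))
    stop("no informative SCNA: purity is unidentifiable from these segments")
  # segments whose two nearest branches are nearly equidistant (the
  # ambiguous region where e.g. the ABB and ABBB branches cross) carry
  # weak prevalence evidence: they may not contradict unambiguous
  # segments, but they may seed a cluster where they are the only
  # evidence
  amb <- ns$dist > (1 - ambiguity_frac) * ns$dist_alt
  # balanced states carry no usable prevalence of their own: the whole
  # (k, k, p) branch family is mutually coincident ((2,2,p) equals
  # (3,3,p/2) in both scores), so such segments corroborate but never
  # seed a prevalence
  bal <- ax == ay & !(ax == 1 & ay == 1)
  use <- keep & !amb & !bal
  if (!any(use)) use <- keep & !amb
  if (!any(use)) use <- keep
  pv <- ap[use]
  weak_idx <- which(keep & !use)
  if (any(use) && length(weak_idx) > 0) {
    # a weak (ambiguous or balanced) segment is absorbed when ANY of its
    # near-tied interpretations lands near existing evidence; it only
    # seeds a new cluster when every interpretation is isolated
    for (i in weak_idx) {
      cand_p <- ns$near_p[[i]]
      if (bal[i] && ax[i] >= 2) {
        # analytic coincidence family of balanced states:
        # (k, k, p) sits where (k', k', p (k-1)/(k'-1)) sits
        ks <- 2:max(2, floor(max_total_copy / 2))
        fam <- ap[i] * (ax[i] - 1) / (ks - 1)
        cand_p <- unique(c(cand_p, fam[fam <= 1]))
      }
      if (!any(outer(cand_p, pv, function(a, b) abs(a - b) < cluster_cutoff)))
        pv <- c(pv, ap[i])
    }
  }
  if (length(pv) == 1) return(pv)
  cl <- stats::cutree(stats::hclust(stats::dist(pv), method = "average"),
                      h = cluster_cutoff)
  med <- tapply(pv, cl, stats::median)
  groups <- split(pv, cl)
  # enforce the minimum separation on the cluster medians
  repeat {
    med <- vapply(groups, stats::median, 0)
    o <- order(med)
    if (length(med) < 2) break
    gaps <- diff(med[o])
    if (all(gaps >= cluster_cutoff)) break
    j <- which.min(gaps)
    groups[[o[j]]] <- c(groups[[o[j]]], groups[[o[j + 1]]])
    groups[[o[j + 1]]] <- NULL
  }
  sort(unname(vapply(groups, stats::median, 0)), decreasing = TRUE)
}

#' Assign an ASCN state to every segment
#'
#' Step (iii).  With the prevalence set fixed, each adjusted segment gets
#' the `(x, y, p)` branch point minimizing the Euclidean distance in
#' `(R, HDS)`, with `p` restricted to the detected prevalences plus the
#' normal disomy state AB.  Ties break toward the smaller total copy
#' number, then the larger prevalence.
#'
#' @param bubbles Adjusted bubbles (column `r_adj`).
#' @param prevalences Non-empty prevalence set from
#'   [detect_prevalences()], descending.
#' @param max_total_copy Lattice bound on `x + y`.
#' @return A `clone_callset`: list with `tau_t`/`phi` (`NA` here; filled
#'   by [call_clones()]), `purity`, `subclone_prevalences`, `assignments`
#'   (per-segment rows with `x`, `y`, `p`, `genotype`, expected `r_exp`,
#'   `hds_exp`, `baf_exp_lo`, `baf_exp_hi`, and the distance `dist`),
#'   `fit_residual` (length-weighted mean distance) and `warnings`.
#' @export
assign_ascn <- function(bubbles, prevalences, max_total_copy = 10) {
  stopifnot(length(prevalences) >= 1, all(prevalences > 0),
            all(prevalences <= 1))
  prevalences <- sort(unique(prevalences), decreasing = TRUE)
  lat <- branch_lattice(max_total_copy, p_grid = prevalences)
  ns <- nearest_state(bubbles$r_adj, bubble_hds(bubbles)$h, lat)
  a <- bubbles
  a$x <- lat$x[ns$idx]
  a$y <- lat$y[ns$idx]
  a$p <- lat$p[ns$idx]
  a$genotype <- genotype_label(a$x, a$y, ascii = TRUE)
  a$r_exp <- lat$r[ns$idx]
  a$hds_exp <- lat$hds[ns$idx]
  # expected BAF pair (B-allele fraction and its mirror); the homozygous
  # deletion is evaluated just short of p = 1 where BAF is undefined
  bexp <- baf(a$x, a$y, ifelse(a$x == 0 & a$y == 0, pmin(a$p, 1 - 1e-9), a$p))
  a$baf_exp_hi <- bexp
  a$baf_exp_lo <- 1 - bexp
  a$dist <- ns$dist
  w <- bubble_weights(bubbles)
  structure(list(tau_t = NA_real_, phi = NA_real_,
                 purity = prevalences[1],
                 subclone_prevalences = prevalences,
                 assignments = a,
                 fit_residual = sum(w * ns$dist) / sum(w),
                 alternative = NULL,
                 warnings = character(0)),
            class = "clone_callset")
}

#' @export
print.clone_callset <- function(x, ...) {
  cat("clone callset\n")
  cat(sprintf("  tumor ploidy tau_t: %s (Phi = %s)\n",
              format(x$tau_t), format(x$phi)))
  cat(sprintf("  purity: %.3f\n", x$purity))
  cat(sprintf("  prevalences: %s\n",
              paste(sprintf("%.3f", x$subclone_prevalences), collapse = ", ")))
  cat(sprintf("  segments assigned: %d (residual %.4g)\n",
              nrow(x$assignments), x$fit_residual))
  if (!is.null(x$alternative))
    cat(sprintf("  alternative solution: tau_t = %g, purity = %.3f\n",
                x$alternative$tau_t, x$alternative$purity))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Run the full three-step caller
#'
#' Convenience wrapper: [fit_ploidy()], one purity refinement of `Phi`,
#' [detect_prevalences()], [assign_ascn()].
#'
#' @inheritParams fit_ploidy
#' @inheritParams detect_prevalences
#' @return A `clone_callset` with `tau_t`, `phi` and `alternative` filled.
#' @export
call_clones <- function(bubbles, candidate_ploidies = c(2, 3, 4),
                        prefer_high_purity = TRUE,
                        large_threshold_bp = 5e6, p_grid_step = 0.005,
                        cluster_cutoff = 0.2, max_total_copy = 10) {
  pf <- fit_ploidy(bubbles, candidate_ploidies = candidate_ploidies,
                   prefer_high_purity = prefer_high_purity,
                   large_threshold_bp = large_threshold_bp,
                   max_total_copy = max_total_copy)
  b <- pf$bubbles
  prev <- detect_prevalences(b, large_threshold_bp = large_threshold_bp,
                             p_grid_step = p_grid_step,
                             cluster_cutoff = cluster_cutoff,
                             max_total_copy = max_total_copy)
  cs <- assign_ascn(b, prev, max_total_copy = max_total_copy)
  cs$tau_t <- pf$tau_t
  cs$phi <- pf$phi
  cs$alternative <- pf$alternative
  cs$warnings <- c(pf$warnings, cs$warnings)
  cs
}

#' Exhaustive per-segment fit (test oracle)
#'
#' Scores every `(x, y, p)` on a dense lattice for every segment and
#' keeps the global minimum of the total weighted residual.  Because the
#' per-segment terms are independent, the global optimum is the
#' per-segment nearest lattice point; this routine exists as an
#' independent check of the three-step heuristic on small instances and
#' refuses large ones.
#'
#' @param bubbles Adjusted bubbles (column `r_adj`), at most `max_bubbles`
#'   rows.
#' @param max_total_copy Lattice bound on `x + y`.
#' @param p_grid Prevalence grid (default `seq(0.005, 1, 0.005)`).
#' @param max_bubbles Combinatorial guard (default 12).
#' @return A `clone_callset` (with `subclone_prevalences` the distinct
#'   assigned non-AB prevalences).
#' @export
brute_force_fit <- function(bubbles, max_total_copy = 10,
                            p_grid = seq(0.005, 1, by = 0.005),
                            max_bubbles = 12) {
  if (nrow(bubbles) > max_bubbles)
    stop(sprintf("brute_force_fit: refusing %d segments (> %d); this is a test oracle",
                 nrow(bubbles), max_bubbles))
  lat <- branch_lattice(max_total_copy, p_grid = p_grid)
  ns <- nearest_state(bubbles$r_adj, bubble_hds(bubbles)$h, lat)
  a <- bubbles
  a$x <- lat$x[ns$idx]; a$y <- lat$y[ns$idx]; a$p <- lat$p[ns$idx]
  a$genotype <- genotype_label(a$x, a$y, ascii = TRUE)
  a$r_exp <- lat$r[ns$idx]; a$hds_exp <- lat$hds[ns$idx]
  a$dist <- ns$dist
  w <- bubble_weights(bubbles)
  keep <- !(a$x == 1 & a$y == 1)
  prev <- sort(unique(a$p[keep]), decreasing = TRUE)
  structure(list(tau_t = NA_real_, phi = NA_real_,
                 purity = if (length(prev)) prev[1] else NA_real_,
                 subclone_prevalences = prev, assignments = a,
                 fit_residual = sum(w * ns$dist) / sum(w),
                 alternative = NULL, warnings = character(0)),
            class = "clone_callset")
}

#' Three-track report of a fitted callset
#'
#' Per-segment, genome-ordered rows combining the allele-specific copy
#' number call, the expected BAF pair on top of the observed medians, and
#' the expected R on top of the adjusted ratio -- the flat-file analogue
#' of the usual three-track figure.
#'
#' @param callset A `clone_callset` with assignments.
#' @param loci Optional het-locus table; when given, per-locus expected
#'   BAFs are attached as attribute `"loci"`.
#' @return data.frame of per-segment rows.
#' @export
report_tracks <- function(callset, loci = NULL) {
  stopifnot(inherits(callset, "clone_callset"))
  a <- callset$assignments
  ord <- order(chrom_rank(a$chrom), a$start)
  cols <- intersect(c("chrom", "start", "end", "length_bp", "n_het",
                      "x", "y", "p", "genotype", "r_adj", "hds_median",
                      "r_exp", "hds_exp", "baf_exp_lo", "baf_exp_hi",
                      "dist"), names(a))
  out <- a[ord, cols, drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(loci)) {
    idx <- match_loci_segments(loci, out)
    l <- loci
    l$baf_exp_hi <- out$baf_exp_hi[idx]
    l$baf_exp_lo <- out$baf_exp_lo[idx]
    attr(out, "loci") <- l
  }
  out
}
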