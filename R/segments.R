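#' Fold a B-allele frequency onto the deviation scale
#'
#' The heterozygous-deviation score of a locus is phase-agnostic:
#' `|BAF - 0.5|`, so mirrored allele fractions (0.2 and 0.8) fold to the
#' same value.
#'
#' @param baf_obs Observed allele fraction(s) in `[0, 1]`.
#' @return Folded value(s) in `[0, 0.5]`.
#' @export
fold_baf <- function(baf_obs) {
  if (any(baf_obs < 0 | baf_obs > 1, na.rm = TRUE))
    stop("fold_baf: allele fractions must lie in [0, 1]")
  abs(baf_obs - 0.5)
}

#' Select germline heterozygous loci with usable tumor allele depths
#'
#' Keeps loci whose normal-sample allele fraction marks a heterozygote and
#' whose tumor depth is sufficient for a stable allele-fraction estimate.
#' Records lacking allele-depth information are skipped (counted, not
#' fatal).
#'
#' @param variants data.frame with columns `chrom`, `pos`, `tumor_ref`,
#'   `tumor_alt` and either `normal_ref`/`normal_alt` or a logical
#'   `normal_het`.  [read_het_vcf()] and [read_het_tsv()] produce this
#'   layout.
#' @param min_depth Minimum tumor depth (`ref + alt`), default 15.
#' @param baf_window Normal-sample allele-fraction window declaring a
#'   heterozygote, default `c(0.4, 0.6)`.
#' @param min_normal_depth Minimum normal depth for the window call,
#'   default 10.
#' @return data.frame of class `het_loci`: `chrom`, `pos`, `ref_count`,
#'   `alt_count`, `baf_obs`, with attribute `n_skipped` (records dropped
#'   for missing allele depths).
#' @export
select_het_loci <- function(variants, min_depth = 15,
                            baf_window = c(0.4, 0.6),
                            min_normal_depth = 10) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "tumor_ref", "tumor_alt") %in% names(variants)))
  v <- variants
  incomplete <- !is.finite(v$tumor_ref) | !is.finite(v$tumor_alt)
  if ("normal_het" %in% names(v)) {
    het <- v$normal_het %in% TRUE
  } else {
    stopifnot(all(c("normal_ref", "normal_alt") %in% names(v)))
    incomplete <- incomplete | !is.finite(v$normal_ref) | !is.finite(v$normal_alt)
    ndp <- v$normal_ref + v$normal_alt
    nbaf <- ifelse(ndp > 0, v$normal_alt / ndp, NA_real_)
    het <- !is.na(nbaf) & ndp >= min_normal_depth &
      nbaf >= baf_window[1] & nbaf <= baf_window[2]
  }
  n_skipped <- sum(incomplete)
  if (n_skipped > 0)
    message(sprintf("select_het_loci: skipped %d record(s) without allele depths",
                    n_skipped))
  keep <- !incomplete & het & (v$tumor_ref + v$tumor_alt) >= min_depth
  out <- data.frame(chrom = as.character(v$chrom[keep]),
                    pos = v$pos[keep],
                    ref_count = v$tumor_ref[keep],
                    alt_count = v$tumor_alt[keep])
  out$baf_obs <- out$alt_count / (out$ref_count + out$alt_count)
  out <- out[order(chrom_rank(out$chrom), out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("het_loci", "data.frame")
  out
}

# Internal: locate loci inside segments (both 1-based inclusive).
# Returns an integer index into `segments` per locus (NA = outside).
match_loci_segments <- function(loci, segments) {
  idx <- rep(NA_integer_, nrow(loci))
  for (ch in unique(segments$chrom)) {
    s <- which(segments$chrom == ch)
    l <- which(loci$chrom == ch)
    if (length(l) == 0) next
    o <- s[order(segments$start[s])]
    j <- findInterval(loci$pos[l], segments$start[o])
    ok <- j >= 1
    ok[ok] <- loci$pos[l][ok] <= segments$end[o][j[ok]]
    idx[l[ok]] <- o[j[ok]]
  }
  idx
}

#' Homogenize raw segments into bubbles
#'
#' Attaches the tumor BAFs of the germline heterozygous loci to each raw
#' copy-ratio segment, summarizes each segment by its median folded BAF
#' (the segment HDS) and the dispersion of the per-locus values, and
#' discards segments that are not homogeneous: locus-HDS standard
#' deviation above `sd_cutoff`, or too few informative loci.
#'
#' @param segments data.frame of raw segments: `chrom`, `start`, `end`
#'   (1-based inclusive), `r_raw` (linear-scale tumor/normal ratio) and
#'   optionally `n_markers`.  Segments must not overlap within a
#'   chromosome.
#' @param loci Heterozygous loci as from [select_het_loci()].
#' @param sd_cutoff Homogeneity filter: segments whose per-locus HDS
#'   standard deviation exceeds this are excluded (default 0.2).
#' @param min_het Minimum contributing loci per segment (default 10).
#' @return List with `bubbles` (surviving segments: `chrom`, `start`,
#'   `end`, `length_bp`, `n_markers`, `n_het`, `r_raw`, `hds_median`,
#'   `hds_sd`, `hds_floor`, `hds_fit`, `depth_median`, `r_adj` (NA until
#'   ploidy adjustment)) and `excluded` (dropped segments with a
#'   `reason` code: `"hds_sd"` or `"too_few_het"`).
#'
#' @details Two segment-level HDS summaries are produced.  `hds_median`
#'   is the median of the per-locus folded BAFs -- the conventional
#'   score, but biased upward near zero because the folded median of
#'   binomial noise has a sampling floor of about
#'   `0.674 * sqrt(0.25 / depth)`.  `hds_fit` is the maximum-likelihood
#'   deviation under a symmetric binomial mixture (each locus draws its
#'   alt count from `Binom(depth, 0.5 + h)` or `Binom(depth, 0.5 - h)`
#'   with equal probability, reflecting unknown phase), which is
#'   essentially unbiased and is what the caller consumes.
#' @export
homogenize <- function(segments, loci, sd_cutoff = 0.2, min_het = 10) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end", "r_raw") %in% names(segments)))
  segments <- as.data.frame(segments)
  segments$chrom <- as.character(segments$chrom)
  if (any(segments$start > segments$end))
    stop("homogenize: segment start exceeds end")
  if (any(segments$r_raw < 0))
    stop("homogenize: negative copy ratio")
  # overlap check per chromosome
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1) {
      bad <- which(s$start[-1] <= s$end[-nrow(s)])
      if (length(bad) > 0)
        stop(sprintf(
          "homogenize: overlapping segments on %s: [%d, %d] and [%d, %d]",
          ch, s$start[bad[1]], s$end[bad[1]],
          s$start[bad[1] + 1], s$end[bad[1] + 1]))
    }
  }
  idx <- match_loci_segments(loci, segments)
  hdsv <- fold_baf(loci$baf_obs)
  depth <- loci$ref_count + loci$alt_count

  # phase-agnostic MLE of the allele-fraction deviation of one segment;
  # a coarse scan brackets the optimum first (at high depth the
  # likelihood is too sharply peaked for a blind golden-section search)
  hds_mle <- function(k, n) {
    nll <- function(h) {
      -sum(log(0.5 * stats::dbinom(k, n, 0.5 + h) +
                 0.5 * stats::dbinom(k, n, 0.5 - h) + 1e-300))
    }
    grid <- seq(0, 0.4999, by = 0.005)
    v <- vapply(grid, nll, 0)
    h0 <- grid[which.min(v)]
    stats::optimize(nll, c(max(0, h0 - 0.005),
                           min(0.5 - 1e-6, h0 + 0.005)))$minimum
  }

  n <- nrow(segments)
  out <- data.frame(chrom = segments$chrom,
                    start = segments$start, end = segments$end,
                    length_bp = segments$end - segments$start + 1,
                    n_markers = if ("n_markers" %in% names(segments))
                      segments$n_markers else NA_integer_,
                    n_het = 0L, r_raw = segments$r_raw,
                    hds_median = NA_real_, hds_sd = NA_real_,
                    hds_floor = 0, hds_fit = NA_real_,
                    depth_median = NA_real_, r_adj = NA_real_)
  for (i in seq_len(n)) {
    sel <- which(idx == i)
    out$n_het[i] <- length(sel)
    if (length(sel) > 0) {
      out$hds_median[i] <- stats::median(hdsv[sel])
      out$hds_sd[i] <- if (length(sel) > 1) stats::sd(hdsv[sel]) else 0
      out$depth_median[i] <- stats::median(depth[sel])
      # sampling floor of the folded-BAF median under a balanced binomial:
      # median |Binom(d, .5)/d - .5| ~ 0.674 * sqrt(0.25 / d)
      out$hds_floor[i] <- 0.674 * sqrt(0.25 / max(out$depth_median[i], 1))
      out$hds_fit[i] <- hds_mle(loci$alt_count[sel], depth[sel])
    }
  }
  drop_few <- out$n_het < min_het
  drop_sd <- !drop_few & !is.na(out$hds_sd) & out$hds_sd > sd_cutoff
  reason <- rep(NA_character_, n)
  reason[drop_few] <- "too_few_het"
  reason[drop_sd] <- "hds_sd"
  keep <- is.na(reason)
  bubbles <- out[keep, , drop = FALSE]
  excluded <- cbind(out[!keep, , drop = FALSE], reason = reason[!keep])
  ord <- order(chrom_rank(bubbles$chrom), bubbles$start)
  bubbles <- bubbles[ord, , drop = FALSE]
  rownames(bubbles) <- NULL
  rownames(excluded) <- NULL
  list(bubbles = bubbles, excluded = excluded)
}
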