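# Chronology of somatic point mutations relative to copy-number events.
#
# A somatic variant present on `m` copies in a fraction `p_m` of cells
# inside a segment fitted as (x, y, p) has expected allele frequency
#   VAF = m * p_m / ((x + y) p + 2 (1 - p)),
# the mutant-copy count over the total copy number of the cell mixture.
# The four canonical scenarios are instantiations of (m, p_m): a mutation
# on allele B before the SCNA rides the amplification (m = y), one on
# allele A likewise (m = x), one after the SCNA sits on a single copy
# (m = 1), and one unique to a subclone has p_m equal to that subclone's
# prevalence.

#' Expected somatic variant allele frequency
#'
#' @param x,y Allele copy numbers of the host segment's fitted state.
#' @param p Prevalence of the host segment's state.
#' @param multiplicity Copies carrying the mutation (`m >= 1`, at most
#'   `max(x, y)`).
#' @param carrier_prevalence Fraction of all cells carrying the mutation
#'   (`p_m <= p`).
#' @return Expected VAF in `[0, 1]`.
#' @examples
#' expected_vaf(1, 1, 1, multiplicity = 1, carrier_prevalence = 1)  # 0.5
#' @export
expected_vaf <- function(x, y, p, multiplicity, carrier_prevalence) {
  st <- ascn_state(x, y, p)
  n <- nrow(st)
  m <- rep_len(multiplicity, n)
  pm <- rep_len(carrier_prevalence, n)
  if (any(m < 1) || any(m != round(m)))
    stop("expected_vaf: multiplicity must be a positive integer")
  if (any(m > pmax(st$x, st$y)))
    stop("expected_vaf: multiplicity exceeds the allele copy number")
  if (any(pm < 0) || any(pm > st$p + 1e-12))
    stop("expected_vaf: carrier prevalence must lie in [0, p]")
  den <- (st$x + st$y) * st$p + 2 * (1 - st$p)
  if (any(den <= 0))
    stop("expected_vaf: no DNA present (homozygous deletion at p = 1)")
  m * pm / den
}

#' Expected-VAF bands for the four chronology scenarios
#'
#' Instantiates every scenario compatible with a fitted segment state and
#' the detected subclone prevalences.  Scenarios with zero mutant copies
#' (e.g. the lost allele of an LOH segment) are dropped, and bands with
#' identical expected VAF are collapsed (keeping the earliest scenario in
#' the order B-pre, A-pre, post-SCNA, subclone) -- on a disomic segment
#' all clonal scenarios collapse to `p / 2`.
#'
#' @param x,y,p Fitted segment state (scalars).
#' @param subclone_prevalences Prevalences of subclones nested below `p`
#'   (values `>= p` are ignored: the dominant clone has no sub-structure
#'   at its own segment).
#' @return data.frame with `label`, `multiplicity`, `carrier_prevalence`,
#'   `vaf_expected`, sorted by decreasing `vaf_expected`.
#' @export
scenario_bands <- function(x, y, p, subclone_prevalences = numeric(0)) {
  stopifnot(length(x) == 1, length(y) == 1, length(p) == 1)
  ascn_state(x, y, p)
  subs <- subclone_prevalences[subclone_prevalences < p - 1e-9]
  rows <- list()
  add <- function(label, m, pm) {
    if (m >= 1 && m <= max(x, y))
      rows[[length(rows) + 1]] <<- data.frame(
        label = label, multiplicity = m, carrier_prevalence = pm,
        vaf_expected = expected_vaf(x, y, p, m, pm))
  }
  add("B_pre_clonal", y, p)
  add("A_pre_clonal", x, p)
  add("post_scna_single", 1, p)
  for (p1 in subs) {
    add("subclone_B", y, p1)
    add("subclone_B", 1, p1)
  }
  if (length(rows) == 0)
    return(data.frame(label = character(0), multiplicity = numeric(0),
                      carrier_prevalence = numeric(0),
                      vaf_expected = numeric(0)))
  out <- do.call(rbind, rows)
  pri <- match(out$label, c("B_pre_clonal", "A_pre_clonal",
                            "post_scna_single", "subclone_B"))
  out <- out[order(round(out$vaf_expected, 12), pri), , drop = FALSE]
  out <- out[!duplicated(round(out$vaf_expected, 12)), , drop = FALSE]
  out <- out[order(-out$vaf_expected), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify somatic variants into chronology strata
#'
#' Each variant is matched to the nearest expected-VAF band of its host
#' segment.  A match requires the observed VAF to lie within a fixed
#' margin plus the binomial 95% interval implied by the variant's depth;
#' otherwise the variant is `"unexplained"`.  Variants outside every
#' fitted segment are `"unassigned"`.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref_count`,
#'   `alt_count` (see [read_somatic_tsv()]).
#' @param callset A fitted `clone_callset`.
#' @param tolerance Fixed VAF margin added to the binomial interval
#'   (default 0.05).
#' @return The variants with columns `vaf_obs`, `segment_id`, `label`,
#'   `vaf_expected`, `multiplicity`, `carrier_prevalence`, `residual`.
#' @export
classify_variants <- function(variants, callset, tolerance = 0.05) {
  stopifnot(inherits(callset, "clone_callset"))
  v <- variants
  v$chrom <- normalize_chrom(v$chrom)
  dp <- v$ref_count + v$alt_count
  if (any(dp <= 0)) stop("classify_variants: zero-depth variant")
  v$vaf_obs <- v$alt_count / dp
  a <- callset$assignments
  subs <- callset$subclone_prevalences
  v$segment_id <- match_loci_segments(v, a)
  v$label <- "unassigned"
  v$vaf_expected <- NA_real_
  v$multiplicity <- NA_real_
  v$carrier_prevalence <- NA_real_
  v$residual <- NA_real_
  for (i in which(!is.na(v$segment_id))) {
    s <- a[v$segment_id[i], ]
    # a disomic segment's branch position is prevalence-free (its
    # lattice p is a placeholder), but its mutations are carried by the
    # tumor: the clonal prevalence there is the purity
    if (s$x == 1 && s$y == 1 && !is.na(callset$purity)) s$p <- callset$purity
    if (s$x == 0 && s$y == 0 && s$p >= 1) { v$label[i] <- "unexplained"; next }
    bands <- scenario_bands(s$x, s$y, s$p, subs)
    if (nrow(bands) == 0) { v$label[i] <- "unexplained"; next }
    res <- abs(bands$vaf_expected - v$vaf_obs[i])
    j <- which.min(res)
    half <- 1.96 * sqrt(v$vaf_obs[i] * (1 - v$vaf_obs[i]) / dp[i])
    v$residual[i] <- res[j]
    if (res[j] <= tolerance + half) {
      v$label[i] <- bands$label[j]
      v$vaf_expected[i] <- bands$vaf_expected[j]
      v$multiplicity[i] <- bands$multiplicity[j]
      v$carrier_prevalence[i] <- bands$carrier_prevalence[j]
    } else {
      v$label[i] <- "unexplained"
    }
  }
  v
}
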