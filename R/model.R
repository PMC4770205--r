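#' Validate allele-specific copy-number states
#'
#' An allele-specific copy-number (ASCN) state is the triple `(x, y, p)`:
#' integer copy numbers of the two parental alleles at a segment, with the
#' convention `x <= y` (allele B is the one with at least as many copies),
#' and the prevalence `p` -- the fraction of *all* cells in the biopsy
#' (tumor plus contaminating normal) that carry the state.  The background
#' against which a state is mixed is always the diploid heterozygous normal
#' genotype AB.
#'
#' @param x,y Integer allele copy numbers, `0 <= x <= y`. Recycled.
#' @param p Prevalence in `[0, 1]`. Recycled.
#' @return Invisibly, a data.frame with columns `x`, `y`, `p`.
#' @examples
#' ascn_state(0, 1, 0.75)
#' @export
ascn_state <- function(x, y, p) {
  n <- max(length(x), length(y), length(p))
  x <- rep_len(x, n); y <- rep_len(y, n); p <- rep_len(p, n)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(p)))
    stop("ascn_state: x, y and p must be finite")
  if (any(x < 0) || any(y < 0) || any(x != round(x)) || any(y != round(y)))
    stop("ascn_state: x and y must be non-negative integers")
  if (any(x > y))
    stop("ascn_state: the copy number of allele A may not exceed that of B (x <= y)")
  if (any(p < 0) || any(p > 1))
    stop("ascn_state: prevalence p must lie in [0, 1]")
  invisible(data.frame(x = x, y = y, p = p))
}

#' Genotype label of an ASCN state
#'
#' `x` letters `A` followed by `y` letters `B`; the null genotype
#' (homozygous deletion, `x = y = 0`) is rendered as `"Ø"` by default
#' or `"0"` when an ASCII-safe label is requested (machine-readable output).
#'
#' @inheritParams ascn_state
#' @param ascii Use `"0"` instead of the empty-set glyph for `x = y = 0`.
#' @return Character vector of labels.
#' @examples
#' genotype_label(c(0, 0, 1, 0), c(0, 1, 1, 2))
#' @export
genotype_label <- function(x, y, ascii = FALSE) {
  st <- ascn_state(x, y, 0)
  lab <- paste0(strrep("A", st$x), strrep("B", st$y))
  lab[st$x == 0 & st$y == 0] <- if (ascii) "0" else "Ø"
  lab
}

#' Expected total copy number of a mixed segment
#'
#' For a segment in state `(x, y)` carried by a fraction `p` of cells on a
#' diploid background: `CN = 2(1 - p) + (x + y) p`.
#'
#' @inheritParams ascn_state
#' @return Numeric vector of expected copy numbers (>= 0).
#' @examples
#' expected_copy_number(0, 1, 0.75)  # 1.25
#' @export
expected_copy_number <- function(x, y, p) {
  st <- ascn_state(x, y, p)
  2 * (1 - st$p) + (st$x + st$y) * st$p
}

#' Expected copy-number ratio R
#'
#' The ratio of the segment's expected copy number to the diploid normal,
#' `R = CN / 2 = (1 - p) + (x + y) p / 2`.
#'
#' @inheritParams ascn_state
#' @return Numeric vector of expected ratios (>= 0).
#' @examples
#' r_score(0, 1, 0.75)  # 0.625
#' @export
r_score <- function(x, y, p) {
  expected_copy_number(x, y, p) / 2
}

#' Expected B-allele frequency
#'
#' Fraction of reads carrying the B allele at a heterozygous locus inside
#' the segment: `BAF = (y p + (1 - p)) / ((x + y) p + 2 (1 - p))`.
#' Undefined for a homozygous deletion at full prevalence (no DNA present).
#'
#' @inheritParams ascn_state
#' @return Numeric vector of expected BAFs in `[0, 1]`.
#' @examples
#' baf(0, 1, 0.75)  # 0.8
#' @export
baf <- function(x, y, p) {
  st <- ascn_state(x, y, p)
  den <- (st$x + st$y) * st$p + 2 * (1 - st$p)
  if (any(den <= 0))
    stop("baf: undefined for a homozygous deletion at prevalence 1 (no DNA present)")
  (st$y * st$p + (1 - st$p)) / den
}

#' Expected heterozygous-deviation score
#'
#' `HDS = |BAF - 0.5| = p |y - x| / (2 [(x + y) p + 2 (1 - p)])`.
#' Zero for balanced alleles, up to 0.5 for complete loss of heterozygosity.
#'
#' @inheritParams ascn_state
#' @return Numeric vector of expected HDS values in `[0, 0.5]`.
#' @examples
#' hds(0, 1, 0.75)  # 0.3
#' hds(1, 2, 1.0)   # 1/6, the ceiling for a triploid genome
#' @export
hds <- function(x, y, p) {
  st <- ascn_state(x, y, p)
  den <- (st$x + st$y) * st$p + 2 * (1 - st$p)
  if (any(den <= 0))
    stop("hds: undefined for a homozygous deletion at prevalence 1 (no DNA present)")
  st$p * abs(st$y - st$x) / (2 * den)
}

# Internal: hds with the continuity convention for the homozygous
# deletion at p = 1 (hds is 0 for every p < 1, so the limit is 0).
# Used for branch construction, where the strict error would reject the
# Ø branch tip.
hds_branch <- function(x, y, p) {
  den <- (x + y) * p + 2 * (1 - p)
  ifelse(den > 0, p * abs(y - x) / (2 * den), 0)
}

#' Enumerate ASCN genotypes up to a total copy number
#'
#' @param max_total_copy Largest total copy number `x + y` considered.
#' @return data.frame with columns `x`, `y` (one row per genotype,
#'   `0 <= x <= y`, `x + y <= max_total_copy`), sorted by
#'   `(x + y, y - x)`.
#' @export
ascn_genotypes <- function(max_total_copy = 10) {
  stopifnot(max_total_copy >= 1)
  g <- expand.grid(x = 0:max_total_copy, y = 0:max_total_copy)
  g <- g[g$x <= g$y & g$x + g$y <= max_total_copy, , drop = FALSE]
  g <- g[order(g$x + g$y, g$y - g$x), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Build the branch lattice of the R-HDS plane
#'
#' Each genotype `(x, y)` traces a branch: the curve of expected
#' `(R, HDS)` coordinates as the prevalence `p` runs over its ticks.  All
#' branches emanate from the normal point `(1, 0)` at `p = 0`.
#'
#' @param max_total_copy Largest `x + y` on the lattice (default 10,
#'   i.e. states up to decasomy).
#' @param prevalence_ticks Prevalences at which branch points are placed,
#'   each in `(0, 1]`.  Default `seq(0.05, 1, by = 0.05)`.
#' @return data.frame with columns `genotype`, `x`, `y`, `p`, `r`, `hds`,
#'   sorted by `(x + y, y - x, p)`.
#' @examples
#' head(build_branches(2, prevalence_ticks = 1))
#' @export
build_branches <- function(max_total_copy = 10,
                           prevalence_ticks = seq(0.05, 1, by = 0.05)) {
  ticks <- sort(unique(prevalence_ticks))
  if (length(ticks) == 0 || any(ticks <= 0) || any(ticks > 1))
    stop("build_branches: prevalence ticks must lie in (0, 1]")
  g <- ascn_genotypes(max_total_copy)
  b <- merge(g, data.frame(p = ticks))
  b <- b[order(b$x + b$y, b$y - b$x, b$p), , drop = FALSE]
  b$genotype <- genotype_label(b$x, b$y)
  b$r <- r_score(b$x, b$y, b$p)
  b$hds <- hds_branch(b$x, b$y, b$p)
  rownames(b) <- NULL
  b[, c("genotype", "x", "y", "p", "r", "hds")]
}

#' Ploidy adjustment factor
#'
#' The raw copy ratio `R'` (tumor read depth over normal, each normalized
#' to its own genome average) understates or overstates the model's `R`
#' when the tumor genome ploidy `tau_t` differs from 2.  The correction is
#' multiplicative: `Phi = (tau_t p + 2 (1 - p)) / 2` and `R = R' * Phi`.
#'
#' @param tau_t Tumor genome ploidy (> 0); 2 for a diploid tumor.
#' @param p Tumor purity used for the adjustment (may be a vector).
#' @return An object of class `ploidy_adjustment`: a list with `tau_t`,
#'   `p`, `phi` and a function `adjust_r(r_raw)` returning `r_raw * phi`.
#' @examples
#' ploidy_phi(3, 0.723)$phi  # ~1.3615
#' @export
ploidy_phi <- function(tau_t, p) {
  stopifnot(length(tau_t) == 1, tau_t > 0, all(p >= 0), all(p <= 1))
  phi <- (tau_t * p + 2 * (1 - p)) / 2
  structure(
    list(tau_t = tau_t, p = p, phi = phi,
         adjust_r = function(r_raw) r_raw * phi),
    class = "ploidy_adjustment")
}

#' @export
print.ploidy_adjustment <- function(x, ...) {
  cat(sprintf("ploidy adjustment: tau_t = %.3g, p = %.3g, Phi = %.4g\n",
              x$tau_t, x$p[1], x$phi[1]))
  if (length(x$p) > 1) cat(sprintf("  (+%d more)\n", length(x$p) - 1))
  invisible(x)
}

#' Diploid-equivalent purity of a tetraploid solution
#'
#' A tetraploid tumor with purity `p` presents the same raw `(R', HDS)`
#' observables as a diploid tumor with purity `p' = p / (1 + p) <= 0.5`,
#' so the two interpretations cannot be separated on these scores alone.
#'
#' @param p Tetraploid-solution purity in `[0, 1]`.
#' @return The purity of the degenerate diploid solution.
#' @examples
#' diploid_equivalent_purity(0.70)  # 0.41
#' @export
diploid_equivalent_purity <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  p / (1 + p)
}
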