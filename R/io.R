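#' Normalize chromosome names
#'
#' Strips a leading `chr`/`Chr` prefix so that inputs with mixed naming
#' conventions line up.
#'
#' @param chrom Character vector of chromosome names.
#' @return Normalized character vector.
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc]hr", "", as.character(chrom))
}

# Internal: sortable rank for chromosome names (1..22, X, Y, MT, then
# anything else alphabetically after).
chrom_rank <- function(chrom) {
  ch <- normalize_chrom(chrom)
  num <- suppressWarnings(as.numeric(ch))
  r <- ifelse(!is.na(num), num,
              ifelse(ch == "X", 100,
                     ifelse(ch == "Y", 101, ifelse(ch %in% c("M", "MT"), 102, 200))))
  r + match(ch, sort(unique(ch))) / (2 * (length(unique(ch)) + 1))
}

#' Read a SEG-format segment table
#'
#' Expects the conventional header `ID chrom loc.start loc.end num.mark
#' seg.mean`.  `seg.mean` follows the log2-ratio convention of CBS
#' output, so values are transformed to the linear scale (`2^seg.mean`)
#' unless `log2 = FALSE`.
#'
#' @param path Path to a tab-separated SEG file.
#' @param log2 Is `seg.mean` a log2 ratio?  Default `TRUE` (a notice is
#'   emitted when transforming).
#' @return data.frame with `chrom`, `start`, `end`, `n_markers`, `r_raw`,
#'   sorted by genome position.
#' @export
read_seg <- function(path, log2 = TRUE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "loc.start", "loc.end", "seg.mean")
  if (!all(need %in% names(d)))
    stop(sprintf("read_seg: %s lacks SEG columns (%s)", path,
                 paste(setdiff(need, names(d)), collapse = ", ")))
  r <- d$seg.mean
  if (log2) {
    message("read_seg: interpreting seg.mean as log2 ratio; applying 2^value")
    r <- 2^r
  }
  out <- data.frame(chrom = normalize_chrom(d$chrom),
                    start = as.integer(d$loc.start),
                    end = as.integer(d$loc.end),
                    n_markers = if ("num.mark" %in% names(d))
                      as.integer(d$num.mark) else NA_integer_,
                    r_raw = r)
  ord <- order(chrom_rank(out$chrom), out$start)
  if (is.unsorted(ord)) message("read_seg: segments re-sorted into genome order")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a plain segment table (TSV or BED+ratio)
#'
#' Accepts a tab-separated table with columns `chrom`, `start`, `end`,
#' `r_raw` (linear-scale tumor/normal ratio) and optional `n_markers`.
#' With `bed = TRUE` the coordinates are taken as 0-based half-open and
#' converted to the 1-based inclusive convention used internally.
#'
#' @param path Path to the file.
#' @param bed Input uses BED coordinates.  Default `FALSE`.
#' @return data.frame as for [read_seg()].
#' @export
read_segments_tsv <- function(path, bed = FALSE) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "r_raw")
  if (!all(need %in% names(d)))
    stop(sprintf("read_segments_tsv: %s lacks columns (%s)", path,
                 paste(setdiff(need, names(d)), collapse = ", ")))
  out <- data.frame(chrom = normalize_chrom(d$chrom),
                    start = as.integer(d$start) + if (bed) 1L else 0L,
                    end = as.integer(d$end),
                    n_markers = if ("n_markers" %in% names(d))
                      as.integer(d$n_markers) else NA_integer_,
                    r_raw = as.numeric(d$r_raw))
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read tumor/normal allele depths from a TSV
#'
#' Columns: `chrom`, `pos`, `tumor_ref`, `tumor_alt`, plus either
#' `normal_ref`/`normal_alt` or logical `normal_het`.
#'
#' @param path Path to the file.
#' @return data.frame suitable for [select_het_loci()].
#' @export
read_het_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "tumor_ref", "tumor_alt")
  if (!all(need %in% names(d)))
    stop(sprintf("read_het_tsv: %s lacks columns (%s)", path,
                 paste(setdiff(need, names(d)), collapse = ", ")))
  d$chrom <- normalize_chrom(d$chrom)
  d
}

# Internal: extract "ref,alt" AD pairs from a vcfR AD matrix column.
parse_ad <- function(ad) {
  ref <- alt <- rep(NA_real_, length(ad))
  ok <- !is.na(ad) & ad != "." & grepl(",", ad)
  parts <- strsplit(ad[ok], ",", fixed = TRUE)
  ref[ok] <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  alt[ok] <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  list(ref = ref, alt = alt)
}

#' Read paired tumor/normal allele depths from a VCF
#'
#' Uses the `AD` FORMAT field (ref,alt allele depths) of the named tumor
#' and normal samples.  Multi-allelic records and records without `AD`
#' are skipped with a summary count.
#'
#' @param path Path to a VCF (plain text or bgzipped).
#' @param tumor,normal Sample names; default the first and second sample
#'   columns.
#' @return data.frame suitable for [select_het_loci()].
#' @export
read_het_vcf <- function(path, tumor = NULL, normal = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_het_vcf: the vcfR package is required for VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  if (length(samples) < 2)
    stop("read_het_vcf: need tumor and normal sample columns")
  if (is.null(tumor)) tumor <- samples[1]
  if (is.null(normal)) normal <- samples[2]
  ad <- vcfR::extract.gt(v, element = "AD")
  if (!all(c(tumor, normal) %in% colnames(ad)))
    stop("read_het_vcf: sample name not present in VCF")
  tum <- parse_ad(ad[, tumor])
  nor <- parse_ad(ad[, normal])
  fix <- vcfR::getFIX(v)
  out <- data.frame(chrom = normalize_chrom(fix[, "CHROM"]),
                    pos = as.integer(fix[, "POS"]),
                    tumor_ref = tum$ref, tumor_alt = tum$alt,
                    normal_ref = nor$ref, normal_alt = nor$alt)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_bad <- sum(multi | is.na(out$tumor_ref) | is.na(out$normal_ref))
  if (n_bad > 0)
    message(sprintf("read_het_vcf: %d record(s) skipped (multi-allelic or no AD)",
                    n_bad))
  out[!multi, , drop = FALSE]
}

#' Read somatic variant allele depths (tumor sample)
#'
#' TSV columns: `chrom`, `pos`, `ref_count`, `alt_count`.
#'
#' @param path Path to the file.
#' @return data.frame with `chrom`, `pos`, `ref_count`, `alt_count`,
#'   `vaf_obs`.
#' @export
read_somatic_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref_count", "alt_count")
  if (!all(need %in% names(d)))
    stop(sprintf("read_somatic_tsv: %s lacks columns (%s)", path,
                 paste(setdiff(need, names(d)), collapse = ", ")))
  d$chrom <- normalize_chrom(d$chrom)
  dp <- d$ref_count + d$alt_count
  if (any(dp <= 0)) stop("read_somatic_tsv: zero-depth variant")
  d$vaf_obs <- d$alt_count / dp
  d
}

#' Write bubbles to a TSV
#'
#' @param bubbles Bubble table from [homogenize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bubbles_tsv <- function(bubbles, path) {
  utils::write.table(bubbles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read bubbles back from a TSV
#' @param path Path written by [write_bubbles_tsv()].
#' @return Bubble data.frame.
#' @export
read_bubbles_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  d$chrom <- as.character(d$chrom)
  d
}

#' Serialize a fitted callset to JSON
#'
#' Writes ploidy, purity, prevalences, residual, the per-segment
#' assignments and any alternative solution.
#'
#' @param callset A `clone_callset` from [call_clones()] or
#'   [assign_ascn()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callset_json <- function(callset, path) {
  stopifnot(inherits(callset, "clone_callset"))
  obj <- list(tau_t = callset$tau_t,
              phi = callset$phi,
              purity = callset$purity,
              subclone_prevalences = callset$subclone_prevalences,
              fit_residual = callset$fit_residual,
              warnings = callset$warnings,
              assignments = callset$assignments,
              alternative = callset$alternative)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' Read a callset written by [write_callset_json()]
#' @param path JSON path.
#' @return A `clone_callset` object.
#' @export
read_callset_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$assignments <- as.data.frame(obj$assignments)
  class(obj) <- "clone_callset"
  obj
}
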