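# Two-caller concordance: site-level intersection / union keyed on the
# exact (contig, pos, ref, alt) identity of decomposed, left-normalized
# records, plus the per-callset descriptive summary (variant counts by
# type, multiallelic tallies, TsTv and hetNRhom ratios).

check_mergeable <- function(A, B, allow_sample_mismatch) {
  shared <- intersect(names(A$contig_lengths), names(B$contig_lengths))
  if (!identical(A$contig_lengths[shared], B$contig_lengths[shared]))
    stop("callsets disagree on contig lengths")
  if (!setequal(A$samples, B$samples) && !allow_sample_mismatch)
    stop("callsets have different sample sets; ",
         "pass allow_sample_mismatch = TRUE to intersect samples")
  common <- intersect(A$samples, B$samples)
  if (!length(common)) stop("callsets share no samples")
  common
}

subset_samples <- function(cs, keep) {
  idx <- match(keep, cs$samples)
  cs$samples <- keep
  cs$gt_a <- cs$gt_a[, idx, drop = FALSE]
  cs$gt_b <- cs$gt_b[, idx, drop = FALSE]
  cs
}

subset_sites <- function(cs, idx) {
  callset(cs$sites[idx, , drop = FALSE],
          cs$gt_a[idx, , drop = FALSE], cs$gt_b[idx, , drop = FALSE],
          cs$samples, cs$contig_lengths)
}

#' Intersect two callsets by site key
#'
#' Keeps the sites whose `(contig, pos, ref, alt)` key occurs in both
#' callsets. Genotypes, annotations and multiallelic flags are taken from
#' the donor callset (`A` by default).
#'
#' @param A,B decomposed [callset]s over the same reference.
#' @param genotype_from `"A"` or `"B"`: whose genotypes the result carries.
#' @param allow_sample_mismatch when the sample sets differ, set `TRUE` to
#'   take the sample intersection instead of erroring.
#' @return a [callset].
#' @export
intersect_callsets <- function(A, B, genotype_from = c("A", "B"),
                               allow_sample_mismatch = FALSE) {
  genotype_from <- match.arg(genotype_from)
  common <- check_mergeable(A, B, allow_sample_mismatch)
  donor <- if (genotype_from == "A") A else B
  other <- if (genotype_from == "A") B else A
  donor <- subset_samples(donor, common)
  keep <- site_keys(donor) %in% site_keys(other)
  cl <- c(donor$contig_lengths,
          other$contig_lengths[setdiff(names(other$contig_lengths),
                                       names(donor$contig_lengths))])
  donor$contig_lengths <- cl
  subset_sites(donor, which(keep))
}

#' Union of two callsets by site key
#'
#' Sites present in either callset; records present only in `B` carry `B`'s
#' genotypes, all others carry `A`'s. Satisfies
#' `|A| + |B| = |union| + |intersection|`.
#'
#' @inheritParams intersect_callsets
#' @return a [callset].
#' @export
union_callsets <- function(A, B, allow_sample_mismatch = FALSE) {
  common <- check_mergeable(A, B, allow_sample_mismatch)
  A <- subset_samples(A, common)
  B <- subset_samples(B, common)
  b_only <- !(site_keys(B) %in% site_keys(A))
  cl <- c(A$contig_lengths,
          B$contig_lengths[setdiff(names(B$contig_lengths),
                                   names(A$contig_lengths))])
  # keep B-origin ma_ids distinct from A's
  bsites <- B$sites[b_only, , drop = FALSE]
  off <- max(0L, A$sites$ma_id, na.rm = TRUE)
  bsites$ma_id <- bsites$ma_id + off
  callset(rbind(A$sites, bsites),
          rbind(A$gt_a, B$gt_a[b_only, , drop = FALSE]),
          rbind(A$gt_b, B$gt_b[b_only, , drop = FALSE]),
          common, cl)
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Descriptive summary of a callset
#'
#' Counts by variant type, multiallelic-site tallies (from pre-decomposition
#' flags), the transition/transversion ratio over SNVs, and the cohort
#' heterozygous / non-reference-homozygous genotype ratio aggregated over
#' all sites and samples (missing genotypes excluded). A zero denominator
#' yields an `NA` ratio with a warning rather than an error.
#'
#' @param cs a decomposed [callset].
#' @return a `callset_summary` list: `n_variants`, `n_snps`, `n_indels`,
#'   `n_other`, `n_ma_sites`, `n_ma_snp_sites`, `n_ts`, `n_tv`,
#'   `ts_tv_ratio`, `n_het`, `n_hom_alt`, `het_nrhom_ratio`.
#' @export
summarize_callset <- function(cs) {
  stopifnot(inherits(cs, "callset"))
  vt <- cs$sites$vtype
  snp <- vt == "SNP"
  n_ts <- sum(snp & is_transition(cs$sites$ref, cs$sites$alt))
  n_tv <- sum(snp) - n_ts
  ma_id <- cs$sites$ma_id[cs$sites$ma]
  n_ma <- length(unique(ma_id))
  # multiallelic input records whose decomposed alternates are all SNPs
  n_ma_snp <- if (n_ma) sum(tapply(snp[cs$sites$ma], ma_id, all)) else 0L
  n_het <- sum(het_matrix(cs))
  n_hom <- sum(homalt_matrix(cs))
  tstv <- if (n_tv == 0) {
    if (n_ts > 0) warning("no transversions: TsTv undefined")
    NA_real_
  } else n_ts / n_tv
  hnr <- if (n_hom == 0) {
    if (n_het > 0) warning("no homozygous-alternate genotypes: hetNRhom undefined")
    NA_real_
  } else n_het / n_hom
  structure(list(n_variants = nrow(cs$sites), n_snps = sum(snp),
                 n_indels = sum(vt == "INDEL"), n_other = sum(vt == "OTHER"),
                 n_ma_sites = n_ma, n_ma_snp_sites = as.integer(n_ma_snp),
                 n_ts = n_ts, n_tv = n_tv, ts_tv_ratio = tstv,
                 n_het = n_het, n_hom_alt = n_hom, het_nrhom_ratio = hnr),
            class = "callset_summary")
}

#' @export
print.callset_summary <- function(x, ...) {
  cat(sprintf(paste0("callset summary: %d variants ",
                     "(%d SNPs, %d indels, %d other; %d multiallelic sites)\n",
                     "  TsTv = %s   hetNRhom = %s\n"),
              x$n_variants, x$n_snps, x$n_indels, x$n_other, x$n_ma_sites,
              format(x$ts_tv_ratio, digits = 4),
              format(x$het_nrhom_ratio, digits = 4)))
  invisible(x)
}

#' @export
as.data.frame.callset_summary <- function(x, ...) {
  data.frame(lapply(unclass(x), identity))
}
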