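# Cohort metrics: per-sample and per-site summaries, MAF spectrum,
# variants-per-kb rates, the depth-of-coverage association, and
# depth-adjusted estimated marginal means by breed.

#' Per-sample summaries
#'
#' One row per sample: breed and depth from the sheet, counts of variant
#' sites carried (>= 1 alternate allele: heterozygous plus
#' homozygous-alternate), het / hom-alt split, SNP / indel split of carried
#' sites, transition / transversion counts of carried SNVs, and the
#' fraction of sites with a missing genotype.
#'
#' @param cs a [callset].
#' @param sheet sample sheet data.frame (`sample`, `breed`, `doc`) covering
#'   every callset sample.
#' @return data.frame, one row per sample.
#' @export
per_sample_summaries <- function(cs, sheet) {
  validate_sample_sheet(sheet, cs$samples)
  called <- called_matrix(cs)
  het <- het_matrix(cs)
  hom <- homalt_matrix(cs)
  carrier <- het | hom
  vt <- cs$sites$vtype
  snp <- vt == "SNP"
  ts <- snp & is_transition(cs$sites$ref, cs$sites$alt)
  m <- match(cs$samples, sheet$sample)
  data.frame(
    sample = cs$samples,
    breed = sheet$breed[m],
    doc = sheet$doc[m],
    n_variant_sites = colSums(carrier),
    n_het = colSums(het),
    n_hom_alt = colSums(hom),
    n_snp = colSums(carrier & snp),
    n_indel = colSums(carrier & (vt == "INDEL")),
    n_ts = colSums(carrier & ts),
    n_tv = colSums(carrier & snp & !ts),
    missingness = 1 - colMeans(called),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-site summaries
#'
#' One row per site: alternate allele count `AC` and called allele number
#' `AN` over fully called genotypes, alternate and minor allele frequency,
#' site missingness, and the singleton flag (`AC == 1`).
#'
#' @param cs a [callset].
#' @return data.frame keyed by `contig`, `pos`, `ref`, `alt`.
#' @export
site_summaries <- function(cs) {
  called <- called_matrix(cs)
  s <- cs$gt_a + cs$gt_b
  s[!called] <- 0L
  ac <- rowSums(s)
  an <- 2L * rowSums(called)
  af <- ifelse(an > 0, ac / an, NA_real_)
  data.frame(cs$sites[c("contig", "pos", "ref", "alt", "vtype")],
             AC = ac, AN = an, af = af,
             maf = pmin(af, 1 - af),
             missingness = 1 - rowMeans(called),
             singleton = ac == 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Minor-allele-frequency spectrum
#'
#' Histogram of site MAF over `[0, 0.5]`; sites with no called alleles are
#' excluded (their count is reported in the `n_excluded_an0` attribute and
#' a message).
#'
#' @param sites per-site summary from [site_summaries].
#' @param bin_width bin width; must divide 0.5. The last bin is closed so
#'   MAF 0.5 is counted.
#' @return data.frame `lower`, `upper`, `count`.
#' @export
maf_spectrum <- function(sites, bin_width = 0.05) {
  nb <- 0.5 / bin_width
  if (abs(nb - round(nb)) > 1e-9) stop("bin_width must divide 0.5")
  nb <- as.integer(round(nb))
  excl <- sum(sites$AN == 0)
  if (excl > 0) message(excl, " site(s) with AN = 0 excluded from MAF spectrum")
  maf <- sites$maf[sites$AN > 0]
  bin <- pmin(floor(maf / bin_width), nb - 1L)
  out <- data.frame(lower = (seq_len(nb) - 1L) * bin_width,
                    upper = seq_len(nb) * bin_width,
                    count = tabulate(bin + 1L, nbins = nb))
  attr(out, "n_excluded_an0") <- excl
  out
}

#' Fraction of sites below a MAF threshold
#'
#' @param sites per-site summary from [site_summaries].
#' @param threshold strict MAF cutoff.
#' @return fraction of sites (with called alleles) having `maf < threshold`.
#' @export
maf_fraction_below <- function(sites, threshold) {
  maf <- sites$maf[sites$AN > 0]
  mean(maf < threshold)
}

#' Cohort variant density per kb
#'
#' @param cs a [callset].
#' @return variants per kb of genome (`sum(contig_lengths) / 1000`).
#' @export
variants_per_kb <- function(cs) {
  kb <- sum(cs$contig_lengths) / 1000
  if (kb <= 0) stop("zero genome length")
  nrow(cs$sites) / kb
}

#' Per-sample variant and heterozygosity rates per kb
#'
#' @param summaries per-sample summary from [per_sample_summaries].
#' @param cs the [callset] the summaries came from (for genome length).
#' @return data.frame `sample`, `variants_per_kb`, `het_per_kb`.
#' @export
per_sample_rates <- function(summaries, cs) {
  kb <- sum(cs$contig_lengths) / 1000
  if (kb <= 0) stop("zero genome length")
  data.frame(sample = summaries$sample,
             variants_per_kb = summaries$n_variant_sites / kb,
             het_per_kb = summaries$n_het / kb,
             stringsAsFactors = FALSE)
}

#' Association between depth of coverage and variants detected
#'
#' Spearman rank correlation between per-sample depth and the number of
#' variant sites carried, plus a least-squares fit of the saturating curve
#' `count ~ a * (1 - exp(-doc/b))` capturing the non-linear, plateauing
#' gain of variant yield with depth. The curve is conditionally linear in
#' `a`, so `a` is profiled out analytically and the scale `b` found by
#' one-dimensional least-squares optimization — stable even when most
#' samples sit on the plateau.
#'
#' @param summaries per-sample summary from [per_sample_summaries].
#' @return list `rho` (rank correlation), `a` (plateau), `b` (depth scale),
#'   `sse` (residual sum of squares).
#' @export
doc_association <- function(summaries) {
  if (nrow(summaries) < 3) stop("need at least 3 samples")
  doc <- summaries$doc
  n <- summaries$n_variant_sites
  if (stats::sd(doc) == 0) {
    warning("constant depth of coverage: correlation undefined")
    return(list(rho = NA_real_, a = NA_real_, b = NA_real_, sse = NA_real_))
  }
  rho <- stats::cor(doc, n, method = "spearman")
  a_of <- function(b) {
    f <- 1 - exp(-doc / b)
    sum(f * n) / sum(f * f)
  }
  sse_of_logb <- function(lb) {
    b <- exp(lb)
    f <- 1 - exp(-doc / b)
    a <- sum(f * n) / sum(f * f)
    sum((n - a * f)^2)
  }
  opt <- stats::optimize(sse_of_logb,
                         lower = log(min(doc) / 100), upper = log(max(doc) * 10))
  b <- exp(opt$minimum)
  list(rho = rho, a = a_of(b), b = b, sse = opt$objective)
}

#' Depth-adjusted estimated marginal means by breed
#'
#' Fits `response ~ breed + doc` by least squares and evaluates each
#' breed's fitted mean at the grand-mean depth of coverage, with standard
#' errors from the fit's covariance and t-based confidence intervals.
#' When depth is constant it drops out of the model and the estimated
#' marginal means equal the raw breed means.
#'
#' @param response numeric response per sample (e.g. variant count).
#' @param breed breed label per sample (>= 2 breeds, >= 2 samples each).
#' @param doc depth of coverage per sample.
#' @param conf_level confidence level for the intervals.
#' @return data.frame `breed`, `emmean`, `se`, `lower`, `upper`.
#' @export
emmeans_by_breed <- function(response, breed, doc, conf_level = 0.95) {
  stopifnot(length(response) == length(breed), length(breed) == length(doc))
  breed <- factor(breed)
  if (nlevels(breed) < 2) stop("need at least 2 breeds")
  if (any(table(breed) < 2)) stop("need at least 2 samples per breed")
  dat <- data.frame(response = response, breed = breed, doc = doc)
  constant_doc <- stats::sd(doc) == 0
  fit <- if (constant_doc) stats::lm(response ~ breed, data = dat)
         else stats::lm(response ~ breed + doc, data = dat)
  if (anyNA(stats::coef(fit)))
    stop("singular design: breed is confounded with depth of coverage")
  em <- emmeans::emmeans(fit, "breed", level = conf_level)
  s <- as.data.frame(summary(em))
  data.frame(breed = as.character(s$breed), emmean = s$emmean, se = s$SE,
             lower = s$lower.CL, upper = s$upper.CL,
             stringsAsFactors = FALSE)
}

#' Singleton catalog
#'
#' @param sites per-site summary from [site_summaries].
#' @return the rows with alternate allele count exactly 1.
#' @export
singleton_catalog <- function(sites) {
  out <- sites[sites$AN > 0 & sites$AC == 1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}
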