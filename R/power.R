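# Closed-form detection-power and Hardy-Weinberg expectation arithmetic
# for cohort design: the probability of observing an allele of a given
# frequency at least once in a cohort, the cohort size needed for a target
# power, the cohort size at which one homozygote is expected under HWE,
# and the expected variant count per genomic window.

#' Probability of detecting an allele in a cohort
#'
#' `1 - (1 - maf)^(n * draws_per_individual)`: the probability that an
#' allele at population frequency `maf` is carried by at least one of `n`
#' sampled individuals. The default treats each individual as a single
#' draw; `draws_per_individual = 2` treats individuals as two independent
#' chromosome draws.
#'
#' @param maf allele frequency in `[0, 1]`.
#' @param n number of individuals sampled (>= 1).
#' @param draws_per_individual 1 or 2.
#' @return detection probability in `[0, 1]`.
#' @export
detection_power <- function(maf, n, draws_per_individual = 1) {
  stopifnot(all(maf >= 0 & maf <= 1), all(n >= 1),
            all(draws_per_individual %in% c(1, 2)))
  1 - (1 - maf)^(n * draws_per_individual)
}

#' Smallest cohort reaching a target detection power
#'
#' Inverts [detection_power]: the smallest integer `n` with
#' `detection_power(maf, n) >= target_power`, i.e.
#' `ceil(log(1 - target_power) / (draws * log(1 - maf)))`.
#'
#' @param maf allele frequency in `(0, 1)`.
#' @param target_power target in `(0, 1)`.
#' @param draws_per_individual 1 or 2.
#' @return integer cohort size.
#' @export
min_cohort_for_power <- function(maf, target_power, draws_per_individual = 1) {
  stopifnot(maf > 0, maf < 1, target_power > 0, target_power < 1)
  n <- ceiling(log(1 - target_power) / (draws_per_individual * log(1 - maf)))
  as.integer(max(1, n))
}

#' Cohort size at which one homozygote is expected under HWE
#'
#' Under Hardy-Weinberg equilibrium a homozygote for an allele of
#' frequency `maf` occurs at rate `maf^2`, so the expected homozygote
#' count reaches 1 at `floor(1 / maf^2)` individuals.
#'
#' @param maf allele frequency in `(0, 1]`.
#' @return integer cohort size.
#' @export
cohort_size_for_one_homozygote <- function(maf) {
  if (maf <= 0) stop("maf must be > 0")
  stopifnot(maf <= 1)
  as.integer(floor(1 / maf^2 + 1e-9))  # guard binary-fraction round-off
}

#' Expected sites per genomic window
#'
#' `n_sites * window_bp / genome_bp`: the mean number of catalog sites
#' expected in a window of given width under uniform placement.
#'
#' @param n_sites total number of sites in the catalog.
#' @param genome_bp genome length in bp.
#' @param window_bp window width in bp.
#' @return expected count per window.
#' @export
sites_per_window_density <- function(n_sites, genome_bp, window_bp) {
  stopifnot(n_sites > 0, genome_bp > 0, window_bp > 0)
  n_sites * window_bp / genome_bp
}
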