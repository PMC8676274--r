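# Breed-stratified allele-frequency tables and variant-class screens:
# rare/common discrepancies between breeds and against the rest of the
# population, breed-shared and breed-unique variants, genic proximity,
# no-homozygote sites, and present-in-all / homozygous-in-all sites.

#' Screen configuration
#'
#' @param rare_threshold strict MAF cutoff below which a variant is rare.
#' @param common_threshold strict MAF cutoff above which it is common.
#' @param genic_distance bp distance from a gene within which a variant is
#'   called genic.
#' @param target_breeds breeds the screens iterate over; `NULL` = all
#'   breeds present in the sample sheet.
#' @return a `screen_config` list.
#' @export
screen_config <- function(rare_threshold = 0.03, common_threshold = 0.10,
                          genic_distance = 5000, target_breeds = NULL) {
  stopifnot(rare_threshold > 0, rare_threshold < common_threshold,
            common_threshold < 0.5, genic_distance >= 0)
  structure(list(rare_threshold = rare_threshold,
                 common_threshold = common_threshold,
                 genic_distance = genic_distance,
                 target_breeds = target_breeds),
            class = "screen_config")
}

#' Per-breed allele count/frequency table
#'
#' For every site and every breed label in the sheet: alternate allele
#' count `AC_b` and called allele number `AN_b` over that breed's samples,
#' the folded per-breed MAF, and the rest-of-population MAF computed by
#' excluding that breed's samples entirely. Breeds with zero called
#' alleles at a site get `NA` frequencies there (excluded from screens).
#'
#' @param cs a [callset].
#' @param sheet sample sheet covering every callset sample.
#' @param config a [screen_config] (reserved; breeds come from the sheet).
#' @return a `breed_af_table`: list with `keys` (site data.frame), `breeds`,
#'   matrices `AC`, `AN`, `maf`, `rest_maf` (sites x breeds), vectors
#'   `cohort_AC`, `cohort_AN`, `n_breeds_present`.
#' @export
breed_af_table <- function(cs, sheet, config = screen_config()) {
  validate_sample_sheet(sheet, cs$samples)
  breeds <- sort(unique(sheet$breed))
  breed_of <- sheet$breed[match(cs$samples, sheet$sample)]
  ind <- vapply(breeds, function(b) as.numeric(breed_of == b),
                numeric(length(cs$samples)))
  called <- called_matrix(cs)
  s <- cs$gt_a + cs$gt_b
  s[!called] <- 0L
  AC <- s %*% ind
  AN <- 2 * (called %*% ind)
  tot_ac <- rowSums(AC)
  tot_an <- rowSums(AN)
  af <- ifelse(AN > 0, AC / AN, NA_real_)
  maf <- pmin(af, 1 - af)
  rest_an <- tot_an - AN
  rest_af <- ifelse(rest_an > 0, (tot_ac - AC) / rest_an, NA_real_)
  rest_maf <- pmin(rest_af, 1 - rest_af)
  dimnames(AC) <- dimnames(AN) <- dimnames(maf) <- dimnames(rest_maf) <-
    list(NULL, breeds)
  structure(list(keys = cs$sites[c("contig", "pos", "ref", "alt")],
                 breeds = breeds, AC = AC, AN = AN, maf = maf,
                 rest_maf = rest_maf,
                 cohort_AC = tot_ac, cohort_AN = tot_an,
                 n_breeds_present = rowSums(AC > 0)),
            class = "breed_af_table")
}

#' Classify a MAF as rare / intermediate / common
#'
#' Strict inequalities: rare iff `maf < rare_threshold`, common iff
#' `maf > common_threshold`; values at either threshold are intermediate.
#'
#' @param maf numeric vector of folded MAFs in `[0, 0.5]` (NA allowed).
#' @param config a [screen_config].
#' @return character vector in `{"rare","intermediate","common"}` (NA for NA).
#' @export
classify_maf <- function(maf, config = screen_config()) {
  out <- ifelse(maf < config$rare_threshold, "rare",
                ifelse(maf > config$common_threshold, "common",
                       "intermediate"))
  out[is.na(maf)] <- NA_character_
  out
}

screen_breeds <- function(bat, config) {
  tb <- config$target_breeds
  if (is.null(tb)) bat$breeds else {
    miss <- setdiff(tb, bat$breeds)
    if (length(miss)) stop("target breed(s) absent: ", paste(miss, collapse = ", "))
    tb
  }
}

#' Sites rare in one breed and common in another
#'
#' @param bat a [breed_af_table].
#' @param breed_i,breed_j the two breeds.
#' @param config a [screen_config].
#' @return list `rare_i_common_j`, `rare_j_common_i`; each a site key
#'   data.frame with both breeds' MAFs.
#' @export
pairwise_discrepancies <- function(bat, breed_i, breed_j,
                                   config = screen_config()) {
  stopifnot(breed_i %in% bat$breeds, breed_j %in% bat$breeds)
  ci <- classify_maf(bat$maf[, breed_i], config)
  cj <- classify_maf(bat$maf[, breed_j], config)
  pick <- function(sel) {
    out <- cbind(bat$keys[sel, , drop = FALSE],
                 maf_i = bat$maf[sel, breed_i], maf_j = bat$maf[sel, breed_j])
    rownames(out) <- NULL
    out
  }
  list(rare_i_common_j = pick(which(ci == "rare" & cj == "common")),
       rare_j_common_i = pick(which(cj == "rare" & ci == "common")))
}

#' Breed-versus-rest rare/common screens
#'
#' For each target breed: sites rare in the breed and common in the rest of
#' the population (breed-specific rare), and sites common in the breed and
#' rare in the rest (breed-specific common). "Rest" excludes the focal
#' breed's samples entirely.
#'
#' @param bat a [breed_af_table].
#' @param config a [screen_config].
#' @return data.frame `contig`, `pos`, `ref`, `alt`, `breed`, `class`
#'   (`breed_specific_rare` / `breed_specific_common`), `breed_maf`,
#'   `rest_maf`.
#' @export
breed_vs_rest_screens <- function(bat, config = screen_config()) {
  rows <- lapply(screen_breeds(bat, config), function(b) {
    cb <- classify_maf(bat$maf[, b], config)
    cr <- classify_maf(bat$rest_maf[, b], config)
    sel_r <- which(cb == "rare" & cr == "common")
    sel_c <- which(cb == "common" & cr == "rare")
    sel <- c(sel_r, sel_c)
    if (!length(sel)) return(NULL)
    cbind(bat$keys[sel, , drop = FALSE],
          breed = b,
          class = rep(c("breed_specific_rare", "breed_specific_common"),
                      c(length(sel_r), length(sel_c))),
          breed_maf = bat$maf[sel, b], rest_maf = bat$rest_maf[sel, b])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- cbind(bat$keys[0, ], breed = character(0), class = character(0),
                 breed_maf = numeric(0), rest_maf = numeric(0))
  rownames(out) <- NULL
  out
}

#' Breed-shared and breed-unique variants
#'
#' Presence in a breed means `AC_b > 0`. Shared = present in at least two
#' breed labels; unique = present in exactly one (which is reported).
#'
#' @param bat a [breed_af_table].
#' @return list `shared` (site keys with `n_breeds_present`), `unique`
#'   (site keys with the single carrying `breed`).
#' @export
shared_and_unique <- function(bat) {
  nbp <- bat$n_breeds_present
  shared <- cbind(bat$keys[nbp >= 2, , drop = FALSE],
                  n_breeds_present = nbp[nbp >= 2])
  uniq_sel <- which(nbp == 1)
  uniq_breed <- bat$breeds[max.col(bat$AC[uniq_sel, , drop = FALSE] > 0,
                                   ties.method = "first")]
  uniq <- cbind(bat$keys[uniq_sel, , drop = FALSE], breed = uniq_breed)
  rownames(shared) <- rownames(uniq) <- NULL
  list(shared = shared, unique = uniq)
}

#' Genic-proximity annotation
#'
#' Flags each variant whose anchor position lies within `genic_distance` bp
#' of a gene interval (strand-agnostic; all overlapping genes reported).
#' Contigs absent from the interval set are flagged non-genic with a
#' warning.
#'
#' @param cs a [callset] (or a site data.frame with `contig`, `pos`).
#' @param genes gene intervals from [read_gene_intervals] (0-based
#'   half-open).
#' @param config a [screen_config] supplying `genic_distance`.
#' @return data.frame of site keys plus `genic` flag and comma-separated
#'   `gene_ids`.
#' @export
annotate_genic <- function(cs, genes, config = screen_config()) {
  sites <- if (inherits(cs, "callset")) cs$sites else cs
  d <- config$genic_distance
  miss <- setdiff(unique(sites$contig), unique(genes$contig))
  if (length(miss))
    warning("contig(s) with no gene intervals: ", paste(miss, collapse = ", "))
  var_gr <- GenomicRanges::GRanges(sites$contig,
                                   IRanges::IRanges(sites$pos, sites$pos))
  # 0-based half-open [start-d, end+d) -> 1-based inclusive [start-d+1, end+d]
  gene_gr <- GenomicRanges::GRanges(
    genes$contig,
    IRanges::IRanges(pmax(genes$start - d + 1, 1), genes$end + d))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(var_gr, gene_gr))
  ids <- rep(NA_character_, nrow(sites))
  if (length(ov)) {
    hit <- tapply(genes$gene_id[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov),
                  function(g) paste(sort(unique(g)), collapse = ","))
    ids[as.integer(names(hit))] <- unname(hit)
  }
  data.frame(sites[c("contig", "pos", "ref", "alt")],
             genic = !is.na(ids), gene_ids = ids,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sites with heterozygotes but no homozygous-alternate genotypes
#'
#' Keeps sites with at least one heterozygous and zero homozygous-alternate
#' genotypes among called samples. Because no genotype carries two
#' alternate alleles, the reported alternate allele frequency is always
#' at most 0.5 (exactly 0.5 when every called genotype is heterozygous).
#'
#' @param cs a [callset].
#' @return data.frame of site keys with `n_het` and the alternate allele
#'   frequency `af`.
#' @export
screen_no_homozygotes <- function(cs) {
  het <- rowSums(het_matrix(cs))
  hom <- rowSums(homalt_matrix(cs))
  an <- 2L * rowSums(called_matrix(cs))
  sel <- which(het >= 1L & hom == 0L)
  out <- cbind(cs$sites[sel, c("contig", "pos", "ref", "alt"), drop = FALSE],
               n_het = het[sel], af = het[sel] / an[sel])
  rownames(out) <- NULL
  out
}

#' Sites present (or homozygous) in every sample
#'
#' `present_in_all`: every sample has a called genotype carrying at least
#' one alternate allele; `homozygous_in_all`: every sample is called and
#' homozygous-alternate (a subset of the former). A missing genotype in
#' any sample disqualifies the site from both sets.
#'
#' @param cs a [callset].
#' @return list of two site-key data.frames: `present_in_all`,
#'   `homozygous_in_all`.
#' @export
screen_present_in_all <- function(cs) {
  n <- length(cs$samples)
  called <- called_matrix(cs)
  hom <- homalt_matrix(cs)
  carrier <- het_matrix(cs) | hom
  all_called <- rowSums(called) == n
  keys <- cs$sites[c("contig", "pos", "ref", "alt")]
  pia <- keys[all_called & rowSums(carrier) == n, , drop = FALSE]
  hia <- keys[all_called & rowSums(hom) == n, , drop = FALSE]
  rownames(pia) <- rownames(hia) <- NULL
  list(present_in_all = pia, homozygous_in_all = hia)
}
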