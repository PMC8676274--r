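# End-to-end driver: reads the inputs, runs (optional) two-caller
# concordance, cohort summaries, breed screens, the window scan and the
# power report, and writes one TSV per stage plus a MANIFEST. Every output
# carries a provenance header recording the package version, seed and the
# thresholds actually applied.

provenance_header <- function(seed, config, window_size) {
  c(sprintf("# breedvar %s", as.character(utils::packageVersion("breedvar"))),
    sprintf("# seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("# rare<%g common>%g genic_distance=%d window_size=%d",
            config$rare_threshold, config$common_threshold,
            as.integer(config$genic_distance), as.integer(window_size)))
}

write_stage_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_bed3 <- function(df, path) {
  utils::write.table(df[c("contig", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the full variant-catalog pipeline
#'
#' Stages: optional two-caller concordance (when `vcf_b` is given, the
#' downstream stages run on the intersection), per-sample and per-site
#' summaries, MAF spectrum, depth-adjusted estimated marginal means of
#' per-sample variant counts by breed, breed screens (breed-vs-rest,
#' unique/shared, no-homozygote, present-in-all, genic annotation when
#' gene intervals are given), the 10 kb window scan, and the closed-form
#' power report for the cohort size actually analyzed. A `MANIFEST` file
#' in `out_dir` lists every completed artifact; it is written
#' incrementally so a failed run shows which stages finished.
#'
#' @param vcf path to the (merged or caller-A) multi-sample VCF.
#' @param sheet_path path to the sample sheet TSV.
#' @param out_dir output directory (created if needed).
#' @param vcf_b optional second caller's VCF for concordance.
#' @param genes_path optional BED/GFF3 gene intervals.
#' @param config a [screen_config].
#' @param window_size window width for the density scan (bp).
#' @param seed recorded in output headers (the pipeline itself is
#'   deterministic; the seed matters when the VCF came from
#'   [generate_cohort]).
#' @return invisibly, the character vector of artifact paths.
#' @export
run_pipeline <- function(vcf, sheet_path, out_dir,
                         vcf_b = NULL, genes_path = NULL,
                         config = screen_config(), window_size = 10000,
                         seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- file.path(out_dir, "MANIFEST")
  artifacts <- character(0)
  note <- function(path) {
    artifacts <<- c(artifacts, path)
    writeLines(basename(artifacts), manifest_path)
    path
  }
  hdr <- provenance_header(seed, config, window_size)

  cs <- read_vcf(vcf)
  sheet <- read_sample_sheet(sheet_path)

  if (!is.null(vcf_b)) {
    cs_b <- read_vcf(vcf_b)
    inter <- intersect_callsets(cs, cs_b)
    uni <- union_callsets(cs, cs_b)
    conc <- rbind(cbind(callset = "A", as.data.frame(summarize_callset(cs))),
                  cbind(callset = "B", as.data.frame(summarize_callset(cs_b))),
                  cbind(callset = "union", as.data.frame(summarize_callset(uni))),
                  cbind(callset = "intersect",
                        as.data.frame(summarize_callset(inter))))
    note(write_stage_tsv(conc, file.path(out_dir, "concordance.tsv"), hdr))
    note(write_vcf(inter, file.path(out_dir, "intersect.vcf")))
    note(write_vcf(uni, file.path(out_dir, "union.vcf")))
    cs <- inter
  }

  note(write_stage_tsv(as.data.frame(summarize_callset(cs)),
                       file.path(out_dir, "callset_summary.tsv"), hdr))

  samp <- per_sample_summaries(cs, sheet)
  note(write_stage_tsv(samp, file.path(out_dir, "per_sample.tsv"), hdr))
  ss <- site_summaries(cs)
  note(write_stage_tsv(ss, file.path(out_dir, "per_site.tsv"), hdr))
  note(write_stage_tsv(maf_spectrum(ss),
                       file.path(out_dir, "maf_spectrum.tsv"), hdr))

  if (length(unique(samp$breed)) >= 2 && all(table(samp$breed) >= 2)) {
    em <- emmeans_by_breed(samp$n_variant_sites, samp$breed, samp$doc)
    note(write_stage_tsv(em, file.path(out_dir, "emmeans_variants.tsv"), hdr))
    em_h <- emmeans_by_breed(samp$n_hom_alt, samp$breed, samp$doc)
    note(write_stage_tsv(em_h, file.path(out_dir, "emmeans_homozygous.tsv"), hdr))
  }

  bat <- breed_af_table(cs, sheet, config)
  note(write_stage_tsv(breed_vs_rest_screens(bat, config),
                       file.path(out_dir, "breed_vs_rest.tsv"), hdr))
  su <- shared_and_unique(bat)
  note(write_stage_tsv(su$unique, file.path(out_dir, "unique_to_breed.tsv"), hdr))
  noh <- screen_no_homozygotes(cs)
  pia <- screen_present_in_all(cs)
  if (!is.null(genes_path)) {
    genes <- read_gene_intervals(genes_path)
    ann <- annotate_genic(cs, genes, config)
    gmap <- stats::setNames(ann$genic, site_keys(ann))
    noh$genic <- unname(gmap[site_keys(noh)])
    pia$present_in_all$genic <- unname(gmap[site_keys(pia$present_in_all)])
  }
  note(write_stage_tsv(noh, file.path(out_dir, "no_homozygotes.tsv"), hdr))
  note(write_stage_tsv(pia$present_in_all,
                       file.path(out_dir, "present_in_all.tsv"), hdr))
  note(write_stage_tsv(pia$homozygous_in_all,
                       file.path(out_dir, "homozygous_in_all.tsv"), hdr))

  win <- classify_windows(window_counts(cs, window_size))
  note(write_stage_tsv(win, file.path(out_dir, "windows.tsv"), hdr))
  note(write_bed3(win[win$classification == "high", , drop = FALSE],
                  file.path(out_dir, "high_windows.bed")))
  note(write_bed3(win[win$classification == "low", , drop = FALSE],
                  file.path(out_dir, "low_windows.bed")))

  n <- length(cs$samples)
  pow <- data.frame(
    maf = c(0.03, 0.005, 0.03, 0.005),
    quantity = c("detection_power", "detection_power",
                 "min_cohort_power_0.8", "min_cohort_power_0.8"),
    value = c(detection_power(0.03, n), detection_power(0.005, n),
              min_cohort_for_power(0.03, 0.8), min_cohort_for_power(0.005, 0.8)))
  pow <- rbind(pow, data.frame(maf = 0.03, quantity = "cohort_for_one_homozygote",
                               value = cohort_size_for_one_homozygote(0.03)))
  note(write_stage_tsv(pow, file.path(out_dir, "power.tsv"), hdr))

  invisible(artifacts)
}

#' Write the artifacts of a generated cohort to disk
#'
#' Emits the VCF, sample sheet TSV, gene BED and truth tables of a
#' [generate_cohort] result so the pipeline can be exercised from files.
#'
#' @param cohort result of [generate_cohort].
#' @param out_dir output directory (created if needed).
#' @return invisibly, named vector of the written paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
             sheet = file.path(out_dir, "samples.tsv"),
             genes = file.path(out_dir, "genes.bed"),
             truth_classes = file.path(out_dir, "truth_classes.tsv"),
             truth_freq = file.path(out_dir, "truth_site_freq.tsv"))
  write_vcf(cohort$callset, paths["vcf"])
  utils::write.table(cohort$sheet, paths["sheet"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- cohort$genes
  utils::write.table(data.frame(g$contig, g$start, g$end, g$gene_id),
                     paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(cohort$truth$classes, paths["truth_classes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$truth$site_freq, paths["truth_freq"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
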