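two_breed_callset <- function() {
  # breed1 samples s1,s2; breed2 samples s3,s4
  g <- matrix(c("0/1", "0/0", "1/1", "1/1",
                "0/0", "0/0", "0/1", "0/0",
                "0/1", "0/1", "0/0", "0/0"),
              nrow = 3, byrow = TRUE)
  cs <- toy_callset("c1", c(100L, 200L, 300L), c("A", "C", "G"),
                    c("G", "T", "A"), g,
                    samples = c("s1", "s2", "s3", "s4"),
                    contig_lengths = c(c1 = 1000))
  sheet <- data.frame(sample = paste0("s", 1:4),
                      breed = rep(c("breed1", "breed2"), each = 2),
                      doc = 10, stringsAsFactors = FALSE)
  list(cs = cs, sheet = sheet)
}

test_that("per-breed frequencies come from that breed's called alleles", {
  tb <- two_breed_callset()
  bat <- breed_af_table(tb$cs, tb$sheet)
  af1 <- bat$AC[1, ] / bat$AN[1, ]
  expect_equal(unname(af1), c(0.25, 1.0))
  expect_equal(unname(bat$maf[1, ]), c(0.25, 0.0))
  # rest-of-population MAF excludes the focal breed entirely
  expect_equal(unname(bat$rest_maf[1, "breed1"]), 0.0)   # rest = breed2, af 1
  expect_equal(unname(bat$rest_maf[1, "breed2"]), 0.25)
  expect_equal(unname(bat$n_breeds_present), c(2, 1, 1))
  expect_equal(rowSums(bat$AC), bat$cohort_AC)  # cohort AC = sum of breed ACs
})

test_that("a single-breed cohort has undefined rest-of-population MAF", {
  tb <- two_breed_callset()
  sheet <- tb$sheet
  sheet$breed <- "only"
  bat <- breed_af_table(tb$cs, sheet)
  expect_true(all(is.na(bat$rest_maf)))
})

test_that("per-breed frequency estimates track the drifted truth", {
  cfg <- cohort_config(n_breeds = 4, samples_per_breed = 40, n_sites = 400,
                       contig_lengths = c(chr1 = 1e5),
                       missingness_d0 = NULL, seed = 53)
  co <- generate_cohort(cfg)
  bat <- breed_af_table(co$callset, co$sheet)
  q_b <- as.matrix(co$truth$site_freq[, bat$breeds])
  af <- bat$AC / bat$AN
  sd3 <- 3 * sqrt(q_b * (1 - q_b) / bat$AN)
  expect_gt(mean(abs(af - q_b) <= sd3 + 1e-12), 0.98)
})

test_that("MAF classes use strict thresholds", {
  cfg <- screen_config()
  expect_identical(classify_maf(c(0.02, 0.15, 0.03, 0.10, 0.05, NA), cfg),
                   c("rare", "common", "intermediate", "intermediate",
                     "intermediate", NA))
})

test_that("pairwise discrepancies select rare-in-one common-in-other sites", {
  tb <- two_breed_callset()
  bat <- breed_af_table(tb$cs, tb$sheet)
  pd <- pairwise_discrepancies(bat, "breed1", "breed2")
  # sites 100, 300: common in breed1 (maf 0.25 / 0.5), rare in breed2 (maf 0)
  expect_setequal(pd$rare_j_common_i$pos, c(100L, 300L))
  # site 200: rare in breed1 (maf 0), common in breed2 (maf 0.25)
  expect_identical(pd$rare_i_common_j$pos, 200L)
})

test_that("breed-vs-rest screens catch breed-specific rare and common sites", {
  g <- matrix(c("0/0", "0/0", "0/1", "0/1",   # rare in b1, common in rest
                "0/1", "0/1", "0/0", "0/0"),  # common in b1, rare in rest
              nrow = 2, byrow = TRUE)
  cs <- toy_callset("c1", c(10L, 20L), c("A", "C"), c("G", "T"), g,
                    samples = paste0("s", 1:4), contig_lengths = c(c1 = 100))
  sheet <- data.frame(sample = paste0("s", 1:4),
                      breed = rep(c("b1", "b2"), each = 2), doc = 10)
  sc <- breed_vs_rest_screens(breed_af_table(cs, sheet))
  b1 <- sc[sc$breed == "b1", ]
  expect_identical(b1$class[b1$pos == 10], "breed_specific_rare")
  expect_identical(b1$class[b1$pos == 20], "breed_specific_common")
})

test_that("shared and unique sets partition by breed presence", {
  g <- matrix(c("0/1", "1/1", "0/0", "0/0", "0/0", "0/0",
                "0/1", "0/0", "0/1", "0/1", "1/1", "0/0"),
              nrow = 2, byrow = TRUE)
  cs <- toy_callset("c1", c(10L, 20L), c("A", "C"), c("G", "T"), g,
                    samples = paste0("s", 1:6), contig_lengths = c(c1 = 100))
  sheet <- data.frame(sample = paste0("s", 1:6),
                      breed = rep(c("b1", "b2", "b3"), each = 2), doc = 10)
  su <- shared_and_unique(breed_af_table(cs, sheet))
  expect_identical(su$unique$pos, 10L)
  expect_identical(su$unique$breed, "b1")
  expect_identical(su$shared$pos, 20L)
  expect_identical(su$shared$n_breeds_present, 3)
})

test_that("genic annotation applies the distance rule at exact boundaries", {
  genes <- data.frame(contig = "c1", start = 10000L, end = 12000L,
                      gene_id = "gX")
  cfg <- screen_config(genic_distance = 5000)
  sites <- data.frame(contig = "c1", pos = c(8000L, 4999L, 5001L, 11000L, 17000L, 17001L),
                      ref = "A", alt = "G")
  ann <- annotate_genic(sites, genes, cfg)
  expect_identical(ann$genic, c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(ann$gene_ids[4], "gX")
  sites2 <- data.frame(contig = "c9", pos = 100L, ref = "A", alt = "G")
  expect_warning(ann2 <- annotate_genic(sites2, genes, cfg), "c9")
  expect_false(ann2$genic)
})

test_that("no-homozygote screen keeps het-only sites with AF <= 0.5", {
  g <- matrix(c("0/1", "0/1", "0/0",
                "0/1", "1/1", "0/0",
                "0/1", "0/1", "0/1"),
              nrow = 3, byrow = TRUE)
  cs <- toy_callset("c1", c(10L, 20L, 30L), c("A", "C", "G"),
                    c("G", "T", "A"), g, contig_lengths = c(c1 = 100))
  noh <- screen_no_homozygotes(cs)
  expect_setequal(noh$pos, c(10L, 30L))
  expect_equal(noh$af[noh$pos == 30], 0.5)  # het in every sample
  set.seed(59)
  rcs <- random_callset(300, 10)
  rn <- screen_no_homozygotes(rcs)
  expect_true(all(rn$af <= 0.5))
  expect_setequal(site_keys(rn), brute_no_homozygotes(rcs))
})

test_that("present-in-all requires a called carrier genotype in every sample", {
  g <- matrix(c("1/1", "1/1",
                "0/1", "1/1",
                "0/1", "./.",
                "0/1", "0/0"),
              nrow = 4, byrow = TRUE)
  cs <- toy_callset("c1", c(10L, 20L, 30L, 40L), c("A", "C", "G", "T"),
                    c("G", "T", "A", "C"), g, contig_lengths = c(c1 = 100))
  sc <- screen_present_in_all(cs)
  expect_setequal(sc$present_in_all$pos, c(10L, 20L))
  expect_identical(sc$homozygous_in_all$pos, 10L)
  # a missing genotype disqualifies from both sets
  expect_false(30L %in% sc$present_in_all$pos)
  set.seed(61)
  rcs <- random_callset(300, 6)
  rsc <- screen_present_in_all(rcs)
  o <- brute_present_in_all(rcs)
  expect_setequal(site_keys(rsc$present_in_all), o$present_in_all)
  expect_setequal(site_keys(rsc$homozygous_in_all), o$homozygous_in_all)
  expect_true(all(site_keys(rsc$homozygous_in_all) %in%
                  site_keys(rsc$present_in_all)))
})

test_that("injected truth classes are recovered from a generated cohort", {
  cfg <- cohort_config(n_breeds = 3, samples_per_breed = 8, n_sites = 4000,
                       contig_lengths = c(chr1 = 4e5),
                       injections = inject_counts(6, 8, 5, 4), seed = 67)
  co <- generate_cohort(cfg)
  cs <- co$callset
  tr <- co$truth$classes
  tr_key <- paste(tr$contig, tr$pos, tr$ref, tr$alt, sep = ":")
  noh <- site_keys(screen_no_homozygotes(cs))
  sc <- screen_present_in_all(cs)
  bat <- breed_af_table(cs, co$sheet)
  su <- shared_and_unique(bat)
  expect_true(all(tr_key[tr$class == "no_homozygote"] %in% noh))
  expect_true(all(tr_key[tr$class == "present_in_all"] %in%
                  site_keys(sc$present_in_all)))
  expect_true(all(tr_key[tr$class == "homozygous_in_all"] %in%
                  site_keys(sc$homozygous_in_all)))
  bu <- tr[tr$class == "breed_unique", ]
  m <- match(paste(bu$contig, bu$pos, bu$ref, bu$alt, sep = ":"),
             site_keys(su$unique))
  expect_false(anyNA(m))
  expect_identical(su$unique$breed[m], bu$breed)
})
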