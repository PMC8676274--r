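sheet_for <- function(cs, breed = "b1", doc = 10) {
  data.frame(sample = cs$samples,
             breed = rep_len(breed, length(cs$samples)),
             doc = rep_len(doc, length(cs$samples)),
             stringsAsFactors = FALSE)
}

test_that("per-sample counts split carried sites into het and hom-alt", {
  cs <- toy_callset("c1", c(10L, 20L, 30L), rep("A", 3), rep("G", 3),
                    matrix(c("0/1", "1/1", "0/0"), 3, 1))
  s <- per_sample_summaries(cs, sheet_for(cs))
  expect_identical(s$n_variant_sites, 2)
  expect_identical(s$n_het, 1)
  expect_identical(s$n_hom_alt, 1)
  expect_equal(s$missingness, 0)

  cs2 <- toy_callset("c1", c(10L, 20L), c("A", "C"), c("G", "T"),
                     matrix("./.", 2, 1))
  s2 <- per_sample_summaries(cs2, sheet_for(cs2))
  expect_equal(s2$missingness, 1)
  expect_identical(s2$n_variant_sites, 0)
  cs3 <- toy_callset("c1", 10L, "A", "G", matrix("0/1"))
  expect_error(per_sample_summaries(cs3, data.frame(sample = "zz", breed = "b",
                                                    doc = 1)), "absent")
})

test_that("per-sample and per-site tallies agree with brute-force loops", {
  set.seed(31)
  cs <- random_callset(400, 12)
  samp <- per_sample_summaries(cs, sheet_for(cs))
  sites <- site_summaries(cs)
  o_samp <- brute_sample_rows(cs)
  o_site <- brute_site_rows(cs)
  expect_equal(samp$n_het, unname(o_samp[, "n_het"]))
  expect_equal(samp$n_hom_alt, unname(o_samp[, "n_hom_alt"]))
  expect_equal(samp$missingness, unname(o_samp[, "n_missing"]) / n_sites(cs))
  expect_equal(sites$AC, unname(o_site[, "AC"]))
  expect_equal(sites$AN, unname(o_site[, "AN"]))
  expect_equal(sites$missingness, unname(o_site[, "miss"]) / n_samples(cs))
  # double-counting identities
  expect_equal(sum(samp$n_het), summarize_callset(cs)$n_het)
  expect_equal(sum(samp$missingness) * n_sites(cs),
               sum(sites$missingness) * n_samples(cs))
})

test_that("HWE carrier expectation matches simulated per-sample counts", {
  cfg <- cohort_config(n_breeds = 3, samples_per_breed = 50, n_sites = 5000,
                       contig_lengths = c(chr1 = 1e6),
                       F_per_breed = rep(0, 3), missingness_d0 = NULL,
                       seed = 17)
  co <- generate_cohort(cfg)
  q <- co$truth$site_freq$q
  p_carrier <- 2 * q - q^2  # 1 - (1-q)^2
  expected <- sum(p_carrier)
  samp <- per_sample_summaries(co$callset, co$sheet)
  se_mean <- sqrt(sum(p_carrier * (1 - p_carrier))) / sqrt(nrow(samp))
  expect_lt(abs(mean(samp$n_variant_sites) - expected), 3 * se_mean)
})

test_that("MAF spectrum bins fold correctly and the neutral spectrum decays", {
  sites <- data.frame(AC = c(1, 2, 10, 0), AN = c(100, 50, 50, 0),
                      maf = c(0.01, 0.04, 0.2, NA))
  expect_message(sp <- maf_spectrum(sites, 0.05), "AN = 0")
  expect_identical(sum(sp$count), 3L)
  expect_identical(sp$count[1], 2L)
  expect_equal(maf_fraction_below(sites, 0.05), 2 / 3)
  expect_error(maf_spectrum(sites, 0.07), "divide")
  # monomorphic: everything in the first bin
  mono <- data.frame(AC = c(0, 0), AN = c(10, 10), maf = c(0, 0))
  expect_identical(maf_spectrum(mono, 0.05)$count[1], 2L)
  # a MAF of exactly 0.5 lands in the closed last bin
  half <- data.frame(AC = 5, AN = 10, maf = 0.5)
  expect_identical(maf_spectrum(half, 0.05)$count[10], 1L)

  cfg <- cohort_config(n_breeds = 2, samples_per_breed = 40, n_sites = 20000,
                       contig_lengths = c(chr1 = 2e6),
                       F_per_breed = c(0, 0), seed = 23)
  co <- generate_cohort(cfg)
  sp2 <- maf_spectrum(site_summaries(co$callset))
  expect_identical(which.max(sp2$count), 1L)
  expect_lt(cor(seq_len(10), sp2$count, method = "spearman"), 0)
})

test_that("variant and heterozygosity rates per kb use the genome length", {
  set.seed(5)
  cs <- random_callset(2000, 3, contig_lengths = c(c1 = 6e5, c2 = 4e5))
  expect_equal(variants_per_kb(cs), 2.0)
  samp <- per_sample_summaries(cs, sheet_for(cs))
  r <- per_sample_rates(samp, cs)
  expect_equal(r$het_per_kb, samp$n_het / 1000)
  expect_equal(mean(r$variants_per_kb),
               mean(samp$n_variant_sites) / 1000)
})

test_that("depth association: monotone counts give rank correlation 1", {
  s <- data.frame(doc = c(2, 5, 9, 14, 30),
                  n_variant_sites = c(100, 300, 500, 600, 640))
  a <- doc_association(s)
  expect_equal(a$rho, 1.0)
  expect_true(is.finite(a$a) && is.finite(a$b))
  expect_error(doc_association(s[1:2, ]), "3 samples")
  s$doc <- 7
  expect_warning(a2 <- doc_association(s), "constant")
  expect_true(is.na(a2$rho))
})

test_that("depth association is null under permutation", {
  set.seed(19)
  n <- 1000
  s <- data.frame(doc = rgamma(n, 2, 0.2),
                  n_variant_sites = sample(rpois(n, 500)))
  a <- doc_association(s)
  expect_lt(abs(a$rho), 3 / sqrt(n))
})

test_that("the saturating-curve fit recovers the generator's dropout scale", {
  cfg <- cohort_config(n_breeds = 10, samples_per_breed = 20, n_sites = 5000,
                       contig_lengths = c(chr1 = 1e6),
                       missingness_d0 = 2, seed = 29)
  co <- generate_cohort(cfg)
  samp <- per_sample_summaries(co$callset, co$sheet)
  samp$doc <- co$truth$doc[samp$sample]  # exact depths, not the rounded sheet
  a <- doc_association(samp)
  expect_gt(a$rho, 0)
  expect_lt(abs(a$b - 2) / 2, 0.5)  # within 50% of d0
})

test_that("constant depth makes estimated marginal means equal raw means", {
  set.seed(37)
  breed <- rep(c("A", "B", "C"), each = 10)
  y <- rnorm(30, mean = rep(c(10, 20, 30), each = 10))
  em <- emmeans_by_breed(y, breed, doc = rep(7, 30))
  expect_equal(em$emmean, as.numeric(tapply(y, breed, mean)), tolerance = 1e-10)
  expect_true(all(em$lower <= em$emmean & em$emmean <= em$upper))
})

test_that("estimated marginal means recover a simulated breed offset", {
  set.seed(41)
  n <- 50
  breed <- rep(c("A", "B"), each = n)
  doc <- rgamma(2 * n, 4, 0.4)
  y <- 100 * (breed == "B") + 10 * doc + rnorm(2 * n)
  em <- emmeans_by_breed(y, breed, doc)
  diff <- em$emmean[em$breed == "B"] - em$emmean[em$breed == "A"]
  se <- sqrt(sum(em$se^2))
  expect_lt(abs(diff - 100), 3 * se)
  # agrees with a hand-computed least-squares evaluation at the mean depth
  man <- manual_emmeans(y, breed, doc)
  expect_equal(em$emmean, man$emmean, tolerance = 1e-8)
  expect_equal(em$se, man$se, tolerance = 1e-8)
  expect_equal(em$lower, man$lower, tolerance = 1e-8)
})

test_that("identically generated breeds give overlapping intervals", {
  set.seed(43)
  overlaps <- replicate(500, {
    breed <- rep(c("A", "B"), each = 10)
    doc <- rgamma(20, 4, 0.4)
    y <- 5 * doc + rnorm(20)
    em <- emmeans_by_breed(y, breed, doc)
    em$lower[1] <= em$upper[2] && em$lower[2] <= em$upper[1]
  })
  expect_gte(mean(overlaps), 0.94)
})

test_that("singular and degenerate designs are rejected", {
  breed <- rep(c("A", "B"), each = 5)
  y <- rnorm(10)
  expect_error(emmeans_by_breed(y, rep("A", 10), rnorm(10)), "2 breeds")
  expect_error(emmeans_by_breed(y[1:3], c("A", "A", "B"), rnorm(3)),
               "2 samples per breed")
  doc_conf <- ifelse(breed == "A", 5, 9)  # depth confounded with breed
  expect_error(emmeans_by_breed(y, breed, doc_conf), "singular")
})

test_that("singletons are exactly the AC == 1 sites", {
  sites <- data.frame(contig = "c1", pos = 1:4, ref = "A", alt = "G",
                      AC = c(1, 2, 1, 5), AN = c(10, 10, 2, 10),
                      maf = c(0.1, 0.2, 0.5, 0.5))
  sg <- singleton_catalog(sites)
  expect_identical(nrow(sg), 2L)
  expect_true(all(sg$AC == 1))
  # AC = 1 with only one sample called is still a singleton
  expect_true(3 %in% sg$pos)
  set.seed(47)
  cs <- random_callset(500, 10)
  ss <- site_summaries(cs)
  o <- brute_site_rows(cs)
  expect_identical(singleton_catalog(ss)$pos,
                   ss$pos[o[, "AC"] == 1 & o[, "AN"] > 0])
})
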