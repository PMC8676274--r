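# Fixture builders and independent brute-force oracles. The oracles
# recompute every statistic with plain per-site / per-sample loops so the
# vectorized implementations are checked against a second, simpler route.

# build allele matrices from genotype strings like "0/1", "./.", "0/."
gt_from_strings <- function(strs) {
  m <- as.matrix(strs)
  code <- function(x) suppressWarnings(as.integer(x))
  a <- matrix(code(sub("/.*$", "", m)), nrow = nrow(m))
  b <- matrix(code(sub("^.*/", "", m)), nrow = nrow(m))
  list(a = a, b = b)
}

toy_callset <- function(contig, pos, ref, alt, gt_strs,
                        samples = NULL, contig_lengths = NULL, ...) {
  gt <- gt_from_strings(gt_strs)
  contig <- rep_len(contig, length(pos))
  ref <- rep_len(ref, length(pos))
  alt <- rep_len(alt, length(pos))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(gt$a)))
  if (is.null(contig_lengths)) {
    contig_lengths <- tapply(pos + nchar(ref) + 10, contig, max)
    contig_lengths <- structure(as.numeric(contig_lengths),
                                names = names(contig_lengths))
  }
  sites <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE, ...)
  callset(sites, gt$a, gt$b, samples, contig_lengths)
}

# random biallelic callset for property tests (keys drawn from a shared
# pool so two draws overlap)
random_callset <- function(n_sites, n_samples, contig_lengths = c(c1 = 5e4),
                           pool_size = 2 * n_sites) {
  pool_pos <- sample.int(contig_lengths[[1]] - 10, pool_size)
  idx <- sample(pool_size, n_sites)
  pos <- sort(pool_pos[idx])
  bases <- c("A", "C", "G", "T")
  ref <- bases[(pos %% 4) + 1]                  # key-determined alleles so
  alt <- bases[((pos %/% 4) %% 3 + 1 + (pos %% 4)) %% 4 + 1]  # shared pools agree
  fix <- alt == ref
  alt[fix] <- bases[((pos[fix] + 1) %% 4) + 1]
  alt[alt == ref] <- "N"
  g <- matrix(sample(c("0/0", "0/1", "1/1", "./."), n_sites * n_samples,
                     replace = TRUE, prob = c(0.5, 0.3, 0.15, 0.05)),
              nrow = n_sites)
  toy_callset(rep(names(contig_lengths)[1], n_sites), pos, ref, alt, g,
              contig_lengths = contig_lengths)
}

subset_sites_for_test <- function(cs, idx) {
  callset(cs$sites[idx, , drop = FALSE], cs$gt_a[idx, , drop = FALSE],
          cs$gt_b[idx, , drop = FALSE], cs$samples, cs$contig_lengths)
}

# ---- brute-force oracles ----------------------------------------------

gt_pair <- function(cs, i, s) c(cs$gt_a[i, s], cs$gt_b[i, s])
is_called_pair <- function(g) !anyNA(g)

brute_summarize <- function(cs) {
  n_ts <- 0L; n_tv <- 0L; n_snp <- 0L; n_indel <- 0L; n_other <- 0L
  ts_pairs <- c("A>G", "G>A", "C>T", "T>C")
  for (i in seq_len(nrow(cs$sites))) {
    r <- cs$sites$ref[i]; a <- cs$sites$alt[i]
    if (nchar(r) != nchar(a)) n_indel <- n_indel + 1L
    else if (nchar(r) == 1L) {
      n_snp <- n_snp + 1L
      if (paste0(r, ">", a) %in% ts_pairs) n_ts <- n_ts + 1L
      else n_tv <- n_tv + 1L
    } else n_other <- n_other + 1L
  }
  n_het <- 0L; n_hom <- 0L
  for (i in seq_len(nrow(cs$sites))) for (s in seq_along(cs$samples)) {
    g <- gt_pair(cs, i, s)
    if (is_called_pair(g)) {
      if (sum(g) == 1L) n_het <- n_het + 1L
      if (sum(g) == 2L) n_hom <- n_hom + 1L
    }
  }
  list(n_variants = nrow(cs$sites), n_snps = n_snp, n_indels = n_indel,
       n_other = n_other, n_ts = n_ts, n_tv = n_tv,
       ts_tv = if (n_tv > 0) n_ts / n_tv else NA_real_,
       n_het = n_het, n_hom_alt = n_hom,
       het_nrhom = if (n_hom > 0) n_het / n_hom else NA_real_)
}

brute_site_rows <- function(cs) {
  t(vapply(seq_len(nrow(cs$sites)), function(i) {
    ac <- 0L; an <- 0L; miss <- 0L
    for (s in seq_along(cs$samples)) {
      g <- gt_pair(cs, i, s)
      if (is_called_pair(g)) { ac <- ac + sum(g); an <- an + 2L }
      else miss <- miss + 1L
    }
    c(AC = ac, AN = an, miss = miss)
  }, c(AC = 0, AN = 0, miss = 0)))
}

brute_sample_rows <- function(cs) {
  t(vapply(seq_along(cs$samples), function(s) {
    het <- 0L; hom <- 0L; miss <- 0L
    for (i in seq_len(nrow(cs$sites))) {
      g <- gt_pair(cs, i, s)
      if (!is_called_pair(g)) miss <- miss + 1L
      else if (sum(g) == 1L) het <- het + 1L
      else if (sum(g) == 2L) hom <- hom + 1L
    }
    c(n_het = het, n_hom_alt = hom, n_missing = miss)
  }, c(n_het = 0, n_hom_alt = 0, n_missing = 0)))
}

brute_breed_ac <- function(cs, sheet, breed) {
  cols <- which(sheet$breed[match(cs$samples, sheet$sample)] == breed)
  t(vapply(seq_len(nrow(cs$sites)), function(i) {
    ac <- 0L; an <- 0L
    for (s in cols) {
      g <- gt_pair(cs, i, s)
      if (is_called_pair(g)) { ac <- ac + sum(g); an <- an + 2L }
    }
    c(AC = ac, AN = an)
  }, c(AC = 0, AN = 0)))
}

brute_no_homozygotes <- function(cs) {
  keep <- logical(nrow(cs$sites))
  for (i in seq_len(nrow(cs$sites))) {
    het <- 0L; hom <- 0L
    for (s in seq_along(cs$samples)) {
      g <- gt_pair(cs, i, s)
      if (is_called_pair(g)) {
        if (sum(g) == 1L) het <- het + 1L
        if (sum(g) == 2L) hom <- hom + 1L
      }
    }
    keep[i] <- het >= 1L && hom == 0L
  }
  site_keys(cs)[keep]
}

brute_present_in_all <- function(cs) {
  pia <- logical(nrow(cs$sites)); hia <- logical(nrow(cs$sites))
  for (i in seq_len(nrow(cs$sites))) {
    all_called <- TRUE; all_carry <- TRUE; all_hom <- TRUE
    for (s in seq_along(cs$samples)) {
      g <- gt_pair(cs, i, s)
      if (!is_called_pair(g)) { all_called <- FALSE; break }
      if (sum(g) == 0L) all_carry <- FALSE
      if (sum(g) != 2L) all_hom <- FALSE
    }
    pia[i] <- all_called && all_carry
    hia[i] <- all_called && all_hom
  }
  list(present_in_all = site_keys(cs)[pia], homozygous_in_all = site_keys(cs)[hia])
}

brute_window_counts <- function(cs, ws) {
  out <- list()
  for (ct in names(cs$contig_lengths)) {
    n_win <- max(1, ceiling(cs$contig_lengths[[ct]] / ws))
    cnt <- integer(n_win)
    for (i in seq_len(nrow(cs$sites))) {
      if (cs$sites$contig[i] == ct) {
        w <- (cs$sites$pos[i] - 1) %/% ws + 1
        cnt[w] <- cnt[w] + 1L
      }
    }
    out[[ct]] <- cnt
  }
  out
}

# hand-rolled EMMEAN at grand-mean covariate, from the lm fit directly
manual_emmeans <- function(response, breed, doc, conf_level = 0.95) {
  breed <- factor(breed)
  fit <- stats::lm(response ~ breed + doc)
  X <- vapply(levels(breed), function(b) {
    v <- c(1, as.numeric(levels(breed)[-1] == b), mean(doc))
    v
  }, numeric(nlevels(breed) + 1))
  est <- as.numeric(t(X) %*% stats::coef(fit))
  se <- sqrt(diag(t(X) %*% stats::vcov(fit) %*% X))
  tq <- stats::qt(1 - (1 - conf_level) / 2, fit$df.residual)
  data.frame(breed = levels(breed), emmean = est, se = se,
             lower = est - tq * se, upper = est + tq * se,
             stringsAsFactors = FALSE)
}

inject_counts <- function(bu = 0, nh = 0, pa = 0, ha = 0) {
  c(breed_unique = bu, no_homozygote = nh, present_in_all = pa,
    homozygous_in_all = ha)
}
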