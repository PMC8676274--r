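# Synthetic multi-breed diploid cohort generator.
#
# The generator emulates the structure of a multi-breed WGS variant catalog:
# an ancestral neutral allele-frequency spectrum (density ~ 1/q), per-breed
# frequencies drifted under the Balding-Nichols Beta model, Hardy-Weinberg
# genotypes, a controlled transition fraction among SNVs, an SNP/indel mix,
# gamma-distributed per-sample depth of coverage with depth-dependent
# genotype dropout, and injected ground-truth variant classes so every
# downstream screen can be validated exactly.

# run expr with a private RNG stream; caller's RNG state is untouched
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the design of a multi-breed horse WGS survey at desk
#' scale: 10 breeds of 15 diploid individuals, a cohort variant density of
#' about 12.5 sites per kb (so a 10 kb window carries ~125 variants), a
#' transition fraction of 0.66 among SNVs (TsTv ~ 1.94), a 7% indel share,
#' depth of coverage drawn from a gamma law with mean 11.5X, and genotype
#' dropout probability `exp(-doc/d0)` with `d0 = 2` (about 1% missingness at
#' the median depth).
#'
#' @param n_breeds number of breeds.
#' @param samples_per_breed diploid individuals per breed.
#' @param contig_lengths named vector of contig lengths (bp).
#' @param n_sites total variant sites to simulate.
#' @param q_min,q_max truncation bounds of the ancestral frequency spectrum.
#' @param F_per_breed Balding-Nichols drift coefficient per breed in `[0,1)`;
#'   default spreads 0.05-0.20 across breeds.
#' @param ts_fraction probability that a simulated SNV is a transition.
#' @param indel_fraction probability that a site is an indel.
#' @param doc_shape,doc_mean gamma shape and mean of per-sample depth (X);
#'   draws are floored at 1X.
#' @param missingness_d0 depth scale of the dropout curve `exp(-doc/d0)`;
#'   `NULL` disables missingness.
#' @param injections named counts of truth classes to inject:
#'   `breed_unique`, `no_homozygote`, `present_in_all`, `homozygous_in_all`.
#' @param window_multipliers optional data.frame (`contig`, `window`,
#'   `multiplier`) scaling site placement density in 0-based
#'   `window_size`-bp windows.
#' @param window_size window width used for density multipliers (bp).
#' @param n_genes random gene intervals to emit for genic annotation.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_breeds = 10, samples_per_breed = 15,
                          contig_lengths = c(chr1 = 2e6, chr2 = 2e6),
                          n_sites = 50000,
                          q_min = 0.001, q_max = 1,
                          F_per_breed = NULL,
                          ts_fraction = 0.66, indel_fraction = 0.07,
                          doc_shape = 1.54, doc_mean = 11.5,
                          missingness_d0 = 2,
                          injections = c(breed_unique = 0, no_homozygote = 0,
                                         present_in_all = 0,
                                         homozygous_in_all = 0),
                          window_multipliers = NULL,
                          window_size = 10000,
                          n_genes = 40,
                          seed = 1) {
  if (is.null(F_per_breed))
    F_per_breed <- seq(0.05, 0.20, length.out = n_breeds)
  inj <- c(breed_unique = 0, no_homozygote = 0, present_in_all = 0,
           homozygous_in_all = 0)
  inj[names(injections)] <- injections
  cfg <- list(n_breeds = as.integer(n_breeds),
              samples_per_breed = as.integer(samples_per_breed),
              contig_lengths = contig_lengths, n_sites = as.integer(n_sites),
              q_min = q_min, q_max = q_max, F_per_breed = F_per_breed,
              ts_fraction = ts_fraction, indel_fraction = indel_fraction,
              doc_shape = doc_shape, doc_mean = doc_mean,
              missingness_d0 = missingness_d0, injections = inj,
              window_multipliers = window_multipliers,
              window_size = as.integer(window_size),
              n_genes = as.integer(n_genes), seed = as.integer(seed))
  stopifnot(cfg$n_breeds >= 1, cfg$samples_per_breed >= 1, cfg$n_sites >= 0,
            cfg$q_min > 0, cfg$q_min <= cfg$q_max, cfg$q_max <= 1,
            all(cfg$F_per_breed >= 0), all(cfg$F_per_breed < 1),
            length(cfg$F_per_breed) == cfg$n_breeds,
            cfg$ts_fraction >= 0, cfg$ts_fraction <= 1,
            cfg$indel_fraction >= 0, cfg$indel_fraction <= 1,
            all(inj >= 0), is.null(missingness_d0) || missingness_d0 > 0)
  if (!is.null(window_multipliers)) {
    stopifnot(all(c("contig", "window", "multiplier") %in%
                  names(window_multipliers)),
              all(window_multipliers$multiplier > 0))
  }
  if (sum(inj) > cfg$n_sites) stop("requested injections exceed n_sites")
  class(cfg) <- "cohort_config"
  cfg
}

#' Draw ancestral allele frequencies from a truncated neutral spectrum
#'
#' Density proportional to `1/q` on `[q_min, q_max]`, realized by the
#' inverse-CDF map `q = q_min * (q_max/q_min)^u`, `u ~ Uniform(0,1)` (so
#' `log q` is uniform). This spectrum makes the cohort-aggregate
#' heterozygous / non-reference-homozygous genotype ratio of an HWE cohort
#' equal `2(1-a)/(1+a)` at truncation `a`, i.e. the classical expectation
#' of 2 for small `a`.
#'
#' @param n number of draws.
#' @param q_min,q_max truncation bounds, `0 < q_min <= q_max <= 1`.
#' @return numeric vector in `[q_min, q_max]`.
#' @export
sample_ancestral_frequencies <- function(n, q_min = 0.001, q_max = 1) {
  stopifnot(q_min > 0, q_min <= q_max, q_max <= 1)
  if (q_min == q_max) return(rep(q_min, n))
  q_min * (q_max / q_min)^stats::runif(n)
}

#' Drift an ancestral frequency into per-breed frequencies
#'
#' Balding-Nichols model: `q_b ~ Beta(q(1-F)/F, (1-q)(1-F)/F)`, which has
#' mean `q` and variance `F q (1-q)`. `F = 0` returns `q` unchanged, as do
#' fixed frequencies (`q` of 0 or 1).
#'
#' @param q ancestral frequency vector.
#' @param F_b drift coefficient in `[0, 1)` (scalar).
#' @return vector of drifted frequencies, same length as `q`.
#' @export
breed_frequencies <- function(q, F_b) {
  stopifnot(F_b >= 0, F_b < 1)
  if (F_b == 0) return(q)
  out <- q
  idx <- q > 0 & q < 1
  if (any(idx)) {
    s <- (1 - F_b) / F_b
    out[idx] <- stats::rbeta(sum(idx), q[idx] * s, (1 - q[idx]) * s)
  }
  out
}

#' Draw Hardy-Weinberg diploid genotypes
#'
#' Each genotype is two independent Bernoulli(`q`) alleles, giving genotype
#' proportions `(1-q)^2`, `2q(1-q)`, `q^2`.
#'
#' @param q allele frequency: scalar, per-site vector, or a sites x samples
#'   matrix of per-sample frequencies.
#' @param n_samples number of individuals (ignored when `q` is a matrix).
#' @return list with integer matrices `a` and `b` (sites x samples).
#' @export
draw_genotypes_hwe <- function(q, n_samples = NULL) {
  if (is.matrix(q)) {
    p <- q
  } else {
    stopifnot(!is.null(n_samples))
    p <- matrix(q, nrow = length(q), ncol = n_samples)
  }
  stopifnot(all(p >= 0 & p <= 1))
  dr <- function() matrix(stats::rbinom(length(p), 1L, p), nrow = nrow(p))
  list(a = dr(), b = dr())
}

#' Apply depth-dependent genotype dropout
#'
#' Each sample's genotype at each site is set missing independently with
#' probability `exp(-doc/d0)`: missingness declines non-linearly with depth
#' of coverage and saturates near zero past a few multiples of `d0`.
#'
#' @param gt list with matrices `a`, `b` as from [draw_genotypes_hwe].
#' @param doc per-sample depth of coverage (length = ncol).
#' @param d0 depth scale (> 0) of the dropout curve.
#' @return `gt` with both alleles of dropped genotypes set `NA`.
#' @export
apply_missingness <- function(gt, doc, d0) {
  stopifnot(d0 > 0, length(doc) == ncol(gt$a))
  p_miss <- exp(-doc / d0)
  drop <- matrix(stats::rbinom(length(gt$a), 1L,
                               rep(p_miss, each = nrow(gt$a))) == 1L,
                 nrow = nrow(gt$a))
  gt$a[drop] <- NA_integer_
  gt$b[drop] <- NA_integer_
  gt
}

# --- allele construction -----------------------------------------------

BASES <- c("A", "C", "G", "T")
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

draw_alleles <- function(n, ts_fraction, indel_fraction) {
  is_indel <- stats::runif(n) < indel_fraction
  ref <- sample(BASES, n, replace = TRUE)
  alt <- character(n)
  # SNVs: transition with prob ts_fraction, else one of the two transversions
  snv <- !is_indel
  is_ts <- stats::runif(n) < ts_fraction
  alt[snv & is_ts] <- TRANSITION_OF[ref[snv & is_ts]]
  tv_idx <- which(snv & !is_ts)
  if (length(tv_idx)) {
    alt[tv_idx] <- vapply(ref[tv_idx], function(r) {
      sample(setdiff(BASES, c(r, TRANSITION_OF[[r]])), 1L)
    }, character(1))
  }
  # indels: 1-5 bp insertions or deletions anchored on the ref base
  ind_idx <- which(is_indel)
  if (length(ind_idx)) {
    len <- sample(1:5, length(ind_idx), replace = TRUE)
    ins <- stats::runif(length(ind_idx)) < 0.5
    extra <- vapply(len, function(l)
      paste(sample(BASES, l, replace = TRUE), collapse = ""), character(1))
    alt[ind_idx[ins]] <- paste0(ref[ind_idx[ins]], extra[ins])
    ref[ind_idx[!ins]] <- paste0(ref[ind_idx[!ins]], extra[!ins])
    alt[ind_idx[!ins]] <- substr(ref[ind_idx[!ins]], 1L, 1L)
  }
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# place n sites across window-weighted genome positions; unique per contig
draw_positions <- function(n, contig_lengths, window_size, multipliers) {
  win <- do.call(rbind, lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    n_win <- ceiling(len / window_size)
    start <- (seq_len(n_win) - 1L) * window_size
    data.frame(contig = ct, window = seq_len(n_win) - 1L, start = start,
               width = pmin(start + window_size, len) - start,
               mult = 1, stringsAsFactors = FALSE)
  }))
  if (!is.null(multipliers)) {
    m <- match(paste(win$contig, win$window),
               paste(multipliers$contig, multipliers$window))
    hit <- !is.na(m)
    win$mult[hit] <- multipliers$multiplier[m[hit]]
  }
  w <- win$width * win$mult
  cnt <- as.vector(stats::rmultinom(1, n, prob = w / sum(w)))
  over <- cnt > win$width
  if (any(over)) stop("window too dense: more sites than positions")
  pos <- integer(0); contig <- character(0)
  for (i in which(cnt > 0)) {
    pos <- c(pos, win$start[i] + sample.int(win$width[i], cnt[i]))  # 1-based
    contig <- c(contig, rep(win$contig[i], cnt[i]))
  }
  data.frame(contig = contig, pos = pos, stringsAsFactors = FALSE)
}

#' Generate a synthetic multi-breed cohort with ground truth
#'
#' Produces a decomposed biallelic [callset], a sample sheet, random gene
#' intervals, and a truth table recording ancestral and per-breed
#' frequencies, per-sample depth, and the keys and classes of all injected
#' sites. Injected sites are mutually disjoint and exempt from missingness
#' so screens can assert their exact recovery. The same configuration and
#' seed always reproduce the identical cohort.
#'
#' @param config a [cohort_config].
#' @return list with elements `callset`, `sheet`, `genes`, `truth`
#'   (`classes`, `site_freq`, `doc`), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_local_seed(config$seed, {
    nb <- config$n_breeds
    spb <- config$samples_per_breed
    n <- nb * spb
    breeds <- sprintf("breed%02d", seq_len(nb))
    breed_of <- rep(breeds, each = spb)
    samples <- sprintf("%s_s%02d", breed_of, rep(seq_len(spb), times = nb))
    doc <- pmax(stats::rgamma(n, shape = config$doc_shape,
                              rate = config$doc_shape / config$doc_mean), 1)
    sheet <- data.frame(sample = samples, breed = breed_of,
                        doc = round(doc, 2), stringsAsFactors = FALSE)

    ns <- config$n_sites
    loc <- draw_positions(ns, config$contig_lengths, config$window_size,
                          config$window_multipliers)
    # unique (contig,pos) by construction -> unique keys whatever the alleles
    alle <- draw_alleles(ns, config$ts_fraction, config$indel_fraction)
    # cap ref length so deletions stay on-contig
    too_long <- nchar(alle$ref) + loc$pos - 1 > config$contig_lengths[loc$contig]
    if (any(too_long)) {
      alle$ref[too_long] <- substr(alle$ref[too_long], 1L, 1L)
      alle$alt[too_long] <- TRANSITION_OF[alle$ref[too_long]]
    }

    q <- sample_ancestral_frequencies(ns, config$q_min, config$q_max)
    q_b <- vapply(seq_len(nb),
                  function(b) breed_frequencies(q, config$F_per_breed[b]),
                  numeric(ns))
    q_b <- matrix(q_b, nrow = ns, dimnames = list(NULL, breeds))

    p_sample <- q_b[, match(breed_of, breeds), drop = FALSE]
    gt <- draw_genotypes_hwe(p_sample)

    # --- injected truth classes ---------------------------------------
    inj <- config$injections
    total_inj <- sum(inj)
    classes <- data.frame(contig = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          class = character(0), breed = character(0),
                          stringsAsFactors = FALSE)
    inj_idx <- integer(0)
    if (total_inj > 0) {
      inj_idx <- sample.int(ns, total_inj)
      lab <- rep(names(inj), times = inj)
      cls_breed <- rep(NA_character_, total_inj)
      for (j in seq_len(total_inj)) {
        i <- inj_idx[j]
        a <- rep(0L, n); b <- rep(0L, n)
        if (lab[j] == "breed_unique") {
          focal <- breeds[((j - 1L) %% nb) + 1L]
          cls_breed[j] <- focal
          qs <- stats::runif(1, 0.2, 0.5)
          in_breed <- which(breed_of == focal)
          a[in_breed] <- stats::rbinom(length(in_breed), 1L, qs)
          b[in_breed] <- stats::rbinom(length(in_breed), 1L, qs)
          if (!any(a[in_breed] + b[in_breed] > 0))
            a[in_breed[1L]] <- 1L
          q_b[i, ] <- 0; q_b[i, focal] <- qs
        } else if (lab[j] == "no_homozygote") {
          k <- min(n - 1L, max(1L, stats::rbinom(1, n, 0.5)))
          carriers <- sample.int(n, k)
          a[carriers] <- 1L  # heterozygous in every carrier, never homozygous
        } else if (lab[j] == "present_in_all") {
          hom <- stats::runif(n) < 0.5
          a[] <- 1L
          b[hom] <- 1L
          if (all(hom)) b[1L] <- 0L  # keep >= 1 het: not homozygous-in-all
        } else {  # homozygous_in_all
          a[] <- 1L; b[] <- 1L
        }
        gt$a[i, ] <- a
        gt$b[i, ] <- b
      }
      classes <- data.frame(contig = loc$contig[inj_idx],
                            pos = loc$pos[inj_idx],
                            ref = alle$ref[inj_idx], alt = alle$alt[inj_idx],
                            class = lab, breed = cls_breed,
                            stringsAsFactors = FALSE)
    }

    if (!is.null(config$missingness_d0)) {
      keep_a <- gt$a[inj_idx, , drop = FALSE]
      keep_b <- gt$b[inj_idx, , drop = FALSE]
      gt <- apply_missingness(gt, doc, config$missingness_d0)
      gt$a[inj_idx, ] <- keep_a  # injected sites stay fully called
      gt$b[inj_idx, ] <- keep_b
    }

    sites <- data.frame(contig = loc$contig, pos = loc$pos,
                        ref = alle$ref, alt = alle$alt,
                        stringsAsFactors = FALSE)
    cs <- callset(sites, gt$a, gt$b, samples, config$contig_lengths)

    # truth rows follow the callset's canonical site order
    ord <- match(site_keys(cs), site_key_strings(sites))
    site_freq <- data.frame(contig = sites$contig[ord], pos = sites$pos[ord],
                            ref = sites$ref[ord], alt = sites$alt[ord],
                            q = q[ord], stringsAsFactors = FALSE)
    site_freq <- cbind(site_freq, q_b[ord, , drop = FALSE])

    genes <- random_gene_intervals(config$n_genes, config$contig_lengths)

    list(callset = cs, sheet = sheet, genes = genes,
         truth = list(classes = classes, site_freq = site_freq,
                      doc = stats::setNames(doc, samples)),
         config = config)
  })
}

random_gene_intervals <- function(n_genes, contig_lengths) {
  if (n_genes == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0)))
  ct <- sample(names(contig_lengths), n_genes, replace = TRUE,
               prob = contig_lengths / sum(contig_lengths))
  len <- as.integer(stats::runif(n_genes, 2000, 20000))
  start <- vapply(seq_len(n_genes), function(i)
    as.integer(stats::runif(1, 0, max(1, contig_lengths[[ct[i]]] - len[i]))),
    integer(1))
  data.frame(contig = ct, start = start,
             end = pmin(start + len, as.integer(contig_lengths[ct])),
             gene_id = sprintf("gene%03d", seq_len(n_genes)),
             stringsAsFactors = FALSE)
}
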