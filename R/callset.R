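# Genotype allele codes: 0 = reference, 1 = alternate, NA = missing.
# A genotype (cell of gt_a/gt_b) counts as "called" only when both alleles
# are non-missing; half-missing genotypes arise from multiallelic
# decomposition and are treated as missing by every downstream tally.

#' Construct a callset
#'
#' A `callset` is the package's in-memory representation of a decomposed,
#' left-normalized, biallelic multi-sample variant callset: a site table plus
#' two integer allele matrices (sites x samples).
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based position of
#'   the first REF base), `ref`, `alt`, and optionally `vtype`, `ma`
#'   (multiallelic-origin flag), `ma_id` (input record id shared by records
#'   decomposed from one multiallelic line) and `ann` (free-text annotation).
#' @param gt_a,gt_b integer matrices (`nrow(sites)` x `length(samples)`) of
#'   first/second allele codes; 0 = ref, 1 = alt, NA = missing.
#' @param samples character vector of unique sample identifiers.
#' @param contig_lengths named integer vector of contig lengths in bp; every
#'   site contig must be present and `pos` must not exceed its length.
#' @return An object of class `callset`.
#' @export
callset <- function(sites, gt_a, gt_b, samples, contig_lengths) {
  stopifnot(is.data.frame(sites), is.character(samples))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths))))
    stop("contig_lengths must be a named vector")
  contig_lengths <- structure(as.numeric(contig_lengths),
                              names = names(contig_lengths))

  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns: ", paste(need, collapse = ", "))
  }
  sites$contig <- as.character(sites$contig)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- toupper(as.character(sites$ref))
  sites$alt <- toupper(as.character(sites$alt))
  if (is.null(sites$vtype)) sites$vtype <- classify_variant_type(sites$ref, sites$alt)
  if (is.null(sites$ma)) sites$ma <- rep(FALSE, nrow(sites))
  if (is.null(sites$ma_id)) sites$ma_id <- rep(NA_integer_, nrow(sites))
  if (is.null(sites$ann)) sites$ann <- rep(NA_character_, nrow(sites))

  if (any(sites$pos < 1L)) stop("pos must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  bad <- setdiff(unique(sites$contig), names(contig_lengths))
  if (length(bad)) stop("contig(s) missing from contig_lengths: ",
                        paste(bad, collapse = ", "))
  if (any(sites$pos > contig_lengths[sites$contig]))
    stop("variant position beyond contig length")

  gt_a <- as.matrix(gt_a); gt_b <- as.matrix(gt_b)
  storage.mode(gt_a) <- "integer"; storage.mode(gt_b) <- "integer"
  if (!identical(dim(gt_a), c(nrow(sites), length(samples))) ||
      !identical(dim(gt_b), dim(gt_a)))
    stop("genotype matrices must be n_sites x n_samples")
  if (!all(gt_a[!is.na(gt_a)] %in% c(0L, 1L)) ||
      !all(gt_b[!is.na(gt_b)] %in% c(0L, 1L)))
    stop("genotype allele codes must be 0, 1 or NA")

  ord <- order(match(sites$contig, names(contig_lengths)),
               sites$pos, sites$ref, sites$alt)
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  gt_a <- gt_a[ord, , drop = FALSE]
  gt_b <- gt_b[ord, , drop = FALSE]
  dimnames(gt_a) <- dimnames(gt_b) <- list(NULL, samples)

  key <- site_key_strings(sites)
  if (anyDuplicated(key)) stop("duplicate site keys after normalization")

  structure(list(samples = samples, sites = sites,
                 gt_a = gt_a, gt_b = gt_b,
                 contig_lengths = contig_lengths),
            class = "callset")
}

#' @export
print.callset <- function(x, ...) {
  cat(sprintf("callset: %d sites x %d samples over %d contig(s) (%.3g Mb)\n",
              nrow(x$sites), length(x$samples), length(x$contig_lengths),
              sum(x$contig_lengths) / 1e6))
  print(utils::head(x$sites, 5))
  invisible(x)
}

#' Number of sites / samples in a callset
#' @param x a `callset`.
#' @return integer count.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

# "contig:pos:ref:alt" string keys; the canonical site identity.
site_key_strings <- function(sites) {
  paste(sites$contig, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Site keys of a callset
#'
#' @param x a `callset` or a site data.frame.
#' @return character vector `"contig:pos:ref:alt"`.
#' @export
site_keys <- function(x) {
  if (inherits(x, "callset")) x <- x$sites
  site_key_strings(x)
}

# Logical matrices used by every genotype tally.
called_matrix <- function(cs) !is.na(cs$gt_a) & !is.na(cs$gt_b)
het_matrix <- function(cs) {
  s <- cs$gt_a + cs$gt_b
  !is.na(s) & s == 1L
}
homalt_matrix <- function(cs) {
  s <- cs$gt_a + cs$gt_b
  !is.na(s) & s == 2L
}

#' Classify a REF/ALT allele pair
#'
#' SNP when both alleles are single bases, INDEL when lengths differ, OTHER
#' (multi-nucleotide substitution) when lengths are equal and greater than 1.
#'
#' @param ref,alt character vectors of uppercase allele strings (ACGTN).
#' @return character vector in `{"SNP","INDEL","OTHER"}`.
#' @export
classify_variant_type <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (!length(ref)) return(character(0))
  if (any(!nzchar(ref)) || any(!nzchar(alt))) stop("empty allele string")
  if (any(grepl("[^ACGTN]", c(ref, alt)))) stop("alleles must match [ACGTN]+")
  nr <- nchar(ref); na_ <- nchar(alt)
  ifelse(nr != na_, "INDEL", ifelse(nr == 1L, "SNP", "OTHER"))
}

# Left-normalize one allele pair: trim shared trailing bases, then shared
# leading bases (position advances), always keeping at least one base each.
normalize_allele <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
    r <- r[-1L]; a <- a[-1L]; pos <- pos + 1L
  }
  list(pos = as.integer(pos), ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Decompose a multiallelic record into biallelic sites
#'
#' Each alternate allele yields one biallelic record. In the re-coded
#' genotypes an allele is 1 where the original call matches that alternate,
#' 0 where it is reference, and missing where it is a *different* alternate
#' (so per-alternate allele counts use only informative chromosomes).
#' Records from a multiallelic input keep a shared `ma_id` so multiallelic
#' site tallies survive decomposition. Alleles are left-normalized.
#'
#' @param contig,pos,ref position of the input record.
#' @param alts character vector of alternate alleles (length k >= 1).
#' @param gt_a,gt_b integer vectors over samples of original allele indices
#'   (0 = ref, 1..k = alternates, NA = missing).
#' @param ma_id integer id to stamp on decomposed records when k > 1.
#' @param ann optional annotation string carried to every record.
#' @return list with `sites` (data.frame) and `gt_a`, `gt_b` (k x n matrices).
#' @export
decompose_multiallelic <- function(contig, pos, ref, alts, gt_a, gt_b,
                                   ma_id = NA_integer_, ann = NA_character_) {
  k <- length(alts)
  stopifnot(k >= 1L, length(gt_a) == length(gt_b))
  ma <- k > 1L
  out_sites <- vector("list", k)
  out_a <- matrix(NA_integer_, k, length(gt_a))
  out_b <- matrix(NA_integer_, k, length(gt_b))
  recode <- function(g, alt_idx) {
    out <- rep(NA_integer_, length(g))
    out[!is.na(g) & g == 0L] <- 0L
    out[!is.na(g) & g == alt_idx] <- 1L
    out  # other alternates stay NA
  }
  for (i in seq_len(k)) {
    nrm <- normalize_allele(pos, ref, alts[i])
    out_sites[[i]] <- data.frame(
      contig = contig, pos = nrm$pos, ref = nrm$ref, alt = nrm$alt,
      vtype = classify_variant_type(nrm$ref, nrm$alt),
      ma = ma, ma_id = if (ma) ma_id else NA_integer_,
      ann = ann, stringsAsFactors = FALSE)
    out_a[i, ] <- recode(gt_a, i)
    out_b[i, ] <- recode(gt_b, i)
  }
  list(sites = do.call(rbind, out_sites), gt_a = out_a, gt_b = out_b)
}

#' Read a multi-sample VCF into a callset
#'
#' Sites are multiallelic-decomposed and left-normalized on the way in.
#' Genotypes must be diploid (`a/b` or `a|b`); haploid or polyploid GT
#' entries are an error. Half-missing genotypes (`0/.`) are kept
#' allele-wise, matching the representation decomposition produces.
#' Contig lengths are taken from `##contig` header lines unless supplied.
#'
#' @param path path to a VCF 4.x text file with GT in FORMAT.
#' @param contig_lengths optional named vector overriding header lengths.
#' @return a [callset].
#' @export
read_vcf <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  meta <- v@meta
  if (is.null(contig_lengths)) {
    cl <- meta[grepl("^##contig=", meta)]
    if (!length(cl)) stop("no ##contig header lines and no contig_lengths given")
    ids <- sub(".*[<,]ID=([^,>]+).*", "\\1", cl)
    lens <- suppressWarnings(as.numeric(sub(".*[<,]length=([0-9]+).*", "\\1", cl)))
    if (anyNA(lens)) stop("##contig line without a length= field")
    contig_lengths <- structure(lens, names = ids)
  }
  samples <- colnames(v@gt)[-1]
  if (is.null(samples)) stop("VCF has no sample columns / FORMAT field")

  fix <- v@fix
  if (nrow(fix) == 0L) {
    empty <- data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0))
    z <- matrix(NA_integer_, 0, length(samples))
    return(callset(empty, z, z, samples, contig_lengths))
  }

  gt_str <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  gt_str <- matrix(as.character(gt_str), nrow = nrow(fix))
  gt_str[is.na(gt_str)] <- "./."  # read.vcfR masks fully-missing GT as NA
  # split diploid "a/b" or "a|b"
  sep_ok <- grepl("^[0-9.]+[/|][0-9.]+$", gt_str)
  if (any(!sep_ok)) {
    i <- which(!sep_ok)[1]
    stop("non-diploid or malformed GT '", gt_str[i], "' at record ",
         ((i - 1) %% nrow(fix)) + 1)
  }
  a_str <- sub("[/|].*$", "", gt_str)
  b_str <- sub("^.*[/|]", "", gt_str)
  to_code <- function(x) {
    out <- suppressWarnings(as.integer(x))
    out  # "." -> NA
  }
  A <- matrix(to_code(a_str), nrow = nrow(fix))
  B <- matrix(to_code(b_str), nrow = nrow(fix))
  # half-missing genotypes ("0/.") are kept allele-wise: they are legal
  # VCF and arise when writing decomposed multiallelic records back out

  info <- fix[, "INFO"]
  ann <- ifelse(grepl("(^|;)ANN=", info),
                sub(".*(^|;)ANN=([^;]*).*", "\\2", info), NA_character_)

  pieces <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (!length(alts) || any(!nzchar(alts)) || any(alts == "."))
      stop("record without a concrete ALT allele at line for pos ", fix[i, "POS"])
    mx <- max(c(A[i, ], B[i, ]), na.rm = TRUE)
    if (!is.finite(mx)) mx <- 0L
    if (mx > length(alts)) stop("GT allele index exceeds ALT count at pos ", fix[i, "POS"])
    pieces[[i]] <- decompose_multiallelic(
      contig = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
      ref = toupper(fix[i, "REF"]), alts = toupper(alts),
      gt_a = A[i, ], gt_b = B[i, ], ma_id = i, ann = ann[i])
  }
  sites <- do.call(rbind, lapply(pieces, `[[`, "sites"))
  gt_a <- do.call(rbind, lapply(pieces, `[[`, "gt_a"))
  gt_b <- do.call(rbind, lapply(pieces, `[[`, "gt_b"))
  callset(sites, gt_a, gt_b, samples, contig_lengths)
}

#' Write a callset as a plain-text VCF 4.2 file
#'
#' The inverse of [read_vcf] for decomposed biallelic callsets: reading the
#' written file recovers the same sites, types and genotypes. Half-missing
#' alleles (possible after decomposition) are written allele-wise (`0/.`).
#'
#' @param cs a [callset].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cs, path) {
  stopifnot(inherits(cs, "callset"))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>",
                   names(cs$contig_lengths), as.integer(cs$contig_lengths)),
           "##INFO=<ID=ANN,Number=1,Type=String,Description=\"Functional annotation\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", cs$samples), collapse = "\t"))
  al <- function(m) ifelse(is.na(m), ".", as.character(m))
  gt <- matrix(paste(al(cs$gt_a), al(cs$gt_b), sep = "/"),
               nrow = nrow(cs$sites))
  info <- ifelse(is.na(cs$sites$ann), ".", paste0("ANN=", cs$sites$ann))
  body <- cbind(cs$sites$contig, cs$sites$pos, ".", cs$sites$ref,
                cs$sites$alt, ".", "PASS", info, "GT", gt)
  lines <- c(hdr, apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet (sample, breed, doc)
#'
#' @param path tab-separated file with header columns `sample`, `breed`,
#'   `doc` (mean depth of coverage, X).
#' @return data.frame with those three columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "breed", "doc")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  validate_sample_sheet(df)
  df
}

validate_sample_sheet <- function(df, samples = NULL) {
  if (anyDuplicated(df$sample)) stop("duplicate sample id in sample sheet")
  if (any(!nzchar(df$breed)) || anyNA(df$breed)) stop("empty breed label")
  if (anyNA(df$doc) || any(df$doc <= 0)) stop("depth of coverage must be > 0")
  if (!is.null(samples)) {
    miss <- setdiff(samples, df$sample)
    if (length(miss)) stop("sample(s) absent from sheet: ",
                           paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Read gene intervals from BED or GFF3
#'
#' BED input is taken as 0-based half-open; GFF3 (1-based inclusive,
#' `gene` features only) is converted. Intervals are stored 0-based
#' half-open throughout the package.
#'
#' @param path path to a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data.frame `contig`, `start`, `end` (0-based half-open), `gene_id`.
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, bed = "bed", gff = "gff3", gff3 = "gff3",
                     gtf = "gff3",
                     stop("cannot infer interval file dialect from '.", ext, "'"))
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  md <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(md)) md <- md[md$type == "gene", , drop = FALSE]
    id <- if (!is.null(md$ID) && !all(is.na(md$ID))) md$ID
          else if (!is.null(md$Name)) md$Name else md$gene_id
  } else {
    id <- md$name
  }
  if (is.null(id) || anyNA(id) || any(!nzchar(id)))
    stop("gene interval without an identifier")
  out <- data.frame(contig = as.character(md$seqnames),
                    start = md$start - 1L,  # GRanges is 1-based inclusive
                    end = md$end,
                    gene_id = as.character(id),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("gene interval with start >= end")
  rownames(out) <- NULL
  out
}
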