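# Genome-window variability scan: tile every contig into fixed windows,
# count variants per window, and classify windows as high (more than twice
# the genome-wide mean count) or low (less than half the mean) variability.

#' Per-window variant counts
#'
#' Tiles each contig from position 0 into `window_size`-bp windows
#' (0-based half-open; the final window of a contig may be partial) and
#' counts the variants whose anchor position falls in each window, split
#' by type, with per-window TsTv and mean MAF. Empty windows are emitted
#' with zero counts.
#'
#' @param cs a [callset].
#' @param window_size window width in bp.
#' @param drop_partial drop final windows shorter than `window_size`.
#' @return data.frame `contig`, `window`, `start`, `end`, `n_variants`,
#'   `n_snps`, `n_indels`, `n_ts`, `n_tv`, `ts_tv`, `mean_maf`.
#' @export
window_counts <- function(cs, window_size = 10000, drop_partial = FALSE) {
  stopifnot(window_size >= 1)
  ss <- site_summaries(cs)
  per_contig <- lapply(names(cs$contig_lengths), function(ct) {
    len <- cs$contig_lengths[[ct]]
    n_win <- max(1L, as.integer(ceiling(len / window_size)))
    start <- (seq_len(n_win) - 1) * window_size
    end <- pmin(start + window_size, len)
    sel <- cs$sites$contig == ct
    pos0 <- cs$sites$pos[sel] - 1L  # anchor in 0-based space
    if (any(pos0 >= len)) stop("variant beyond contig length on ", ct)
    w <- pos0 %/% window_size
    cnt <- function(keep) tabulate((w + 1L)[keep], nbins = n_win)
    snp <- cs$sites$vtype[sel] == "SNP"
    ts <- snp & is_transition(cs$sites$ref[sel], cs$sites$alt[sel])
    maf <- as.numeric(ss$maf[sel])
    mean_maf <- rep(NA_real_, n_win)
    if (length(maf)) {
      maf_sum <- rowsum(ifelse(is.na(maf), 0, maf), w, reorder = FALSE)
      maf_n <- rowsum(as.numeric(!is.na(maf)), w, reorder = FALSE)
      idx <- as.integer(rownames(maf_sum)) + 1L
      mean_maf[idx] <- ifelse(maf_n[, 1] > 0, maf_sum[, 1] / maf_n[, 1],
                              NA_real_)
    }
    n_ts <- cnt(ts); n_tv <- cnt(snp & !ts)
    data.frame(contig = ct, window = seq_len(n_win) - 1L,
               start = start, end = end,
               n_variants = cnt(rep(TRUE, sum(sel))),
               n_snps = cnt(snp),
               n_indels = cnt(cs$sites$vtype[sel] == "INDEL"),
               n_ts = n_ts, n_tv = n_tv,
               ts_tv = ifelse(n_tv > 0, n_ts / n_tv, NA_real_),
               mean_maf = mean_maf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_contig)
  if (drop_partial) out <- out[out$end - out$start == window_size, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify windows by variant density
#'
#' With `m` the mean variant count over all windows (empty and partial
#' windows included), a window is `high` when its count strictly exceeds
#' `2m` and `low` when strictly below `m/2`; otherwise `normal`. The scan
#' summary (counts and per-class composition) is attached as the
#' `"scan_summary"` attribute, retrievable with [scan_summary].
#'
#' @param windows data.frame from [window_counts].
#' @return the input with a `classification` column.
#' @export
classify_windows <- function(windows) {
  stopifnot(nrow(windows) >= 1)
  m <- sum(windows$n_variants) / nrow(windows)
  cls <- ifelse(windows$n_variants > 2 * m, "high",
                ifelse(windows$n_variants < m / 2, "low", "normal"))
  windows$classification <- cls
  per_class <- do.call(rbind, lapply(c("high", "normal", "low"), function(k) {
    sel <- cls == k
    data.frame(classification = k, n_windows = sum(sel),
               mean_variants = if (any(sel)) mean(windows$n_variants[sel]) else NA_real_,
               mean_snps = if (any(sel)) mean(windows$n_snps[sel]) else NA_real_,
               mean_indels = if (any(sel)) mean(windows$n_indels[sel]) else NA_real_,
               ts_tv = if (sum(windows$n_tv[sel]) > 0)
                 sum(windows$n_ts[sel]) / sum(windows$n_tv[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(windows, "scan_summary") <-
    list(mean_variants_per_window = m,
         n_windows = nrow(windows),
         n_high = sum(cls == "high"), n_low = sum(cls == "low"),
         per_class = per_class)
  windows
}

#' Scan summary of classified windows
#' @param windows output of [classify_windows].
#' @return the scan summary list.
#' @export
scan_summary <- function(windows) {
  s <- attr(windows, "scan_summary")
  if (is.null(s)) stop("windows have not been classified")
  s
}

#' Per-class variant catalog for a window scan
#'
#' Maps every variant to its window's classification and reports, per
#' class, the variant count, mean MAF and type composition; when the
#' callset carries an annotation field, a per-class tally of annotation
#' values is included (otherwise it is omitted with a message).
#'
#' @param windows classified windows from [classify_windows].
#' @param cs the [callset] the scan was computed from.
#' @return list `variants` (site keys with `classification` and `maf`),
#'   `per_class` (summary data.frame), `impact` (annotation tally or NULL).
#' @export
region_variant_report <- function(windows, cs) {
  if (is.null(windows$classification)) stop("windows have not been classified")
  ws <- max(windows$end - windows$start)  # full window width
  key <- paste(windows$contig, windows$window)
  w_of <- (cs$sites$pos - 1L) %/% ws
  cls <- windows$classification[match(paste(cs$sites$contig, w_of), key)]
  ss <- site_summaries(cs)
  variants <- data.frame(cs$sites[c("contig", "pos", "ref", "alt", "vtype")],
                         maf = ss$maf, classification = cls,
                         stringsAsFactors = FALSE, row.names = NULL)
  per_class <- do.call(rbind, lapply(c("high", "normal", "low"), function(k) {
    sel <- !is.na(cls) & cls == k
    data.frame(classification = k, n_variants = sum(sel),
               n_snps = sum(sel & cs$sites$vtype == "SNP"),
               n_indels = sum(sel & cs$sites$vtype == "INDEL"),
               mean_maf = if (any(sel)) mean(ss$maf[sel], na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  impact <- NULL
  if (any(!is.na(cs$sites$ann))) {
    sel <- !is.na(cls) & !is.na(cs$sites$ann)
    impact <- as.data.frame(table(classification = cls[sel],
                                  impact = cs$sites$ann[sel]),
                            stringsAsFactors = FALSE)
  } else {
    message("no annotation field present: impact table omitted")
  }
  list(variants = variants, per_class = per_class, impact = impact)
}
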