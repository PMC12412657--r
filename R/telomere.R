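# Telomeric hexamer scanning: terminal arrays vs interstitial telomeric
# sequences (ITS).

#' Scan a sequence for telomeric repeat units
#'
#' Counts non-overlapping exact matches of `unit` (forward) and of its
#' reverse complement per tiling window. Matching is window-local (a match
#' must lie entirely within the window). Density is
#' `nchar(unit) * (fwd + rev) / window_width`.
#'
#' @param seq DNA sequence (character scalar).
#' @param unit Repeat unit (default vertebrate telomere "TTAGGG").
#' @param window Window width in bp (default 10 kb).
#' @return data.frame: start, end, fwd_count, rev_count, density.
#' @export
scan_telomeric_repeats <- function(seq, unit = "TTAGGG", window = 10000) {
  unit <- toupper(unit)
  if (grepl("[^ACGT]", unit)) stop("repeat unit must be over ACGT")
  if (nchar(unit) < 4) stop("repeat unit too short")
  seq <- toupper(seq)
  L <- nchar(seq)
  runit <- revcomp(unit)
  starts <- seq(0, max(0, L - 1), by = window)
  count_in <- function(sub, pat) {
    m <- gregexpr(pat, sub, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }
  rows <- lapply(starts, function(s) {
    e <- min(s + window, L)
    sub <- substr(seq, s + 1, e)
    fwd <- count_in(sub, unit)
    rev <- count_in(sub, runit)
    data.frame(start = s, end = e, fwd_count = fwd, rev_count = rev,
               density = nchar(unit) * (fwd + rev) / (e - s))
  })
  do.call(rbind, rows)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Call terminal and interstitial telomeric arrays from a window scan
#'
#' Windows with density >= `min_density` are merged when at most
#' `merge_gap` windows apart; merged runs spanning >= `min_span` bp are
#' emitted. A run touching the first or last `end_margin` bp of the
#' chromosome is `terminal`, otherwise `interstitial` (ITS).
#'
#' @param scan Window scan from [scan_telomeric_repeats()] (one
#'   chromosome, ordered).
#' @param chrom_length Chromosome length in bp; default the scan extent.
#' @param min_density Minimum window density (default 0.4).
#' @param min_span Minimum merged span in bp (default 1 kb).
#' @param end_margin Distance from a chromosome end within which a run is
#'   terminal (default 100 kb).
#' @param merge_gap Maximum number of below-threshold windows bridged when
#'   merging (default 1).
#' @return data.frame: start, end, span_bp, kind, mean_density.
#' @export
call_its <- function(scan, chrom_length = max(scan$end), min_density = 0.4,
                     min_span = 1000, end_margin = 1e5, merge_gap = 1) {
  if (is.unsorted(scan$start)) stop("scan windows must be ordered")
  dense <- which(scan$density >= min_density)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      span_bp = numeric(0), kind = character(0),
                      mean_density = numeric(0))
  if (length(dense) == 0L) return(empty)
  runs <- split(dense, cumsum(c(1, diff(dense) > merge_gap + 1)))
  rows <- lapply(runs, function(ix) {
    s <- scan$start[ix[1]]; e <- scan$end[ix[length(ix)]]
    data.frame(start = s, end = e, span_bp = e - s,
               kind = if (s < end_margin || e > chrom_length - end_margin)
                 "terminal" else "interstitial",
               mean_density = mean(scan$density[ix]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[out$span_bp >= min_span, , drop = FALSE]
}

#' Genome-wide telomeric repeat content
#'
#' @param scans Named list of per-chromosome window scans
#'   ([scan_telomeric_repeats()]), with the repeat-unit length used.
#' @param unit_len Repeat unit length in bp (default 6).
#' @return List: total_hits, motif_bases, genome_bases, fraction.
#' @export
telomere_content_summary <- function(scans, unit_len = 6) {
  hits <- sum(vapply(scans, function(s) sum(s$fwd_count + s$rev_count),
                     numeric(1)))
  bases <- sum(vapply(scans, function(s) max(s$end), numeric(1)))
  list(total_hits = hits, motif_bases = unit_len * hits,
       genome_bases = bases, fraction = unit_len * hits / bases)
}
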