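# Bias-clustered substitutions (BCS), the UBCS window statistic, and
# fission dating from the UBCS ratio formula.

#' Find bias-clustered substitutions
#'
#' A substitution is a BCS iff it is weak-to-strong (AT->GC) and lies in at
#' least one window of width `cluster_window` containing at least
#' `min_subs` SNDs of this lineage of which a fraction of at least
#' `min_ws_frac` are weak-to-strong. All integer window offsets are
#' considered (evaluated exactly, by enumerating every distinct window
#' content). Only the ws substitutions in a qualifying window are counted
#' as BCS.
#'
#' @param snds data.frame with columns `pos` (0-based, sorted ascending)
#'   and `ws` (logical); a single lineage on a single chromosome.
#' @param cluster_window Window width in bp (default 300).
#' @param min_subs Minimum SNDs per qualifying window (default 4).
#' @param min_ws_frac Minimum ws fraction per qualifying window (default 0.8).
#' @return `snds` with logical `is_bcs` and integer `window_start` columns
#'   (`window_start` is the left edge of one qualifying window, NA for
#'   non-BCS).
#' @export
find_bcs <- function(snds, cluster_window = 300, min_subs = 4,
                     min_ws_frac = 0.8) {
  pos <- as.integer(snds$pos)
  if (is.unsorted(pos)) stop("SND positions must be sorted ascending")
  res <- bcs_flags_cpp(pos, as.logical(snds$ws), as.integer(cluster_window),
                       as.integer(min_subs), min_ws_frac)
  out <- as.data.frame(snds)
  out$is_bcs <- res$is_bcs
  out$window_start <- res$window_start
  out
}

#' UBCS statistic for one region
#'
#' UBCS = observed BCS count minus the expected count under `n_perm`
#' permutations that shuffle the ws labels uniformly over the region's SND
#' positions (positions and the region's ws count preserved). The sign
#' convention is observed - expected, so positive values mean an excess of
#' clustered GC-biased substitutions (telomere-like history).
#'
#' @param snds SND table (see [polarize_snds()]); may contain both lineages.
#' @param lineage "target" or "query".
#' @param region Single-row region data.frame (see [region()]).
#' @param cluster_window,min_subs,min_ws_frac BCS parameters ([find_bcs()]).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Base RNG seed. The effective per-region seed is derived from
#'   `seed` and the region start so that a region equal to a tile of
#'   [ubcs_by_window()] reproduces that tile's value exactly.
#' @return One-row data.frame: chrom, start, end, label, lineage,
#'   n_snds, observed_bcs, expected_bcs, ubcs, n_perm, seed.
#' @export
ubcs_for_region <- function(snds, lineage, region, cluster_window = 300,
                            min_subs = 4, min_ws_frac = 0.8,
                            n_perm = 1000, seed = 1) {
  stopifnot(nrow(region) == 1L, lineage %in% c("target", "query"))
  if ((region$end - region$start) < cluster_window) {
    stop("region smaller than the cluster window")
  }
  sel <- snds$derived_lineage == lineage & snds$chrom == region$chrom &
    snds$pos >= region$start & snds$pos < region$end
  sub <- snds[sel, , drop = FALSE]
  sub <- sub[order(sub$pos), , drop = FALSE]
  n <- nrow(sub)
  if (n == 0L) {
    warning("region contains no SNDs; UBCS is 0")
    obs <- 0L; expd <- 0
  } else {
    obs <- bcs_count_cpp(as.integer(sub$pos), as.logical(sub$ws),
                         as.integer(cluster_window), as.integer(min_subs),
                         min_ws_frac)
    region_seed <- (as.numeric(seed) + region$start %% 1e8) %% 2147483647
    set.seed(as.integer(region_seed))
    expd <- expected_bcs_perm_cpp(as.integer(sub$pos), sum(sub$ws),
                                  as.integer(cluster_window),
                                  as.integer(min_subs), min_ws_frac,
                                  as.integer(n_perm))
  }
  data.frame(chrom = region$chrom, start = region$start, end = region$end,
             label = region$label, lineage = lineage, n_snds = n,
             observed_bcs = obs, expected_bcs = expd, ubcs = obs - expd,
             n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
}

#' UBCS in tiling windows along a chromosome
#'
#' @inheritParams ubcs_for_region
#' @param chrom Chromosome to tile.
#' @param chrom_length Length of the chromosome (bp).
#' @param window Tile width in bp (default 1 Mb).
#' @return data.frame with one row per tile (columns as in
#'   [ubcs_for_region()]). Permutations are window-local.
#' @export
ubcs_by_window <- function(snds, lineage, chrom, chrom_length,
                           window = 1e6, cluster_window = 300, min_subs = 4,
                           min_ws_frac = 0.8, n_perm = 1000, seed = 1) {
  if (window < cluster_window) stop("window smaller than the cluster window")
  starts <- seq(0, chrom_length - 1, by = window)
  rows <- lapply(starts, function(s) {
    reg <- region(chrom, s, min(s + window, chrom_length), "window")
    suppressWarnings(
      ubcs_for_region(snds, lineage, reg, cluster_window, min_subs,
                      min_ws_frac, n_perm, seed))
  })
  do.call(rbind, rows)
}

#' Date a chromosomal fission from UBCS ratios
#'
#' Implements T = T_div * (1 - R1/R2), where R1 is the ratio of UBCS in the
#' breakpoint flank for query-derived vs target-derived SNDs, and R2 is the
#' ratio of query-derived UBCS between the initial telomeric region and an
#' interior control region of identical length. The formula is applied as
#' printed; T is reported even outside \[0, T_div\], with an out-of-range flag.
#'
#' @param T_div Divergence time of the two lineages (years); supplied by
#'   the user, never inferred here.
#' @param ubcs_query_bp,ubcs_target_bp UBCS in the breakpoint flank for
#'   query- and target-derived SNDs.
#' @param ubcs_query_tel,ubcs_query_ctrl Query-derived UBCS in the
#'   telomeric region and in the interior control region.
#' @return List of class `fission_time`: T_div, R1, R2, T_years,
#'   out_of_range.
#' @export
estimate_fission_time <- function(T_div, ubcs_query_bp, ubcs_target_bp,
                                  ubcs_query_tel, ubcs_query_ctrl) {
  if (ubcs_target_bp == 0) {
    stop("degenerate UBCS: target breakpoint-flank UBCS is zero (R1 undefined)")
  }
  if (ubcs_query_ctrl == 0) {
    stop("degenerate UBCS: query control-region UBCS is zero (R2 undefined)")
  }
  R1 <- ubcs_query_bp / ubcs_target_bp
  R2 <- ubcs_query_tel / ubcs_query_ctrl
  if (R2 == 0) stop("degenerate UBCS: R2 is zero")
  T_years <- T_div * (1 - R1 / R2)
  out <- list(T_div = T_div, R1 = R1, R2 = R2, T_years = T_years,
              out_of_range = (T_years < 0 || T_years > T_div))
  class(out) <- "fission_time"
  out
}

#' @export
print.fission_time <- function(x, ...) {
  cat(sprintf("Fission-time estimate: T = %.4g years (T_div = %.4g, R1 = %.4g, R2 = %.4g)%s\n",
              x$T_years, x$T_div, x$R1, x$R2,
              if (x$out_of_range) " [outside 0..T_div]" else ""))
  invisible(x)
}

#' End-to-end fission dating from an SND table and labelled regions
#'
#' Computes the four regional UBCS values (query and target UBCS in the
#' `breakpoint_flank` region; query UBCS in the `telomeric` and `control`
#' regions) and applies [estimate_fission_time()].
#'
#' @param snds SND table.
#' @param regions region data.frame containing labels `breakpoint_flank`,
#'   `telomeric` and `control` (one row each).
#' @param T_div Divergence time in years.
#' @param ... Passed to [ubcs_for_region()] (cluster parameters, `n_perm`,
#'   `seed`).
#' @return `fission_time` list with an extra `ubcs` data.frame of the four
#'   regional values.
#' @export
date_fission <- function(snds, regions, T_div, ...) {
  pick <- function(lab) {
    r <- regions[regions$label == lab, , drop = FALSE]
    if (nrow(r) != 1L) stop("need exactly one region labelled '", lab, "'")
    r
  }
  u_q_bp <- ubcs_for_region(snds, "query", pick("breakpoint_flank"), ...)
  u_t_bp <- ubcs_for_region(snds, "target", pick("breakpoint_flank"), ...)
  u_q_tel <- ubcs_for_region(snds, "query", pick("telomeric"), ...)
  u_q_ctrl <- ubcs_for_region(snds, "query", pick("control"), ...)
  est <- estimate_fission_time(T_div, u_q_bp$ubcs, u_t_bp$ubcs,
                               u_q_tel$ubcs, u_q_ctrl$ubcs)
  est$ubcs <- rbind(u_q_bp, u_t_bp, u_q_tel, u_q_ctrl)
  est
}
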