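# Fission/fusion polarisation from synteny-block tables, with breakpoint
# localisation.

#' Classify fission vs fusion per reference chromosome
#'
#' For each reference chromosome, blocks are partitioned by query
#' chromosome. A candidate split exists when at least two query chromosomes
#' each cover >= `min_frac` of the reference chromosome with >=
#' `min_blocks` blocks. The outgroup table polarises a candidate split:
#' continuous coverage by a single outgroup chromosome across the
#' breakpoint means the split arose in the query lineage
#' (`fission_in_query`); different outgroup chromosomes on the two sides
#' mean the joined state of the reference chromosome is derived
#' (`fusion`, i.e. fusion in the reference lineage); anything else is
#' `ambiguous`. A 1:1 reference chromosome whose outgroup mapping splits is
#' also a `fusion`. A complementary query-side pass detects the mirrored
#' signatures: a query chromosome covered by two reference chromosomes
#' whose outgroup mapping is continuous across the junction is a
#' `fission_in_ref`; with the outgroup split, a `fusion_in_query`.
#' Inversions are irrelevant to the call (strand is ignored).
#'
#' @param ref_query_blocks Block table (reference vs query), already
#'   length-filtered ([read_synteny_blocks()]).
#' @param ref_outgroup_blocks Block table (reference vs outgroup).
#' @param min_frac Minimum covered fraction of the reference chromosome per
#'   supporting query chromosome (default 0.05).
#' @param min_blocks Minimum supporting blocks per query chromosome
#'   (default 2).
#' @param chrom_lengths Optional named vector of reference chromosome
#'   lengths; default max block end per chromosome.
#' @return data.frame: ref_chrom, event (fission_in_query, fusion,
#'   fission_in_ref, fusion_in_query, none, ambiguous), query_chroms
#'   (comma-joined), breakpoint_start, breakpoint_end (NA unless localised).
#' @export
call_rearrangements <- function(ref_query_blocks, ref_outgroup_blocks,
                                min_frac = 0.05, min_blocks = 2,
                                chrom_lengths = NULL) {
  if (nrow(ref_query_blocks) == 0L) stop("empty ref-query block table")
  chroms <- unique(ref_query_blocks$ref_chrom)
  if (is.null(chrom_lengths)) {
    both <- rbind(ref_query_blocks[, c("ref_chrom", "ref_end")],
                  ref_outgroup_blocks[, c("ref_chrom", "ref_end")])
    chrom_lengths <- tapply(both$ref_end, both$ref_chrom, max)
  }
  supported_partners <- function(blocks, cc) {
    b <- blocks[blocks$ref_chrom == cc, , drop = FALSE]
    if (nrow(b) == 0L) return(character(0))
    cov <- tapply(b$length, b$query_chrom, sum) / chrom_lengths[[cc]]
    nb <- tapply(b$length, b$query_chrom, length)
    names(cov)[cov >= min_frac & nb >= min_blocks]
  }
  rows <- lapply(chroms, function(cc) {
    b <- ref_query_blocks[ref_query_blocks$ref_chrom == cc, , drop = FALSE]
    qs <- supported_partners(ref_query_blocks, cc)
    os <- supported_partners(ref_outgroup_blocks, cc)
    bp_s <- NA_real_; bp_e <- NA_real_
    if (length(qs) >= 2) {
      # keep the two best-covered query chromosomes
      cov <- tapply(b$length, b$query_chrom, sum)[qs]
      top2 <- names(sort(cov, decreasing = TRUE))[1:2]
      loc <- localize_breakpoint(b[b$query_chrom %in% top2, , drop = FALSE])
      if (loc$ambiguous) {
        ev <- "ambiguous"
      } else {
        bp_s <- loc$start; bp_e <- loc$end
        side <- outgroup_sides(ref_outgroup_blocks, cc, (bp_s + bp_e) / 2)
        ev <- if (side$continuous) "fission_in_query"
              else if (side$split) "fusion" else "ambiguous"
      }
      data.frame(ref_chrom = cc, event = ev,
                 query_chroms = paste(sort(top2), collapse = ","),
                 breakpoint_start = bp_s, breakpoint_end = bp_e,
                 stringsAsFactors = FALSE)
    } else if (length(os) >= 2) {
      data.frame(ref_chrom = cc, event = "fusion",
                 query_chroms = paste(sort(unique(b$query_chrom)),
                                      collapse = ","),
                 breakpoint_start = NA_real_, breakpoint_end = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(ref_chrom = cc, event = "none",
                 query_chroms = paste(sort(unique(b$query_chrom)),
                                      collapse = ","),
                 breakpoint_start = NA_real_, breakpoint_end = NA_real_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  # query-side pass: mirrored fission/fusion signatures
  qchroms <- unique(ref_query_blocks$query_chrom)
  qrows <- lapply(qchroms, function(qc) {
    b <- ref_query_blocks[ref_query_blocks$query_chrom == qc, , drop = FALSE]
    refs <- unique(b$ref_chrom)
    if (length(refs) < 2) return(NULL)
    big <- refs[vapply(refs, function(rc) {
      sum(b$length[b$ref_chrom == rc]) >= min_frac *
        sum(b$length) && sum(b$ref_chrom == rc) >= min_blocks
    }, logical(1))]
    if (length(big) < 2) return(NULL)
    # the involved ref chromosomes already carry their own ref-side event;
    # only emit when the ref-side pass saw nothing (true mirrored case)
    ref_ev <- out$event[out$ref_chrom %in% big]
    if (any(ref_ev != "none")) return(NULL)
    og <- ref_outgroup_blocks[ref_outgroup_blocks$ref_chrom %in% big, ,
                              drop = FALSE]
    o_per_ref <- tapply(og$length, list(og$ref_chrom, og$query_chrom), sum)
    main_o <- apply(o_per_ref, 1, function(z) names(which.max(z)))
    ev <- if (length(unique(main_o)) == 1) "fission_in_ref"
          else "fusion_in_query"
    data.frame(ref_chrom = paste(sort(big), collapse = ","), event = ev,
               query_chroms = qc, breakpoint_start = NA_real_,
               breakpoint_end = NA_real_, stringsAsFactors = FALSE)
  })
  qrows <- qrows[!vapply(qrows, is.null, logical(1))]
  if (length(qrows)) out <- rbind(out, do.call(rbind, qrows))
  rownames(out) <- NULL
  out
}

outgroup_sides <- function(og_blocks, cc, bp_mid) {
  b <- og_blocks[og_blocks$ref_chrom == cc, , drop = FALSE]
  if (nrow(b) == 0L) return(list(continuous = FALSE, split = FALSE))
  left <- b[b$ref_start < bp_mid, , drop = FALSE]
  right <- b[b$ref_end > bp_mid, , drop = FALSE]
  if (nrow(left) == 0L || nrow(right) == 0L) {
    return(list(continuous = FALSE, split = FALSE))
  }
  main_chrom <- function(bb) {
    cov <- tapply(bb$length, bb$query_chrom, sum)
    names(which.max(cov))
  }
  lc <- main_chrom(left); rc <- main_chrom(right)
  list(continuous = identical(lc, rc), split = !identical(lc, rc))
}

#' Localise the breakpoint of a split reference chromosome
#'
#' Orders the blocks of the two query chromosomes along the reference,
#' chooses the split point minimising misassigned blocks, and returns the
#' gap between the last block on the left side and the first on the right.
#' Stray blocks (wrong side of the split) are tolerated up to
#' `tolerance` as a fraction of blocks, and reported.
#'
#' @param blocks Blocks of one reference chromosome mapping to exactly two
#'   query chromosomes.
#' @param tolerance Maximum fraction of misassigned blocks (default 0.1).
#' @return List: start, end (breakpoint interval on the reference), width,
#'   midpoint, strays (data.frame of misassigned blocks), ambiguous.
#' @export
localize_breakpoint <- function(blocks, tolerance = 0.1) {
  qcs <- unique(blocks$query_chrom)
  if (length(qcs) != 2L) stop("need blocks of exactly two query chromosomes")
  b <- blocks[order(blocks$ref_start), , drop = FALSE]
  n <- nrow(b)
  is_a <- b$query_chrom == qcs[1]
  # split after index k: left = 1..k; cost = #A right of split + #B left
  cost <- vapply(0:n, function(k) {
    sum(!is_a[seq_len(k)]) + sum(is_a[setdiff(seq_len(n), seq_len(k))])
  }, numeric(1))
  cost2 <- vapply(0:n, function(k) {  # other orientation (B left)
    sum(is_a[seq_len(k)]) + sum(!is_a[setdiff(seq_len(n), seq_len(k))])
  }, numeric(1))
  if (min(cost2) < min(cost)) { is_a <- !is_a; cost <- cost2 }
  k <- which.min(cost) - 1L
  mis <- cost[k + 1L]
  if (mis / n > tolerance || k == 0L || k == n) {
    return(list(start = NA_real_, end = NA_real_, width = NA_real_,
                midpoint = NA_real_, strays = b[0, ], ambiguous = TRUE))
  }
  left_ok <- seq_len(k)[is_a[seq_len(k)]]
  right_ok <- setdiff(seq_len(n), seq_len(k))
  right_ok <- right_ok[!is_a[right_ok]]
  s <- max(b$ref_end[left_ok])
  e <- min(b$ref_start[right_ok])
  strays <- b[c(seq_len(k)[!is_a[seq_len(k)]],
                setdiff(seq_len(n), seq_len(k))[is_a[setdiff(seq_len(n),
                                                             seq_len(k))]]),
              , drop = FALSE]
  if (e < s) { tmp <- s; s <- e; e <- tmp }
  list(start = s, end = e, width = e - s, midpoint = (s + e) / 2,
       strays = strays, ambiguous = FALSE)
}
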