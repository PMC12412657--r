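# Windowed diversity/differentiation statistics, Da dating, variant and SV
# filtering, and region-class contrasts.

#' Build a two-population genotype matrix container
#'
#' @param chrom Chromosome name (single value).
#' @param pos 0-based site positions (sorted).
#' @param gx,gy Integer matrices (sites x samples) of alt-allele dosages
#'   0/1/2, NA = missing, for populations X and Y.
#' @return List of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, gx, gy) {
  stopifnot(nrow(gx) == length(pos), nrow(gy) == length(pos))
  if (is.unsorted(pos)) stop("positions must be sorted")
  structure(list(chrom = chrom, pos = as.numeric(pos), gx = gx, gy = gy),
            class = "genotype_matrix")
}

#' Split a variant set into a two-population genotype matrix
#'
#' @param vs `variant_set` from [read_vcf()].
#' @param samples_x,samples_y Sample names of the two populations.
#' @return `genotype_matrix` (multiallelic sites dropped).
#' @export
vcf_genotype_matrix <- function(vs, samples_x, samples_y) {
  stopifnot(inherits(vs, "variant_set"))
  miss <- setdiff(c(samples_x, samples_y), vs$samples)
  if (length(miss)) stop("sample(s) not in variant set: ",
                         paste(miss, collapse = ", "))
  keep <- !vs$sites$multiallelic
  genotype_matrix(vs$sites$chrom[which(keep)[1]], vs$sites$pos[keep],
                  vs$gt[keep, samples_x, drop = FALSE],
                  vs$gt[keep, samples_y, drop = FALSE])
}

# Vectorised per-site statistics. Returns a data.frame with one row per
# site: pi_x, pi_y, dxy and the Weir & Cockerham (1984) variance components
# a (among populations), b (among individuals within populations) and
# c (within individuals). Sites with an all-missing population get NA and
# are excluded from window sums.
site_stats_matrix <- function(gx, gy) {
  cnt <- function(g) {
    called <- rowSums(!is.na(g))            # diploids called
    j <- rowSums(g, na.rm = TRUE)           # alt allele count
    het <- rowSums(g == 1L, na.rm = TRUE)   # heterozygote count
    list(n = called, j = j, het = het)
  }
  x <- cnt(gx); y <- cnt(gy)
  ok <- x$n > 0 & y$n > 0
  nx <- 2 * x$n; ny <- 2 * y$n
  pi_one <- function(j, nchr) {
    p <- ifelse(nchr >= 2, 2 * j * (nchr - j) / (nchr * (nchr - 1)), NA_real_)
    p
  }
  pi_x <- pi_one(x$j, nx)
  pi_y <- pi_one(y$j, ny)
  px <- x$j / nx
  py <- y$j / ny
  dxy <- px * (1 - py) + py * (1 - px)
  # Weir & Cockerham components, r = 2 populations
  n1 <- x$n; n2 <- y$n
  h1 <- x$het / n1; h2 <- y$het / n2
  p1 <- px; p2 <- py
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  res <- data.frame(pi_x = pi_x, pi_y = pi_y, dxy = dxy,
                    a = a, b = b, c = cc)
  res[!ok, ] <- NA_real_
  res$ok <- ok
  res
}

#' Per-site diversity and differentiation components
#'
#' For one biallelic site: nucleotide diversity within each population
#' (unbiased pairwise estimator 2j(n-j)/(n(n-1)) over called chromosomes),
#' raw divergence dxy = px(1-py) + py(1-px), and the Weir & Cockerham
#' (1984) two-population variance components a, b, c (site FST would be
#' a/(a+b+c); windows use the ratio-of-sums).
#'
#' @param genotypes_x,genotypes_y Integer dosage vectors (0/1/2, NA) for
#'   the site in populations X and Y.
#' @return List: pi_x, pi_y, dxy, a, b, c.
#' @export
site_stats <- function(genotypes_x, genotypes_y) {
  r <- site_stats_matrix(matrix(genotypes_x, nrow = 1),
                         matrix(genotypes_y, nrow = 1))
  if (!r$ok[1]) stop("site has an all-missing population")
  as.list(r[1, c("pi_x", "pi_y", "dxy", "a", "b", "c")])
}

#' Sliding-window diversity and differentiation
#'
#' Per window: per-site pi and dxy are summed and divided by the number of
#' callable sites (so monomorphic callable sites contribute zero,
#' consistent with all-sites genotyping); FST is the ratio-of-sums
#' (weighted) Weir-Cockerham estimator sum(a)/sum(a+b+c); Da = dxy -
#' (pi_x+pi_y)/2.
#'
#' @param geno `genotype_matrix` (variant sites only).
#' @param window_size,step Window width and step in bp.
#' @param chrom_length Extent tiled; default `max(pos) + 1`.
#' @param callable Either NULL (every base callable), a region data.frame
#'   of callable intervals, or a numeric vector of callable counts, one
#'   per window.
#' @return data.frame: chrom, start, end, n_sites (variant sites used),
#'   n_callable, pi_x, pi_y, dxy, fst, da.
#' @export
window_stats <- function(geno, window_size = 20000, step = window_size,
                         chrom_length = NULL, callable = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (window_size < step) stop("window_size must be >= step")
  if (is.null(chrom_length)) chrom_length <- max(geno$pos) + 1
  starts <- seq(0, max(0, chrom_length - 1), by = step)
  ss <- site_stats_matrix(geno$gx, geno$gy)
  n_win <- length(starts)
  callable_in <- function(s, e) {
    if (is.null(callable)) return(e - s)
    if (is.data.frame(callable)) {
      ov <- pmin(callable$end, e) - pmax(callable$start, s)
      return(sum(pmax(ov, 0)))
    }
    stop("callable must be NULL, a region data.frame, or per-window counts")
  }
  if (is.numeric(callable) && !is.data.frame(callable)) {
    if (length(callable) != n_win) stop("need one callable count per window")
    ncall <- callable
  } else {
    ncall <- vapply(seq_len(n_win), function(i) {
      callable_in(starts[i], min(starts[i] + window_size, chrom_length))
    }, numeric(1))
  }
  out <- lapply(seq_len(n_win), function(i) {
    s <- starts[i]; e <- min(s + window_size, chrom_length)
    in_w <- geno$pos >= s & geno$pos < e & ss$ok
    nc <- ncall[i]
    if (nc <= 0) {
      return(data.frame(chrom = geno$chrom, start = s, end = e,
                        n_sites = sum(in_w), n_callable = 0,
                        pi_x = NA_real_, pi_y = NA_real_, dxy = NA_real_,
                        fst = NA_real_, da = NA_real_))
    }
    pi_x <- sum(ss$pi_x[in_w]) / nc
    pi_y <- sum(ss$pi_y[in_w]) / nc
    dxy <- sum(ss$dxy[in_w]) / nc
    denom <- sum(ss$a[in_w] + ss$b[in_w] + ss$c[in_w], na.rm = TRUE)
    fst <- if (denom > 0) sum(ss$a[in_w], na.rm = TRUE) / denom else NA_real_
    data.frame(chrom = geno$chrom, start = s, end = e,
               n_sites = sum(in_w), n_callable = nc,
               pi_x = pi_x, pi_y = pi_y, dxy = dxy, fst = fst,
               da = dxy - (pi_x + pi_y) / 2)
  })
  do.call(rbind, out)
}

#' Net divergence and divergence time
#'
#' Da = Dxy - (pi_x + pi_y)/2; the divergence time in generations is
#' T = Da / (2 mu). Negative or zero Da leaves T undefined (flagged, not
#' clamped).
#'
#' @param dxy,pi_x,pi_y Per-site divergence and diversities.
#' @param mu Mutation rate per site per generation (> 0).
#' @param gen_years Generation time in years (default 1).
#' @return List: da, T_generations, T_years, defined (logical).
#' @export
da_and_time <- function(dxy, pi_x, pi_y, mu, gen_years = 1) {
  if (mu <= 0) stop("mu must be positive")
  da <- dxy - (pi_x + pi_y) / 2
  if (da > 0) {
    tg <- da / (2 * mu)
    list(da = da, T_generations = tg, T_years = tg * gen_years,
         defined = TRUE)
  } else {
    list(da = da, T_generations = NA_real_, T_years = NA_real_,
         defined = FALSE)
  }
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: sums the probabilities, conditional on the allele
#' counts, of every heterozygote count no more probable than the observed
#' one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Exact p-value.
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1.0)
  hets <- seq(nA %% 2, min(nA, na), by = 2)
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((na - hets) / 2) + hets * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[hets == n_Aa]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

#' Variant filter configuration
#'
#' Defaults follow common resequencing practice: genotypes are masked
#' (set missing) when GQ < `min_gq` or DP outside \[`min_dp`, `max_dp`\];
#' sites are then removed when multiallelic, within `indel_proximity_bp`
#' of an indel, called in fewer than `max_missing` of genotypes, with
#' minor-allele frequency below `maf`, or with exact HWE p below
#' `hwe_alpha`. `max_missing` uses the vcftools meaning: the minimum
#' fraction of genotypes that must be called (1 = no missing allowed).
#'
#' @param maf Minimum minor-allele frequency (default 0.05).
#' @param min_dp,max_dp Genotype depth bounds (default 5, 150).
#' @param min_gq Minimum genotype quality (default 20).
#' @param hwe_alpha HWE exact-test p cutoff (default 0.001).
#' @param max_missing Minimum called-genotype fraction (default 0.95).
#' @param indel_proximity_bp Exclusion distance around indels (default 5).
#' @param sv_min_len Minimum SV length kept (default 50).
#' @param sv_max_missing Maximum SV missing rate (default 0.05).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(maf = 0.05, min_dp = 5, max_dp = 150, min_gq = 20,
                          hwe_alpha = 0.001, max_missing = 0.95,
                          indel_proximity_bp = 5, sv_min_len = 50,
                          sv_max_missing = 0.05) {
  stopifnot(maf >= 0, maf <= 1, max_missing >= 0, max_missing <= 1,
            min_dp >= 0, max_dp >= min_dp, min_gq >= 0, hwe_alpha >= 0)
  structure(list(maf = maf, min_dp = min_dp, max_dp = max_dp,
                 min_gq = min_gq, hwe_alpha = hwe_alpha,
                 max_missing = max_missing,
                 indel_proximity_bp = indel_proximity_bp,
                 sv_min_len = sv_min_len, sv_max_missing = sv_max_missing),
            class = "filter_config")
}

#' Filter a variant set
#'
#' Genotype-level masking first (GQ/DP), then ordered site-level filters:
#' multiallelic, indel proximity, missingness, MAF, HWE. Each removed site
#' carries its first failing rule, so the audit trail is reproducible.
#'
#' @param vs `variant_set`.
#' @param config `filter_config`.
#' @param indel_positions Numeric vector of 0-based indel positions
#'   (default none).
#' @return List: `kept` (filtered `variant_set`), `removed` (data.frame
#'   chrom, pos, reason), `n_masked_genotypes`.
#' @export
filter_variants <- function(vs, config = filter_config(),
                            indel_positions = numeric(0)) {
  stopifnot(inherits(vs, "variant_set"), inherits(config, "filter_config"))
  gt <- vs$gt
  mask <- (!is.na(vs$gq) & vs$gq < config$min_gq) |
    (!is.na(vs$dp) & (vs$dp < config$min_dp | vs$dp > config$max_dp))
  n_masked <- sum(mask & !is.na(gt))
  gt[mask] <- NA_integer_
  n <- nrow(vs$sites)
  reason <- rep(NA_character_, n)
  called <- rowSums(!is.na(gt))
  total <- ncol(gt)
  j <- rowSums(gt, na.rm = TRUE)
  p <- ifelse(called > 0, j / (2 * called), NA_real_)
  maf <- pmin(p, 1 - p)
  near_indel <- if (length(indel_positions)) {
    vapply(vs$sites$pos, function(x) {
      any(abs(indel_positions - x) <= config$indel_proximity_bp)
    }, logical(1))
  } else rep(FALSE, n)
  for (i in seq_len(n)) {
    if (vs$sites$multiallelic[i]) { reason[i] <- "multiallelic"; next }
    if (near_indel[i]) { reason[i] <- "indel_proximity"; next }
    if (called[i] / total < config$max_missing) { reason[i] <- "missing"; next }
    if (is.na(maf[i]) || maf[i] < config$maf) { reason[i] <- "maf"; next }
    g <- gt[i, ]
    hp <- hwe_exact_p(sum(g == 0L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                      sum(g == 2L, na.rm = TRUE))
    if (hp < config$hwe_alpha) { reason[i] <- "hwe"; next }
  }
  keep <- is.na(reason)
  kept <- list(sites = vs$sites[keep, , drop = FALSE],
               gt = gt[keep, , drop = FALSE],
               dp = vs$dp[keep, , drop = FALSE],
               gq = vs$gq[keep, , drop = FALSE],
               samples = vs$samples)
  class(kept) <- "variant_set"
  list(kept = kept,
       removed = data.frame(chrom = vs$sites$chrom[!keep],
                            pos = vs$sites$pos[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE),
       n_masked_genotypes = n_masked)
}

#' Screen structural variants for species-specific fixation
#'
#' Flags SVs that pass the length and missing-rate filters, are
#' homozygous-present in every called individual of the focal species, and
#' absent in every called individual of all other species.
#'
#' @param svs data.frame with columns `id` and `length`.
#' @param genotypes Integer matrix (SVs x samples) of SV-allele dosages
#'   0/1/2, NA = missing.
#' @param species Character vector, one species label per sample column.
#' @param focal_species Focal species label.
#' @param config `filter_config` (uses `sv_min_len`, `sv_max_missing`).
#' @return Character vector of flagged SV ids.
#' @export
sv_fixation_screen <- function(svs, genotypes, species, focal_species,
                               config = filter_config()) {
  if (!focal_species %in% species) {
    stop("unknown focal species: ", focal_species)
  }
  stopifnot(nrow(svs) == nrow(genotypes), length(species) == ncol(genotypes))
  focal <- species == focal_species
  keep_len <- svs$length >= config$sv_min_len
  miss_rate <- rowMeans(is.na(genotypes))
  keep_miss <- miss_rate <= config$sv_max_missing
  gf <- genotypes[, focal, drop = FALSE]
  go <- genotypes[, !focal, drop = FALSE]
  fixed_focal <- rowSums(!is.na(gf)) > 0 &
    rowSums(is.na(gf) | gf == 2L) == ncol(gf)
  absent_other <- rowSums(is.na(go) | go == 0L) == ncol(go)
  svs$id[keep_len & keep_miss & fixed_focal & absent_other]
}

#' Density of selected sites per window
#'
#' Counts sites whose externally computed normalised score exceeds
#' `threshold` (selection in the focal population) or falls below
#' `-threshold` (selection in the other population), per tiling window.
#'
#' @param pos 0-based site positions.
#' @param scores Normalised per-site scores (e.g. XP-nSL), same length.
#' @param threshold Score cutoff (default 2).
#' @param window Window width in bp (default 100 kb).
#' @param chrom_length Extent tiled; default `max(pos) + 1`.
#' @return data.frame: start, end, n_focal, n_other.
#' @export
selected_site_density <- function(pos, scores, threshold = 2.0,
                                  window = 1e5, chrom_length = NULL) {
  stopifnot(length(pos) == length(scores))
  if (is.null(chrom_length)) chrom_length <- if (length(pos)) max(pos) + 1 else window
  starts <- seq(0, max(0, chrom_length - 1), by = window)
  idx <- findInterval(pos, starts)
  data.frame(
    start = starts,
    end = pmin(starts + window, chrom_length),
    n_focal = vapply(seq_along(starts), function(i) {
      sum(idx == i & scores > threshold)
    }, numeric(1)),
    n_other = vapply(seq_along(starts), function(i) {
      sum(idx == i & scores < -threshold)
    }, numeric(1)))
}

#' Exact/approximate two-sided Mann-Whitney p-value
#'
#' Exact enumeration of the permutation distribution of the rank sum
#' (midranks for ties, dynamic programming over all C(n+m, n) group
#' assignments) when both groups have at most `exact_limit` observations;
#' otherwise the normal approximation with tie and continuity correction
#' (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest per-group n for the exact path (default 12).
#' @return List: p, method ("exact"/"approx"), U (statistic for `x`).
#' @export
mann_whitney_p <- function(x, y, exact_limit = 12) {
  n <- length(x); m <- length(y)
  stopifnot(n >= 1, m >= 1)
  pooled <- c(x, y)
  r <- rank(pooled)  # midranks
  W <- sum(r[seq_len(n)])
  U <- W - n * (n + 1) / 2
  if (n <= exact_limit && m <= exact_limit) {
    # DP over doubled midranks (integers); count subsets of size n by sum
    dr <- as.integer(round(2 * r))
    N <- n + m
    maxs <- sum(sort(dr, decreasing = TRUE)[seq_len(n)])
    # f[[k+1]][s+1] = number of size-k subsets with doubled-rank sum s
    f <- vector("list", n + 1)
    f[[1]] <- c(1, rep(0, maxs))
    for (k in seq_len(n)) f[[k + 1]] <- rep(0, maxs + 1)
    for (it in dr) {
      for (k in n:1) {
        v <- f[[k]]
        shifted <- c(rep(0, it), v[seq_len(maxs + 1 - it)])
        f[[k + 1]] <- f[[k + 1]] + shifted
      }
    }
    counts <- f[[n + 1]]
    sums <- (0:maxs) / 2
    total <- choose(N, n)
    mu <- n * (N + 1) / 2
    dev_obs <- abs(W - mu)
    p <- sum(counts[abs(sums - mu) >= dev_obs - 1e-9]) / total
    list(p = min(1, p), method = "exact", U = U)
  } else {
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(p = wt$p.value, method = "approx", U = U)
  }
}

#' Contrast a window statistic between region classes
#'
#' Per class: n, mean, median of the chosen statistic; pairwise two-sided
#' Mann-Whitney tests between classes ([mann_whitney_p()]). Classes with
#' fewer than 2 windows are summarised but excluded from comparisons.
#'
#' @param stats Window-statistic data.frame with a class column.
#' @param statistic Name of the numeric column to contrast (e.g. "fst").
#' @param class_col Name of the class column (default "region_class").
#' @return List: `summary` data.frame (class, n, mean, median),
#'   `comparisons` data.frame (class_a, class_b, p, method), `notes`.
#' @export
region_contrast <- function(stats, statistic, class_col = "region_class") {
  vals <- stats[[statistic]]
  cls <- stats[[class_col]]
  keep <- !is.na(vals) & !is.na(cls)
  vals <- vals[keep]; cls <- as.character(cls[keep])
  classes <- sort(unique(cls))
  summ <- data.frame(
    class = classes,
    n = vapply(classes, function(k) sum(cls == k), numeric(1)),
    mean = vapply(classes, function(k) mean(vals[cls == k]), numeric(1)),
    median = vapply(classes, function(k) median(vals[cls == k]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  notes <- character(0)
  usable <- summ$class[summ$n >= 2]
  skipped <- setdiff(classes, usable)
  if (length(skipped)) {
    notes <- paste0("class '", skipped,
                    "' has fewer than 2 windows; comparisons omitted")
  }
  comps <- list()
  if (length(usable) >= 2) {
    pairs <- utils::combn(usable, 2)
    comps <- lapply(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      mw <- mann_whitney_p(vals[cls == a], vals[cls == b])
      data.frame(class_a = a, class_b = b, p = mw$p, method = mw$method,
                 stringsAsFactors = FALSE)
    })
  }
  list(summary = summ,
       comparisons = if (length(comps)) do.call(rbind, comps) else
         data.frame(class_a = character(), class_b = character(),
                    p = numeric(), method = character()),
       notes = notes)
}

#' Assign region classes to windows
#'
#' Windows are classified by midpoint membership in the labelled regions;
#' windows matching no region get class `default`.
#'
#' @param stats Window-statistic data.frame (chrom, start, end).
#' @param regions Labelled region data.frame.
#' @param default Class for unmatched windows (default "other").
#' @return `stats` with a `region_class` column.
#' @export
classify_windows <- function(stats, regions, default = "other") {
  mid <- (stats$start + stats$end) / 2
  cls <- rep(default, nrow(stats))
  for (i in seq_len(nrow(regions))) {
    hit <- stats$chrom == regions$chrom[i] &
      mid >= regions$start[i] & mid < regions$end[i]
    cls[hit] <- regions$label[i]
  }
  stats$region_class <- cls
  stats
}

#' Foreign-ancestry fraction per window
#'
#' Summarises per-haplotype local-ancestry segments into the fraction of
#' haplotype-bases in a window assigned to the other species' ancestry.
#'
#' @param segments data.frame: hap (haplotype id), start, end (0-based
#'   half-open), ancestry (label).
#' @param window Single-row region data.frame.
#' @param self_ancestry Label counted as "own" ancestry; everything else
#'   is foreign.
#' @param n_haps Number of haplotypes; default the number of distinct hap
#'   ids in `segments`.
#' @return Fraction in \[0, 1\].
#' @export
ancestry_fraction_by_window <- function(segments, window,
                                        self_ancestry = "self",
                                        n_haps = length(unique(segments$hap))) {
  stopifnot(nrow(window) == 1L, n_haps >= 1)
  for (h in unique(segments$hap)) {
    seg <- segments[segments$hap == h, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)])) {
      stop("overlapping ancestry segments on haplotype ", h)
    }
  }
  foreign <- segments[segments$ancestry != self_ancestry, , drop = FALSE]
  if (nrow(foreign) == 0L) return(0)
  ov <- pmin(foreign$end, window$end) - pmax(foreign$start, window$start)
  sum(pmax(ov, 0)) / (n_haps * (window$end - window$start))
}

#' Gene counts per tiling window
#'
#' Each gene is counted once, in the window containing its start.
#'
#' @param genes data.frame: chrom, start, end (0-based half-open).
#' @param window Window width in bp (default 50 kb).
#' @param chrom_lengths Named vector of chromosome lengths; default
#'   inferred from the data.
#' @return List: `windows` data.frame (chrom, start, end, n_genes),
#'   `mean_per_chrom` named vector, `mean_genome` scalar.
#' @export
gene_density <- function(genes, window = 50000, chrom_lengths = NULL) {
  chroms <- unique(genes$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(cc) {
      max(genes$end[genes$chrom == cc])
    }, numeric(1))
  }
  wins <- lapply(names(chrom_lengths), function(cc) {
    starts <- seq(0, max(0, chrom_lengths[[cc]] - 1), by = window)
    g <- genes$start[genes$chrom == cc]
    idx <- findInterval(g, starts)
    data.frame(chrom = cc, start = starts,
               end = pmin(starts + window, chrom_lengths[[cc]]),
               n_genes = tabulate(idx, nbins = length(starts)))
  })
  wins <- do.call(rbind, wins)
  mpc <- tapply(wins$n_genes, wins$chrom, mean)
  list(windows = wins, mean_per_chrom = mpc, mean_genome = mean(wins$n_genes))
}
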