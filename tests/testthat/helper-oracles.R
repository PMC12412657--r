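# Independent oracles used across the suite. These deliberately use
# different algorithms/algebra than the package implementation.

# Exhaustive BCS oracle: evaluates every integer window offset covering the
# positions and marks ws SNDs inside any qualifying window.
brute_force_bcs <- function(pos, ws, w = 300, min_subs = 4, min_frac = 0.8) {
  n <- length(pos)
  if (n == 0) return(logical(0))
  stopifnot(!is.unsorted(pos))
  cws <- c(0, cumsum(ws))
  is_bcs <- rep(FALSE, n)
  s_all <- (min(pos) - w):max(pos)             # every integer offset
  lo <- findInterval(s_all - 0.5, pos) + 1     # first index with pos >= s
  hi <- findInterval(s_all + w - 0.5, pos)     # last index with pos <= s+w-1
  cnt <- hi - lo + 1
  wsc <- cws[hi + 1] - cws[lo]
  qual <- which(cnt >= min_subs & wsc >= min_frac * cnt - 1e-9)
  for (k in qual) {
    idx <- lo[k]:hi[k]
    is_bcs[idx[ws[idx]]] <- TRUE
  }
  is_bcs
}

# Brute-force pi: mean pairwise difference over all pairs of called
# chromosomes (explicit double loop).
brute_pi <- function(g) {
  alleles <- unlist(lapply(g[!is.na(g)], function(d) {
    c(as.integer(d >= 1), as.integer(d == 2))
  }))
  m <- length(alleles)
  if (m < 2) return(NA_real_)
  tot <- 0; np <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    tot <- tot + (alleles[i] != alleles[j]); np <- np + 1
  }
  tot / np
}

# Brute-force dxy: mean difference over all cross-population chromosome
# pairs.
brute_dxy <- function(gx, gy) {
  ax <- unlist(lapply(gx[!is.na(gx)], function(d) c(as.integer(d >= 1),
                                                    as.integer(d == 2))))
  ay <- unlist(lapply(gy[!is.na(gy)], function(d) c(as.integer(d >= 1),
                                                    as.integer(d == 2))))
  tot <- 0; np <- 0
  for (i in seq_along(ax)) for (j in seq_along(ay)) {
    tot <- tot + (ax[i] != ay[j]); np <- np + 1
  }
  tot / np
}

# Weir & Cockerham (1984) variance components through the ANOVA
# mean-squares route (different algebra from the closed-form a/b/c used in
# the package). Returns c(a, b, c).
wc_anova <- function(gx, gy) {
  pops <- list(gx[!is.na(gx)], gy[!is.na(gy)])
  n_i <- vapply(pops, length, numeric(1))
  r <- 2
  n_tot <- sum(n_i)
  p_i <- vapply(pops, function(g) sum(g) / (2 * length(g)), numeric(1))
  h_i <- vapply(pops, function(g) mean(g == 1L), numeric(1))
  p_bar <- sum(n_i * p_i) / n_tot
  n_c <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
  # sums of squares for the allele indicator, hierarchical ANOVA
  ssp <- 2 * sum(n_i * (p_i - p_bar)^2)
  # SSI = sum over pops of 2 n_i p_i(1-p_i) - n_i h_i / 2  (textbook form)
  ssi <- sum(2 * n_i * p_i * (1 - p_i) - n_i * h_i / 2)
  ssg <- sum(n_i * h_i) / 2
  msp <- ssp / (r - 1)
  msi <- ssi / (n_tot - r)
  msg <- ssg / n_tot
  a <- (msp - msi) / (2 * n_c)
  b <- (msi - msg) / 2
  c <- msg
  c(a = a, b = b, c = c)
}

# Exact HWE probabilities by the Wigginton-style recurrence (independent of
# the lfactorial route used by the package); returns the two-sided p.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa; na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1.0)
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- setNames(numeric(length(hets)), hets)
  # start from the largest het count and recurse downward:
  # P(h-2)/P(h) = h (h-1) / ((nAA+1)(naa+1) * 4) with nAA, naa at h
  h0 <- max(hets)
  probs[as.character(h0)] <- 1
  h <- h0
  while (h - 2 >= hets[1]) {
    nAA_h <- (nA - h) / 2; naa_h <- (na - h) / 2
    probs[as.character(h - 2)] <- probs[as.character(h)] *
      h * (h - 1) / (4 * (nAA_h + 1) * (naa_h + 1))
    h <- h - 2
  }
  probs <- probs / sum(probs)
  p_obs <- probs[as.character(n_Aa)]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# Exact two-sided Mann-Whitney by explicit enumeration of all C(N, n)
# assignments (tiny n only).
mw_oracle <- function(x, y) {
  n <- length(x); N <- n + length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- n * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n)]) - mu)
  sets <- utils::combn(N, n)
  devs <- apply(sets, 2, function(ix) abs(sum(r[ix]) - mu))
  mean(devs >= obs - 1e-9)
}

# First premature stop of a skipped-exon CDS through Biostrings
# translation; returns list(cds_pos, exon) or NULL. Independent mapping of
# CDS positions to exons by walking the unskipped exon list.
ptc_oracle <- function(model, skip_id) {
  ex <- model$exons
  keep <- ex$id != skip_id
  tx <- paste(ex$seq[keep], collapse = "")
  cds <- substr(tx, model$cds_offset + 1, nchar(tx))
  cds <- substr(cds, 1, (nchar(cds) %/% 3) * 3)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  stars <- gregexpr("*", aa, fixed = TRUE)[[1]]
  if (stars[1] == -1L) return(NULL)
  cod <- stars[1]
  if (cod == nchar(aa)) return(NULL)          # terminal stop, not premature
  cds_pos <- 3 * (cod - 1)
  # map CDS nt position to the exon carrying it (skipped transcript)
  tx_pos <- model$cds_offset + cds_pos
  offset <- 0
  for (i in seq_len(nrow(ex))) {
    if (!keep[i]) next
    len <- nchar(ex$seq[i])
    if (tx_pos < offset + len) return(list(cds_pos = cds_pos, exon = ex$id[i]))
    offset <- offset + len
  }
  NULL
}

# Small crafted VCF exercising each site filter exactly once (plain text).
write_filter_fixture_vcf <- function(path, n_samples = 20) {
  samples <- sprintf("S%02d", seq_len(n_samples))
  gtline <- function(gts) paste(paste0(gts, ":30:99"), collapse = "\t")
  hom_mix <- function(n0, n1, n2, nmiss = 0) {
    c(rep("0/0", n0), rep("0/1", n1), rep("1/1", n2), rep("./.", nmiss))
  }
  rows <- c(
    paste("chr1", 100, ".", "A", "G,T", ".", "PASS", ".", "GT:DP:GQ",
          gtline(hom_mix(10, 5, 5)), sep = "\t"),             # multiallelic
    paste("chr1", 200, ".", "C", "T", ".", "PASS", ".", "GT:DP:GQ",
          gtline(hom_mix(10, 5, 5)), sep = "\t"),             # near indel
    paste("chr1", 300, ".", "G", "A", ".", "PASS", ".", "GT:DP:GQ",
          gtline(hom_mix(7, 5, 5, 3)), sep = "\t"),           # missing
    paste("chr1", 400, ".", "T", "C", ".", "PASS", ".", "GT:DP:GQ",
          gtline(hom_mix(19, 1, 0)), sep = "\t"),             # maf 0.025
    paste("chr1", 500, ".", "A", "C", ".", "PASS", ".", "GT:DP:GQ",
          gtline(hom_mix(10, 0, 10)), sep = "\t"),            # hwe
    paste("chr1", 600, ".", "G", "C", ".", "PASS", ".", "GT:DP:GQ",
          gtline(hom_mix(6, 8, 6)), sep = "\t"))              # survivor
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), path)
  path
}

# Random DNA with every occurrence of a motif (either strand) destroyed.
motif_free_seq <- function(L, unit = "TTAGGG") {
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  for (pat in c(unit, fissionkit:::revcomp(unit))) {
    repeat {
      m <- regexpr(pat, s, fixed = TRUE)
      if (m == -1L) break
      substr(s, m, m) <- "A"
      if (substr(s, m, m) == substr(pat, 1, 1)) substr(s, m, m) <- "C"
    }
  }
  s
}
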