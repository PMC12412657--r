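test_that("single-site statistics match hand-computed fixtures", {
  # both populations fixed for the reference allele
  s <- site_stats(c(0L, 0L), c(0L, 0L))
  expect_equal(c(s$pi_x, s$pi_y, s$dxy), c(0, 0, 0))
  # opposite fixation: dxy = 1, windowed FST = 1
  s <- site_stats(c(0L, 0L), c(2L, 2L))
  expect_equal(s$dxy, 1)
  expect_equal(s$a / (s$a + s$b + s$c), 1)
  # j = 2 alt among 4 chromosomes: pi = 2*2*2/(4*3) = 2/3, matching the
  # brute-force average over all 6 chromosome pairs (4 differing pairs)
  s <- site_stats(c(1L, 1L), c(0L, 0L))
  expect_equal(s$pi_x, 2 / 3)
  expect_equal(s$pi_x, brute_pi(c(1L, 1L)))
  expect_error(site_stats(c(NA_integer_, NA_integer_), c(0L, 1L)),
               "all-missing")
})

test_that("pi, dxy and WC components match brute-force oracles", {
  set.seed(31)
  for (rep in 1:8) {
    nx <- sample(2:10, 1); ny <- sample(2:10, 1)
    n_sites <- 40
    gx <- matrix(sample(c(0:2, NA), n_sites * nx, TRUE,
                        prob = c(.4, .25, .25, .1)), n_sites, nx)
    gy <- matrix(sample(c(0:2, NA), n_sites * ny, TRUE,
                        prob = c(.35, .3, .25, .1)), n_sites, ny)
    ss <- fissionkit:::site_stats_matrix(gx, gy)
    for (i in seq_len(n_sites)) {
      if (!ss$ok[i]) next
      x <- gx[i, ]; y <- gy[i, ]
      if (sum(!is.na(x)) < 1 || sum(!is.na(y)) < 1) next
      expect_equal(ss$pi_x[i], brute_pi(x), tolerance = 1e-12)
      expect_equal(ss$pi_y[i], brute_pi(y), tolerance = 1e-12)
      expect_equal(ss$dxy[i], brute_dxy(x, y), tolerance = 1e-12)
      w <- wc_anova(x, y)
      if (all(is.finite(w)) && all(is.finite(c(ss$a[i], ss$b[i], ss$c[i])))) {
        expect_equal(c(ss$a[i], ss$b[i], ss$c[i]), unname(w),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("windowed statistics divide by callable sites and pool FST", {
  # one fixed difference among 10 callable sites -> dxy = 0.1
  geno <- genotype_matrix("chr1", 4, matrix(2L, 1, 3), matrix(0L, 1, 3))
  w <- window_stats(geno, window_size = 10, step = 10, chrom_length = 10)
  expect_equal(w$dxy, 0.1)
  expect_equal(w$da, 0.1)
  # monomorphic matrix: all zeros
  geno0 <- genotype_matrix("chr1", c(3, 7), matrix(0L, 2, 4),
                           matrix(0L, 2, 4))
  w0 <- window_stats(geno0, window_size = 10, step = 10, chrom_length = 20)
  expect_true(all(w0$pi_x == 0 & w0$dxy == 0))
  # ratio-of-sums FST over two windows equals the single-window pass
  set.seed(13)
  gx <- matrix(sample(0:2, 40 * 6, TRUE), 40, 6)
  gy <- matrix(sample(0:2, 40 * 6, TRUE, prob = c(.6, .3, .1)), 40, 6)
  pos <- sort(sample.int(200, 40)) - 1
  geno2 <- genotype_matrix("chr1", pos, gx, gy)
  two <- window_stats(geno2, window_size = 100, step = 100, chrom_length = 200)
  one <- window_stats(geno2, window_size = 200, step = 200, chrom_length = 200)
  ss <- fissionkit:::site_stats_matrix(gx, gy)
  expect_equal(one$fst, sum(ss$a) / sum(ss$a + ss$b + ss$c))
  expect_equal(one$dxy * one$n_callable,
               sum(two$dxy * two$n_callable))
  # zero callable sites: stats missing but the window is still emitted
  w3 <- window_stats(geno2, window_size = 100, step = 100,
                     chrom_length = 200, callable = c(100, 0))
  expect_true(is.na(w3$dxy[2]))
})

test_that("Da dating applies T = Da/(2 mu) with undefined flagging", {
  expect_false(da_and_time(0.01, 0.01, 0.01, 1e-8)$defined)
  r <- da_and_time(6.06e-4, 0, 0, 3.03e-9)
  expect_equal(r$T_generations, 1e5)
  expect_equal(r$T_years, 1e5)
  r2 <- da_and_time(2 * 6.06e-4, 0, 0, 3.03e-9)
  expect_equal(r2$T_generations, 2e5)
  expect_error(da_and_time(0.01, 0, 0, 0), "mu")
})

test_that("genotype masking precedes the site filters", {
  pop <- simulate_divergent_populations(L = 2e4, seed = 6, n_x = 4, n_y = 4)
  vs <- pop$vcf
  vs$gq[1, 1] <- 19   # below min_gq 20 -> masked
  vs$dp[2, 2] <- 4    # below min_dp 5 -> masked
  vs$dp[2, 3] <- 151  # above max_dp -> masked
  res <- filter_variants(vs, filter_config(max_missing = 0, maf = 0,
                                           hwe_alpha = 0))
  expect_equal(res$n_masked_genotypes, 3L)
  expect_true(is.na(res$kept$gt[1, 1]))
  expect_true(all(is.na(res$kept$gt[2, 2:3])))
})

test_that("variant filtering is idempotent and audits reasons", {
  pop <- simulate_divergent_populations(L = 5e4, seed = 8)
  once <- filter_variants(pop$vcf, filter_config(hwe_alpha = 1e-6))
  twice <- filter_variants(once$kept, filter_config(hwe_alpha = 1e-6))
  expect_equal(nrow(twice$removed), 0L)
  expect_equal(twice$kept$sites, once$kept$sites)
  expect_true(all(once$removed$reason %in%
                    c("multiallelic", "indel_proximity", "missing",
                      "maf", "hwe")))
})

test_that("the exact HWE test matches the recurrence oracle", {
  expect_equal(hwe_exact_p(5, 0, 0), 1.0)
  expect_equal(hwe_exact_p(0, 2, 0), 1.0)  # both configurations included
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(1:30, 1)
    nAa <- sample(0:n, 1)
    nAA <- sample(0:(n - nAa), 1)
    naa <- n - nAa - nAA
    p1 <- hwe_exact_p(nAA, nAa, naa)
    expect_equal(p1, hwe_oracle(nAA, nAa, naa), tolerance = 1e-9)
    expect_equal(p1, hwe_exact_p(naa, nAa, nAA), tolerance = 1e-12)
    expect_gt(p1, 0); expect_lte(p1, 1)
  }
})

test_that("Mann-Whitney exact path matches enumeration and the approximation", {
  set.seed(23)
  for (rep in 1:10) {
    x <- sample(1:8, 5, TRUE); y <- sample(1:8, 4, TRUE)  # ties likely
    expect_equal(mann_whitney_p(x, y)$p, mw_oracle(x, y), tolerance = 1e-9)
  }
  # exact vs normal approximation at n = 12 vs 12
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(12, mean = 0.5)
    pe <- mann_whitney_p(x, y, exact_limit = 12)$p
    pa <- mann_whitney_p(x, y, exact_limit = 0)$p
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("region contrasts summarise classes and omit tiny ones", {
  stats <- data.frame(chrom = "chr1", start = 0:5 * 10, end = 1:6 * 10,
                      fst = c(.1, .2, .3, .8, .9, .5),
                      region_class = c("other", "other", "other",
                                       "breakpoint_flank", "breakpoint_flank",
                                       "lonely"))
  rc <- region_contrast(stats, "fst")
  expect_equal(rc$summary$n[rc$summary$class == "other"], 3)
  expect_equal(rc$summary$mean[rc$summary$class == "breakpoint_flank"], 0.85)
  expect_equal(rc$summary$median[rc$summary$class == "other"], 0.2)
  expect_true(any(grepl("lonely", rc$notes)))
  expect_false("lonely" %in% c(rc$comparisons$class_a, rc$comparisons$class_b))
})

test_that("window classification uses midpoints with a default class", {
  stats <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                      end = c(100, 200, 300))
  regs <- region("chr1", 90, 210, "breakpoint_flank")
  out <- classify_windows(stats, regs)
  expect_equal(out$region_class, c("other", "breakpoint_flank", "other"))
})

test_that("ancestry fractions count foreign haplotype-bases", {
  win <- region("chr1", 0, 40000, "w")
  segs <- data.frame(hap = c("h1", "h2"), start = c(0, 0),
                     end = c(40000, 40000),
                     ancestry = c("self", "self"))
  expect_equal(ancestry_fraction_by_window(segs, win), 0)
  segs$ancestry[2] <- "foreign"
  expect_equal(ancestry_fraction_by_window(segs, win), 0.5)
  segs2 <- data.frame(hap = c("h1", "h2"), start = c(0, 5000),
                      end = c(40000, 15000),
                      ancestry = c("self", "foreign"))
  expect_equal(ancestry_fraction_by_window(segs2, win), 0.125)
  overlap <- data.frame(hap = "h1", start = c(0, 500), end = c(1000, 1500),
                        ancestry = "foreign")
  expect_error(ancestry_fraction_by_window(overlap, win), "overlapping")
})

test_that("gene density counts genes once by start position", {
  genes <- data.frame(chrom = "chr1",
                      start = c(1000, 2000, 49000, 60000),
                      end = c(1500, 2500, 55000, 61000))
  gd <- gene_density(genes, window = 50000, chrom_lengths = c(chr1 = 1e5))
  expect_equal(gd$windows$n_genes, c(3, 1))
  expect_equal(sum(gd$windows$n_genes), nrow(genes))
  expect_equal(gd$mean_genome, 2)
})

test_that("selected-site densities conserve the exceedance count", {
  set.seed(3)
  pos <- sort(sample.int(5e5, 300)) - 1
  sc <- rnorm(300, sd = 1.5)
  d <- selected_site_density(pos, sc, threshold = 2, window = 1e5,
                             chrom_length = 5e5)
  expect_equal(sum(d$n_focal), sum(sc > 2))
  expect_equal(sum(d$n_other), sum(sc < -2))
  d0 <- selected_site_density(pos, rep(0, 300), window = 1e5,
                              chrom_length = 5e5)
  expect_true(all(d0$n_focal == 0 & d0$n_other == 0))
})

test_that("SV screening flags only fixed-in-focal, absent-elsewhere SVs", {
  svs <- data.frame(id = c("sv1", "sv2", "sv3"),
                    length = c(1129, 2459, 49))
  species <- c(rep("focal", 14), rep("otherA", 80), rep("otherB", 79))
  g <- matrix(0L, 3, length(species))
  g[, species == "focal"] <- 2L               # all three fixed in focal
  g[2, which(species == "focal")[1]] <- 1L    # sv2: one het -> not fixed
  flagged <- sv_fixation_screen(svs, g, species, "focal")
  expect_equal(flagged, "sv1")                # sv3 fails the length filter
  expect_error(sv_fixation_screen(svs, g, species, "missing_species"),
               "unknown")
})
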