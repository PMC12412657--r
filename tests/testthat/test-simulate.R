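test_that("generators are seed-deterministic and carry truth records", {
  a <- simulate_fission_triple(chrom_length = 2e5, breakpoint = 1e5,
                               region_width = 3e4, seed = 5,
                               emit_genomes = TRUE, its_span = 5e3)
  b <- simulate_fission_triple(chrom_length = 2e5, breakpoint = 1e5,
                               region_width = 3e4, seed = 5,
                               emit_genomes = TRUE, its_span = 5e3)
  expect_identical(a$snds, b$snds)
  expect_identical(a$genomes, b$genomes)
  expect_identical(a$truth$params, b$truth$params)
  c <- simulate_fission_triple(chrom_length = 2e5, breakpoint = 1e5,
                               region_width = 3e4, seed = 6,
                               emit_genomes = FALSE)
  expect_false(identical(a$snds$pos, c$snds$pos))
  expect_equal(a$truth$expected$T_years, 0.4 * 2.8e6)
  expect_error(simulate_fission_triple(f = 1.2), "0, 1")
  expect_error(simulate_fission_triple(k_tel = 1), "k_tel")
})

test_that("fission-triple outputs validate through the format round-trips", {
  td <- withr::local_tempdir()
  sim <- simulate_fission_triple(chrom_length = 2e5, breakpoint = 1e5,
                                 region_width = 3e4, seed = 2,
                                 emit_genomes = TRUE, its_span = 5e3,
                                 out_dir = td)
  expect_true(all(file.exists(file.path(td, c("snds.tsv", "regions.bed",
                                              "truth.json", "triple.fa")))))
  fa <- read_fasta(file.path(td, "triple.fa"))
  expect_equal(names(fa), c("target", "query", "outgroup"))
  expect_equal(unname(nchar(fa)), rep(2e5, 3))
  snds <- read_snd_table(file.path(td, "snds.tsv"))
  expect_equal(snds$pos, sim$snds$pos)
  regs <- read_regions_bed(file.path(td, "regions.bed"))
  expect_setequal(regs$label, c("telomeric", "control", "breakpoint_flank",
                                "fissioned"))
  truth <- jsonlite::read_json(file.path(td, "truth.json"))
  expect_equal(truth$params$f, 0.4)
})

test_that("population simulator hits its diversity and divergence targets", {
  set.seed(1)
  dxy_hat <- pi_hat <- numeric(6)
  for (s in 1:6) {
    pop <- simulate_divergent_populations(L = 4e5, seed = s)
    geno <- vcf_genotype_matrix(pop$vcf, pop$samples_x, pop$samples_y)
    ws <- window_stats(geno, 4e5, 4e5, chrom_length = 4e5,
                       callable = pop$callable)
    dxy_hat[s] <- ws$dxy
    pi_hat[s] <- ws$pi_x
  }
  truth <- simulate_divergent_populations(L = 1e3, seed = 1)$truth
  expect_equal(mean(dxy_hat), truth$expected$dxy, tolerance = 0.05)
  expect_equal(mean(pi_hat), 1e-3, tolerance = 0.1)
  expect_error(simulate_divergent_populations(T_gen = 1e10, mu = 1e-6),
               "exceed 1")
})

test_that("degenerate population parameters give identical monomorphs", {
  pop <- simulate_divergent_populations(L = 1e4, T_gen = 0, pi_x = 0,
                                        pi_y = 0, seed = 3)
  expect_equal(nrow(pop$vcf$sites), 0L)
  geno <- vcf_genotype_matrix(
    simulate_divergent_populations(L = 1e4, seed = 4)$vcf,
    sprintf("X%02d", 1:14), sprintf("Y%02d", 1:13))
  expect_true(all(geno$gx %in% 0:2))
})

test_that("rearrangement tables respect the block-length filter contract", {
  td <- withr::local_tempdir()
  sim <- simulate_rearranged_genomes("fission", seed = 8, out_dir = td)
  back <- read_synteny_blocks(file.path(td, "ref_query.tsv"), min_len = 8000)
  expect_gte(nrow(back), nrow(sim$ref_query) - 2)  # strays none here
  expect_true(all(back$length >= 8000))
  expect_identical(
    simulate_rearranged_genomes("fusion", seed = 9)$ref_query,
    simulate_rearranged_genomes("fusion", seed = 9)$ref_query)
})

test_that("transcript loci honour the requested frame class and planted word", {
  tl <- simulate_transcript_locus(seed = 13, skippable_mod3 = 1,
                                  plant_ese = list(exon = 6, offset = 10,
                                                   word = "CAGCAGA"))
  ex6 <- tl$model$exons$seq[6]
  expect_equal(substr(ex6, 11, 17), "CAGCAGA")
  cds_len6 <- nchar(ex6)
  expect_equal(cds_len6 %% 3, 1)
  # the designated skip yields a frameshift downstream
  expect_false(skipping_consequence(tl$model, 6)$frame_preserving)
  # no internal stop in the annotated frame
  tx <- paste(tl$model$exons$seq, collapse = "")
  n_cod <- nchar(tx) %/% 3
  codons <- substring(tx, 3 * (0:(n_cod - 1)) + 1, 3 * (1:n_cod))
  expect_false(any(codons[-n_cod] %in% c("TAA", "TAG", "TGA")))
  expect_equal(codons[n_cod], "TAA")
})

test_that("the end-to-end demo produces a coherent report", {
  td <- withr::local_tempdir()
  rep1 <- run_fission_demo(seed = 7, out_dir = td, n_perm = 50)
  expect_true(file.exists(file.path(td, "demo_report.json")))
  expect_true(is.finite(rep1$fission_time$T_years))
  expect_true("fission_in_query" %in% rep1$rearrangement$event)
  expect_gte(nrow(rep1$telomere_calls), 1L)
  expect_true(all(rep1$population_contrast$summary$n >= 1))
})
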