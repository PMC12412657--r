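test_that("clean fission, fusion and 1:1 tables classify as expected", {
  fis <- simulate_rearranged_genomes("fission", seed = 1)
  calls <- call_rearrangements(fis$ref_query, fis$ref_outgroup)
  c1 <- calls[calls$ref_chrom == "chr1", ]
  expect_equal(c1$event, "fission_in_query")
  expect_equal(calls$event[calls$ref_chrom == "chr2"], "none")
  # breakpoint near the planted position (block resolution)
  expect_lt(abs((c1$breakpoint_start + c1$breakpoint_end) / 2 - 1.2e7),
            2e7 / 12)
  fus <- simulate_rearranged_genomes("fusion", seed = 2)
  calls2 <- call_rearrangements(fus$ref_query, fus$ref_outgroup)
  expect_equal(calls2$event[calls2$ref_chrom == "chr1"], "fusion")
  non <- simulate_rearranged_genomes("none", seed = 3)
  calls3 <- call_rearrangements(non$ref_query, non$ref_outgroup)
  expect_true(all(calls3$event == "none"))
  expect_error(call_rearrangements(fis$ref_query[0, ], fis$ref_outgroup),
               "empty")
})

test_that("inversions and stray blocks do not change the call", {
  sim <- simulate_rearranged_genomes("fission", seed = 4, inversions = 4,
                                     strays = 1)
  calls <- call_rearrangements(sim$ref_query, sim$ref_outgroup)
  c1 <- calls[calls$ref_chrom == "chr1", ]
  expect_equal(c1$event, "fission_in_query")
  # the stray is reported by the localiser
  b1 <- sim$ref_query[sim$ref_query$ref_chrom == "chr1", ]
  loc <- localize_breakpoint(b1)
  expect_false(loc$ambiguous)
  expect_equal(nrow(loc$strays), 1L)
  expect_equal(loc$strays$length, 10000)
})

test_that("breakpoint localisation on a clean split returns the gap", {
  blocks <- data.frame(
    ref_chrom = "chr1",
    ref_start = c(0, 50, 100, 161, 220, 280) * 1e6 / 1e3,
    ref_end = c(49, 99, 159, 219, 279, 330) * 1e6 / 1e3,
    query_chrom = rep(c("qA", "qB"), each = 3),
    query_start = 0, query_end = 1,
    stringsAsFactors = FALSE)
  blocks$length <- blocks$ref_end - blocks$ref_start
  loc <- localize_breakpoint(blocks)
  expect_equal(loc$start, 159000)
  expect_equal(loc$end, 161000)
  expect_equal(loc$width, 2000)
})

test_that("fully interleaved assignments are ambiguous", {
  blocks <- data.frame(
    ref_chrom = "chr1",
    ref_start = 0:9 * 1000, ref_end = 0:9 * 1000 + 900,
    query_chrom = rep(c("qA", "qB"), 5),
    query_start = 0, query_end = 900, stringsAsFactors = FALSE)
  blocks$length <- 900
  loc <- localize_breakpoint(blocks)
  expect_true(loc$ambiguous)
})

test_that("the mirrored table attributes the split to the same lineage", {
  sim <- simulate_rearranged_genomes("fission", seed = 6)
  # swap the roles: the old query becomes the reference
  mirror <- sim$ref_query
  names(mirror)[1:6] <- c("query_chrom", "query_start", "query_end",
                          "ref_chrom", "ref_start", "ref_end")
  mirror <- mirror[, c("ref_chrom", "ref_start", "ref_end", "query_chrom",
                       "query_start", "query_end", "strand")]
  mirror$length <- mirror$ref_end - mirror$ref_start
  # outgroup blocks must be lifted onto the new reference coordinates:
  # the generator's outgroup table shares ref coordinates with ref_query,
  # so join on overlapping ref intervals via the block identity
  og <- sim$ref_outgroup
  og_m <- data.frame(ref_chrom = sim$ref_query$query_chrom,
                     ref_start = sim$ref_query$query_start,
                     ref_end = sim$ref_query$query_end,
                     query_chrom = og$query_chrom,
                     query_start = og$query_start,
                     query_end = og$query_end,
                     strand = og$strand,
                     length = sim$ref_query$query_end -
                       sim$ref_query$query_start,
                     stringsAsFactors = FALSE)
  calls <- call_rearrangements(mirror, og_m)
  # the derived split still belongs to the old query lineage, which is now
  # the reference side: a query-side (mirrored) fission-in-ref signature
  expect_true("fission_in_ref" %in% calls$event)
  expect_false("fission_in_query" %in% calls$event)
})
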