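test_that("BCS calls follow the cluster window rule on hand fixtures", {
  # 3 ws SNDs within 100 bp: below the 4-substitution minimum
  r <- find_bcs(data.frame(pos = c(0, 50, 100), ws = TRUE))
  expect_false(any(r$is_bcs))
  # 4 ws within one 300-bp window qualify; an isolated ws at 600 does not
  r <- find_bcs(data.frame(pos = c(0, 100, 200, 290, 600), ws = TRUE))
  expect_equal(r$is_bcs, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # 5 SNDs, 4 ws (fraction exactly 0.8): the ws are BCS, the non-ws is not
  r <- find_bcs(data.frame(pos = c(10, 30, 50, 70, 90),
                           ws = c(TRUE, TRUE, FALSE, TRUE, TRUE)))
  expect_equal(r$is_bcs, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_error(find_bcs(data.frame(pos = c(5, 1), ws = TRUE)), "sorted")
})

test_that("BCS detection covers windows not anchored at any SND", {
  # the only qualifying window [50, 350) isolates the four ws SNDs from the
  # trailing non-ws pair; windows anchored at SND positions all fail
  snds <- data.frame(pos = c(100, 110, 120, 130, 350, 360),
                     ws = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  r <- find_bcs(snds)
  expect_equal(r$is_bcs, c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$is_bcs, brute_force_bcs(snds$pos, snds$ws))
})

test_that("adding a ws SND inside a qualifying window never removes BCS", {
  set.seed(5)
  for (rep in 1:20) {
    pos <- sort(sample.int(2000, 60))
    ws <- runif(60) < 0.6
    base <- find_bcs(data.frame(pos = pos, ws = ws))
    hit <- which(base$is_bcs)
    if (length(hit) == 0) next
    newpos <- base$window_start[hit[1]] + 1L
    while (newpos %in% pos) newpos <- newpos + 1L
    aug <- rbind(data.frame(pos = pos, ws = ws),
                 data.frame(pos = newpos, ws = TRUE))
    aug <- aug[order(aug$pos), ]
    r2 <- find_bcs(aug)
    expect_gte(sum(r2$is_bcs), sum(base$is_bcs))
  }
})

test_that("regional UBCS handles empty and saturated regions", {
  reg <- region("chr1", 0, 1e4, "w")
  empty <- data.frame(chrom = character(), pos = numeric(),
                      derived_lineage = character(), ws = logical())
  expect_warning(u <- ubcs_for_region(empty, "query", reg, n_perm = 10),
                 "no SNDs")
  expect_equal(u$ubcs, 0)
  # all-ws region: the label shuffle is a no-op, so ubcs is exactly 0
  snds <- data.frame(chrom = "chr1", pos = sort(sample.int(1e4, 50)) - 1,
                     derived_lineage = "query", ws = TRUE)
  u <- ubcs_for_region(snds, "query", reg, n_perm = 50, seed = 3)
  expect_equal(u$observed_bcs, u$expected_bcs)
  expect_equal(u$ubcs, 0)
  expect_error(ubcs_for_region(snds, "query", region("chr1", 0, 100, "w")),
               "cluster window")
})

test_that("a region equal to a tile reproduces the tiled UBCS exactly", {
  set.seed(8)
  snds <- data.frame(chrom = "chr1",
                     pos = sort(sample.int(3e6, 4000)) - 1,
                     derived_lineage = "query",
                     ws = runif(4000) < 0.45)
  tiles <- ubcs_by_window(snds, "query", "chr1", 3e6, window = 1e6,
                          n_perm = 100, seed = 21)
  one <- ubcs_for_region(snds, "query", region("chr1", 1e6, 2e6, "window"),
                         n_perm = 100, seed = 21)
  expect_equal(one$ubcs, tiles$ubcs[2])
  expect_equal(one$expected_bcs, tiles$expected_bcs[2])
})

test_that("the fission-time formula reproduces its algebraic identities", {
  expect_equal(estimate_fission_time(2.8e6, 5, 5, 7, 7)$T_years, 0)
  expect_equal(estimate_fission_time(2.8e6, 0, 3, 6, 2)$T_years, 2.8e6)
  est <- estimate_fission_time(2.8e6, 1.2, 1, 2, 1)
  expect_equal(est$R1, 1.2)
  expect_equal(est$R2, 2)
  expect_equal(est$T_years, 1.12e6)
  expect_false(est$out_of_range)
  neg <- estimate_fission_time(2.8e6, 3, 1, 2, 1)
  expect_true(neg$out_of_range)
  expect_error(estimate_fission_time(2.8e6, 1, 0, 2, 1), "target breakpoint")
  expect_error(estimate_fission_time(2.8e6, 1, 1, 2, 0), "control")
})

test_that("date_fission wires the four regional UBCS values correctly", {
  sim <- simulate_fission_triple(chrom_length = 2e6, breakpoint = 1.2e6,
                                 region_width = 3e5, seed = 4,
                                 emit_genomes = FALSE)
  est <- date_fission(sim$snds, sim$regions, T_div = 2.8e6,
                      n_perm = 100, seed = 4)
  u <- est$ubcs
  expect_equal(u$label, c("breakpoint_flank", "breakpoint_flank",
                          "telomeric", "control"))
  expect_equal(u$lineage, c("query", "target", "query", "query"))
  expect_equal(est$R1, u$ubcs[1] / u$ubcs[2])
  expect_equal(est$R2, u$ubcs[3] / u$ubcs[4])
  # elevated telomeric bias must give positive UBCS under the sign decision
  expect_gt(u$ubcs[3], 0)
})
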