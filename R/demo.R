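# End-to-end toy analysis driving every stage on one seed.

#' Run the end-to-end toy fission analysis
#'
#' Simulates a fission triple, polarises SNDs from the aligned genomes,
#' dates the fission from UBCS ratios, simulates two diverged populations
#' and contrasts windowed FST between the breakpoint flank and the rest,
#' scans the synthetic genome for telomeric arrays, and polarises a
#' simulated rearrangement from synteny tables. Problem sizes are scaled
#' down so the demo runs in seconds.
#'
#' @param seed RNG seed driving every stage.
#' @param out_dir Optional directory for a `demo_report.json`.
#' @param n_perm Label permutations for the UBCS expectation (default 200).
#' @return List (the report): fission_time, population_contrast,
#'   telomere_calls, rearrangement, seed.
#' @export
run_fission_demo <- function(seed = 1, out_dir = NULL, n_perm = 200) {
  chrom_len <- 2e6
  sim <- simulate_fission_triple(chrom_length = chrom_len,
                                 breakpoint = 1.2e6, region_width = 3e5,
                                 cluster_rate = 2e-4, seed = seed,
                                 emit_genomes = TRUE, its_span = 2e4)
  # re-derive the SND table from the aligned genomes (full pipeline path)
  snds <- polarize_snds(sim$genomes$target, sim$genomes$query,
                        sim$genomes$outgroup, chrom = "chr1")
  est <- date_fission(snds, sim$regions, T_div = sim$truth$params$T_div,
                      n_perm = n_perm, seed = seed)
  pop <- simulate_divergent_populations(L = 2e5, seed = seed)
  geno <- vcf_genotype_matrix(pop$vcf, pop$samples_x, pop$samples_y)
  ws <- window_stats(geno, window_size = 2e4, step = 2e4,
                     chrom_length = 2e5, callable = pop$callable)
  ws <- classify_windows(ws, region("chr1", 0, 6e4, "breakpoint_flank"))
  contrast <- region_contrast(ws, "fst")
  scan <- scan_telomeric_repeats(sim$genomes$target, window = 5000)
  its <- call_its(scan, chrom_length = chrom_len, end_margin = 5e4)
  rearr <- simulate_rearranged_genomes("fission", seed = seed)
  calls <- call_rearrangements(rearr$ref_query, rearr$ref_outgroup)
  report <- list(
    seed = seed,
    fission_time = list(T_years = est$T_years, R1 = est$R1, R2 = est$R2,
                        T_div = est$T_div, n_perm = n_perm),
    population_contrast = list(summary = contrast$summary,
                               comparisons = contrast$comparisons),
    telomere_calls = its,
    rearrangement = calls)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "demo_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  report
}
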