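# Seed-deterministic synthetic-data generators. Every generator returns a
# truth record sufficient to recompute its expectations, and (optionally)
# writes its outputs in the standard interchange formats.

truth_record <- function(generator, seed, params, expected = list()) {
  structure(list(generator = generator, seed = seed, params = params,
                 expected = expected), class = "truth_record")
}

#' Write a truth record as JSON
#' @param truth `truth_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a target/query/outgroup triple with a planted centric fission
#'
#' Generates lineage-polarised SNDs along one chromosome: a Poisson
#' background of substitutions (weak-to-strong with probability
#' `ws_base_frac`) plus 300-bp cluster seeds of weak-to-strong
#' substitutions whose local intensity is elevated in telomere-like
#' regions. Cluster intensity is `cluster_rate` per bp times a regional
#' multiplier: `k_tel` in the telomeric regions of both lineages, 1 in the
#' interior control and in the target breakpoint flank, and
#' `k_tel * (1 - f)` in the query breakpoint flank, where `f = T / T_div`
#' is the fraction of the divergence time since the fission. This
#' calibration makes the UBCS ratio estimator recover `T = f * T_div` in
#' expectation (E(R1)/E(R2) = 1 - f); it is formula-consistent by
#' construction, so recovery tests validate the pipeline, not the
#' formula's biological derivation. The aligned genomes (optional) carry
#' terminal telomere arrays and an interstitial telomeric array at the
#' breakpoint, shared by all three sequences.
#'
#' @param chrom_length Chromosome length in bp (default 10 Mb).
#' @param snd_rate Background SND rate per bp per lineage (default 0.004).
#' @param ws_base_frac Background weak-to-strong fraction (default 0.3).
#' @param cluster_rate Baseline cluster-seed rate per bp (default 6e-5).
#' @param cluster_snds Weak-to-strong SNDs planted per cluster (default 12).
#' @param k_tel Telomeric intensity amplification (> 1; default 3).
#' @param f Fission onset fraction T/T_div in \[0, 1\] (default 0.4).
#' @param T_div Divergence time in years (default 2.8e6).
#' @param breakpoint Fission breakpoint position (default 7 Mb).
#' @param region_width Width of the telomeric/control regions and of the
#'   whole breakpoint flank (default 2 Mb; flank = breakpoint +/- 1 Mb).
#' @param seed RNG seed.
#' @param emit_genomes Generate the three aligned sequences (default TRUE).
#' @param its_span Width of the interstitial telomeric array planted at
#'   the breakpoint (default 30 kb); terminal arrays are `its_span`-wide.
#' @param out_dir Optional directory: writes snds.tsv, regions.bed,
#'   truth.json and (with genomes) triple.fa.
#' @return List: `snds` (snd_table), `regions`, `genomes` (named list
#'   target/query/outgroup or NULL), `truth`.
#' @export
simulate_fission_triple <- function(chrom_length = 1e7, snd_rate = 0.004,
                                    ws_base_frac = 0.3, cluster_rate = 6e-5,
                                    cluster_snds = 12, k_tel = 3, f = 0.4,
                                    T_div = 2.8e6, breakpoint = 7e6,
                                    region_width = 2e6, seed = 1,
                                    emit_genomes = TRUE, its_span = 3e4,
                                    out_dir = NULL) {
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  if (k_tel <= 1) stop("k_tel must exceed 1")
  if (breakpoint <= region_width || breakpoint >= chrom_length - region_width) {
    stop("breakpoint must lie inside the chromosome, clear of the regions")
  }
  set.seed(as.integer(seed))
  chrom <- "chr1"
  half <- region_width / 2
  regions <- rbind(
    region(chrom, 0, region_width, "telomeric"),
    region(chrom, 1.5 * region_width, 2.5 * region_width, "control"),
    region(chrom, breakpoint - half, breakpoint + half, "breakpoint_flank"),
    region(chrom, 0, chrom_length, "fissioned"))
  mult_for <- function(lineage) {
    m <- data.frame(start = numeric(0), end = numeric(0), mult = numeric(0))
    add <- function(m, s, e, k) rbind(m, data.frame(start = s, end = e, mult = k))
    m <- add(m, 0, region_width, k_tel)                       # telomeric
    m <- add(m, chrom_length - region_width, chrom_length, k_tel)
    bp_mult <- if (lineage == "query") k_tel * (1 - f) else 1
    m <- add(m, breakpoint - half, breakpoint + half, bp_mult)
    m
  }
  gen_lineage <- function(lineage) {
    n_bg <- rpois(1, snd_rate * chrom_length)
    pos <- floor(runif(n_bg) * chrom_length)
    ws <- runif(n_bg) < ws_base_frac
    m <- mult_for(lineage)
    # baseline clusters outside special regions
    special <- m
    base_len <- chrom_length - sum(special$end - special$start)
    n_base <- rpois(1, cluster_rate * base_len)
    cl_starts <- numeric(0)
    if (n_base > 0) {
      s <- floor(runif(2 * n_base + 20) * chrom_length)
      in_special <- rep(FALSE, length(s))
      for (i in seq_len(nrow(special))) {
        in_special <- in_special | (s >= special$start[i] & s < special$end[i])
      }
      cl_starts <- s[!in_special][seq_len(min(n_base, sum(!in_special)))]
    }
    for (i in seq_len(nrow(special))) {
      lambda <- cluster_rate * (special$end[i] - special$start[i]) * special$mult[i]
      k <- rpois(1, lambda)
      if (k > 0) {
        cl_starts <- c(cl_starts,
                       special$start[i] +
                         floor(runif(k) * (special$end[i] - special$start[i] - 300)))
      }
    }
    for (s in cl_starts) {
      cp <- s + floor(runif(cluster_snds) * 300)
      pos <- c(pos, cp)
      ws <- c(ws, rep(TRUE, cluster_snds))
    }
    o <- order(pos)
    pos <- pos[o]; ws <- ws[o]
    dup <- duplicated(pos)
    data.frame(pos = pos[!dup], ws = ws[!dup],
               derived_lineage = lineage, stringsAsFactors = FALSE)
  }
  tg <- gen_lineage("target")
  qu <- gen_lineage("query")
  qu <- qu[!(qu$pos %in% tg$pos), , drop = FALSE]  # one derived lineage per column
  snds <- rbind(tg, qu)
  snds <- snds[order(snds$pos), , drop = FALSE]
  # repeat arrays shared by all three genomes; SNDs inside them are removed
  arrays <- rbind(
    data.frame(start = 0, end = its_span, kind = "terminal"),
    data.frame(start = chrom_length - its_span, end = chrom_length,
               kind = "terminal"),
    data.frame(start = breakpoint - its_span / 2,
               end = breakpoint + its_span / 2, kind = "interstitial"))
  in_array <- rep(FALSE, nrow(snds))
  for (i in seq_len(nrow(arrays))) {
    in_array <- in_array | (snds$pos >= arrays$start[i] &
                              snds$pos < arrays$end[i])
  }
  snds <- snds[!in_array, , drop = FALSE]
  # assign bases: ws => ancestral A/T, derived G/C; otherwise any non-ws pair
  n <- nrow(snds)
  anc <- der <- character(n)
  is_ws <- snds$ws
  anc[is_ws] <- sample(c("A", "T"), sum(is_ws), replace = TRUE)
  der[is_ws] <- sample(c("G", "C"), sum(is_ws), replace = TRUE)
  nonws_pairs <- cbind(
    c("A", "C", "C", "C", "G", "G", "G", "T"),
    c("T", "A", "G", "T", "A", "C", "T", "A"))
  pick <- sample.int(nrow(nonws_pairs), sum(!is_ws), replace = TRUE)
  anc[!is_ws] <- nonws_pairs[pick, 1]
  der[!is_ws] <- nonws_pairs[pick, 2]
  snd_tab <- data.frame(
    chrom = chrom, pos = snds$pos,
    target = ifelse(snds$derived_lineage == "target", der, anc),
    query = ifelse(snds$derived_lineage == "query", der, anc),
    outgroup = anc, derived_lineage = snds$derived_lineage,
    ws = is_ws, stringsAsFactors = FALSE)
  class(snd_tab) <- c("snd_table", "data.frame")
  genomes <- NULL
  if (emit_genomes) {
    base <- sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE)
    unit <- strsplit("TTAGGG", "")[[1]]
    for (i in seq_len(nrow(arrays))) {
      span <- arrays$end[i] - arrays$start[i]
      base[(arrays$start[i] + 1):arrays$end[i]] <-
        rep(unit, length.out = span)
    }
    t_vec <- q_vec <- base
    at <- snd_tab$pos + 1
    t_vec[at] <- snd_tab$target
    q_vec[at] <- snd_tab$query
    o_vec <- base
    o_vec[at] <- snd_tab$outgroup
    genomes <- list(target = paste(t_vec, collapse = ""),
                    query = paste(q_vec, collapse = ""),
                    outgroup = paste(o_vec, collapse = ""))
  }
  truth <- truth_record(
    "simulate_fission_triple", seed,
    params = list(chrom_length = chrom_length, snd_rate = snd_rate,
                  ws_base_frac = ws_base_frac, cluster_rate = cluster_rate,
                  cluster_snds = cluster_snds, k_tel = k_tel, f = f,
                  T_div = T_div, breakpoint = breakpoint,
                  region_width = region_width, its_span = its_span,
                  arrays = arrays),
    expected = list(R1 = k_tel * (1 - f), R2 = k_tel, T_years = f * T_div))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_snd_table(snd_tab, file.path(out_dir, "snds.tsv"))
    write_regions_bed(regions, file.path(out_dir, "regions.bed"))
    write_truth(truth, file.path(out_dir, "truth.json"))
    if (!is.null(genomes)) {
      write_fasta(unlist(genomes), file.path(out_dir, "triple.fa"))
    }
  }
  list(snds = snd_tab, regions = regions, genomes = genomes, truth = truth)
}

#' Simulate two diverged diploid populations
#'
#' Site-independent model: each site is a fixed interspecies difference
#' with probability `2 * mu * T_gen`, or a shared ancestral polymorphism
#' (same allele frequency q ~ U(0,1) in both populations, independent
#' binomial genotype draws) at the rate needed to hit the common
#' within-population diversity target in expectation. With equal diversity
#' targets this makes E(Da) = 2 * mu * T_gen exact; an excess of one
#' population's target is added as private low-frequency polymorphism
#' (q ~ U(0, 0.1)), which biases Dxy upward by < 4% of the excess.
#'
#' @param L Number of callable sites (default 1e6).
#' @param T_gen Divergence time in generations (default 1e5).
#' @param mu Mutation rate per site per generation (default 3.03e-9).
#' @param pi_x,pi_y Within-population diversity targets (default 1e-3).
#' @param n_x,n_y Diploid sample sizes (default 14 and 13).
#' @param seed RNG seed.
#' @param out_dir Optional directory: writes sites.vcf, callable.bed,
#'   samples_x.txt, samples_y.txt, truth.json.
#' @return List: `vcf` (`variant_set` of segregating/fixed sites),
#'   `callable` (region), `samples_x`, `samples_y`, `truth`.
#' @export
simulate_divergent_populations <- function(L = 1e6, T_gen = 1e5,
                                           mu = 3.03e-9, pi_x = 1e-3,
                                           pi_y = 1e-3, n_x = 14, n_y = 13,
                                           seed = 1, out_dir = NULL) {
  stopifnot(L > 0, T_gen >= 0, mu > 0, n_x >= 1, n_y >= 1,
            pi_x >= 0, pi_y >= 0)
  d <- 2 * mu * T_gen
  pi_s <- min(pi_x, pi_y)
  s_shared <- 3 * pi_s                       # E[2q(1-q)] = 1/3 for q~U(0,1)
  qmax <- 0.1
  h_ex <- qmax - 2 * qmax^2 / 3              # E[2q(1-q)] for q~U(0,qmax)
  s_x <- if (pi_x > pi_s) (pi_x - pi_s) / h_ex else 0
  s_y <- if (pi_y > pi_s) (pi_y - pi_s) / h_ex else 0
  if (d + s_shared + s_x + s_y > 1) stop("site-class probabilities exceed 1")
  set.seed(as.integer(seed))
  counts <- as.vector(rmultinom(1, L, c(d, s_shared, s_x, s_y,
                                        1 - d - s_shared - s_x - s_y)))
  n_var <- sum(counts[1:4])
  pos <- sort(sample.int(L, n_var)) - 1       # 0-based
  cls <- sample(rep.int(c("fixed", "shared", "px", "py"), counts[1:4]))
  gx <- matrix(0L, n_var, n_x)
  gy <- matrix(0L, n_var, n_y)
  for (i in seq_len(n_var)) {
    if (cls[i] == "fixed") {
      gx[i, ] <- 2L
    } else if (cls[i] == "shared") {
      q <- runif(1)
      gx[i, ] <- rbinom(n_x, 2, q)
      gy[i, ] <- rbinom(n_y, 2, q)
    } else if (cls[i] == "px") {
      gx[i, ] <- rbinom(n_x, 2, runif(1, 0, qmax))
    } else {
      gy[i, ] <- rbinom(n_y, 2, runif(1, 0, qmax))
    }
  }
  seg <- rowSums(gx) + rowSums(gy) > 0
  pos <- pos[seg]; gx <- gx[seg, , drop = FALSE]; gy <- gy[seg, , drop = FALSE]
  samples_x <- sprintf("X%02d", seq_len(n_x))
  samples_y <- sprintf("Y%02d", seq_len(n_y))
  nv <- length(pos)
  ref_alt <- matrix(sample(c("A", "C", "G", "T"), 2 * nv, replace = TRUE),
                    ncol = 2)
  if (nv > 0) {
    same <- ref_alt[, 1] == ref_alt[, 2]
    ref_alt[same, 2] <- chartr("ACGT", "GTAC", ref_alt[same, 1])
  }
  gt <- cbind(gx, gy)
  colnames(gt) <- c(samples_x, samples_y)
  vs <- list(sites = data.frame(chrom = rep("chr1", nv), pos = pos,
                                ref = ref_alt[, 1], alt = ref_alt[, 2],
                                multiallelic = logical(nv),
                                stringsAsFactors = FALSE),
             gt = gt,
             dp = matrix(30, nv, n_x + n_y,
                         dimnames = list(NULL, c(samples_x, samples_y))),
             gq = matrix(99, nv, n_x + n_y,
                         dimnames = list(NULL, c(samples_x, samples_y))),
             samples = c(samples_x, samples_y))
  class(vs) <- "variant_set"
  callable <- region("chr1", 0, L, "callable")
  truth <- truth_record(
    "simulate_divergent_populations", seed,
    params = list(L = L, T_gen = T_gen, mu = mu, pi_x = pi_x, pi_y = pi_y,
                  n_x = n_x, n_y = n_y),
    expected = list(dxy = d + (pi_x + pi_y) / 2, da = d, T_gen = T_gen))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(vs, file.path(out_dir, "sites.vcf"))
    write_regions_bed(callable, file.path(out_dir, "callable.bed"))
    writeLines(samples_x, file.path(out_dir, "samples_x.txt"))
    writeLines(samples_y, file.path(out_dir, "samples_y.txt"))
    write_truth(truth, file.path(out_dir, "truth.json"))
  }
  list(vcf = vs, callable = callable, samples_x = samples_x,
       samples_y = samples_y, truth = truth)
}

#' Simulate synteny-block tables for a rearrangement
#'
#' Builds reference-query and reference-outgroup block tables consistent
#' with the requested event, with block-boundary jitter, inter-block gaps,
#' optional inversions and optional stray (misassigned) blocks. The
#' outgroup always represents the ancestral state: joined for a fission in
#' the query, split for a fusion.
#'
#' @param event "fission", "fusion" or "none".
#' @param ref_chrom_lengths Named vector of reference chromosome lengths.
#' @param event_chrom Reference chromosome carrying the event.
#' @param breakpoint Event position on `event_chrom`.
#' @param blocks_per_chrom Syntenic blocks per chromosome (default 12).
#' @param inversions Number of randomly inverted blocks (default 0).
#' @param strays Number of small misassigned blocks planted on the event
#'   chromosome (default 0).
#' @param seed RNG seed.
#' @param out_dir Optional directory: writes ref_query.tsv,
#'   ref_outgroup.tsv, truth.json.
#' @return List: `ref_query`, `ref_outgroup` (block data.frames), `truth`.
#' @export
simulate_rearranged_genomes <- function(event = c("fission", "fusion", "none"),
                                        ref_chrom_lengths = c(chr1 = 2e7,
                                                              chr2 = 1.5e7),
                                        event_chrom = "chr1",
                                        breakpoint = 1.2e7,
                                        blocks_per_chrom = 12,
                                        inversions = 0, strays = 0,
                                        seed = 1, out_dir = NULL) {
  event <- match.arg(event)
  set.seed(as.integer(seed))
  tile_chrom <- function(cc, L) {
    n <- blocks_per_chrom
    edges <- round(seq(0, L, length.out = n + 1) +
                     c(0, runif(n - 1, -0.15, 0.15) * L / n, 0))
    starts <- edges[-(n + 1)]; ends <- edges[-1]
    gap <- pmax(1, round(runif(n, 0.005, 0.02) * (ends - starts)))
    data.frame(ref_chrom = cc, ref_start = starts + gap,
               ref_end = ends - gap, stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, lapply(names(ref_chrom_lengths), function(cc) {
    tile_chrom(cc, ref_chrom_lengths[[cc]])
  }))
  assign_partner <- function(b, split_chrom, split_at, prefix) {
    part <- paste0(prefix, b$ref_chrom)
    if (!is.null(split_chrom)) {
      on_c <- b$ref_chrom == split_chrom
      right <- on_c & (b$ref_start + b$ref_end) / 2 >= split_at
      part[right] <- paste0(prefix, split_chrom, "_new")
    }
    part
  }
  q_split <- if (event == "fission") event_chrom else NULL
  o_split <- if (event == "fusion") event_chrom else NULL
  make_table <- function(partner) {
    out <- blocks
    out$query_chrom <- partner
    # query coordinates: cumulative along each partner chromosome
    out$query_start <- NA_real_; out$query_end <- NA_real_
    for (qc in unique(partner)) {
      ix <- which(partner == qc)
      lens <- out$ref_end[ix] - out$ref_start[ix]
      qs <- cumsum(c(0, lens[-length(lens)] + 1000))
      out$query_start[ix] <- qs
      out$query_end[ix] <- qs + lens
    }
    out$strand <- "+"
    if (inversions > 0) {
      inv <- sample.int(nrow(out), min(inversions, nrow(out)))
      out$strand[inv] <- "-"
    }
    out$length <- out$ref_end - out$ref_start
    out
  }
  rq <- make_table(assign_partner(blocks, q_split, breakpoint, "q_"))
  ro <- make_table(assign_partner(blocks, o_split, breakpoint, "o_"))
  if (strays > 0 && event == "fission") {
    qcs <- unique(rq$query_chrom[rq$ref_chrom == event_chrom])
    for (i in seq_len(strays)) {
      s <- round(runif(1, 0.05, 0.4) * breakpoint)  # inside left territory
      stray <- data.frame(ref_chrom = event_chrom, ref_start = s,
                          ref_end = s + 10000,
                          query_chrom = qcs[2],   # wrong side
                          query_start = 0, query_end = 10000,
                          strand = "+", length = 10000,
                          stringsAsFactors = FALSE)
      rq <- rbind(rq, stray)
    }
    rq <- rq[order(rq$ref_chrom, rq$ref_start), , drop = FALSE]
  }
  truth <- truth_record(
    "simulate_rearranged_genomes", seed,
    params = list(event = event, event_chrom = event_chrom,
                  breakpoint = breakpoint,
                  blocks_per_chrom = blocks_per_chrom,
                  inversions = inversions, strays = strays),
    expected = list(event = switch(event, fission = "fission_in_query",
                                   fusion = "fusion", none = "none")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_synteny_blocks(rq, file.path(out_dir, "ref_query.tsv"))
    write_synteny_blocks(ro, file.path(out_dir, "ref_outgroup.tsv"))
    write_truth(truth, file.path(out_dir, "truth.json"))
  }
  list(ref_query = rq, ref_outgroup = ro, truth = truth)
}

#' Simulate a toy transcript locus with a skippable exon
#'
#' Generates a coding-compatible multi-exon transcript: random non-stop
#' codons with a terminal TAA, exon lengths adjusted so that the
#' designated skippable exon has the requested coding length mod 3, and
#' optionally a planted ESE word at a requested exon offset.
#'
#' @param n_exons Number of exons (default 10).
#' @param exon_lengths Optional integer vector of exon lengths; default
#'   random in 60..200, adjusted for `skippable_mod3` and codon totals.
#' @param skippable_exon Exon designated for skipping tests (default 6).
#' @param skippable_mod3 Required skipped-exon coding length mod 3
#'   (default 1, i.e. a frameshifting skip).
#' @param plant_ese Optional list(exon, offset, word) planting `word` at
#'   the 0-based `offset` within that exon.
#' @param domains Domain-to-exon map (default FHA exons 1-3, PBZ 7-9).
#' @param intron_length Length of the uniform synthetic introns
#'   (default 120).
#' @param seed RNG seed.
#' @return List: `model` (`transcript_model`), `genomic_seq`, `truth`.
#' @export
simulate_transcript_locus <- function(n_exons = 10, exon_lengths = NULL,
                                      skippable_exon = 6, skippable_mod3 = 1,
                                      plant_ese = NULL,
                                      domains = list(FHA = c(1, 3),
                                                     PBZ = c(7, 9)),
                                      intron_length = 120, seed = 1) {
  stopifnot(n_exons >= 3, skippable_exon > 1, skippable_exon < n_exons)
  set.seed(as.integer(seed))
  if (is.null(exon_lengths)) {
    exon_lengths <- sample(60:200, n_exons, replace = TRUE)
  }
  # coding length of the skippable exon must be skippable_mod3 (mod 3),
  # and the total must be a codon multiple
  k <- skippable_exon
  exon_lengths[k] <- exon_lengths[k] - (exon_lengths[k] %% 3) + skippable_mod3
  total <- sum(exon_lengths)
  exon_lengths[n_exons] <- exon_lengths[n_exons] + (3 - total %% 3) %% 3
  total <- sum(exon_lengths)
  n_cod <- total %/% 3
  codons <- all_codons()[!all_codons() %in% c("TAA", "TAG", "TGA")]
  cds <- c(sample(codons, n_cod - 1, replace = TRUE), "TAA")
  seq <- paste(cds, collapse = "")
  if (!is.null(plant_ese)) {
    off <- sum(exon_lengths[seq_len(plant_ese$exon - 1)]) + plant_ese$offset
    substr(seq, off + 1, off + nchar(plant_ese$word)) <- plant_ese$word
    # repair any stop codon the planted word may have created nearby
    for (ci in seq_len(n_cod - 1)) {
      cd <- substr(seq, 3 * ci - 2, 3 * ci)
      if (cd %in% c("TAA", "TAG", "TGA")) {
        word_rng <- c(off, off + nchar(plant_ese$word))
        if (3 * ci - 3 >= word_rng[2] || 3 * ci <= word_rng[1]) {
          substr(seq, 3 * ci - 2, 3 * ci) <- "AAA"
        } else {
          stop("planted word introduces an in-frame stop codon")
        }
      }
    }
  }
  ends_tx <- cumsum(exon_lengths)
  starts_tx <- c(0, ends_tx[-n_exons])
  g_starts <- starts_tx + (seq_len(n_exons) - 1) * intron_length
  exons <- data.frame(id = seq_len(n_exons), start = g_starts,
                      end = g_starts + exon_lengths,
                      seq = substring(seq, starts_tx + 1, ends_tx),
                      stringsAsFactors = FALSE)
  model <- transcript_model(exons, cds_start_exon = 1, cds_start_offset = 0,
                            cds_len = total, domains = domains)
  introns <- replicate(n_exons - 1, paste(
    sample(c("A", "C", "G", "T"), intron_length, replace = TRUE),
    collapse = ""))
  genomic <- paste0(paste0(exons$seq[-n_exons], introns, collapse = ""),
                    exons$seq[n_exons])
  truth <- truth_record(
    "simulate_transcript_locus", seed,
    params = list(n_exons = n_exons, exon_lengths = exon_lengths,
                  skippable_exon = skippable_exon,
                  skippable_mod3 = skippable_mod3,
                  plant_ese = plant_ese, domains = domains),
    expected = list(frameshift = skippable_mod3 != 0))
  list(model = model, genomic_seq = genomic, truth = truth)
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
}
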