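# ESE motif scoring and exon-skipping consequence prediction.

#' Construct a transcript model
#'
#' @param exons data.frame with columns `id` (integer, 1..n in transcript
#'   order), `start`, `end` (genomic, 0-based half-open, non-overlapping,
#'   ordered) and `seq` (exon sequence, length end - start).
#' @param cds_start_exon,cds_start_offset Exon id and 0-based offset within
#'   that exon where the CDS begins.
#' @param cds_len CDS length in nt (including the stop codon); default
#'   from the CDS start to the transcript end, trimmed to a codon multiple.
#' @param strand "+" or "-" (informational; exon sequences are given in
#'   transcript orientation).
#' @param domains Named list of `c(first_exon, last_exon)` integer ranges.
#' @return List of class `transcript_model`.
#' @export
transcript_model <- function(exons, cds_start_exon, cds_start_offset,
                             cds_len = NULL, strand = "+", domains = list()) {
  stopifnot(all(c("id", "start", "end", "seq") %in% names(exons)))
  exons <- exons[order(exons$id), , drop = FALSE]
  if (any(nchar(exons$seq) != exons$end - exons$start)) {
    stop("exon sequence length must equal end - start")
  }
  if (any(diff(exons$start) <= 0) ||
      any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("exons must be ordered and non-overlapping")
  }
  if (!cds_start_exon %in% exons$id) stop("CDS start exon not in model")
  tx_starts <- cumsum(c(0, nchar(exons$seq)))[seq_len(nrow(exons))]
  cds_off <- tx_starts[match(cds_start_exon, exons$id)] + cds_start_offset
  tx_len <- sum(nchar(exons$seq))
  if (is.null(cds_len)) cds_len <- ((tx_len - cds_off) %/% 3) * 3
  if (cds_len < 3) stop("CDS shorter than one codon")
  structure(list(exons = exons, tx_starts = tx_starts,
                 cds_start_exon = cds_start_exon,
                 cds_start_offset = cds_start_offset,
                 cds_offset = cds_off, cds_len = cds_len,
                 strand = strand, domains = domains),
            class = "transcript_model")
}

transcript_seq <- function(model) paste(model$exons$seq, collapse = "")

# transcript coordinate -> exon id (0-based tx position)
tx_pos_to_exon <- function(model, pos) {
  model$exons$id[findInterval(pos, model$tx_starts)]
}

#' Score a sequence against ESE position weight matrices
#'
#' Every window of each matrix's width is scored as the sum of the
#' per-position weights of its bases; windows meeting the matrix threshold
#' are reported as hits. Matrices are strand-specific: the sequence is
#' scanned as given.
#'
#' @param seq DNA sequence over ACGT.
#' @param matrices List of PWMs ([read_pwm()], [load_sr_matrices()]).
#' @param all_scores If TRUE, return every window, not only hits.
#' @return data.frame: factor, pos (0-based window start), word, score,
#'   passes_threshold.
#' @export
scan_ese <- function(seq, matrices, all_scores = FALSE) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("sequence must be over ACGT")
  rows <- lapply(matrices, function(pwm) {
    L <- nchar(seq)
    w <- pwm$width
    if (L < w) return(NULL)
    starts <- 0:(L - w)
    words <- substring(seq, starts + 1, starts + w)
    scores <- vapply(words, score_word, numeric(1), pwm = pwm,
                     USE.NAMES = FALSE)
    df <- data.frame(factor = pwm$factor, pos = starts, word = words,
                     score = scores,
                     passes_threshold = scores >= pwm$threshold,
                     stringsAsFactors = FALSE)
    if (all_scores) df else df[df$passes_threshold, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(factor = character(), pos = numeric(),
                                      word = character(), score = numeric(),
                                      passes_threshold = logical())
  rownames(out) <- NULL
  out
}

score_word <- function(word, pwm) {
  bases <- strsplit(word, "", fixed = TRUE)[[1]]
  sum(pwm$matrix[cbind(seq_along(bases), match(bases, c("A", "C", "G", "T")))])
}

#' Impact of a point mutation on ESE scores
#'
#' For each factor, the best score among all matrix windows overlapping
#' the mutated position, before and after the substitution. A factor is
#' `disrupted` when the wild type passes the threshold and the mutant does
#' not, `created` in the reverse case, else `neutral`.
#'
#' @param seq Wild-type sequence.
#' @param pos 0-based position of the substitution.
#' @param alt_base Mutant base (must differ from the reference base).
#' @param matrices List of PWMs.
#' @return data.frame: factor, wt_best_score, mut_best_score,
#'   wt_passes, mut_passes, delta, classification.
#' @export
mutation_ese_impact <- function(seq, pos, alt_base, matrices) {
  seq <- toupper(seq); alt_base <- toupper(alt_base)
  L <- nchar(seq)
  stopifnot(pos >= 0, pos < L)
  ref <- substr(seq, pos + 1, pos + 1)
  if (identical(ref, alt_base)) stop("alt base equals the reference base")
  mut <- seq
  substr(mut, pos + 1, pos + 1) <- alt_base
  rows <- lapply(matrices, function(pwm) {
    w <- pwm$width
    starts <- max(0, pos - w + 1):min(L - w, pos)
    if (length(starts) == 0L || starts[1] > pos) {
      return(data.frame(factor = pwm$factor, wt_best_score = NA_real_,
                        mut_best_score = NA_real_, wt_passes = FALSE,
                        mut_passes = FALSE, delta = NA_real_,
                        classification = "neutral"))
    }
    sc <- function(s) {
      max(vapply(starts, function(st) {
        score_word(substr(s, st + 1, st + w), pwm)
      }, numeric(1)))
    }
    wt <- sc(seq); mu <- sc(mut)
    wp <- wt >= pwm$threshold; mp <- mu >= pwm$threshold
    cls <- if (wp && !mp) "disrupted" else if (!wp && mp) "created" else "neutral"
    data.frame(factor = pwm$factor, wt_best_score = wt, mut_best_score = mu,
               wt_passes = wp, mut_passes = mp, delta = mu - wt,
               classification = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Consequences of skipping one exon
#'
#' Frame preservation is decided by the skipped exon's coding length mod 3.
#' The post-skip CDS is translated to locate a premature termination codon
#' (PTC): the first stop codon that is not the final codon of the new CDS.
#' Domains are `lost` when their exon range begins at/after the PTC exon
#' (or lies entirely downstream of the skipped exon under a frameshift)
#' and `partially_truncated` when the PTC falls inside their range. With
#' primers given, amplicon lengths for the inclusion and exclusion
#' isoforms are returned.
#'
#' @param model `transcript_model`.
#' @param skipped_exon_id Id of the (internal, at least partly coding)
#'   exon to skip.
#' @param primers Optional list with `fwd = c(exon_id, offset)` and
#'   `rev = c(exon_id, offset)`; offsets are 0-based within the exon, the
#'   reverse offset marks the last base of the amplicon.
#' @return List of class `skipping_consequence`: skipped_exon,
#'   skipped_cds_len, frame_preserving, ptc (list exon, cds_pos, codon or
#'   NULL), lost_domains, partially_truncated_domains,
#'   inclusion_amplicon_bp, exclusion_amplicon_bp.
#' @export
skipping_consequence <- function(model, skipped_exon_id, primers = NULL) {
  stopifnot(inherits(model, "transcript_model"))
  ex <- model$exons
  idx <- match(skipped_exon_id, ex$id)
  if (is.na(idx)) stop("exon not in model: ", skipped_exon_id)
  if (idx == 1L || idx == nrow(ex)) stop("cannot skip a terminal exon")
  if (skipped_exon_id == model$cds_start_exon) {
    stop("unsupported: skipping the CDS-start exon")
  }
  tx_s <- model$tx_starts[idx]
  tx_e <- tx_s + nchar(ex$seq[idx])
  cds_s <- model$cds_offset
  cds_e <- model$cds_offset + model$cds_len
  cod_s <- max(tx_s, cds_s); cod_e <- min(tx_e, cds_e)
  skipped_cds_len <- max(0, cod_e - cod_s)
  if (skipped_cds_len == 0) stop("skipped exon is entirely non-coding")
  frame_preserving <- skipped_cds_len %% 3 == 0
  tx <- transcript_seq(model)
  new_tx <- paste0(substr(tx, 1, tx_s), substr(tx, tx_e + 1, nchar(tx)))
  # CDS start is upstream of the skipped exon (cds-start exon not skippable)
  new_cds <- substr(new_tx, cds_s + 1, nchar(new_tx))
  n_cod <- nchar(new_cds) %/% 3
  ptc <- NULL
  if (n_cod >= 1) {
    codons <- substring(new_cds, 3 * (0:(n_cod - 1)) + 1, 3 * (1:n_cod))
    stop_i <- which(codons %in% c("TAA", "TAG", "TGA"))
    # a stop is premature unless it is the final complete codon
    if (length(stop_i) && stop_i[1] < n_cod) {
      cds_pos <- 3 * (stop_i[1] - 1)   # 0-based nt in the new CDS
      new_tx_pos <- cds_s + cds_pos
      # map back to an original exon id (positions after the skip junction
      # shift up by the skipped exon length)
      orig_pos <- if (new_tx_pos >= tx_s) new_tx_pos + (tx_e - tx_s) else new_tx_pos
      ptc <- list(exon = tx_pos_to_exon(model, orig_pos),
                  cds_pos = cds_pos, codon = codons[stop_i[1]])
    }
  }
  lost <- character(0); partial <- character(0)
  for (nm in names(model$domains)) {
    rng <- model$domains[[nm]]
    if (!is.null(ptc)) {
      if (rng[1] >= ptc$exon) lost <- c(lost, nm)
      else if (rng[2] >= ptc$exon) partial <- c(partial, nm)
    } else if (!frame_preserving && rng[1] > skipped_exon_id) {
      lost <- c(lost, nm)
    }
  }
  inc_amp <- exc_amp <- NULL
  if (!is.null(primers)) {
    p_tx <- function(p) model$tx_starts[match(p[1], ex$id)] + p[2]
    fwd <- p_tx(primers$fwd); rev <- p_tx(primers$rev)
    if (rev <= fwd) stop("reverse primer must lie downstream of forward")
    inc_amp <- rev - fwd + 1
    shift <- function(p) if (p >= tx_e) p - (tx_e - tx_s) else p
    if (fwd >= tx_s && fwd < tx_e) stop("forward primer inside skipped exon")
    if (rev >= tx_s && rev < tx_e) stop("reverse primer inside skipped exon")
    exc_amp <- shift(rev) - shift(fwd) + 1
  }
  structure(list(skipped_exon = skipped_exon_id,
                 skipped_cds_len = skipped_cds_len,
                 frame_preserving = frame_preserving, ptc = ptc,
                 lost_domains = lost, partially_truncated_domains = partial,
                 inclusion_amplicon_bp = inc_amp,
                 exclusion_amplicon_bp = exc_amp),
            class = "skipping_consequence")
}
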