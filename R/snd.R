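# Outgroup polarisation of single-nucleotide differences (SNDs).

#' Polarise single-nucleotide differences with an outgroup
#'
#' Scans three equal-length aligned sequences (target, query, outgroup).
#' A column yields an SND only when target != query and the outgroup base
#' equals exactly one of them; the derived lineage is the one the outgroup
#' does not match. `ws` flags weak-to-strong substitutions (ancestral A/T,
#' derived G/C), the signature amplified by GC-biased gene conversion.
#' Columns containing any non-ACGT character (gap, N, IUPAC code) are
#' skipped; no parsimony rescue is attempted when the outgroup matches
#' neither base or carries a fourth allele.
#'
#' @param target_seq,query_seq,outgroup_seq Aligned sequences (equal length).
#' @param chrom Chromosome name recorded on the output (target coordinates).
#' @param offset 0-based position of the first alignment column.
#' @return data.frame (class `snd_table`): chrom, pos (0-based), target,
#'   query, outgroup, derived_lineage ("target"/"query"), ws (logical).
#' @export
polarize_snds <- function(target_seq, query_seq, outgroup_seq,
                          chrom = "chr1", offset = 0) {
  n <- nchar(target_seq)
  if (nchar(query_seq) != n || nchar(outgroup_seq) != n) {
    stop("aligned sequences must have equal length")
  }
  t <- str_bases(target_seq)
  q <- str_bases(query_seq)
  o <- str_bases(outgroup_seq)
  acgt <- c("A", "C", "G", "T")
  ok <- t %in% acgt & q %in% acgt & o %in% acgt
  cand <- ok & t != q & (o == t | o == q)  # polarisable mismatch columns
  idx <- which(cand)
  derived_lineage <- ifelse(o[idx] == t[idx], "query", "target")
  ancestral <- o[idx]
  derived <- ifelse(derived_lineage == "query", q[idx], t[idx])
  ws <- ancestral %in% c("A", "T") & derived %in% c("G", "C")
  out <- data.frame(chrom = rep(chrom, length(idx)),
                    pos = offset + idx - 1,
                    target = t[idx], query = q[idx], outgroup = o[idx],
                    derived_lineage = derived_lineage, ws = ws,
                    stringsAsFactors = FALSE)
  class(out) <- c("snd_table", "data.frame")
  out
}

str_bases <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

#' Write an SND table to TSV
#' @param snds `snd_table` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snd_table <- function(snds, path) {
  df <- as.data.frame(snds)
  df$ws <- ifelse(df$ws, "1", "0")
  df$pos <- format_int(df$pos)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an SND table from TSV
#' @param path TSV written by [write_snd_table()].
#' @return `snd_table` data.frame.
#' @export
read_snd_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  bad <- setdiff(unique(df$derived_lineage), c("target", "query"))
  if (length(bad)) stop("unknown derived_lineage token(s): ",
                        paste(bad, collapse = ", "))
  df$ws <- df$ws %in% c("1", "TRUE", "true")
  class(df) <- c("snd_table", "data.frame")
  df
}
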