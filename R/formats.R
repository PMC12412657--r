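# IO for every external representation the pipeline touches.
# Convention: 0-based half-open coordinates internally; 1-based inclusive
# only in region strings and VCF POS.

#' Read a FASTA file
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector of uppercased sequences, in file order.
#' @details Sequences are uppercased; records must have unique names and
#'   non-empty sequences. Alphabet is not restricted here (N and IUPAC
#'   codes pass through); downstream operations skip non-ACGT columns.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  nm <- names(ss)
  nm <- sub("\\s.*$", "", nm)  # first token of the header line
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA record name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record(s): ", paste(nm[nchar(seqs) == 0L], collapse = ", "))
  }
  names(seqs) <- nm
  seqs
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Parse a samtools-style region string
#'
#' Converts `"chr:start-end"` (1-based, inclusive) to the internal 0-based
#' half-open convention.
#'
#' @param text Region string such as `"chr1:1-100"`.
#' @param label Optional label attached to the region.
#' @return A `region` data.frame with columns chrom, start, end, label.
#' @examples
#' parse_region("chr1:1-100")  # start 0, end 100
#' @export
parse_region <- function(text, label = "region") {
  m <- regmatches(text, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", text))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", text)
  start1 <- as.numeric(gsub(",", "", m[3]))
  end1 <- as.numeric(gsub(",", "", m[4]))
  if (end1 < start1) stop("region end before start: ", text)
  region(m[2], start1 - 1, end1, label)
}

#' Construct a region table
#'
#' @param chrom,start,end,label Vectors (recycled) describing 0-based
#'   half-open intervals with a free-form label (conventional labels:
#'   breakpoint_flank, telomeric, control, fissioned, other).
#' @return data.frame with columns chrom, start, end, label.
#' @export
region <- function(chrom, start, end, label = "region") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0) || any(end <= start)) {
    stop("invalid region: require 0 <= start < end")
  }
  data.frame(chrom = as.character(chrom), start = start, end = end,
             label = as.character(label), stringsAsFactors = FALSE)
}

#' Read regions from a BED3+label file
#'
#' @param path BED file; columns chrom, start, end and optionally name.
#' @return region data.frame.
#' @export
read_regions_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns: ", path)
  lab <- if (ncol(df) >= 4L) as.character(df[[4]]) else "region"
  region(df[[1]], df[[2]], df[[3]], lab)
}

#' Write regions to a BED3+label file
#'
#' @param regions region data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, format_int(regions$start),
                   format_int(regions$end), regions$label)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a VCF into a variant set
#'
#' Parses a VCF v4.x text file (GT plus optional DP/GQ FORMAT keys) into a
#' `variant_set`: a site table plus integer genotype/DP/GQ matrices.
#' Positions are converted to 0-based. Multiallelic records are retained and
#' flagged (their genotypes are set missing); removal is the job of
#' [filter_variants()].
#'
#' @param path VCF path (plain text or gzipped).
#' @param samples Optional character vector restricting and ordering the
#'   samples; an absent sample is an error naming it.
#' @return A list of class `variant_set` with elements `sites` (data.frame:
#'   chrom, pos (0-based), ref, alt, multiallelic), `gt` (sites x samples
#'   integer matrix of alt-allele dosages 0/1/2, NA = missing), `dp`, `gq`
#'   (same shape, NA where absent) and `samples`.
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  all_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- all_samples
  missing_s <- setdiff(samples, all_samples)
  if (length(missing_s)) {
    stop("sample(s) absent from VCF header: ", paste(missing_s, collapse = ", "))
  }
  fix <- v@fix
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt_raw <- gt_raw[, samples, drop = FALSE]
  dose <- gt_dosage(gt_raw)
  dose[multi, ] <- NA_integer_  # dosage undefined for >2 alleles
  dp <- extract_numeric_fmt(v, "DP", samples)
  gq <- extract_numeric_fmt(v, "GQ", samples)
  vs <- list(
    sites = data.frame(chrom = fix[, "CHROM"],
                       pos = as.numeric(fix[, "POS"]) - 1,
                       ref = fix[, "REF"], alt = alt,
                       multiallelic = multi, stringsAsFactors = FALSE),
    gt = dose, dp = dp, gq = gq, samples = samples)
  class(vs) <- "variant_set"
  vs
}

gt_dosage <- function(gt_raw) {
  d <- matrix(NA_integer_, nrow = nrow(gt_raw), ncol = ncol(gt_raw),
              dimnames = dimnames(gt_raw))
  g <- gsub("|", "/", gt_raw, fixed = TRUE)
  d[g %in% c("0/0", "0")] <- 0L
  d[g %in% c("0/1", "1/0")] <- 1L
  d[g %in% c("1/1", "1")] <- 2L
  d
}

extract_numeric_fmt <- function(v, key, samples) {
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  n <- nrow(v@fix)
  if (!(key %in% fmt_keys)) {
    return(matrix(NA_real_, nrow = n, ncol = length(samples),
                  dimnames = list(NULL, samples)))
  }
  m <- suppressWarnings(vcfR::extract.gt(v, element = key, as.numeric = TRUE))
  m[, samples, drop = FALSE]
}

#' Write a variant set as a minimal VCF v4.2 file
#'
#' @param vs A `variant_set` (see [read_vcf()]).
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path) {
  stopifnot(inherits(vs, "variant_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t")), con)
  n <- nrow(vs$sites)
  if (n == 0L) return(invisible(path))
  gt_str <- matrix("./.", n, length(vs$samples))
  gt_str[!is.na(vs$gt) & vs$gt == 0L] <- "0/0"
  gt_str[!is.na(vs$gt) & vs$gt == 1L] <- "0/1"
  gt_str[!is.na(vs$gt) & vs$gt == 2L] <- "1/1"
  fmt_cell <- function(i) {
    dp <- ifelse(is.na(vs$dp[i, ]), ".", format_int(vs$dp[i, ]))
    gq <- ifelse(is.na(vs$gq[i, ]), ".", format_int(vs$gq[i, ]))
    paste(gt_str[i, ], dp, gq, sep = ":")
  }
  lines <- vapply(seq_len(n), function(i) {
    paste(c(vs$sites$chrom[i], format_int(vs$sites$pos[i] + 1), ".",
            vs$sites$ref[i], vs$sites$alt[i], ".", "PASS", ".",
            "GT:DP:GQ", fmt_cell(i)), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read synteny blocks from a 7-column TSV
#'
#' Columns: ref_chrom, ref_start, ref_end, query_chrom, query_start,
#' query_end, strand (+/-). Coordinates 0-based half-open. Blocks shorter
#' than `min_len` on the reference are dropped (alignment-length filter;
#' default 8 kb).
#'
#' @param path TSV path.
#' @param min_len Minimum reference-span length kept (bp). Default 8000.
#' @return data.frame of blocks with a `length` column (ref span).
#' @export
read_synteny_blocks <- function(path, min_len = 8000) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(empty_blocks())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 7L)
  if (length(bad)) stop("malformed synteny row at line ", bad[1], " of ", path)
  m <- do.call(rbind, parts)
  df <- data.frame(
    ref_chrom = m[, 1], ref_start = as.numeric(m[, 2]),
    ref_end = as.numeric(m[, 3]), query_chrom = m[, 4],
    query_start = as.numeric(m[, 5]), query_end = as.numeric(m[, 6]),
    strand = m[, 7], stringsAsFactors = FALSE)
  if (anyNA(df$ref_start) || anyNA(df$ref_end) ||
      any(!df$strand %in% c("+", "-"))) {
    stop("malformed synteny coordinates/strand in ", path)
  }
  df$length <- df$ref_end - df$ref_start
  if (any(df$length <= 0)) stop("non-positive block length in ", path)
  df[df$length >= min_len, , drop = FALSE]
}

empty_blocks <- function() {
  data.frame(ref_chrom = character(), ref_start = numeric(),
             ref_end = numeric(), query_chrom = character(),
             query_start = numeric(), query_end = numeric(),
             strand = character(), length = numeric(),
             stringsAsFactors = FALSE)
}

#' Write synteny blocks to TSV
#' @param blocks Block data.frame (see [read_synteny_blocks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synteny_blocks <- function(blocks, path) {
  df <- blocks[, c("ref_chrom", "ref_start", "ref_end", "query_chrom",
                   "query_start", "query_end", "strand")]
  for (cc in c("ref_start", "ref_end", "query_start", "query_end")) {
    df[[cc]] <- format_int(df[[cc]])
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a position weight matrix with its score threshold
#'
#' Format: TSV with header `pos A C G T`, one row per motif position, plus
#' a `# threshold: <x>` comment line (or a sidecar `<file>.threshold`).
#'
#' @param path PWM TSV path.
#' @return List with `factor` (file stem), `width`, `matrix` (width x 4,
#'   columns A,C,G,T) and `threshold`.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  thr_line <- grep("^#\\s*threshold:", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  df <- read.table(text = body, header = TRUE, sep = "\t")
  need <- c("pos", "A", "C", "G", "T")
  if (!all(need %in% names(df))) stop("PWM needs header 'pos A C G T': ", path)
  mat <- as.matrix(df[order(df$pos), c("A", "C", "G", "T")])
  if (nrow(mat) < 1L || anyNA(mat)) stop("invalid PWM body: ", path)
  thr <- NA_real_
  if (length(thr_line)) {
    thr <- as.numeric(sub("^#\\s*threshold:\\s*", "", thr_line[1]))
  } else if (file.exists(paste0(path, ".threshold"))) {
    thr <- as.numeric(readLines(paste0(path, ".threshold"))[1])
  }
  if (is.na(thr)) stop("no threshold found for PWM: ", path)
  list(factor = sub("\\.[^.]*$", "", basename(path)),
       width = nrow(mat), matrix = mat, threshold = thr)
}

#' Load the bundled synthetic SR-protein matrices
#'
#' The package ships synthetic position weight matrices for four SR
#' splicing factors (SRSF1, SRSF2, SRSF5, SRSF6), modeled on their known
#' consensus preferences. They are stand-ins for demonstration and testing;
#' supply experimentally derived matrices for real analyses.
#'
#' @return Named list of PWMs (see [read_pwm()]).
#' @export
load_sr_matrices <- function() {
  dir <- system.file("extdata", "pwm", package = "fissionkit")
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  pwms <- lapply(files, read_pwm)
  names(pwms) <- vapply(pwms, function(p) sub("_synthetic$", "", p$factor),
                        character(1))
  for (i in seq_along(pwms)) pwms[[i]]$factor <- names(pwms)[i]
  pwms
}
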