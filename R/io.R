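#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Sequences are handled internally as uppercase DNA: lowercase is raised and
#' U is rewritten to T, so RNA-spelled references, reads and whitelists all
#' compare equal. Characters outside A/C/G/T/U/N are rejected.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector, uppercase, U replaced by T.
#' @export
normalize_seq <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("sequence contains non-ACGTUN characters: ",
         substr(x[bad][1L], 1L, 40L))
  }
  x
}

#' Reverse complement of DNA strings
#'
#' @param x character vector (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Read sequences from a FASTA file
#'
#' Gzip is handled transparently. Sequences are normalized to uppercase DNA
#' (U -> T); the record names are preserved.
#'
#' @param path file path (plain or .gz).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  out <- normalize_seq(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Read sequences from a FASTQ file
#'
#' Qualities are dropped; sequences are normalized to uppercase DNA. A
#' truncated quartet raises an error.
#'
#' @param path file path (plain or .gz).
#' @return named character vector of sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e)))
  out <- normalize_seq(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path (".gz" suffix compresses).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  if (is.null(names(ss))) names(ss) <- paste0("seq", seq_along(ss))
  Biostrings::writeXStringSet(ss, path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write sequences to FASTQ with constant qualities
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(ss))) names(ss) <- paste0("read", seq_along(ss))
  qual <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a data frame as TSV
#'
#' Plain tab-separated output, no quoting, no row names: the format every
#' downstream table in the toolkit uses.
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a tRNA gene annotation table
#'
#' Expected columns: gene_id, amino_acid, anticodon, chrom, start, end,
#' strand, introns. Coordinates are 1-based closed; `introns` is empty or a
#' comma-separated list of `start-end` intervals relative to the unspliced
#' transcript. A `genomic_seq` column may be present; otherwise sequences are
#' filled in from `genome`.
#'
#' @param path TSV path.
#' @param genome optional named character vector of chromosome sequences used
#'   to populate `genomic_seq` (transcript-oriented: reverse-complemented for
#'   minus-strand genes).
#' @return data.frame of gene records.
#' @export
read_trna_annotation <- function(path, genome = NULL) {
  df <- read_tsv(path)
  need <- c("gene_id", "amino_acid", "anticodon", "chrom", "start", "end",
            "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(df$introns)) df$introns <- ""
  df$introns[is.na(df$introns)] <- ""
  if (is.null(df$genomic_seq) && !is.null(genome)) {
    df$genomic_seq <- vapply(seq_len(nrow(df)), function(i) {
      g <- df[i, ]
      if (!g$chrom %in% names(genome)) stop("chromosome not found: ", g$chrom)
      s <- substr(genome[[g$chrom]], g$start, g$end)
      if (g$strand == "-") s <- revcomp(s)
      s
    }, character(1))
  }
  df
}

#' Parse an intron-interval string
#'
#' @param x string like `"38-47"` or `"10-14,50-60"`; empty means none.
#' @return two-column integer matrix (start, end), zero rows if none.
#' @export
parse_introns <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  m <- t(vapply(parts, function(p) as.integer(p[1:2]), integer(2)))
  colnames(m) <- c("start", "end")
  if (any(is.na(m)) || any(m[, 2] < m[, 1])) stop("malformed introns: ", x)
  m[order(m[, 1]), , drop = FALSE]
}

#' Read BED intervals as 1-based closed coordinates
#'
#' BED is 0-based half-open; conversion to the 1-based closed convention used
#' throughout the toolkit happens here, at the file boundary.
#'
#' @param path BED(-like) path: chrom, start, end, then optional columns.
#' @return data.frame with chrom, start, end (1-based closed) plus any extra
#'   columns named name, score, strand in BED order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  extra <- c("name", "score", "strand")
  names(df) <- c("chrom", "start", "end",
                 extra[seq_len(max(0, ncol(df) - 3))])[seq_len(ncol(df))]
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  df
}

#' Read a bedGraph-like conservation track
#'
#' Intervals (0-based half-open) are expanded to a per-base score table.
#'
#' @param path bedGraph path: chrom/target_id, start, end, value.
#' @return data.frame with target_id, pos (1-based), score.
#' @export
read_conservation_track <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("target_id", "start", "end", "score"))
  if (!nrow(df)) {
    return(data.frame(target_id = character(0), pos = integer(0),
                      score = numeric(0)))
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    pos <- (df$start[i] + 1L):df$end[i]
    data.frame(target_id = df$target_id[i], pos = pos,
               score = df$score[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
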