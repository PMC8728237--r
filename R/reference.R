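#' Build a mature tRNA from a gene record
#'
#' A mature tRNA is the unspliced transcript with intron intervals removed and
#' the non-templated CCA tail appended. The anticodon is located on the
#' spliced sequence by taking the occurrence of the anticodon triplet nearest
#' the sequence midpoint (tRNA anticodons sit mid-molecule, in the anticodon
#' loop). The anticodon loop is taken as `anticodon_start + loop_offsets`,
#' by default `(-2, +4)`, approximating the canonical 7-nt loop, clipped to
#' the sequence.
#'
#' @param gene one gene record: a one-row data.frame or list with fields
#'   gene_id, amino_acid, anticodon, genomic_seq and (optionally) introns —
#'   intron intervals 1-based closed on the unspliced transcript, either a
#'   string ("s-e,s-e") or a 2-column matrix.
#' @param loop_offsets integer length-2: offsets of the anticodon-loop
#'   boundaries from the first anticodon base.
#' @return an object of class `mature_trna`: list with gene_id, amino_acid,
#'   anticodon, seq (ends in CCA), L, anticodon_start, anticodon_loop.
#' @export
build_mature_trna <- function(gene, loop_offsets = c(-2L, 4L)) {
  gene <- as.list(gene)
  seq <- normalize_seq(gene$genomic_seq)
  introns <- gene$introns
  if (is.null(introns)) {
    introns <- matrix(integer(0), ncol = 2)
  } else if (is.character(introns)) {
    introns <- parse_introns(introns)
  }
  if (nrow(introns)) {
    if (any(introns < 1L) || any(introns > nchar(seq))) {
      stop("intron interval outside transcript for ", gene$gene_id)
    }
    keep <- rep(TRUE, nchar(seq))
    for (i in seq_len(nrow(introns))) keep[introns[i, 1]:introns[i, 2]] <- FALSE
    seq <- paste(strsplit(seq, "", fixed = TRUE)[[1]][keep], collapse = "")
  }
  ac <- normalize_seq(gene$anticodon)
  if (nchar(ac) != 3L) stop("anticodon must be 3 nt for ", gene$gene_id)
  hits <- gregexpr(ac, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) {
    stop("anticodon triplet ", ac, " absent from spliced sequence of ",
         gene$gene_id)
  }
  mid <- (nchar(seq) + 1) / 2
  a <- hits[which.min(abs(hits + 1 - mid))]
  mature <- paste0(seq, "CCA")
  L <- nchar(mature)
  loop <- c(max(1L, a + loop_offsets[1]), min(L, a + loop_offsets[2]))
  structure(list(gene_id = gene$gene_id,
                 amino_acid = gene$amino_acid,
                 anticodon = ac,
                 seq = mature,
                 L = L,
                 anticodon_start = as.integer(a),
                 anticodon_loop = as.integer(loop)),
            class = "mature_trna")
}

#' @export
print.mature_trna <- function(x, ...) {
  cat(sprintf("mature tRNA %s (%s/%s): %d nt, anticodon at %d, loop %d-%d\n",
              x$gene_id, x$amino_acid, x$anticodon, x$L, x$anticodon_start,
              x$anticodon_loop[1], x$anticodon_loop[2]))
  invisible(x)
}

#' Extract the 3' trailer of a tRNA gene from the genome
#'
#' The trailer is the genomic sequence immediately downstream of the gene in
#' transcript orientation (source of tRF-1 fragments); 50 nt by default. At a
#' chromosome boundary the trailer is truncated with a warning.
#'
#' @param gene gene record with chrom, start, end, strand, gene_id.
#' @param genome named character vector of chromosome sequences.
#' @param length trailer length in nt.
#' @return an object of class `trailer_seq`: list with gene_id, seq, length.
#' @export
extract_trailer <- function(gene, genome, length = 50L) {
  gene <- as.list(gene)
  if (!gene$chrom %in% names(genome)) {
    stop("chromosome not found: ", gene$chrom)
  }
  chrom <- genome[[gene$chrom]]
  clen <- nchar(chrom)
  if (!gene$strand %in% c("+", "-")) stop("strand must be + or -")
  if (gene$strand == "+") {
    from <- gene$end + 1L
    to <- gene$end + length
    if (to > clen) {
      warning("trailer of ", gene$gene_id, " truncated at chromosome end")
      to <- clen
    }
    seq <- if (from > to) "" else substr(chrom, from, to)
  } else {
    from <- gene$start - length
    to <- gene$start - 1L
    if (from < 1L) {
      warning("trailer of ", gene$gene_id, " truncated at chromosome start")
      from <- 1L
    }
    seq <- if (from > to) "" else revcomp(substr(chrom, from, to))
  }
  structure(list(gene_id = gene$gene_id, seq = normalize_seq(seq),
                 length = nchar(seq)),
            class = "trailer_seq")
}

#' Load tRNA modification sites
#'
#' Positions are 1-based on the mature (spliced, CCA-appended) sequence.
#' Rows whose position falls outside the mature length of the referenced
#' tRNA — or that reference an unknown gene — are dropped, and the dropped
#' count is reported. Duplicate (gene_id, position) rows collapse to one
#' site.
#'
#' @param table data.frame with gene_id, position, mod_type (or a path to
#'   such a TSV).
#' @param mature_set named list of `mature_trna` objects used for bounds
#'   checking; NULL skips the length check (unknown genes still pass).
#' @return data.frame with gene_id, position, mod_type.
#' @export
load_modification_sites <- function(table, mature_set = NULL) {
  if (is.character(table)) table <- read_tsv(table)
  need <- c("gene_id", "position", "mod_type")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("modification table lacks columns: ",
                         paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.integer(table$position))
  bad <- which(is.na(pos) | !nzchar(as.character(table$gene_id)))
  if (length(bad)) stop("malformed modification row at line ", bad[1] + 1L)
  table$position <- pos
  ok <- table$position >= 1L
  if (!is.null(mature_set)) {
    Ls <- vapply(mature_set, function(m) m$L, integer(1))
    known <- table$gene_id %in% names(mature_set)
    ok <- ok & known & table$position <= Ls[table$gene_id]
    ok[is.na(ok)] <- FALSE
  }
  dropped <- sum(!ok)
  if (dropped) {
    warning(dropped, " modification site(s) outside mature bounds dropped")
  }
  out <- table[ok, need, drop = FALSE]
  out <- out[!duplicated(out[, c("gene_id", "position")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lift a genomic position onto the mature tRNA coordinate
#'
#' Utility for modification tables distributed in genomic coordinates:
#' converts one genomic position to its 1-based position on the mature
#' (spliced) sequence of a gene, honouring strand and skipping introns.
#'
#' @param gene gene record with chrom, start, end, strand, introns.
#' @param genomic_pos integer vector of genomic positions.
#' @return integer vector of mature positions; NA where the position falls
#'   outside the gene or inside an intron.
#' @export
lift_genomic_to_mature <- function(gene, genomic_pos) {
  gene <- as.list(gene)
  introns <- if (is.character(gene$introns)) parse_introns(gene$introns)
             else if (is.null(gene$introns)) matrix(integer(0), ncol = 2)
             else gene$introns
  n <- gene$end - gene$start + 1L
  # transcript-relative (unspliced) position, 1-based, strand aware
  rel <- if (gene$strand == "+") genomic_pos - gene$start + 1L
         else gene$end - genomic_pos + 1L
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(introns))) keep[introns[i, 1]:introns[i, 2]] <- FALSE
  spliced_index <- cumsum(keep)
  out <- rep(NA_integer_, length(rel))
  inside <- !is.na(rel) & rel >= 1L & rel <= n
  ok <- inside & keep[pmax(rel, 1L)]
  out[ok] <- spliced_index[rel[ok]]
  out
}

#' Build the full reference set from an annotation table
#'
#' Convenience wrapper producing, for every gene, the mature tRNA and its
#' 3' trailer.
#'
#' @param genes gene-record data.frame (see [read_trna_annotation()]).
#' @param genome named character vector of chromosome sequences.
#' @param trailer_length trailer length in nt.
#' @return list with `mature` (named list of mature_trna) and `trailers`
#'   (named list of trailer_seq), both keyed by gene_id.
#' @export
build_reference_set <- function(genes, genome, trailer_length = 50L) {
  mature <- lapply(seq_len(nrow(genes)), function(i)
    build_mature_trna(genes[i, ]))
  trailers <- lapply(seq_len(nrow(genes)), function(i)
    extract_trailer(genes[i, ], genome, length = trailer_length))
  names(mature) <- genes$gene_id
  names(trailers) <- genes$gene_id
  list(mature = mature, trailers = trailers)
}
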