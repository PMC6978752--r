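#' Construct a transcript record
#'
#' A transcript record holds one mRNA sequence together with the CDS
#' boundaries that partition it into 5'UTR, CDS and 3'UTR.  All coordinates
#' are 0-based, half-open: the three regions are `[0, cds_start)`,
#' `[cds_start, cds_end)` and `[cds_end, length)`; either UTR may be empty.
#' RNA input (`U`) is normalized to DNA (`T`) and lowercase is uppercased on
#' construction, so the printed extended seed matches target sequences
#' directly.
#'
#' @param transcript_id Character scalar identifier.
#' @param sequence Nucleotide sequence (characters in `A,C,G,T,U,N`, any
#'   case).
#' @param cds_start,cds_end CDS boundaries, 0-based half-open;
#'   `0 <= cds_start < cds_end <= nchar(sequence)`.
#' @param species,gene_symbol Optional annotation strings.
#' @return An object of class `transcript_record`.
#' @examples
#' tx <- transcript_record("tx1", "acguACGT", cds_start = 2, cds_end = 6)
#' tx$sequence   # "ACGTACGT"
#' @export
transcript_record <- function(transcript_id, sequence, cds_start, cds_end,
                              species = "", gene_symbol = "") {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            nzchar(transcript_id),
            is.character(sequence), length(sequence) == 1L)
  seq <- normalize_dna(sequence, what = transcript_id)
  n <- nchar(seq)
  if (n == 0L) stop("transcript '", transcript_id, "': empty sequence")
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (is.na(cds_start) || is.na(cds_end) ||
      cds_start < 0L || cds_start >= cds_end || cds_end > n)
    stop("transcript '", transcript_id, "': invalid CDS bounds [",
         cds_start, ", ", cds_end, ") for length ", n)
  structure(
    list(transcript_id = transcript_id, species = as.character(species),
         gene_symbol = as.character(gene_symbol), sequence = seq,
         cds_start = cds_start, cds_end = cds_end),
    class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  n <- nchar(x$sequence)
  cat(sprintf(
    "<transcript_record> %s (%s %s)\n  length %d nt; 5'UTR [0,%d) CDS [%d,%d) 3'UTR [%d,%d)\n",
    x$transcript_id,
    if (nzchar(x$species)) x$species else "species?",
    if (nzchar(x$gene_symbol)) x$gene_symbol else "gene?",
    n, x$cds_start, x$cds_start, x$cds_end, x$cds_end, n))
  invisible(x)
}

# Uppercase, U -> T, and enforce the DNA alphabet (plus N).
normalize_dna <- function(sequence, what = "sequence") {
  seq <- chartr("u", "T", toupper(sequence))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad))
    stop(what, ": characters outside {A,C,G,T,U,N}: '",
         substr(bad, 1L, 10L), "'")
  seq
}

#' Construct a mature microRNA record
#'
#' @param name miRNA name, e.g. `"let-7g"`.
#' @param mature_sequence Mature sequence, 5'->3', RNA alphabet
#'   (`A,C,G,U`; `T` accepted and read as `U`), length >= 10.
#' @return An object of class `microrna`.
#' @examples
#' microrna("let-7g", "UGAGGUAGUAGUUUGUACAGUU")
#' @export
microrna <- function(name, mature_sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(mature_sequence), length(mature_sequence) == 1L)
  seq <- chartr("T", "U", toupper(mature_sequence))
  bad <- gsub("[ACGU]", "", seq)
  if (nzchar(bad))
    stop("miRNA '", name, "': characters outside {A,C,G,U}: '", bad, "'")
  if (nchar(seq) < 10L)
    stop("miRNA '", name, "': mature sequence shorter than 10 nt")
  structure(list(name = name, mature_sequence = seq), class = "microrna")
}

#' @export
print.microrna <- function(x, ...) {
  cat(sprintf("<microrna> %s  5'-%s-3' (%d nt)\n",
              x$name, x$mature_sequence, nchar(x$mature_sequence)))
  invisible(x)
}

#' Read transcripts from FASTA plus a region-annotation table
#'
#' The annotation is a tab-delimited file with a header row and columns
#' `transcript_id`, `species`, `gene_symbol`, `cds_start`, `cds_end`
#' (0-based, half-open).  Every FASTA record must have an annotation row;
#' input order is preserved.
#'
#' @param fasta_path Path to a (multi-record) FASTA file of transcript
#'   sequences (DNA or RNA alphabet).
#' @param annotation_path Path to the annotation TSV.
#' @return Named list of [transcript_record()] objects, in FASTA order.
#' @seealso [write_transcripts()] for the inverse.
#' @export
read_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ann <- read.delim(annotation_path, stringsAsFactors = FALSE,
                    comment.char = "#")
  need <- c("transcript_id", "species", "gene_symbol", "cds_start", "cds_end")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  ids <- sub("\\s.*$", "", names(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    row <- ann[ann$transcript_id == ids[i], , drop = FALSE]
    if (nrow(row) == 0L)
      stop("no annotation row for transcript '", ids[i], "'")
    if (nrow(row) > 1L)
      stop("duplicate annotation rows for transcript '", ids[i], "'")
    out[[i]] <- transcript_record(
      transcript_id = ids[i], sequence = as.character(seqs[[i]]),
      cds_start = row$cds_start, cds_end = row$cds_end,
      species = row$species, gene_symbol = row$gene_symbol)
  }
  names(out) <- ids
  out
}

#' Write transcripts to FASTA plus a region-annotation table
#'
#' @param transcripts List of [transcript_record()] objects.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, annotation_path) {
  stopifnot(length(transcripts) > 0L)
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "sequence"))
  names(seqs) <- vapply(transcripts, `[[`, "", "transcript_id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  ann <- data.frame(
    transcript_id = names(seqs),
    species = vapply(transcripts, `[[`, "", "species"),
    gene_symbol = vapply(transcripts, `[[`, "", "gene_symbol"),
    cds_start = vapply(transcripts, `[[`, 0L, "cds_start"),
    cds_end = vapply(transcripts, `[[`, 0L, "cds_end"),
    stringsAsFactors = FALSE)
  write.table(ann, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(fasta = fasta_path, annotation = annotation_path))
}

#' Read mature microRNAs from FASTA
#'
#' @param fasta_path Path to a FASTA file of mature miRNA sequences (RNA
#'   alphabet).
#' @return Named list of [microrna()] objects.
#' @export
read_mirnas <- function(fasta_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_along(seqs),
                function(i) microrna(ids[i], as.character(seqs[[i]])))
  names(out) <- ids
  out
}

#' Read an ortholog-pairing table
#'
#' Tab-delimited with header columns `gene_symbol`, `transcript_id_a`,
#' `transcript_id_b`.  When `transcripts` is supplied, every referenced ID
#' must be present and the paired records must share `gene_symbol` and
#' differ in `species`.
#'
#' @param path Path to the pairing TSV.
#' @param transcripts Optional named list of [transcript_record()]s for
#'   validation.
#' @return A data.frame with the three columns above.
#' @export
read_ortholog_pairs <- function(path, transcripts = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene_symbol", "transcript_id_a", "transcript_id_b")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pairing table missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(transcripts)) {
    for (i in seq_len(nrow(tab))) {
      a <- transcripts[[tab$transcript_id_a[i]]]
      b <- transcripts[[tab$transcript_id_b[i]]]
      if (is.null(a) || is.null(b))
        stop("pairing row ", i, ": transcript not found")
      if (!identical(a$gene_symbol, b$gene_symbol))
        stop("pairing row ", i, ": gene_symbol mismatch")
      if (identical(a$species, b$species))
        stop("pairing row ", i, ": both transcripts from species '",
             a$species, "'")
    }
  }
  tab[, need]
}

#' Region label of transcript positions
#'
#' @param transcript A [transcript_record()].
#' @param position Integer vector of 0-based positions within the transcript.
#' @return Character vector of labels among `"UTR5"`, `"CDS"`, `"UTR3"`.
#' @examples
#' tx <- transcript_record("t", "ACGTACGT", 2, 6)
#' region_of(tx, c(0, 5, 6))  # "UTR5" "CDS" "UTR3"
#' @export
region_of <- function(transcript, position) {
  stopifnot(inherits(transcript, "transcript_record"))
  position <- as.integer(position)
  n <- nchar(transcript$sequence)
  if (any(is.na(position) | position < 0L | position >= n))
    stop("position out of range [0, ", n, ") for transcript '",
         transcript$transcript_id, "'")
  ifelse(position < transcript$cds_start, "UTR5",
         ifelse(position < transcript$cds_end, "CDS", "UTR3"))
}

# Absolute [start, end) bounds of one region of a transcript.
region_bounds <- function(transcript, region) {
  n <- nchar(transcript$sequence)
  switch(region,
         UTR5 = c(0L, transcript$cds_start),
         CDS  = c(transcript$cds_start, transcript$cds_end),
         UTR3 = c(transcript$cds_end, n),
         stop("unknown region '", region, "'"))
}
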