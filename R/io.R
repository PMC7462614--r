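#' Read a FASTA file into named character strings
#'
#' @param path FASTA file.
#' @return named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read CDS records from a GTF annotation
#'
#' Coordinates in the file are 1-based closed intervals as usual for GTF;
#' they are kept 1-based closed in the returned table (conversion to the
#' package's 0-based internal coordinates happens in the consumers).
#'
#' @param path GTF file.
#' @return data.table with `chrom`, `start`, `end`, `strand`, `gene_id`,
#'   CDS features only, ordered by position.
#' @export
read_cds_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(df) == 0) stop("no CDS features in ", path)
  out <- data.table::data.table(
    chrom = as.character(df$seqnames),
    start = df$start,
    end = df$end,
    strand = as.character(df$strand),
    gene_id = as.character(df$gene_id))
  data.table::setorder(out, chrom, start)
  out
}

#' Write CDS records as GTF
#'
#' @param cds data.table with `chrom`, `start`, `end` (1-based closed),
#'   `strand`, `gene_id`.
#' @param path output file.
#' @export
write_cds_gtf <- function(cds, path) {
  lines <- sprintf(
    "%s\tpoolpopgen\tCDS\t%d\t%d\t.\t%s\t0\tgene_id \"%s\"; transcript_id \"%s.t1\";",
    cds$chrom, cds$start, cds$end, cds$strand, cds$gene_id, cds$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read a PoPoolation2-style sync file
#'
#' Tab-separated: chromosome, 1-based position, reference base, then one
#' `A:C:G:T:N:del` column per population. N and deletion counts are
#' ignored.
#'
#' @param path sync file.
#' @param pop_names names for the population columns; defaults to
#'   `pop1`, `pop2`, ...
#' @return list with `chrom`, `pos` (1-based integer vector), `ref`
#'   (character vector) and `counts`, a named list of sites x 4 integer
#'   matrices (columns A, C, G, T).
#' @export
read_sync <- function(path, pop_names = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  n_pop <- ncol(dt) - 3L
  if (n_pop < 1) stop("sync file has no population columns: ", path)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(n_pop))
  if (length(pop_names) != n_pop)
    stop("expected ", length(pop_names), " population columns, found ", n_pop)
  counts <- vector("list", n_pop)
  names(counts) <- pop_names
  for (p in seq_len(n_pop)) {
    col <- dt[[3L + p]]
    parts <- data.table::tstrsplit(col, ":", fixed = TRUE, type.convert = FALSE)
    m <- cbind(as.integer(parts[[1]]), as.integer(parts[[2]]),
               as.integer(parts[[3]]), as.integer(parts[[4]]))
    colnames(m) <- c("A", "C", "G", "T")
    counts[[p]] <- m
  }
  list(chrom = as.character(dt[[1]]), pos = as.integer(dt[[2]]),
       ref = toupper(as.character(dt[[3]])), counts = counts)
}

#' Write pooled counts in sync format
#'
#' @param chrom,pos,ref site coordinates (`pos` 1-based) and reference
#'   base.
#' @param counts named list of sites x 4 matrices (A, C, G, T).
#' @param path output file.
#' @export
write_sync <- function(chrom, pos, ref, counts, path) {
  dt <- data.table::data.table(chrom = chrom, pos = pos, ref = ref)
  for (nm in names(counts)) {
    m <- counts[[nm]]
    dt[, (nm) := paste(m[, 1], m[, 2], m[, 3], m[, 4], 0L, 0L, sep = ":")]
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
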