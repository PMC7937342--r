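#' Read a FASTA file of reference sequences
#'
#' Sequences are uppercased and restricted to the A/C/G/T/N alphabet; a file
#' with no records returns an empty tibble with a warning (an empty reference
#' usually signals a truncated download).
#'
#' @param path path to a FASTA file
#' @return a tibble with columns `id` (first word of the header) and
#'   `sequence` (uppercase)
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "acgt"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) abort(sprintf("malformed FASTA in %s: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) {
    warn(sprintf("no FASTA records in %s", path))
    return(tibble(id = character(), sequence = character()))
  }
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence for record '%s' in %s", ids[!nzchar(seqs)][1], path))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(sprintf("record '%s' contains characters outside A/C/G/T/N", ids[bad][1]))
  }
  tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write reference sequences to FASTA
#'
#' @param x tibble with columns `id`, `sequence`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$id
  Biostrings::writeXStringSet(set, path, format = "fasta")
  invisible(path)
}

#' Read single-end reads from FASTQ
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file
#' @return tibble with columns `id`, `sequence`, `quality`, `orientation`
#'   (always `"unknown"` on input: FASTQ carries no strand information)
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    id = unname(sub("\\s.*$", "", names(set))),
    sequence = unname(toupper(as.character(set))),
    quality = unname(as.character(S4Vectors::mcols(set)$qualities)),
    orientation = "unknown"
  )
}

#' Write reads to FASTQ
#'
#' Missing qualities are written as the maximum Phred+33 score `"I"`.
#'
#' @param x tibble with columns `id`, `sequence` and optionally `quality`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(x, path) {
  qual <- if ("quality" %in% names(x) && !anyNA(x$quality)) x$quality else
    vapply(nchar(x$sequence), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", x$id), x$sequence, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read alignments against one reference from SAM or BAM
#'
#' Keeps primary mapped records on `reference_id`; unmapped, secondary and
#' supplementary records and records on other references are skipped (counts
#' of each are attached as the `"skipped"` attribute). SAM input is converted
#' with [Rsamtools::asBam()] under the hood. Positions are returned 0-based;
#' `seq` is in reference orientation (the SAM convention), so downstream base
#' counting needs no re-orientation for reverse-strand reads.
#'
#' @param path SAM or BAM file
#' @param reference_id reference name to keep; must be in the header
#' @return tibble with columns `read_id`, `reference_id`, `pos` (0-based),
#'   `cigar`, `seq`, `is_reverse`, `nm` (NM tag, NA when absent)
#' @export
read_alignments <- function(path, reference_id) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!reference_id %in% names(hdr)) {
    abort(sprintf("reference '%s' not in the SAM/BAM header (%s)",
                  reference_id, paste(names(hdr), collapse = ", ")))
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  par <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "rname", "pos", "cigar", "seq", "strand", "flag"),
    tag = "NM"
  )
  res <- Rsamtools::scanBam(bam, param = par)[[1]]
  mapped <- !is.na(res$pos)
  on_ref <- mapped & !is.na(res$rname) & as.character(res$rname) == reference_id
  nm <- res$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(res$qname))
  out <- tibble(
    read_id = res$qname[on_ref],
    reference_id = as.character(res$rname[on_ref]),
    pos = res$pos[on_ref] - 1L,
    cigar = res$cigar[on_ref],
    seq = as.character(res$seq)[on_ref],
    is_reverse = as.character(res$strand[on_ref]) == "-",
    nm = as.integer(nm[on_ref])
  )
  attr(out, "skipped") <- c(
    unmapped = sum(!mapped),
    other_reference = sum(mapped) - nrow(out)
  )
  out
}

#' Uniformly subsample records without replacement
#'
#' Reproducible for a fixed `seed`; when `n` is at least the number of rows
#' the input is returned unchanged (order-stable). Mirrors the practice of
#' analysing fixed-size subsets (e.g. 1 million reads) of very deep rRNA
#' libraries.
#'
#' @param x a tibble (reads, alignments, any records)
#' @param n number of records to keep
#' @param seed integer seed for the draw
#' @return a tibble with `min(n, nrow(x))` rows, in original relative order
#' @export
subsample_reads <- function(x, n, seed = 1L) {
  if (length(n) != 1L || is.na(n) || n < 0) abort("`n` must be a single non-negative number")
  if (n >= nrow(x)) return(x)
  idx <- with_seed(seed, sort(sample.int(nrow(x), n)))
  x[idx, , drop = FALSE]
}

#' Read a tab-separated gene-by-sample count matrix
#'
#' First column is the gene id, remaining columns one per sample.
#'
#' @param path TSV path
#' @return integer matrix with gene rownames and sample colnames
#' @export
read_count_matrix <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tb[[1]])
  if (any(m < 0, na.rm = TRUE)) abort("negative counts in count matrix")
  m
}

#' Write a count matrix as TSV
#' @param m matrix with gene rownames
#' @param path output TSV
#' @return `path`, invisibly
#' @export
write_count_matrix <- function(m, path) {
  tb <- dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
  readr::write_tsv(tb, path)
  invisible(path)
}

#' Read a sample design table
#'
#' Expected columns: `sample_id`, `spiroplasma` (`present`/`absent`), `wasp`
#' (`none`/`lh`/`gh`), `time` (`T1`/`T2`), `replicate`.
#'
#' @param path TSV/CSV path (delimiter inferred from extension)
#' @return design tibble
#' @export
read_design <- function(path) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  d <- reader(path, show_col_types = FALSE)
  needed <- c("sample_id", "spiroplasma", "wasp", "time", "replicate")
  miss <- setdiff(needed, names(d))
  if (length(miss)) abort(paste("design table missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(d[, c("spiroplasma", "wasp", "time", "replicate")])) {
    abort("duplicate (spiroplasma, wasp, time, replicate) combinations in design")
  }
  d
}

#' Read a differential-expression table for one contrast
#'
#' Accepts any table with columns `gene_id`, `log2fc`, `fdr` (extra columns
#' kept), so DE results from any tool can enter the set-logic stage.
#'
#' @param path TSV path
#' @param contrast one of `"blue"`, `"red"`, `"green"`
#' @return tibble with `gene_id`, `log2fc`, `fdr`, `direction`, `contrast`
#' @export
read_de_table <- function(path, contrast = c("blue", "red", "green")) {
  contrast <- match.arg(contrast)
  d <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("gene_id", "log2fc", "fdr"), names(d))
  if (length(miss)) abort(paste("DE table missing columns:", paste(miss, collapse = ", ")))
  d |>
    mutate(direction = ifelse(.data$log2fc >= 0, "up", "down"),
           contrast = contrast)
}
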