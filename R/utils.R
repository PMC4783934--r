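# shared sequence helpers

BASES <- c("A", "C", "G", "T")

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.rand_dna <- function(n, len) {
  if (length(len) == 1L) len <- rep_len(len, n)
  vapply(len, function(l) paste(sample(BASES, l, replace = TRUE), collapse = ""),
         character(1))
}

.clean_seq <- function(x) {
  out <- gsub("U", "T", toupper(as.character(x)), fixed = TRUE)
  names(out) <- names(x)
  out
}

# read FASTA or FASTQ into a named character vector (format sniffed from the
# first non-empty byte unless given)
.read_seqs <- function(x, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (methods::is(x, "XStringSet")) {
    s <- as.character(x)
    names(s) <- names(x)
    return(.clean_seq(s))
  }
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (format == "auto") {
      first <- readLines(x, n = 1L)
      format <- if (startsWith(first, "@")) "fastq" else "fasta"
    }
    set <- Biostrings::readDNAStringSet(x, format = format,
                                        with.qualities = FALSE)
    s <- as.character(set)
    names(s) <- sub("\\s.*$", "", names(set))
    return(.clean_seq(s))
  }
  if (is.character(x)) return(.clean_seq(x))
  stop("cannot interpret input as sequences: supply a file path, ",
       "character vector or XStringSet")
}

.write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

.write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(x) <- paste0("read", seq_along(seqs))
  q <- Biostrings::PhredQuality(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
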