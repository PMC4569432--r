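# Shared helpers: deterministic seed derivation, primer constants, small IO.

#' V1-V2 amplification primers
#'
#' The forward primer 27Fmod (5'-agrgtttgatymtggctcag-3') and the reverse
#' primer 338R (5'-tgctgcctcccgtaggagt-3') delimiting the 16S rRNA V1-V2
#' region targeted by this pipeline.
#'
#' @format Named character vector with elements `fwd` and `rev`.
#' @export
v1v2_primers <- c(fwd = "AGRGTTTGATYMTGGCTCAG", rev = "TGCTGCCTCCCGTAGGAGT")

#' Stable string hash
#'
#' Deterministic 31-bit hash of a character string, used to derive per-sample
#' random substreams from a single study seed so that any single sample can be
#' regenerated in isolation.
#'
#' @param x character scalar.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Derive a substream seed
#'
#' @param seed integer master seed.
#' @param tag character tag naming the substream (stage or sample id).
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + stable_hash(tag)) %%
               2147483647)
}

#' Reverse complement preserving IUPAC codes
#' @param x character vector of DNA strings.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# internal: random DNA string(s) from ACGT under the current RNG
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# internal: count non-ACGT symbols per sequence
count_ambiguous <- function(seqs) {
  vapply(seqs, function(s) {
    if (is.na(s)) return(NA_integer_)
    sum(strsplit(chartr("acgt", "ACGT", s), "")[[1]] %notin% c("A", "C", "G", "T"))
  }, integer(1), USE.NAMES = FALSE)
}

`%notin%` <- function(x, table) !(x %in% table)

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (Phred+33)
#' @param reads data.frame with columns `id`, `sequence`, `quality`.
#' @param path output file (plain or .gz).
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", reads$quality),
             con)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#' @param path FASTQ file (plain or .gz).
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0) stop("malformed FASTQ: ", path)
  idx <- seq(1, length(lines), by = 4)
  data.frame(id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
             sequence = lines[idx + 1], quality = lines[idx + 3],
             stringsAsFactors = FALSE)
}
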