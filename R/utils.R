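#' @useDynLib srnapipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import Biostrings
#' @importFrom stats rmultinom setNames sd runif rpois
#' @importFrom utils write.table read.table
"_PACKAGE"

#' Normalize a nucleotide string to the DNA alphabet
#'
#' Uppercases and converts U to T so that RNA- and DNA-spelled inputs compare
#' equal. Ambiguity codes other than N are rejected.
#'
#' @param x character vector of sequences.
#' @param allow_n allow N bases (default TRUE).
#' @return character vector in the A/C/G/T(/N) alphabet.
#' @export
norm_dna <- function(x, allow_n = TRUE) {
  stopifnot(is.character(x))
  x <- chartr("u", "U", toupper(x))
  x <- chartr("U", "T", x)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop("non-ACGU/T characters in sequence(s): ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  x
}

#' Reverse complement of DNA sequences
#'
#' @param x character vector (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    norm_dna(x))))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: permutes a sequence while preserving its exact
#' dinucleotide (and hence mononucleotide) composition. Used to build decoy
#' precursors for hairpin-screening specificity checks.
#'
#' @param x a single sequence (character scalar).
#' @return a shuffled sequence with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(x) {
  s <- strsplit(norm_dna(x), "")[[1]]
  n <- length(s)
  if (n < 3L) return(paste(s, collapse = ""))
  verts <- unique(s)
  first <- s[1L]; last <- s[n]
  # edge list: from s[i] to s[i+1]
  edges <- lapply(setNames(verts, verts), function(v) s[which(s[-n] == v) + 1L])
  repeat {
    # pick a candidate last edge for every vertex except the terminal one
    last_edge <- vapply(verts, function(v) {
      if (v == last) NA_character_ else {
        e <- edges[[v]]
        e[sample.int(length(e), 1L)]
      }
    }, character(1))
    # the chosen last edges must form paths that all reach `last`
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      seen <- character(0); cur <- v
      while (!is.na(cur) && cur != last && !(cur %in% seen)) {
        seen <- c(seen, cur)
        cur <- if (cur %in% verts) last_edge[[cur]] else NA_character_
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  # shuffle the remaining edges, append the reserved last edge
  for (v in verts) {
    e <- edges[[v]]
    if (v != last) {
      idx <- match(last_edge[[v]], e)
      e <- e[-idx]
    }
    edges[[v]] <- if (length(e) > 1L) e[sample.int(length(e))] else e
    if (v != last) edges[[v]] <- c(edges[[v]], last_edge[[v]])
  }
  out <- character(n); out[1L] <- first
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- first
  for (i in 2L:n) {
    nxt <- edges[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Write sequences with qualities as FASTQ (Phred+33)
#'
#' @param sequences character vector of reads.
#' @param qualities character vector of quality strings (same widths).
#' @param ids read identifiers.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sequences, qualities, ids, path) {
  stopifnot(length(sequences) == length(qualities),
            length(sequences) == length(ids),
            all(nchar(sequences) == nchar(qualities)))
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  if (length(sequences)) {
    rec <- paste0("@", ids, "\n", sequences, "\n+\n", qualities, "\n")
    writeLines(rec, con, sep = "")
  }
  invisible(path)
}

#' Read a FASTQ file into sequences and qualities
#'
#' @param path FASTQ file (uncompressed, Phred+33).
#' @return list with `sequences`, `qualities`, `ids` character vectors.
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  if (length(ln) %% 4L != 0L) stop("truncated FASTQ: ", path)
  idx <- seq(1L, length(ln), by = 4L)
  list(ids = sub("^@", "", ln[idx]),
       sequences = ln[idx + 1L],
       qualities = ln[idx + 3L])
}

#' Write a named set of sequences as FASTA
#' @param sequences named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(sequences)) {
    writeLines(paste0(">", names(sequences), "\n", unname(sequences), "\n"),
               con, sep = "")
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

# round-half-up to `digits`, matching how published tables print percentages
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# deterministic local RNG scope: derive child seeds below 2^31
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}
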