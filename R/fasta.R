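#' Read fixed-length sequences from a FASTA file
#'
#' Each position of the alignment-free, fixed-length sequences becomes one
#' discrete feature, so a file of N sequences of length L yields an N x L
#' dataset.  Sequences are uppercased on read.  Records of unequal length
#' are rejected (the model is positional).
#'
#' @param path FASTA file (multi-line records allowed).
#' @param alphabet `"auto"` (default), `"dna"`, `"protein"`, or an explicit
#'   character vector of symbols.  `"auto"` picks DNA when only A/C/G/T are
#'   observed, the 20 amino acids when those suffice, and otherwise the
#'   observed symbol set.
#' @param missing Symbol treated as a missing value (default `"-"`); set to
#'   `NA` to disable.
#' @return A `mix_dataset` with one discrete feature per position
#'   (`pos1..posL`), ids from the FASTA headers.
#' @export
read_fasta <- function(path, alphabet = "auto", missing = "-") {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(seqs, function(s) attr(s, "name"), character(1))
  strs <- toupper(vapply(seqs, as.character, character(1)))
  lens <- nchar(strs)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != lens[1L]]
    stop("sequences of unequal length (expected fixed-length records): ",
         paste(off, collapse = ", "))
  }
  L <- lens[1L]
  chars <- matrix(unlist(strsplit(strs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(strs), ncol = L, byrow = TRUE)
  if (!is.na(missing)) chars[chars == toupper(missing)] <- NA
  observed <- sort(unique(as.vector(chars[!is.na(chars)])))
  dna <- c("A", "C", "G", "T")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  ab <- if (identical(alphabet, "auto")) {
    if (all(observed %in% dna)) dna else if (all(observed %in% aa)) aa else observed
  } else if (identical(alphabet, "dna")) {
    bad <- setdiff(observed, dna)
    if (length(bad)) {
      stop("symbol '", bad[1L], "' not in the DNA alphabet {A,C,G,T}")
    }
    dna
  } else if (identical(alphabet, "protein")) {
    bad <- setdiff(observed, aa)
    if (length(bad)) stop("symbol '", bad[1L], "' not in the protein alphabet")
    aa
  } else {
    bad <- setdiff(observed, toupper(alphabet))
    if (length(bad)) {
      stop("symbol '", bad[1L], "' not in the supplied alphabet")
    }
    toupper(alphabet)
  }
  df <- as.data.frame(chars, stringsAsFactors = FALSE)
  colnames(df) <- paste0("pos", seq_len(L))
  mix_dataset(df, schema = rep("discrete", L), ids = ids,
              missing = if (is.na(missing)) "\r" else missing,
              alphabets = stats::setNames(rep(list(ab), L), colnames(df)))
}

#' Write an all-discrete dataset as FASTA
#'
#' Inverse of [read_fasta()]: each row becomes one record whose sequence is
#' the concatenation of its (single-character) symbols; missing values are
#' written as `missing`.
#'
#' @param dataset A `mix_dataset` whose features are all discrete with
#'   single-character symbols.
#' @param path Output path.
#' @param missing Character written for missing values (default `"-"`).
#' @return Invisibly, the path.
#' @export
write_fasta <- function(dataset, path, missing = "-") {
  types <- vapply(dataset$domains, `[[`, character(1), "type")
  if (any(types != "discrete")) stop("write_fasta requires all-discrete features")
  symlen <- unlist(lapply(dataset$domains, function(d) nchar(d$alphabet)))
  if (any(symlen != 1L)) stop("write_fasta requires single-character symbols")
  df <- as.data.frame(dataset)
  df[is.na(df)] <- missing
  seqs <- apply(as.matrix(df), 1, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = dataset$ids, file.out = path,
                      as.string = TRUE, nbchar = 80)
  invisible(path)
}
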