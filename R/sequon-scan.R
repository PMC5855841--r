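# N-glycosylation sequon (N-X-S/T, X != P) scanning of protein sequences,
# and conservation of a sequon-bearing column across an alignment.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Find N-glycosylation sequons in a protein sequence
#'
#' Reports every (possibly overlapping) occurrence of the consensus motif
#' N-X-\[S/T\] with X != P, at 1-based positions of the asparagine. `X` in
#' the input is tolerated as an ambiguity code that matches no motif
#' requirement except "not proline".
#'
#' @param seq Amino-acid string (20-letter alphabet plus `X`).
#' @param id Sequence identifier carried into the result.
#' @return data.frame with columns `sequence_id`, `position`, `triplet`,
#'   ordered by ascending position.
#' @export
find_sequons <- function(seq, id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1)
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), c(AA_ALPHABET, "X"))
  if (length(bad) > 0)
    stop("illegal amino-acid character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- length(chars)
  hits <- integer(0)
  if (n >= 3) {
    pos <- seq_len(n - 2)
    ok <- chars[pos] == "N" & chars[pos + 1] != "P" &
      chars[pos + 2] %in% c("S", "T")
    hits <- pos[ok]
  }
  data.frame(sequence_id = rep(id, length(hits)), position = hits,
             triplet = vapply(hits, function(p)
               paste(chars[p:(p + 2)], collapse = ""), ""))
}

#' Scan a FASTA file for sequons
#'
#' @param path FASTA file of protein sequences.
#' @param out Optional path: when given, the hit table is also written as
#'   TSV.
#' @return data.frame of hits across all sequences (see [find_sequons()]).
#' @export
scan_fasta_sequons <- function(path, out = NULL) {
  seqs <- read_fasta(path)
  hits <- do.call(rbind, lapply(names(seqs), function(id)
    find_sequons(seqs[[id]], id)))
  if (is.null(hits))
    hits <- data.frame(sequence_id = character(0), position = integer(0),
                       triplet = character(0))
  if (!is.null(out))
    utils::write.table(hits, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  hits
}

#' Read protein sequences from FASTA
#'
#' Uses Biostrings when available, otherwise a minimal plain-text reader.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("not a FASTA file: ", path, call. = FALSE)
  ends <- c(hdr[-1] - 1, length(lines))
  out <- vapply(seq_along(hdr), function(i) {
    paste(lines[seq(hdr[i] + 1, ends[i])], collapse = "")
  }, "")
  names(out) <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  out
}

#' Sequon conservation at one alignment column
#'
#' For each sequence of an alignment, reports whether the given column
#' holds an asparagine and whether the *ungapped* downstream context (gaps
#' are skipped when reading the +1/+2 residues) completes an N-X-\[S/T\]
#' sequon with X != P.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences (gap character `-`).
#' @param column 1-based alignment column to interrogate.
#' @return data.frame with columns `sequence_id`, `residue` (character at
#'   the column), `has_n` and `sequon_intact`.
#' @export
site_conservation <- function(alignment, column) {
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequences have unequal lengths", call. = FALSE)
  if (column < 1 || column > lens[1])
    stop("column out of range", call. = FALSE)
  ids <- names(alignment)
  if (is.null(ids)) ids <- paste0("seq", seq_along(alignment))
  rows <- lapply(seq_along(alignment), function(i) {
    chars <- strsplit(toupper(alignment[[i]]), "")[[1]]
    res <- chars[column]
    has_n <- identical(res, "N")
    intact <- FALSE
    if (has_n) {
      downstream <- chars[-seq_len(column)]
      downstream <- downstream[downstream != "-"]
      intact <- length(downstream) >= 2 && downstream[1] != "P" &&
        downstream[2] %in% c("S", "T")
    }
    data.frame(sequence_id = ids[i], residue = res, has_n = has_n,
               sequon_intact = intact)
  })
  do.call(rbind, rows)
}
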