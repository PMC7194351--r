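#' Read a protein FASTA file into a proteome table
#'
#' Parses a (possibly line-wrapped) multi-record FASTA file of protein
#' sequences into a data frame with one row per record. Sequences are
#' canonicalized to upper case; the accession is the first whitespace-
#' delimited token of the header and the remainder becomes the description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame of class `proteome` with columns `id`,
#'   `description`, `sequence` and `length`, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKPLTGKV", ">p2", "aaNNI"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) {
    return(empty_proteome())
  }
  headers <- names(set)
  seqs <- toupper(as.character(set))
  empty <- which(nchar(seqs) == 0L)
  if (length(empty) > 0) {
    stop("empty sequence for record(s) at index: ",
         paste(empty, collapse = ", "))
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  bad <- which(is.na(ids) | ids == "")
  if (length(bad) > 0) {
    stop("malformed header (empty accession) at record index: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate accession(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  proteome(ids, seqs, desc)
}

#' Write a proteome table to FASTA
#'
#' @param proteome A `proteome` data frame (see [read_fasta()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  stopifnot(is.data.frame(proteome), all(c("id", "sequence") %in% names(proteome)))
  set <- Biostrings::AAStringSet(proteome$sequence)
  desc <- proteome$description
  if (is.null(desc)) desc <- rep("", nrow(proteome))
  names(set) <- ifelse(desc == "", proteome$id, paste(proteome$id, desc))
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Construct a proteome table from vectors
#'
#' @param id Accession strings (unique, non-empty).
#' @param sequence Residue strings (canonicalized to upper case).
#' @param description Optional free-text descriptions.
#' @return A `proteome` data frame.
#' @export
proteome <- function(id, sequence, description = "") {
  sequence <- toupper(as.character(sequence))
  id <- as.character(id)
  stopifnot(length(id) == length(sequence), !any(id == ""),
            !anyDuplicated(id))
  out <- data.frame(
    id = id,
    description = rep_len(as.character(description), length(id)),
    sequence = sequence,
    length = nchar(sequence),
    stringsAsFactors = FALSE
  )
  class(out) <- c("proteome", "data.frame")
  out
}

empty_proteome <- function() {
  proteome(character(0), character(0), character(0))
}
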