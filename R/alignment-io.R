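#' Read an aligned FASTA file into a tidy alignment
#'
#' Parses a FASTA file of pre-aligned nucleotide sequences (for example a
#' 658-bp COI barcode alignment) into a tibble with one row per sample.
#' Residues are normalized on the way in: upper-cased, RNA \code{U} mapped to
#' \code{T}, and \code{?} mapped to \code{N}, so that records downloaded from
#' BOLD or GenBank in mixed conventions compare cleanly. The sample id is the
#' first whitespace-delimited token of the header (BOLD process IDs and
#' GenBank accessions appear as the first token); the rest of the description
#' is ignored.
#'
#' @param path Path to a FASTA file.
#' @return A tibble of class \code{barcode_alignment} with columns
#'   \code{sample_id} and \code{sequence}. All sequences have equal length;
#'   record order is preserved.
#' @seealso [write_fasta()], [restrict_alignment()]
#' @examples
#' fa <- system.file("extdata", "KY777529.fasta", package = "barcodiv")
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("input-error: file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("input-error: cannot parse FASTA: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) {
    stop("input-error: empty FASTA file: ", path, call. = FALSE)
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- normalize_residues(as.character(set))
  as_alignment(tibble::tibble(sample_id = ids, sequence = unname(seqs)))
}

#' Coerce a data frame to a validated alignment
#'
#' @param x A data frame with character columns \code{sample_id} and
#'   \code{sequence} (sequences already normalized or plain A/C/G/T).
#' @return The input as a \code{barcode_alignment} tibble, after validation:
#'   ids unique and non-empty, all sequences the same positive length,
#'   residues restricted to A/C/G/T, IUPAC ambiguity codes, N and \code{-}.
#' @export
as_alignment <- function(x) {
  stopifnot(is.data.frame(x), all(c("sample_id", "sequence") %in% names(x)))
  x <- tibble::as_tibble(x)[, c("sample_id", "sequence")]
  if (any(is.na(x$sample_id)) || any(x$sample_id == "")) {
    stop("input-error: empty sample id", call. = FALSE)
  }
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup) > 0) {
    stop("input-error: duplicate sample id(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  lens <- nchar(x$sequence)
  if (length(unique(lens)) != 1) {
    off <- x$sample_id[lens != stats::median(lens)]
    stop("alignment-error: records have unequal lengths (offending: ",
         paste(off, collapse = ", "), ")", call. = FALSE)
  }
  if (lens[1] == 0) {
    stop("alignment-error: zero-length alignment", call. = FALSE)
  }
  allowed <- c("A", "C", "G", "T", IUPAC_AMBIG, "N", "-")
  bad <- setdiff(unique(unlist(strsplit(x$sequence, "", fixed = TRUE))), allowed)
  if (length(bad) > 0) {
    stop("alignment-error: invalid residue(s) after normalization: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(x) <- c("barcode_alignment", class(x))
  x
}

# upper-case, U -> T, ? -> N
normalize_residues <- function(sequences) {
  s <- toupper(sequences)
  s <- gsub("U", "T", s, fixed = TRUE)
  gsub("?", "N", s, fixed = TRUE)
}

#' Number of sites in an alignment
#'
#' @param alignment A \code{barcode_alignment} tibble.
#' @return Integer alignment length (sites).
#' @export
aln_length <- function(alignment) {
  unname(nchar(alignment$sequence[1]))
}

#' Write an alignment to FASTA
#'
#' Writes one record per sample, id as header, sequence wrapped at 70
#' columns. \code{read_fasta(write_fasta(aln, f))} round-trips to an
#' identical alignment.
#'
#' @param alignment A \code{barcode_alignment} tibble.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  stopifnot(is.data.frame(alignment))
  set <- Biostrings::BStringSet(alignment$sequence)
  names(set) <- alignment$sample_id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Restrict an alignment to a set of samples
#'
#' @param alignment A \code{barcode_alignment} tibble.
#' @param ids Character vector of sample ids to keep; all must be present.
#' @return The sub-alignment, in the order of \code{alignment} (not of
#'   \code{ids}); same alignment length.
#' @export
restrict_alignment <- function(alignment, ids) {
  stopifnot(is.data.frame(alignment), is.character(ids))
  if (length(ids) == 0) {
    stop("input-error: empty sample selection", call. = FALSE)
  }
  unknown <- setdiff(ids, alignment$sample_id)
  if (length(unknown) > 0) {
    stop("lookup-error: unknown sample id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  as_alignment(alignment[alignment$sample_id %in% ids, ])
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("# A barcode alignment: %d samples x %d sites\n",
              nrow(x), aln_length(x)))
  NextMethod()
}
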