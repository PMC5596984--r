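#' Read a sample-to-group assignment table
#'
#' Reads a two-column tab-delimited file mapping sample ids to group labels
#' (haplogroups such as \code{"P1"}, or taxon names). Lines starting with
#' \code{#} are comments. Group order is the order of first appearance.
#'
#' Note that a grouping is whatever partition you choose to compare: taxon
#' labels are an \emph{input} (field identifications), while haplogroup
#' membership is typically a \emph{result} (e.g. from
#' [single_linkage_clusters()]); the two need not agree, and their
#' disagreement is exactly what [discordant_samples()] reports.
#'
#' @param path Path to a tab-delimited file, columns \code{sample_id} and
#'   \code{group}.
#' @param header Logical; does the file carry a header line? Default `FALSE`.
#' @return A tibble of class \code{barcode_grouping} with columns
#'   \code{sample_id} and \code{group}.
#' @export
read_grouping <- function(path, header = FALSE) {
  if (!file.exists(path)) {
    stop("input-error: file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.delim(path, header = header, comment.char = "#",
                      colClasses = "character", blank.lines.skip = TRUE),
    error = function(e) stop("input-error: cannot parse grouping table: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("input-error: grouping table needs two columns and at least one row",
         call. = FALSE)
  }
  names(df)[1:2] <- c("sample_id", "group")
  as_grouping(df[, 1:2])
}

#' Coerce a data frame to a validated grouping
#'
#' @param x Data frame with columns \code{sample_id} and \code{group}.
#' @return A \code{barcode_grouping} tibble. A sample listed twice with
#'   conflicting groups is an error; consistent duplicates are collapsed.
#' @export
as_grouping <- function(x) {
  stopifnot(is.data.frame(x), all(c("sample_id", "group") %in% names(x)))
  x <- tibble::as_tibble(x)[, c("sample_id", "group")]
  if (any(is.na(x$group)) || any(trimws(x$group) == "")) {
    stop("input-error: blank group label", call. = FALSE)
  }
  if (any(is.na(x$sample_id)) || any(trimws(x$sample_id) == "")) {
    stop("input-error: blank sample id", call. = FALSE)
  }
  conflict <- x |>
    dplyr::distinct(.data$sample_id, .data$group) |>
    dplyr::count(.data$sample_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(conflict) > 0) {
    stop("input-error: conflicting group assignment for sample(s): ",
         paste(conflict$sample_id, collapse = ", "), call. = FALSE)
  }
  x <- dplyr::distinct(x)
  class(x) <- c("barcode_grouping", class(x))
  x
}

# members of one group, checked against an alignment when given
group_members <- function(grouping, label, alignment = NULL, warn_singleton = FALSE) {
  ids <- grouping$sample_id[grouping$group == label]
  if (length(ids) == 0) {
    stop("input-error: group has no members: ", label, call. = FALSE)
  }
  if (!is.null(alignment)) {
    unknown <- setdiff(ids, alignment$sample_id)
    if (length(unknown) > 0) {
      stop("lookup-error: grouped sample(s) absent from alignment: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (warn_singleton && length(ids) == 1) {
    warning("group '", label, "' has a single member; it is trivially ",
            "invariant at every site", call. = FALSE)
  }
  ids
}

group_labels <- function(grouping) unique(grouping$group)
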