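#' Site-masking policy for distance and diagnostic-site computations
#'
#' Barcode records carry gaps, \code{N}s and IUPAC ambiguity codes; a site
#' policy states which sites enter a comparison.
#'
#' \describe{
#'   \item{mode}{\code{"pairwise_deletion"} drops, for each pair of
#'     sequences, only the sites masked in that pair;
#'     \code{"complete_deletion"} drops a site for everyone if it is masked
#'     in any sequence under consideration.}
#'   \item{ambiguity}{\code{"treat_as_missing"} masks ambiguity codes like
#'     \code{N}; \code{"strict_mismatch"} keeps them in the comparison but an
#'     ambiguous residue never matches anything, including itself.}
#' }
#'
#' The default, pairwise deletion with ambiguities treated as missing, is the
#' de-facto standard for uncorrected distances in barcoding software.
#'
#' @param mode One of \code{"pairwise_deletion"}, \code{"complete_deletion"}.
#' @param ambiguity One of \code{"treat_as_missing"}, \code{"strict_mismatch"}.
#' @return A \code{site_policy} object.
#' @examples
#' site_policy()
#' site_policy("complete_deletion", "strict_mismatch")
#' @export
site_policy <- function(mode = c("pairwise_deletion", "complete_deletion"),
                        ambiguity = c("treat_as_missing", "strict_mismatch")) {
  mode <- match.arg(mode)
  ambiguity <- match.arg(ambiguity)
  structure(list(mode = mode, ambiguity = ambiguity), class = "site_policy")
}

#' @export
print.site_policy <- function(x, ...) {
  cat("site policy:", x$mode, "/", x$ambiguity, "\n")
  invisible(x)
}
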