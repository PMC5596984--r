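#' Uncorrected p-distance between two aligned sequences
#'
#' The elementary barcode divergence measure: the proportion of compared
#' sites at which two equal-length sequences differ, with no multiple-hit
#' correction. Sites masked under the [site_policy()] (gaps and \code{N}
#' always; ambiguity codes when treated as missing) are excluded from the
#' comparison. Under \code{ambiguity = "strict_mismatch"} an ambiguous
#' residue is compared but never matches anything, including itself.
#'
#' @param a,b Residue strings of equal length (normalized, as produced by
#'   [read_fasta()]).
#' @param policy A [site_policy()].
#' @return A one-row tibble with columns \code{p}, \code{compared_sites},
#'   \code{differing_sites}; \code{p = differing_sites / compared_sites}.
#' @examples
#' p_distance("ACGT", "ACGA")
#' p_distance("AC-T", "ACGT")  # gap site excluded: 3 compared, p = 0
#' @export
p_distance <- function(a, b, policy = site_policy()) {
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) {
    stop("alignment-error: sequences have unequal lengths (", nchar(a),
         " vs ", nchar(b), ")", call. = FALSE)
  }
  m <- seq_matrix(c(a, b))
  miss <- missing_mask(m, policy)
  res <- pair_distance(m[1, ], m[2, ], miss[1, ], miss[2, ], policy)
  if (res$compared_sites == 0) {
    stop("undefined-distance: no comparable sites between the sequences",
         call. = FALSE)
  }
  tibble::tibble(p = res$p, compared_sites = res$compared_sites,
                 differing_sites = res$differing_sites)
}

# core per-pair comparison on character vectors + missing masks
pair_distance <- function(ra, rb, ma, mb, policy, keep_global = NULL) {
  keep <- if (is.null(keep_global)) !(ma | mb) else keep_global
  compared <- sum(keep)
  if (compared == 0) {
    return(list(p = NA_real_, compared_sites = 0L, differing_sites = 0L))
  }
  diff <- ra != rb
  if (policy$ambiguity == "strict_mismatch") {
    diff <- diff | ra %in% IUPAC_AMBIG | rb %in% IUPAC_AMBIG
  }
  differing <- sum(diff & keep)
  list(p = differing / compared, compared_sites = as.integer(compared),
       differing_sites = as.integer(differing))
}

#' All pairwise uncorrected p-distances in an alignment
#'
#' Computes the full pairwise distance table underlying closest-pair searches
#' and haplogroup clustering. Under complete deletion, any site masked in any
#' record of the alignment is dropped for all pairs; under pairwise deletion
#' each pair keeps its own comparable sites.
#'
#' @param alignment A \code{barcode_alignment} with at least two records.
#' @param policy A [site_policy()].
#' @return A tibble of class \code{pdist_tbl} with one row per unordered pair
#'   (columns \code{sample_a}, \code{sample_b} in alignment order, \code{p},
#'   \code{compared_sites}, \code{differing_sites}).
#' @seealso [pdist_matrix()] for the square form, [min_intergroup()],
#'   [single_linkage_clusters()]
#' @export
distance_matrix <- function(alignment, policy = site_policy()) {
  alignment <- as_alignment(alignment)
  n <- nrow(alignment)
  if (n < 2) stop("input-error: need at least two records", call. = FALSE)
  m <- seq_matrix(alignment$sequence)
  miss <- missing_mask(m, policy)
  keep_global <- if (policy$mode == "complete_deletion") colSums(miss) == 0 else NULL
  ids <- alignment$sample_id
  idx <- utils::combn(n, 2)
  rows <- purrr::map(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    res <- pair_distance(m[i, ], m[j, ], miss[i, ], miss[j, ], policy, keep_global)
    if (res$compared_sites == 0) {
      stop("undefined-distance: no comparable sites between '", ids[i],
           "' and '", ids[j], "'", call. = FALSE)
    }
    tibble::tibble(sample_a = ids[i], sample_b = ids[j], p = res$p,
                   compared_sites = res$compared_sites,
                   differing_sites = res$differing_sites)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "ids") <- ids
  class(out) <- c("pdist_tbl", class(out))
  out
}

#' Square matrix form of a pairwise distance table
#'
#' @param distances A \code{pdist_tbl} from [distance_matrix()].
#' @return A symmetric numeric matrix with zero diagonal, rows and columns
#'   named by sample id in alignment order.
#' @export
pdist_matrix <- function(distances) {
  ids <- attr(distances, "ids") %||%
    unique(c(distances$sample_a, distances$sample_b))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(distances$sample_a, distances$sample_b)] <- distances$p
  m[cbind(distances$sample_b, distances$sample_a)] <- distances$p
  m
}

#' Minimal inter-group p-distance via the closest sample pair
#'
#' Implements the closest-pair divergence criterion: over all pairs with one
#' member in each group, select the two genetically closest samples and
#' report the uncorrected p-distance between them (computed from both fixed
#' and non-fixed substitutions). Ties at the minimum are broken by
#' lexicographic \code{(sample_a, sample_b)} order; all tying pairs are
#' listed in the \code{ties} list-column.
#'
#' @param distances A \code{pdist_tbl} from [distance_matrix()].
#' @param grouping A \code{barcode_grouping} (see [read_grouping()]).
#' @param group_a,group_b Group labels; must be non-empty and disjoint.
#' @return A one-row tibble of class \code{closest_pair}: \code{group_a},
#'   \code{group_b}, \code{sample_a} (in \code{group_a}), \code{sample_b},
#'   \code{p}, \code{p_percent} (rendered at one decimal),
#'   \code{compared_sites}, \code{differing_sites}, \code{n_ties},
#'   \code{ties}.
#' @export
min_intergroup <- function(distances, grouping, group_a, group_b) {
  grouping <- as_grouping(grouping)
  ids <- attr(distances, "ids") %||%
    unique(c(distances$sample_a, distances$sample_b))
  members_a <- group_members(grouping, group_a)
  members_b <- group_members(grouping, group_b)
  overlap <- intersect(members_a, members_b)
  if (length(overlap) > 0) {
    stop("input-error: groups overlap (", paste(overlap, collapse = ", "), ")",
         call. = FALSE)
  }
  absent <- setdiff(c(members_a, members_b), ids)
  if (length(absent) > 0) {
    stop("lookup-error: sample(s) absent from distance table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  inter <- distances |>
    dplyr::filter(
      (.data$sample_a %in% members_a & .data$sample_b %in% members_b) |
      (.data$sample_a %in% members_b & .data$sample_b %in% members_a))
  # orient every pair as (group_a member, group_b member)
  flip <- inter$sample_a %in% members_b
  oriented <- tibble::tibble(
    sample_a = ifelse(flip, inter$sample_b, inter$sample_a),
    sample_b = ifelse(flip, inter$sample_a, inter$sample_b),
    p = inter$p, compared_sites = inter$compared_sites,
    differing_sites = inter$differing_sites)
  best <- oriented |>
    dplyr::filter(.data$p == min(.data$p)) |>
    dplyr::arrange(.data$sample_a, .data$sample_b)
  out <- tibble::tibble(
    group_a = group_a, group_b = group_b,
    sample_a = best$sample_a[1], sample_b = best$sample_b[1],
    p = best$p[1], p_percent = render_percent(best$p[1]),
    compared_sites = best$compared_sites[1],
    differing_sites = best$differing_sites[1],
    n_ties = nrow(best),
    ties = list(best[, c("sample_a", "sample_b", "p")]))
  class(out) <- c("closest_pair", class(out))
  out
}
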