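#' Fixed (diagnostic) substitutions between two groups
#'
#' Enumerates the sites of the alignment that carry a fixed DNA substitution
#' between two groups — the invariable differences: after masking under the
#' [site_policy()], a site is diagnostic iff every unmasked member of group A
#' shows one single residue, every unmasked member of group B shows one
#' single residue, the two residues differ, and each group has at least one
#' unmasked member at the site. Sites where a group has no unmasked member
#' are not evaluable and are excluded from \code{evaluated_sites}; under
#' complete deletion a site masked in any member of either group is dropped
#' the same way.
#'
#' @param alignment A \code{barcode_alignment}.
#' @param grouping A \code{barcode_grouping} covering both groups.
#' @param group_a,group_b Group labels (non-empty; a singleton group is
#'   permitted with a warning, being trivially invariant).
#' @param policy A [site_policy()].
#' @return A tibble of class \code{diagnostic_sites} with one row per
#'   diagnostic site (columns \code{position} (1-based), \code{state_a},
#'   \code{state_b}), positions strictly increasing. Attributes
#'   \code{group_a}, \code{group_b}, \code{count} (= number of rows) and
#'   \code{evaluated_sites}; see \code{glance()} for a one-row summary.
#' @examples
#' aln <- as_alignment(data.frame(
#'   sample_id = c("s1", "s2", "t1", "t2"),
#'   sequence  = c("ACGT", "ACGA", "TCGT", "TCGA")))
#' grp <- as_grouping(data.frame(sample_id = c("s1", "s2", "t1", "t2"),
#'                               group = c("S", "S", "T", "T")))
#' fixed_substitutions(aln, grp, "S", "T")  # site 1 (A|T); site 4 polymorphic
#' @export
fixed_substitutions <- function(alignment, grouping, group_a, group_b,
                                policy = site_policy()) {
  alignment <- as_alignment(alignment)
  grouping <- as_grouping(grouping)
  ids_a <- group_members(grouping, group_a, alignment, warn_singleton = TRUE)
  ids_b <- group_members(grouping, group_b, alignment, warn_singleton = TRUE)
  m <- seq_matrix(alignment$sequence)
  rownames(m) <- alignment$sample_id
  miss <- missing_mask(m, policy)
  rownames(miss) <- alignment$sample_id
  ma <- m[ids_a, , drop = FALSE]; xa <- miss[ids_a, , drop = FALSE]
  mb <- m[ids_b, , drop = FALSE]; xb <- miss[ids_b, , drop = FALSE]

  obs_a <- colSums(!xa); obs_b <- colSums(!xb)
  evaluable <- obs_a > 0 & obs_b > 0
  if (policy$mode == "complete_deletion") {
    evaluable <- colSums(xa) == 0 & colSums(xb) == 0
  }
  group_state <- function(col, msk) {
    # single observed residue, or NA if polymorphic / strict-ambiguous
    st <- unique(col[!msk])
    if (length(st) != 1) return(NA_character_)
    if (policy$ambiguity == "strict_mismatch" && st %in% IUPAC_AMBIG) {
      return(NA_character_)  # an ambiguity cannot certify invariance
    }
    st
  }
  pos <- which(evaluable)
  state_a <- vapply(pos, function(j) group_state(ma[, j], xa[, j]), character(1))
  state_b <- vapply(pos, function(j) group_state(mb[, j], xb[, j]), character(1))
  diag <- !is.na(state_a) & !is.na(state_b) & state_a != state_b
  sites <- tibble::tibble(position = as.integer(pos[diag]),
                          state_a = state_a[diag], state_b = state_b[diag])
  structure(sites,
            group_a = group_a, group_b = group_b,
            count = nrow(sites), evaluated_sites = as.integer(sum(evaluable)),
            class = c("diagnostic_sites", class(sites)))
}

#' @export
print.diagnostic_sites <- function(x, ...) {
  cat(sprintf("# Fixed substitutions %s | %s: %d diagnostic site(s) over %d evaluated\n",
              attr(x, "group_a"), attr(x, "group_b"),
              attr(x, "count"), attr(x, "evaluated_sites")))
  NextMethod()
}

#' Summarize a diagnostic-site report
#'
#' @param x A \code{diagnostic_sites} object.
#' @param ... Unused.
#' @return One-row tibble: \code{group_a}, \code{group_b}, \code{count},
#'   \code{evaluated_sites}.
#' @method glance diagnostic_sites
#' @export
glance.diagnostic_sites <- function(x, ...) {
  tibble::tibble(group_a = attr(x, "group_a"), group_b = attr(x, "group_b"),
                 count = attr(x, "count"),
                 evaluated_sites = attr(x, "evaluated_sites"))
}

#' Per-pair divergence summary table
#'
#' Applies both divergence criteria — fixed-substitution counts and minimal
#' inter-group p-distance via the closest sample pair — to every unordered
#' pair of groups, producing the table a barcoding study reports per lineage
#' pair.
#'
#' @param alignment A \code{barcode_alignment}.
#' @param grouping A \code{barcode_grouping} with at least two groups, all
#'   members present in the alignment.
#' @param policy A [site_policy()].
#' @return A tibble of class \code{divergence_summary}, one row per group
#'   pair in group order of first appearance: \code{group_a}, \code{group_b},
#'   \code{fixed_count}, \code{evaluated_sites}, \code{min_p},
#'   \code{min_p_percent} (one decimal, round-half-up), \code{closest_a},
#'   \code{closest_b}. Row order is deterministic for identical input.
#' @export
divergence_summary <- function(alignment, grouping, policy = site_policy()) {
  alignment <- as_alignment(alignment)
  grouping <- as_grouping(grouping)
  labels <- group_labels(grouping)
  if (length(labels) < 2) {
    stop("input-error: need at least two groups", call. = FALSE)
  }
  aln <- restrict_alignment(alignment,
                            intersect(alignment$sample_id, grouping$sample_id))
  dists <- distance_matrix(aln, policy)
  pairs <- utils::combn(labels, 2)
  purrr::map(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    fx <- suppressWarnings(fixed_substitutions(aln, grouping, ga, gb, policy))
    cp <- min_intergroup(dists, grouping, ga, gb)
    tibble::tibble(group_a = ga, group_b = gb,
                   fixed_count = attr(fx, "count"),
                   evaluated_sites = attr(fx, "evaluated_sites"),
                   min_p = cp$p, min_p_percent = cp$p_percent,
                   closest_a = cp$sample_a, closest_b = cp$sample_b)
  }) |>
    dplyr::bind_rows() |>
    structure(class = c("divergence_summary", class(tibble::tibble())))
}
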