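#' Distance-threshold haplogroup clustering (single linkage)
#'
#' Recovers haplogroups as the connected components of the graph joining
#' every sample pair with uncorrected p-distance at or below a threshold —
#' equivalently, a single-linkage dendrogram cut at that height. This is a
#' deterministic, parameter-light stand-in for tree-based haplogroup
#' delineation: the haplogroup notion is connectivity-like, so a chain of
#' close haplotypes belongs together even when its ends are farther apart.
#'
#' The default threshold of 0.01 (1 %) sits below typical minimal
#' inter-haplogroup barcode divergences (about 2 % and up in the
#' \emph{Melitaea persea} complex) and above typical within-haplogroup
#' polymorphism.
#'
#' @param distances A \code{pdist_tbl} from [distance_matrix()].
#' @param threshold Maximum within-cluster chain step, as a fraction in
#'   \code{[0, 1]}. Default 0.01.
#' @return A tibble of class \code{haplogroup_clusters}, one row per sample:
#'   \code{sample_id}, \code{cluster} (labels \code{"C1"}, \code{"C2"}, ...
#'   assigned by decreasing cluster size, ties by lexicographically smallest
#'   member), \code{cluster_size}. Attribute \code{threshold} records the
#'   cut.
#' @export
single_linkage_clusters <- function(distances, threshold = 0.01) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold >= 0, threshold <= 1)
  ids <- attr(distances, "ids") %||%
    unique(c(distances$sample_a, distances$sample_b))
  d <- stats::as.dist(pdist_matrix(distances)[ids, ids])
  hc <- stats::hclust(d, method = "single")
  # cutree(h = t) merges every pair chain-connected at height <= t, i.e. the
  # connected components of the p <= t threshold graph
  raw <- stats::cutree(hc, h = threshold)[ids]
  assignment <- tibble::tibble(sample_id = ids, raw = unname(raw))
  sizes <- assignment |>
    dplyr::group_by(.data$raw) |>
    dplyr::summarise(size = dplyr::n(),
                     smallest = min(.data$sample_id), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$smallest) |>
    dplyr::mutate(cluster = paste0("C", dplyr::row_number()))
  out <- assignment |>
    dplyr::left_join(sizes, by = "raw") |>
    dplyr::transmute(.data$sample_id, .data$cluster, cluster_size = .data$size)
  attr(out, "threshold") <- threshold
  class(out) <- c("haplogroup_clusters", class(out))
  out
}

#' Taxon/haplogroup discordance (introgression candidates)
#'
#' Compares an a-priori taxon labelling against a clustering of the same
#' samples and reports every sample whose taxon differs from the majority
#' taxon of its cluster. Under mitochondrial introgression, a minority of
#' one taxon's samples carry another taxon's haplotype and therefore cluster
#' away from their conspecifics; those samples are exactly the rows of this
#' report.
#'
#' Majority ties within a cluster are resolved in favour of the taxon whose
#' own modal (home) cluster is that cluster — i.e. the taxon native to the
#' haplogroup — then lexicographically; tied clusters are flagged in
#' \code{majority_tied}. This keeps an introgressed minority discordant even
#' when it happens to equal the native taxon in count.
#'
#' @param clusters A \code{haplogroup_clusters} tibble from
#'   [single_linkage_clusters()].
#' @param grouping A \code{barcode_grouping} of taxon labels covering every
#'   clustered sample.
#' @return A tibble of class \code{discordance_report} with one row per
#'   discordant sample: \code{sample_id}, \code{taxon}, \code{cluster},
#'   \code{majority_taxon}, \code{majority_tied}. Empty when every taxon is
#'   concordant with its haplogroup.
#' @export
discordant_samples <- function(clusters, grouping) {
  grouping <- as_grouping(grouping)
  uncovered <- setdiff(clusters$sample_id, grouping$sample_id)
  if (length(uncovered) > 0) {
    stop("lookup-error: clustered sample(s) without taxon label: ",
         paste(uncovered, collapse = ", "), call. = FALSE)
  }
  joined <- clusters |>
    dplyr::inner_join(grouping, by = "sample_id") |>
    dplyr::rename(taxon = "group")
  # home (modal) cluster of each taxon, for majority tie-breaking
  home <- joined |>
    dplyr::count(.data$taxon, .data$cluster) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$cluster, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("taxon", home_cluster = "cluster")
  majority <- joined |>
    dplyr::count(.data$cluster, .data$taxon) |>
    dplyr::left_join(home, by = "taxon") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(majority_tied = sum(.data$n == max(.data$n)) > 1) |>
    dplyr::arrange(dplyr::desc(.data$n),
                   dplyr::desc(.data$home_cluster == .data$cluster),
                   .data$taxon, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("cluster", majority_taxon = "taxon",
                  "majority_tied")
  out <- joined |>
    dplyr::left_join(majority, by = "cluster") |>
    dplyr::filter(.data$taxon != .data$majority_taxon) |>
    dplyr::select("sample_id", "taxon", "cluster",
                  "majority_taxon", "majority_tied")
  class(out) <- c("discordance_report", class(out))
  out
}
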