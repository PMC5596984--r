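# Independent brute-force oracles and random-instance generators.
# These deliberately share no code with the package internals: distances are
# computed by explicit per-site loops, components by breadth-first search.

AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

oracle_masked <- function(ch, policy) {
  ch %in% c("-", "N") ||
    (policy$ambiguity == "treat_as_missing" && ch %in% AMBIG)
}

# per-site loop p-distance (pairwise deletion over the two sequences given;
# complete deletion is handled by pre-masking columns in oracle_matrix)
oracle_pdist <- function(a, b, policy, keep = NULL) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  compared <- 0L
  differing <- 0L
  for (i in seq_along(ca)) {
    if (!is.null(keep) && !keep[i]) next
    if (oracle_masked(ca[i], policy) || oracle_masked(cb[i], policy)) next
    compared <- compared + 1L
    mismatch <- ca[i] != cb[i]
    if (policy$ambiguity == "strict_mismatch" &&
        (ca[i] %in% AMBIG || cb[i] %in% AMBIG)) {
      mismatch <- TRUE
    }
    if (mismatch) differing <- differing + 1L
  }
  list(p = if (compared > 0) differing / compared else NA_real_,
       compared = compared, differing = differing)
}

# double-loop distance matrix
oracle_matrix <- function(alignment, policy) {
  n <- nrow(alignment)
  keep <- NULL
  if (policy$mode == "complete_deletion") {
    chars <- strsplit(alignment$sequence, "")
    L <- length(chars[[1]])
    keep <- vapply(seq_len(L), function(i) {
      !any(vapply(chars, function(s) oracle_masked(s[i], policy), logical(1)))
    }, logical(1))
  }
  m <- matrix(0, n, n, dimnames = list(alignment$sample_id,
                                       alignment$sample_id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- oracle_pdist(alignment$sequence[i], alignment$sequence[j],
                        policy, keep)
      m[i, j] <- r$p
      m[j, i] <- r$p
    }
  }
  m
}

# per-site set-comparison fixed-substitution count
oracle_fixed <- function(alignment, grouping, ga, gb, policy) {
  ids_a <- grouping$sample_id[grouping$group == ga]
  ids_b <- grouping$sample_id[grouping$group == gb]
  seqs <- stats::setNames(strsplit(alignment$sequence, ""),
                          alignment$sample_id)
  L <- length(seqs[[1]])
  count <- 0L
  for (i in seq_len(L)) {
    obs_a <- Filter(function(ch) !oracle_masked(ch, policy),
                    vapply(seqs[ids_a], `[`, character(1), i))
    obs_b <- Filter(function(ch) !oracle_masked(ch, policy),
                    vapply(seqs[ids_b], `[`, character(1), i))
    if (policy$mode == "complete_deletion" &&
        (length(obs_a) < length(ids_a) || length(obs_b) < length(ids_b))) next
    if (length(obs_a) == 0 || length(obs_b) == 0) next
    sa <- unique(obs_a); sb <- unique(obs_b)
    if (length(sa) != 1 || length(sb) != 1) next
    if (policy$ambiguity == "strict_mismatch" &&
        (sa %in% AMBIG || sb %in% AMBIG)) next
    if (sa != sb) count <- count + 1L
  }
  count
}

# connected components of the p <= threshold graph, by breadth-first search
oracle_components <- function(dmat, threshold) {
  ids <- rownames(dmat)
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  k <- 0L
  for (s in ids) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      nb <- ids[dmat[v, ] <= threshold & ids != v & is.na(comp)]
      queue <- c(queue, nb)
    }
  }
  comp
}

# random alignment with optional gaps and ambiguity codes
rand_alignment <- function(n, L, gap_prob = 0.05, ambig_prob = 0.05) {
  pool <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(pool, L, replace = TRUE)
    r <- stats::runif(L)
    ch[r < gap_prob] <- sample(c("-", "N"), sum(r < gap_prob), replace = TRUE)
    amb <- r >= gap_prob & r < gap_prob + ambig_prob
    ch[amb] <- sample(AMBIG, sum(amb), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
  as_alignment(tibble::tibble(sample_id = sprintf("s%02d", seq_len(n)),
                              sequence = seqs))
}

both_policies <- list(
  site_policy("pairwise_deletion", "treat_as_missing"),
  site_policy("pairwise_deletion", "strict_mismatch"),
  site_policy("complete_deletion", "treat_as_missing"),
  site_policy("complete_deletion", "strict_mismatch"))

holotype_path <- function() {
  system.file("extdata", "KY777529.fasta", package = "barcodiv")
}
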