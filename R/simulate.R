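#' Simulate a two-population split under Jukes–Cantor evolution
#'
#' Evolves a random root sequence along two independent lineages for a split
#' time \code{t}: per site, the number of substitution events on a branch of
#' duration \eqn{\Delta t} is Poisson with mean \eqn{\mu \Delta t}, each
#' event replacing the base with a uniformly chosen different base (the
#' JC69 model). All samples of a side carry that side's present-day lineage
#' haplotype, so the within-side distance is zero and the expected
#' uncorrected distance between sides is the Jukes–Cantor saturating curve
#' \deqn{E[p] = \frac{3}{4}\left(1 - e^{-\frac{8}{3}\mu t}\right),}
#' which for small divergences is approximately the total branch length
#' \eqn{2\mu t} and saturates at 0.75.
#'
#' An optional introgression event transfers the donor lineage's haplotype
#' at \code{time} Myr before present into \code{n} recipient-side samples;
#' the transferred lineage then evolves independently to the present, so
#' those samples cluster with the donor while keeping the recipient label —
#' the signal [discordant_samples()] detects.
#'
#' @param L Sites (default 658).
#' @param mu Per-lineage substitution rate, substitutions/site/Myr (> 0).
#'   The corresponding pairwise rate is \code{2 * mu} per site, i.e.
#'   \code{200 * mu} \%/Myr.
#' @param t Split time, Myr (>= 0).
#' @param n_per_side Samples per population (default 5).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param introgression \code{NULL}, or
#'   \code{list(donor = "pop1", n = <count>, time = <Myr, <= t>)} planting
#'   \code{n} introgressed samples on the other side.
#' @return A list of class \code{jc_simulation}: \code{alignment},
#'   \code{grouping} (side labels \code{"pop1"}/\code{"pop2"}, introgressed
#'   samples keeping the recipient label), and \code{truth} (parameters, the
#'   closed-form expected inter-side \code{expected_p}, and introgressed
#'   sample ids).
#' @examples
#' sim <- simulate_jc(L = 658, mu = 0.01, t = 1.3, seed = 7)
#' sim$truth$expected_p
#' @export
simulate_jc <- function(L = 658, mu, t, n_per_side = 5, seed,
                        introgression = NULL) {
  stopifnot(L > 0, is.numeric(mu), mu > 0, is.numeric(t), t >= 0)
  if (missing(seed)) stop("input-error: seed is mandatory", call. = FALSE)
  if (!is.null(introgression)) {
    stopifnot(introgression$time <= t, introgression$n < n_per_side,
              introgression$donor %in% c("pop1", "pop2"))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)

  root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  t_i <- if (!is.null(introgression)) introgression$time else 0
  donor <- if (!is.null(introgression)) introgression$donor else "pop1"

  # evolve each lineage, keeping the donor's state at the transfer time
  evolve_with_waypoint <- function(seq) {
    mid <- jc_evolve(seq, mu, t - t_i)
    list(mid = mid, tip = jc_evolve(mid, mu, t_i))
  }
  lin1 <- evolve_with_waypoint(root)
  lin2 <- evolve_with_waypoint(root)
  tips <- list(pop1 = lin1$tip, pop2 = lin2$tip)
  donor_mid <- if (donor == "pop1") lin1$mid else lin2$mid

  recipient <- setdiff(c("pop1", "pop2"), donor)
  ids <- c(); seqs <- c(); side <- c()
  intro_ids <- character(0)
  for (pop in c("pop1", "pop2")) {
    n_intro <- if (!is.null(introgression) && pop == recipient)
      introgression$n else 0
    intro_tip <- if (n_intro > 0) jc_evolve(donor_mid, mu, t_i)
    for (j in seq_len(n_per_side)) {
      id <- sprintf("%s_%02d", pop, j)
      s <- if (j > n_per_side - n_intro) intro_tip else tips[[pop]]
      ids <- c(ids, id); seqs <- c(seqs, paste(s, collapse = ""))
      side <- c(side, pop)
      if (j > n_per_side - n_intro) intro_ids <- c(intro_ids, id)
    }
  }
  alignment <- as_alignment(tibble::tibble(sample_id = ids, sequence = seqs))
  grouping <- as_grouping(tibble::tibble(sample_id = ids, group = side))
  truth <- list(
    L = L, mu = mu, t = t, seed = seed,
    pairwise_rate_per_site = 2 * mu,
    pairwise_rate_percent = 200 * mu,
    expected_p = 0.75 * (1 - exp(-(8 / 3) * mu * t)),
    introgression = if (!is.null(introgression))
      list(donor = donor, recipient = recipient, time = t_i,
           sample_ids = intro_ids))
  structure(list(alignment = alignment, grouping = grouping, truth = truth),
            class = "jc_simulation")
}

# evolve a residue vector for dt Myr at per-lineage rate mu under JC69
jc_evolve <- function(seq, mu, dt) {
  if (dt <= 0) return(seq)
  bases <- c("A", "C", "G", "T")
  hits <- stats::rpois(length(seq), mu * dt)
  for (j in which(hits > 0)) {
    for (k in seq_len(hits[j])) {
      seq[j] <- sample(setdiff(bases, seq[j]), 1)
    }
  }
  seq
}
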