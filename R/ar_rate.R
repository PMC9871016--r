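#' Genome architecture (AR) rate
#'
#' The AR rate of a taxon measures how diverse its mitochondrial gene
#' orders are: with `N_AR` distinct architectures among `N_mtDNA`
#' organisms,
#'
#' \deqn{AR = \frac{N_{AR} - 1}{N_{mtDNA} - 1} \cdot 100}
#'
#' so a taxon where every organism shares one architecture scores 0 and
#' a taxon where every organism is unique scores 100.  Architectures
#' are counted as distinct canonical anchored order strings (compare
#' with and without tRNA genes by anchoring the appropriate orders).
#'
#' @param architectures Character vector of canonical architecture
#'   strings, one per organism (see [anchor()] and [format_order()]).
#' @return AR rate in percent.
#' @examples
#' ar_rate(c("A B C", "A B C", "A C B"))  # 50
#' @export
ar_rate <- function(architectures) {
  n <- length(architectures)
  if (n < 2) stop("AR rate undefined for fewer than 2 organisms")
  100 * (length(unique(architectures)) - 1) / (n - 1)
}

#' Subsample-and-shuffle permutation test for AR rates
#'
#' For every taxonomic class with at least `min_class_size` organisms,
#' draws `iterations` subsamples of `subsample` organisms without
#' replacement and records the AR rate of each draw (the *observed*
#' distribution).  The *expected* distribution repeats the draw after
#' shuffling class labels across the pooled organism set, which makes
#' each draw a random subsample of the global architecture pool.  The
#' class is scored by the two-sided empirical tail probability of the
#' observed mean within the expected distribution, with the add-one
#' correction `p = (b + 1) / (m + 1)`, Bonferroni-corrected across the
#' classes tested.
#'
#' @param architectures Character vector of canonical architecture
#'   strings.
#' @param class_labels Character vector of class labels, parallel to
#'   `architectures`.
#' @param subsample Organisms drawn per iteration (default 21).
#' @param iterations Number of subsampling iterations (default 10000).
#' @param seed Integer RNG seed; recorded in the result.
#' @param min_class_size Minimum class size to test (default
#'   `max(20, subsample)`); smaller classes are skipped with a message.
#' @return Data frame with one row per tested class: `class`, `n`,
#'   `mean_observed`, `mean_expected`, `ratio`, `p`, `p_bonferroni`,
#'   `seed`; the per-class observed/expected distributions are attached
#'   as the `"distributions"` attribute (a named list of two-column
#'   matrices).
#' @export
ar_permutation_test <- function(architectures, class_labels,
                                subsample = 21, iterations = 10000,
                                seed = 1,
                                min_class_size = max(20, subsample)) {
  stopifnot(length(architectures) == length(class_labels))
  set.seed(seed)
  arch_id <- match(architectures, unique(architectures))  # fast unique()
  classes <- unique(class_labels)
  sizes <- table(class_labels)[classes]
  eligible <- classes[sizes >= min_class_size]
  skipped <- setdiff(classes, eligible)
  if (length(skipped)) {
    message("classes below size threshold skipped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(eligible) == 0) stop("no class meets the size threshold")

  subsample_rate <- function(pool) {
    idx <- sample.int(length(pool), subsample)
    x <- pool[idx]
    100 * (length(unique(x)) - 1) / (subsample - 1)
  }

  dists <- list()
  rows <- lapply(eligible, function(cl) {
    pool_cl <- arch_id[class_labels == cl]
    obs <- vapply(seq_len(iterations), function(i) subsample_rate(pool_cl),
                  0)
    # label shuffling across the pooled set: the shuffled class is a
    # uniform random subset of all organisms, so each expected draw is a
    # subsample of the global pool
    exp_ <- vapply(seq_len(iterations), function(i) subsample_rate(arch_id),
                   0)
    t_obs <- mean(obs)
    m <- length(exp_)
    p_lo <- (sum(exp_ <= t_obs) + 1) / (m + 1)
    p_hi <- (sum(exp_ >= t_obs) + 1) / (m + 1)
    p <- min(1, 2 * min(p_lo, p_hi))
    dists[[cl]] <<- cbind(observed = obs, expected = exp_)
    data.frame(class = cl, n = as.integer(sizes[cl]),
               mean_observed = t_obs, mean_expected = mean(exp_),
               ratio = t_obs / mean(exp_), p = p, seed = seed)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  attr(out, "distributions") <- dists
  out
}
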