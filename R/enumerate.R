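# Lexicographic next-permutation; returns NULL after the last permutation.
# Applied to a sorted multiset it visits every distinct ordering exactly once.
next_permutation <- function(x) {
  n <- length(x)
  i <- n - 1L
  while (i >= 1L && x[i] >= x[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (x[j] <= x[i]) j <- j - 1L
  tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  x[(i + 1L):n] <- rev(x[(i + 1L):n])
  x
}

multinomial_count <- function(multiset) {
  m <- table(multiset)
  exp(lgamma(length(multiset) + 1) - sum(lgamma(m + 1)))
}

#' Enumerate all distinct orderings of a covariate multiset
#'
#' Exhaustively lists the unique randomization sequences of a site-level
#' covariate. Sequences that place identically valued sites in different
#' labelled positions are counted once ("unique designs"): the number of
#' sequences is the multinomial coefficient n!/(m_1! m_2! ...). For the
#' canonical three-level covariate with two sites per level this gives 90
#' designs; with four sites per level, 34,650.
#'
#' @param multiset Numeric vector of covariate values (with repeats).
#' @param cap Maximum length for exhaustive enumeration (default 12; the
#'   34,650 twelve-site designs enumerate in well under a second). Longer
#'   multisets should use [sample_sequences()].
#' @return List of numeric vectors, each a distinct ordering, in
#'   lexicographic order.
#' @examples
#' length(enumerate_unique(c(0, 0, 1, 1, 2, 2)))  # 90
#' @export
enumerate_unique <- function(multiset, cap = 12) {
  n <- length(multiset)
  if (n > cap) {
    stop("multiset longer than the exhaustive cap (", cap,
         "); use sample_sequences() for random sampling", call. = FALSE)
  }
  x <- sort(as.numeric(multiset))
  total <- as.integer(round(multinomial_count(x)))
  out <- vector("list", total)
  k <- 1L
  out[[k]] <- x
  repeat {
    x <- next_permutation(x)
    if (is.null(x)) break
    k <- k + 1L
    out[[k]] <- x
  }
  stopifnot(k == total)
  out
}

#' Sample random orderings of a covariate multiset
#'
#' Draws uniform random orderings, the fallback when the number of sites
#' makes exhaustive enumeration infeasible. Draws are independent (the same
#' ordering can recur); set `dedupe = TRUE` to keep first occurrences only.
#'
#' @param multiset Numeric vector of covariate values.
#' @param n Number of draws.
#' @param dedupe Drop duplicate orderings? Default `FALSE`.
#' @param seed Optional integer seed for reproducibility.
#' @return List of numeric vectors.
#' @export
sample_sequences <- function(multiset, n, dedupe = FALSE, seed = NULL) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(n, sample(as.numeric(multiset)), simplify = FALSE)
  if (dedupe) out <- unique(out)
  out
}

# Nearest-rank (ceiling) empirical quantile on sorted values; p in [0, 100].
# p = 0 returns the minimum. Guarantees an achievable value on the discrete,
# heavily tied support of imbalance indices.
nearest_rank_quantile <- function(sorted_values, p) {
  n <- length(sorted_values)
  k <- pmax(1L, ceiling(p / 100 * n))
  sorted_values[k]
}

#' Distribution of the imbalance index over all unique designs
#'
#' Enumerates every distinct ordering of a covariate multiset, computes the
#' chosen imbalance index for each, and summarizes the distribution with
#' nearest-rank percentiles. This characterizes how much sequential
#' imbalance unrestricted randomization can produce for a given site mix.
#'
#' @param multiset Numeric covariate values (with repeats).
#' @param trend Index to compute: `"linear"` (default), `"quadratic"`, or
#'   `"seasonal"`.
#' @param percentiles Percentiles to report. Default
#'   `c(0, 16.7, 33, 50, 67, 83, 100)`.
#' @param cycle Seasonal cycle length (seasonal trend only).
#' @param cap Passed to [enumerate_unique()].
#' @return An object of class `swcrt_index_distribution`: list with
#'   `sequences` (in enumeration order), `index_values` (matching order),
#'   `sorted_values`, and `quantiles` (named numeric vector).
#' @examples
#' d <- index_distribution(c(0, 0, 1, 1, 2, 2))
#' d$quantiles[["50"]]  # 0.359
#' @export
index_distribution <- function(multiset, trend = "linear",
                               percentiles = c(0, 16.7, 33, 50, 67, 83, 100),
                               cycle = NULL, cap = 12) {
  trend <- match.arg(trend, c("linear", "quadratic", "seasonal"))
  seqs <- enumerate_unique(multiset, cap = cap)
  vals <- vapply(seqs, function(v) {
    compute_component_index(v, seq_along(v) + 1, trend, cycle)$value
  }, numeric(1))
  sv <- sort(vals)
  q <- nearest_rank_quantile(sv, percentiles)
  names(q) <- as.character(percentiles)
  structure(list(sequences = seqs, index_values = vals, sorted_values = sv,
                 quantiles = q, trend = trend),
            class = "swcrt_index_distribution")
}

#' @export
print.swcrt_index_distribution <- function(x, ...) {
  cat("Imbalance index distribution (", x$trend, ") over ",
      length(x$sequences), " unique designs\n", sep = "")
  print(round(x$quantiles, 3))
  invisible(x)
}

#' Draw a sequence whose index sits at a given percentile
#'
#' Selects, uniformly at random, one ordering from the exact tie set of
#' sequences whose index equals the nearest-rank percentile value of the
#' enumerated distribution. Used to construct study arms at controlled
#' levels of imbalance (e.g. fully balanced at the 0th percentile, fully
#' imbalanced at the 100th).
#'
#' @param dist An [index_distribution()].
#' @param q Percentile in \[0, 100\].
#' @param seed Optional integer seed.
#' @return List with `sequence`, `value` (the percentile index value),
#'   `tie_count` (size of the exact tie set sampled from), and `tie_set`
#'   (the full list of sequences at that value — e.g. the pool a simulation
#'   scenario re-randomizes over).
#' @export
sequences_at_percentile <- function(dist, q, seed = NULL) {
  stopifnot(inherits(dist, "swcrt_index_distribution"))
  v <- nearest_rank_quantile(dist$sorted_values, q)
  ties <- which(abs(dist$index_values - v) < 1e-12)
  if (!length(ties)) stop("empty tie set at percentile ", q, call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pick <- ties[sample.int(length(ties), 1)]
  list(sequence = dist$sequences[[pick]], value = v,
       tie_count = length(ties), tie_set = dist$sequences[ties])
}

#' Select a minimal-imbalance randomization sequence
#'
#' Computes the overall imbalance index for every candidate ordering of the
#' sites and randomly selects one sequence from the minimizing tie set —
#' the recommended balancing step. Random selection within the tie set
#' preserves genuine randomization; `relax = TRUE` widens the admissible set
#' to the two lowest index tiers when the strict minimum leaves too few
#' options to maintain allocation uncertainty.
#'
#' @param covariates Data frame or matrix of site-level covariates, one row
#'   per site in an arbitrary reference order.
#' @param spec An [imbalance_spec()] defining components and weights.
#' @param candidates Optional list of integer permutations of `1:nrow`,
#'   each a candidate ordering (row `candidates[[c]][k]` crosses over k-th).
#'   Default: all orderings — every permutation of labelled sites when
#'   `labelled = TRUE`, otherwise one representative per distinct covariate
#'   row ordering.
#' @param labelled Treat sites as distinguishable even when their covariate
#'   rows coincide? Default `TRUE` (e.g. 720 orderings for 6 sites).
#' @param relax Admit the second-lowest index tier as well? Default `FALSE`.
#' @param seed Optional integer seed for the random tie-break.
#' @param cap Maximum number of sites for exhaustive candidate generation
#'   (default 8 labelled / 12 unlabelled); supply `candidates` (e.g. from
#'   [sample_sequences()]) beyond that.
#' @return List with `order` (selected permutation of site indices),
#'   `covariates` (rows in selected order), `value` (its overall index),
#'   `tie_count` (size of the admissible tie set), and `all_values` (index
#'   of every candidate, in candidate order).
#' @examples
#' cov <- data.frame(rurality = c(1, 1, 2, 2, 3, 3))
#' sp <- imbalance_spec(data.frame(covariate = "rurality", trend = "linear"))
#' sel <- select_balanced(cov, sp, seed = 1)
#' sel$value  # 0: fully balanced orderings exist
#' @export
select_balanced <- function(covariates, spec, candidates = NULL,
                            labelled = TRUE, relax = FALSE, seed = NULL,
                            cap = if (labelled) 8 else 12) {
  covariates <- as.data.frame(covariates)
  I <- nrow(covariates)
  if (is.null(candidates)) {
    if (I > cap) {
      stop("too many sites for exhaustive candidates (cap ", cap,
           "); supply 'candidates'", call. = FALSE)
    }
    perms <- all_permutations(I)
    if (!labelled) {
      key <- vapply(perms, function(p) {
        paste(apply(covariates[p, , drop = FALSE], 1, paste, collapse = "\r"),
              collapse = "\n")
      }, character(1))
      perms <- perms[!duplicated(key)]
    }
    candidates <- perms
  }
  if (!length(candidates)) stop("empty candidate list", call. = FALSE)
  vals <- vapply(candidates, function(p) {
    imbalance_indices(covariates[p, , drop = FALSE], spec)$overall
  }, numeric(1))
  tiers <- sort(unique(round(vals, 12)))
  admit <- tiers[1]
  if (relax && length(tiers) > 1) admit <- tiers[1:2]
  ties <- which(round(vals, 12) %in% admit)
  if (!is.null(seed)) set.seed(seed)
  pick <- ties[sample.int(length(ties), 1)]
  ord <- candidates[[pick]]
  list(order = ord, covariates = covariates[ord, , drop = FALSE],
       value = vals[pick], tie_count = length(ties), all_values = vals)
}

# All I! permutations of 1:I via next_permutation (distinct labels).
all_permutations <- function(I) {
  x <- seq_len(I)
  out <- vector("list", factorial(I))
  k <- 1L
  out[[k]] <- x
  repeat {
    x <- next_permutation(x)
    if (is.null(x)) break
    k <- k + 1L
    out[[k]] <- x
  }
  out
}
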