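#' Simulate biallelic SNP marker dosages
#'
#' Draws an `N x m` matrix of dosages in `{0, 1, 2}`. Without family
#' structure, each marker `j` gets an allele frequency `p_j` uniform on
#' `freq_range` and dosages are binomial(2, p_j) per individual. With
#' `n_families > 1`, individuals are split into equal-sized families; each
#' family has two simulated parents (two haplotypes each, Bernoulli(p_j))
#' and every offspring receives one randomly transmitted gamete from each
#' parent, so full sibs share parental alleles and are more related than
#' cross-family pairs. Monomorphic columns are dropped after simulation, so
#' every retained marker has observed frequency strictly inside (0, 1).
#'
#' @param N number of individuals (>= 2).
#' @param m number of markers before the monomorphic filter (>= 1).
#' @param freq_range length-2 numeric range for allele frequencies, inside
#'   (0, 1).
#' @param n_families number of equal-sized families; `1` (default) means an
#'   unstructured population.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return An object of class `"marker_matrix"`: list with `genotypes`
#'   (`N x m'` integer matrix after filtering), `allele_freqs` (observed
#'   frequencies, length `m'`), and `family` (integer family labels,
#'   length `N`).
#' @examples
#' mk <- simulate_markers(20, 100, seed = 1)
#' range(mk$allele_freqs)
#' @export
simulate_markers <- function(N, m, freq_range = c(0.05, 0.95),
                             n_families = 1L, seed = 1L) {
  N <- as.integer(N); m <- as.integer(m)
  if (N < 2 || m < 1) stop("need N >= 2 and m >= 1", call. = FALSE)
  if (length(freq_range) != 2 || freq_range[1] > freq_range[2] ||
      freq_range[1] <= 0 || freq_range[2] >= 1) {
    stop("'freq_range' must be an increasing range inside (0, 1)", call. = FALSE)
  }
  n_families <- as.integer(n_families)
  if (n_families < 1 || n_families > N) stop("invalid 'n_families'", call. = FALSE)
  set.seed(as.integer(seed))
  p <- stats::runif(m, freq_range[1], freq_range[2])
  family <- rep(seq_len(n_families), length.out = N)
  family <- sort(family)
  geno <- matrix(0L, N, m)
  if (n_families == 1L) {
    geno <- matrix(stats::rbinom(N * m, 2L, rep(p, each = N)), N, m)
  } else {
    for (f in seq_len(n_families)) {
      members <- which(family == f)
      # two parents, two haplotypes each
      hap <- matrix(stats::rbinom(4L * m, 1L, rep(p, each = 4L)), 4L, m, byrow = FALSE)
      # hap rows: parent1 {1,2}, parent2 {3,4}
      for (i in members) {
        pick1 <- stats::rbinom(m, 1L, 0.5)     # which haplotype parent 1 transmits
        pick2 <- stats::rbinom(m, 1L, 0.5)
        g1 <- ifelse(pick1 == 1L, hap[1, ], hap[2, ])
        g2 <- ifelse(pick2 == 1L, hap[3, ], hap[4, ])
        geno[i, ] <- g1 + g2
      }
    }
  }
  freq <- colMeans(geno) / 2
  keep <- freq > 0 & freq < 1
  if (!any(keep)) stop("all simulated markers are monomorphic", call. = FALSE)
  structure(
    list(
      genotypes = geno[, keep, drop = FALSE],
      allele_freqs = freq[keep],
      family = family
    ),
    class = "marker_matrix"
  )
}

#' Genomic relationship matrix from marker dosages (VanRaden method 1)
#'
#' `G = W W' / (2 sum_j p_j (1 - p_j))` with `W` the dosage matrix centered
#' by twice the observed allele frequencies. The result is then blended with
#' the identity, `G <- (1 - eps) G + eps I`, to guarantee the nonsingularity
#' the design machinery assumes; marker-derived GRMs are otherwise often
#' rank-deficient (rank bounded by min(N, m)).
#'
#' @param markers a `"marker_matrix"` from [simulate_markers()].
#' @param blend_epsilon identity blending weight in (0, 1]; default `0.01`.
#' @return a validated [grm()] object.
#' @export
vanraden_grm <- function(markers, blend_epsilon = 0.01) {
  stopifnot(inherits(markers, "marker_matrix"))
  geno <- markers$genotypes
  p <- markers$allele_freqs
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers are monomorphic; GRM undefined", call. = FALSE)
  W <- sweep(geno, 2, 2 * p)
  G <- tcrossprod(W) / denom
  grm(G, ids = paste0("ind", seq_len(nrow(geno))), blend = blend_epsilon)
}

#' Named synthetic fixtures
#'
#' Frozen study populations used throughout the tests and benchmarks, each a
#' pure function of its name and the seed. All come with `lambda = 1` and an
#' intercept-only fixed-effects matrix:
#' \describe{
#'   \item{`tiny6`}{N = 6, 80 markers, unstructured; small enough for
#'     hand-checkable oracles and full enumeration at any n.}
#'   \item{`small12`}{N = 12, 300 markers, 3 families; `choose(12, 4) = 495`
#'     designs, the scale where exhaustive search is the oracle.}
#'   \item{`medium50`}{N = 50, 1000 markers, 5 families.}
#'   \item{`wheatlike200`}{N = 200, 4670 markers, 20 families; the scale of
#'     a typical wheat training-population problem.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed.
#' @param lambda variance ratio, default 1.
#' @return list with elements `grm` (a [grm()]) and `spec` (a
#'   [model_spec()]).
#' @export
make_fixture <- function(name = c("tiny6", "small12", "medium50", "wheatlike200"),
                         seed = 1L, lambda = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny6 = list(N = 6L, m = 80L, fam = 1L),
    small12 = list(N = 12L, m = 300L, fam = 3L),
    medium50 = list(N = 50L, m = 1000L, fam = 5L),
    wheatlike200 = list(N = 200L, m = 4670L, fam = 20L)
  )
  mk <- simulate_markers(cfg$N, cfg$m, n_families = cfg$fam, seed = seed)
  g <- vanraden_grm(mk, blend_epsilon = 0.01)
  list(grm = g, spec = model_spec(cfg$N, lambda = lambda), name = name, seed = seed)
}
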