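#' Exact conditional Hardy-Weinberg test
#'
#' Conditional on the observed allele counts, the probability of a
#' genotype table under Hardy-Weinberg equilibrium is
#' `P(T) = N! 2^h prod(m_i!) / ((2N)! prod(n_ij!))` with `h` the number of
#' heterozygotes. The p-value is the total probability of tables no more
#' probable than the observed one. Small tables are fully enumerated
#' (recursive allocation over the genotype count matrix with margin
#' pruning); when the enumeration exceeds `max_tables` states the test
#' falls back to a seeded Monte-Carlo shuffle of the `2N` allele copies.
#'
#' @param a1,a2 Allele identity vectors (one element per individual).
#' @param method `"auto"`, `"enumeration"` or `"permutation"`.
#' @param n_perm Monte-Carlo shuffles (default 1e5).
#' @param seed Optional integer seed for the Monte-Carlo path.
#' @param max_tables Enumeration budget before falling back.
#' @return A list with `p_value`, `method`, `n_tables` (enumeration) or
#'   `n_perm`.
#' @export
#' @examples
#' a1 <- rep(c("10", "10", "11"), c(25, 50, 25))
#' a2 <- rep(c("10", "11", "11"), c(25, 50, 25))
#' hwe_test(a1, a2, seed = 1)$p_value  # ideal HWE proportions, p near 1
hwe_test <- function(a1, a2, method = c("auto", "enumeration", "permutation"),
                     n_perm = 1e5, seed = NULL, max_tables = 1e6) {
  method <- match.arg(method)
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- as.character(a1)[keep]
  a2 <- as.character(a2)[keep]
  if (!length(a1)) {
    stopf("no complete genotypes", class = "forenseqr_input_error")
  }
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k == 1) {
    message("monomorphic locus: p = 1 by definition")
    return(list(p_value = 1, method = "monomorphic", n_tables = 1L))
  }
  i1 <- match(a1, alleles)
  i2 <- match(a2, alleles)
  N <- length(i1)
  m <- tabulate(c(i1, i2), nbins = k)
  obs <- genotype_count_matrix(i1, i2, k)
  log_obs <- hwe_log_prob(obs, N, m)
  if (method != "permutation") {
    enum <- hwe_enumerate(m, k, N, log_obs, max_tables)
    if (!is.null(enum)) {
      return(list(p_value = enum$p, method = "enumeration",
                  n_tables = enum$n_tables))
    }
    if (method == "enumeration") {
      stopf("enumeration exceeds max_tables = %g", max_tables)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  pool <- c(i1, i2)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    x <- sample(pool)
    tab <- genotype_count_matrix(x[seq_len(N)], x[N + seq_len(N)], k)
    if (hwe_log_prob(tab, N, m) <= log_obs + 1e-9) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (n_perm + 1), method = "permutation",
       n_perm = n_perm)
}

genotype_count_matrix <- function(i1, i2, k) {
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  tabulate((lo - 1L) * k + hi, nbins = k * k)
}

hwe_log_prob <- function(tab_flat, N, m) {
  h <- 0L
  s <- 0
  k <- length(m)
  for (i in seq_len(k)) {
    for (j in i:k) {
      n_ij <- tab_flat[(i - 1L) * k + j]
      if (n_ij > 0) {
        s <- s + lfactorial(n_ij)
        if (i != j) h <- h + n_ij
      }
    }
  }
  lfactorial(N) + h * log(2) + sum(lfactorial(m)) - lfactorial(2 * N) - s
}

# full enumeration of genotype tables with fixed allele-count margins;
# returns NULL when the budget is exceeded
hwe_enumerate <- function(m, k, N, log_obs, max_tables) {
  pairs <- NULL
  for (i in seq_len(k)) for (j in i:k) pairs <- rbind(pairs, c(i, j))
  # cheap state-space upper bound: one forced pair per allele block, the
  # rest contribute at most min(m_i, m_j) + 1 choices each
  ub <- 1
  for (pi in seq_len(nrow(pairs))) {
    i <- pairs[pi, 1]; j <- pairs[pi, 2]
    last_for_i <- pi == nrow(pairs) || pairs[pi + 1, 1] > i
    if (!last_for_i) {
      ub <- ub * (min(m[i], m[j]) + 1)
      if (ub > max_tables) return(NULL)
    }
  }
  np <- nrow(pairs)
  tab <- integer(k * k)
  n_tables <- 0L
  p_sum <- 0
  overflow <- FALSE

  rec <- function(pi, rem) {
    if (overflow) return()
    if (pi > np) {
      if (all(rem == 0)) {
        n_tables <<- n_tables + 1L
        if (n_tables > max_tables) {
          overflow <<- TRUE
          return()
        }
        lp <- hwe_log_prob(tab, N, m)
        if (lp <= log_obs + 1e-9) p_sum <<- p_sum + exp(lp)
      }
      return()
    }
    i <- pairs[pi, 1]; j <- pairs[pi, 2]
    last_for_i <- pi == np || pairs[pi + 1, 1] > i
    idx <- (i - 1L) * k + j
    if (last_for_i) {
      # the count is forced by allele i's remaining margin
      n_forced <- if (i == j) rem[i] %/% 2L else rem[i]
      ok <- if (i == j) rem[i] %% 2L == 0L else rem[j] >= n_forced
      if (ok) {
        rem2 <- rem
        rem2[i] <- rem2[i] - if (i == j) 2L * n_forced else n_forced
        if (i != j) rem2[j] <- rem2[j] - n_forced
        tab[idx] <<- n_forced
        rec(pi + 1L, rem2)
        tab[idx] <<- 0L
      }
      return()
    }
    n_max <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (n_ij in 0:n_max) {
      rem2 <- rem
      rem2[i] <- rem2[i] - if (i == j) 2L * n_ij else n_ij
      if (i != j) rem2[j] <- rem2[j] - n_ij
      tab[idx] <<- n_ij
      rec(pi + 1L, rem2)
      tab[idx] <<- 0L
      if (overflow) break
    }
  }
  rec(1L, m)
  if (overflow) return(NULL)
  list(p = min(1, p_sum), n_tables = n_tables)
}

#' Permutation test of genotypic linkage disequilibrium
#'
#' Composite genotypic association between two loci: the test statistic is
#' the chi-square distance between the observed genotype-by-genotype
#' contingency table and its independence expectation, and the null
#' distribution is generated by permuting one locus's genotypes across
#' individuals (which preserves both single-locus genotype distributions).
#'
#' @param g1_a1,g1_a2 Allele vectors at the first locus.
#' @param g2_a1,g2_a2 Allele vectors at the second locus.
#' @param n_perm Number of permutations (default 1e5).
#' @param seed Optional integer seed.
#' @return A list with `p_value`, `statistic` and `n_perm`.
#' @export
ld_test <- function(g1_a1, g1_a2, g2_a1, g2_a2, n_perm = 1e5, seed = NULL) {
  keep <- !is.na(g1_a1) & !is.na(g1_a2) & !is.na(g2_a1) & !is.na(g2_a2)
  gt <- function(x, y) {
    paste(pmin(as.character(x), as.character(y)),
          pmax(as.character(x), as.character(y)), sep = "/")
  }
  g1 <- factor(gt(g1_a1[keep], g1_a2[keep]))
  g2 <- factor(gt(g2_a1[keep], g2_a2[keep]))
  n <- length(g1)
  if (n < 2) {
    stopf("linkage test needs at least two individuals",
          class = "forenseqr_input_error")
  }
  chi2 <- function(f1, f2) {
    tab <- table(f1, f2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e, na.rm = TRUE)
  }
  t_obs <- chi2(g1, g2)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (chi2(g1, sample(g2)) >= t_obs - 1e-12) hits <- hits + 1L
  }
  list(p_value = (1 + hits) / (n_perm + 1), statistic = t_obs,
       n_perm = n_perm)
}

#' Pairwise comparison bookkeeping
#'
#' `pair_count(L)` is the number of unordered locus pairs `L(L-1)/2`
#' (325 for 26 loci, 4,371 for 94, 7,140 for 120);
#' `bonferroni(alpha, k)` the corrected per-test level `alpha/k`.
#'
#' @param L Number of loci.
#' @export
pair_count <- function(L) {
  L <- as.integer(L)
  L * (L - 1L) / 2
}

#' @rdname pair_count
#' @param alpha Family-wise error rate.
#' @param k Number of comparisons.
#' @export
bonferroni <- function(alpha, k) alpha / k
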