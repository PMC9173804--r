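#' Pairwise Weir-Cockerham F_ST between populations
#'
#' The Weir & Cockerham (1984) theta estimator from biallelic genotype
#' counts, aggregated across sites as a ratio of sums (sum of per-site `a`
#' variance components over the sum of `a + b + c`). Sites monomorphic
#' across the pair and sites with fewer than two genotyped individuals in a
#' population are skipped. Per-site components may be negative, so estimates
#' near zero can dip slightly below it.
#'
#' @param G integer matrix, individuals x sites, minor-allele dosage
#'   `{0, 1, 2}` with `NA` for missing.
#' @param pops character vector of population labels per individual (row).
#' @return data frame with `pop_a`, `pop_b`, `fst`, `n_sites`.
#' @export
pairwise_fst <- function(G, pops) {
  stopifnot(nrow(G) == length(pops))
  labels <- sort(unique(pops))
  combos <- utils::combn(labels, 2, simplify = FALSE)
  rows <- lapply(combos, function(pr) {
    res <- wc_fst_two(G[pops == pr[1], , drop = FALSE],
                      G[pops == pr[2], , drop = FALSE])
    data.frame(pop_a = pr[1], pop_b = pr[2], fst = res$fst,
               n_sites = res$n_sites, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Weir-Cockerham theta for two populations, vectorized over sites.
wc_fst_two <- function(G1, G2) {
  if (nrow(G1) < 2 || nrow(G2) < 2) stop("need >= 2 individuals per population")
  stat <- function(G) {
    n <- colSums(!is.na(G))                    # genotyped individuals
    p <- colSums(G, na.rm = TRUE) / (2 * n)    # allele frequency
    h <- colSums(G == 1, na.rm = TRUE) / n     # observed het frequency
    list(n = n, p = p, h = h)
  }
  s1 <- stat(G1); s2 <- stat(G2)
  r <- 2
  keep <- s1$n >= 2 & s2$n >= 2 & !((s1$p == 0 & s2$p == 0) | (s1$p == 1 & s2$p == 1))
  if (!any(keep)) return(list(fst = NA_real_, n_sites = 0L))
  n1 <- s1$n[keep]; n2 <- s2$n[keep]
  p1 <- s1$p[keep]; p2 <- s2$p[keep]
  h1 <- s1$h[keep]; h2 <- s2$h[keep]
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- sum(a + b + cc)
  list(fst = if (denom != 0) sum(a) / denom else NA_real_,
       n_sites = sum(keep))
}

#' Rarefied private allelic richness for population pairs
#'
#' Hypergeometric rarefaction to a standardized sample of `g` gene copies:
#' an allele with `N_ij` copies out of `N_i` sampled copies in population `i`
#' appears in a random subsample of size `g` with probability
#' `Q_ij(g) = 1 - C(N_i - N_ij, g) / C(N_i, g)`. For a pair (A, B), an
#' allele that is entirely absent from every other population contributes
#' `Q_Aj(g) * Q_Bj(g)`; contributions are summed over the two alleles of
#' every variable site and divided by the number of variable sites. Missing
#' genotypes are excluded from `N_i`.
#'
#' @param G integer dosage matrix (individuals x sites, `{0, 1, 2}`, `NA`
#'   missing).
#' @param pops population labels per individual.
#' @param g rarefaction depth in gene copies; must not exceed the smallest
#'   per-population genotyped copy count at any variable site.
#' @return data frame with `pop_a`, `pop_b`, `private_richness` (per
#'   variable site).
#' @export
private_allelic_richness <- function(G, pops, g) {
  stopifnot(nrow(G) == length(pops), g >= 1)
  labels <- sort(unique(pops))
  npop <- length(labels)
  # per population and site: copies sampled N_i and alt-allele copies N_ij
  Ncop <- sapply(labels, function(l) colSums(!is.na(G[pops == l, , drop = FALSE])) * 2)
  Nalt <- sapply(labels, function(l) colSums(G[pops == l, , drop = FALSE], na.rm = TRUE))
  tot_alt <- rowSums(Nalt); tot_cop <- rowSums(Ncop)
  variable <- tot_alt > 0 & tot_alt < tot_cop
  if (!any(variable)) stop("no variable sites")
  if (any(Ncop[variable, ] < g)) {
    stop("g exceeds available gene copies in some population at a variable site")
  }
  Qpres <- function(Ni, Nij) {
    # P(allele appears in a subsample of g of the Ni copies)
    1 - exp(lchoose(Ni - Nij, g) - lchoose(Ni, g))
  }
  combos <- utils::combn(labels, 2, simplify = FALSE)
  vs <- which(variable)
  rows <- lapply(combos, function(pr) {
    ia <- match(pr[1], labels); ib <- match(pr[2], labels)
    others <- setdiff(seq_len(npop), c(ia, ib))
    total <- 0
    for (allele in c("alt", "ref")) {
      cnt <- if (allele == "alt") Nalt else Ncop - Nalt
      private <- if (length(others)) {
        rowSums(cnt[vs, others, drop = FALSE]) == 0
      } else rep(TRUE, length(vs))
      qa <- Qpres(Ncop[vs, ia], cnt[vs, ia])
      qb <- Qpres(Ncop[vs, ib], cnt[vs, ib])
      total <- total + sum((qa * qb)[private])
    }
    data.frame(pop_a = pr[1], pop_b = pr[2],
               private_richness = total / length(vs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
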