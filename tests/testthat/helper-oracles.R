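# Independent oracles used to cross-check the implementation. These are
# deliberately naive (enumeration, direct summation) and never call the
# package's own code paths.

# exhaustive enumeration of same-gene het pairs with opposite parental
# origin for a single trio; genotypes are named dosage vectors over variants
brute_force_comphet_pairs <- function(pro, fat, mot, gene_of) {
  hets <- names(pro)[pro == 1L]
  out <- list()
  if (length(hets) < 2) return(out)
  cmb <- utils::combn(hets, 2, simplify = FALSE)
  for (pair in cmb) {
    v1 <- pair[1]; v2 <- pair[2]
    if (gene_of[[v1]] != gene_of[[v2]]) next
    origin <- function(v) {
      f <- isTRUE(fat[v] > 0); m <- isTRUE(mot[v] > 0)
      if (f && !m) "father" else if (m && !f) "mother" else NA_character_
    }
    o1 <- origin(v1); o2 <- origin(v2)
    if (is.na(o1) || is.na(o2) || o1 == o2) next
    out[[length(out) + 1L]] <- sort(c(v1, v2))
  }
  unique(out)
}

# two-sided Fisher p by direct hypergeometric summation over all tables
# with the observed margins
fisher_two_sided_hypergeom <- function(k1, n1, k2, n2) {
  m <- k1 + k2               # total carriers
  x <- 0:min(m, n1)
  probs <- dhyper(x, n1, n2, m)
  p_obs <- dhyper(k1, n1, n2, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive O(n^3) average-linkage clustering; returns sorted merge heights
upgma_reference_heights <- function(mat) {
  n <- nrow(mat)
  d <- as.matrix(stats::dist(mat))
  active <- as.list(seq_len(n))
  dd <- d
  heights <- numeric(0)
  while (length(active) > 1) {
    k <- length(active)
    best <- c(Inf, 0, 0)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (dd[i, j] < best[1]) best <- c(dd[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    ci <- active[[i]]; cj <- active[[j]]
    merged <- c(ci, cj)
    rest <- setdiff(seq_len(k), c(i, j))
    newdd <- matrix(0, k - 1, k - 1)
    newactive <- c(active[rest], list(merged))
    if (length(rest) > 0) {
      newdd[seq_along(rest), seq_along(rest)] <- dd[rest, rest, drop = FALSE]
      for (r in seq_along(rest)) {
        cr <- active[[rest[r]]]
        newdd[r, k - 1] <- newdd[k - 1, r] <-
          mean(d[cr, merged, drop = FALSE])
      }
    }
    dd <- newdd
    active <- newactive
  }
  sort(heights)
}

# two-sample KS statistic and asymptotic p, written from the definition
ks_reference <- function(x, y) {
  n <- length(x); m <- length(y)
  all_v <- sort(unique(c(x, y)))
  Fx <- vapply(all_v, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(all_v, function(t) mean(y <= t), numeric(1))
  D <- max(abs(Fx - Fy))
  ne <- n * m / (n + m)
  lambda <- sqrt(ne) * D
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * lambda^2 * k^2))
  list(statistic = D, p_value = max(min(p, 1), 0))
}

# Benjamini-Hochberg step-up from the definition
bh_reference <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# small random trio fixture: returns genotype/variant/pedigree tibbles plus
# the per-trio dosage vectors used by the brute-force oracle
random_trio_cohort <- function(n_trios, n_genes = 4, n_var_per_gene = 3,
                               seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  variants <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(n_genes * n_var_per_gene)),
    chrom = "1",
    pos = seq_len(n_genes * n_var_per_gene) * 100L,
    gene = rep(genes, each = n_var_per_gene),
    consequence = sample(c("stopgain", "missense", "synonymous",
                           "nonframeshift_indel"),
                         n_genes * n_var_per_gene, replace = TRUE),
    metasvm = sample(c("D", "T"), n_genes * n_var_per_gene, replace = TRUE),
    cadd = runif(n_genes * n_var_per_gene, 0, 40),
    af_panel1 = runif(n_genes * n_var_per_gene, 0, 8e-4),
    af_panel2 = runif(n_genes * n_var_per_gene, 0, 8e-4),
    segdup = FALSE
  )
  nv <- nrow(variants)
  geno <- list(); ped <- list(); raw <- list()
  for (t in seq_len(n_trios)) {
    pro <- sprintf("T%03d_P", t); fat <- sprintf("T%03d_F", t)
    mot <- sprintf("T%03d_M", t)
    df <- setNames(rbinom(nv, 1, 0.25), variants$variant_id)
    dm <- setNames(rbinom(nv, 1, 0.25), variants$variant_id)
    # child inherits each parental allele with prob 1/2, plus some noise hets
    dp <- setNames(as.integer(rbinom(nv, 1, 0.5) * df +
                                rbinom(nv, 1, 0.5) * dm), variants$variant_id)
    dp <- pmin(dp, 2L)
    raw[[t]] <- list(pro = dp, fat = df, mot = dm,
                     ids = c(pro = pro, fat = fat, mot = mot))
    for (s in list(c(pro, "p"), c(fat, "f"), c(mot, "m"))) {
      d <- switch(s[2], p = dp, f = df, m = dm)
      nz <- which(d > 0)
      if (length(nz) > 0) {
        geno[[length(geno) + 1L]] <- tibble::tibble(
          sample = s[1], variant_id = variants$variant_id[nz],
          dosage = as.integer(d[nz]), gq = 99L, dp = 50L, mq = 60,
          alt_reads = 25L)
      }
    }
    ped[[t]] <- tibble::tibble(
      fam = sprintf("T%03d", t),
      sample = c(pro, fat, mot), father = c(fat, "0", "0"),
      mother = c(mot, "0", "0"), sex = c(1L, 1L, 2L),
      phenotype = c(2L, 1L, 1L))
  }
  list(genotypes = dplyr::bind_rows(geno), pedigree = dplyr::bind_rows(ped),
       variants = recburden::classify_variants(variants), raw = raw)
}
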