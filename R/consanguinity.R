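#' Estimate inbreeding coefficients from runs of homozygosity
#'
#' Detects runs of homozygosity (ROH) per sample with a sliding window of
#' consecutive genotypes: every window of `window_markers` markers
#' containing at most `max_het` heterozygous calls is flagged, flagged
#' windows are merged, and merged runs shorter than `min_mb` megabases are
#' discarded. F is the total ROH length divided by the covered autosome
#' length (sum of per-chromosome marker spans). This windowed ROH estimator
#' stands in for haplotype-based HBD phasing while preserving the contract
#' that F approximates the autozygous genome fraction.
#'
#' @param markers an `rb_marker_set` from [simulate_marker_genotypes()], or
#'   a list with `genotypes` (samples x markers integer matrix of dosages
#'   0/1/2) and `map` (tibble `chrom`, `pos` aligned with matrix columns).
#' @param min_markers minimum number of polymorphic markers required
#'   (default 1000).
#' @param window_markers sliding-window width in markers (default 50).
#' @param min_mb minimum ROH length in Mb (default 1.5).
#' @param max_het maximum heterozygous calls tolerated per window
#'   (default 2).
#' @return tibble of class `rb_consanguinity` (sample, f, n_segments) with
#'   the per-segment table in `attr(, "segments")`.
#' @export
estimate_f <- function(markers, min_markers = 1000, window_markers = 50,
                       min_mb = 1.5, max_het = 2) {
  g <- markers$genotypes
  map <- as_tibble(markers$map)
  stopifnot(is.matrix(g), nrow(map) == ncol(g))
  if (ncol(g) < min_markers) {
    abort(sprintf("need at least %d polymorphic markers, got %d",
                  min_markers, ncol(g)))
  }
  ord <- order(map$chrom, map$pos)
  map <- map[ord, ]
  g <- g[, ord, drop = FALSE]
  chroms <- split(seq_len(nrow(map)), map$chrom)
  covered_len <- sum(vapply(chroms, function(ix) {
    diff(range(map$pos[ix]))
  }, numeric(1)))
  samples <- rownames(g) %||% sprintf("S%05d", seq_len(nrow(g)))

  seg_list <- list()
  f <- numeric(nrow(g))
  nseg <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    segs_i <- list()
    for (ci in seq_along(chroms)) {
      ix <- chroms[[ci]]
      segs <- roh_segments_one(g[i, ix] == 1L, map$pos[ix],
                               window_markers, min_mb, max_het)
      if (!is.null(segs)) {
        segs$chrom <- names(chroms)[ci]
        segs_i[[length(segs_i) + 1L]] <- segs
      }
    }
    if (length(segs_i) > 0) {
      segs_i <- bind_rows(segs_i)
      segs_i$sample <- samples[i]
      seg_list[[length(seg_list) + 1L]] <- segs_i
      f[i] <- sum(segs_i$end - segs_i$start) / covered_len
      nseg[i] <- nrow(segs_i)
    }
  }
  segments <- if (length(seg_list) > 0) {
    bind_rows(seg_list) |>
      select("sample", "chrom", "start", "end", "n_markers")
  } else {
    tibble(sample = character(), chrom = character(),
           start = numeric(), end = numeric(), n_markers = integer())
  }
  out <- tibble(sample = samples, f = pmin(f, 1), n_segments = nseg)
  attr(out, "segments") <- segments
  class(out) <- c("rb_consanguinity", class(out))
  out
}

# windows of `w` consecutive markers with <= max_het het calls; merged,
# filtered by physical length
roh_segments_one <- function(is_het, pos, w, min_mb, max_het) {
  n <- length(is_het)
  if (n < w) return(NULL)
  cs <- c(0L, cumsum(is_het))
  ok <- (cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]) <= max_het
  if (!any(ok)) return(NULL)
  # cover: marker j is in a run if any flagged window contains it
  delta <- integer(n + 1L)
  s <- which(ok)
  delta[s] <- delta[s] + 1L
  delta[pmin(s + w, n + 1L)] <- delta[pmin(s + w, n + 1L)] - 1L
  cov <- cumsum(delta)[1:n] > 0L
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0) return(NULL)
  out <- tibble(
    start = pos[starts[runs]], end = pos[ends[runs]],
    n_markers = r$lengths[runs]
  )
  out <- out[(out$end - out$start) / 1e6 >= min_mb, ]
  if (nrow(out) == 0) NULL else out
}

#' Classify consanguinity and assign F strata
#'
#' A proband is consanguineous when F >= `threshold` (default 0.0009, close
#' to the expected F of offspring of a fourth-cousin union). Strata default
#' to the bins >= 0.03, [0.0078, 0.03), [0.002, 0.0078), [0.0009, 0.002)
#' and < 0.0009.
#'
#' @param f_table tibble with `sample` and `f` (e.g. from [estimate_f()]),
#'   or a bare numeric vector of F values.
#' @param threshold consanguinity cutoff on F.
#' @param bins increasing interior bin edges for the strata.
#' @return the input with `consanguineous` (logical) and `stratum` (ordered
#'   factor, lowest first) columns added.
#' @examples
#' classify_consanguinity(c(0.0625, 0.00089, 0.0009))
#' @export
classify_consanguinity <- function(f_table, threshold = 0.0009,
                                   bins = c(0.0009, 0.002, 0.0078, 0.03)) {
  vec_in <- !is.data.frame(f_table)
  f <- if (vec_in) f_table else f_table$f
  stopifnot(all(f >= 0 & f <= 1, na.rm = TRUE), !is.unsorted(bins))
  edges <- c(-Inf, bins, Inf)
  labs <- c(sprintf("<%g", bins[1]),
            sprintf("[%g,%g)", bins[-length(bins)], bins[-1]),
            sprintf(">=%g", bins[length(bins)]))
  stratum <- cut(f, breaks = edges, labels = labs, right = FALSE,
                 ordered_result = TRUE)
  consanguineous <- f >= threshold
  if (vec_in) {
    tibble(f = f, consanguineous = consanguineous, stratum = stratum)
  } else {
    mutate(f_table, consanguineous = consanguineous, stratum = stratum)
  }
}

#' Compare case and control F distributions
#'
#' Standard two-sided two-sample Kolmogorov-Smirnov test; F values are tied
#' at zero for most outbred samples so the asymptotic p-value is used.
#'
#' @param f_cases,f_controls numeric vectors of inbreeding coefficients.
#' @return tibble with `statistic`, `p_value`, `n_cases`, `n_controls`,
#'   `mean_cases`, `mean_controls`.
#' @export
compare_f_distributions <- function(f_cases, f_controls) {
  stopifnot(length(f_cases) > 0, length(f_controls) > 0)
  kt <- suppressWarnings(ks.test(f_cases, f_controls, exact = FALSE))
  tibble(
    statistic = unname(kt$statistic), p_value = kt$p.value,
    n_cases = length(f_cases), n_controls = length(f_controls),
    mean_cases = mean(f_cases), mean_controls = mean(f_controls)
  )
}

#' Fisher test on carrier counts in two cohort strata
#'
#' Builds the 2x2 table (carriers vs non-carriers in stratum 1 vs stratum
#' 2), computes the carrier-rate fold ratio and Fisher's exact p (two-sided
#' by default, with the one-sided "greater" p also reported).
#'
#' @param k1,n1 carriers and total in stratum 1 (e.g. consanguineous).
#' @param k2,n2 carriers and total in stratum 2.
#' @return tibble with fold, p_two_sided, p_one_sided and the table counts.
#' @examples
#' fisher_fold_test(32, 675, 34, 4749)
#' @export
fisher_fold_test <- function(k1, n1, k2, n2) {
  stopifnot(k1 <= n1, k2 <= n2)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  two <- fisher.test(tab, alternative = "two.sided")$p.value
  one <- fisher.test(tab, alternative = "greater")$p.value
  rate1 <- k1 / n1
  rate2 <- k2 / n2
  tibble(
    k1 = k1, n1 = n1, k2 = k2, n2 = n2,
    rate1 = rate1, rate2 = rate2,
    fold = if (rate2 > 0) rate1 / rate2 else NA_real_,
    p_two_sided = two, p_one_sided = one
  )
}

#' Known-gene RG enrichment by consanguinity stratum
#'
#' Counts probands with at least one RG in `gene_set`, split into
#' consanguineous versus nonconsanguineous probands, and tests the 2x2
#' table with Fisher's exact test.
#'
#' @param rg RG tibble.
#' @param consang tibble with `sample` and `consanguineous` columns covering
#'   every proband in the cohort (see [classify_consanguinity()]).
#' @param gene_set character vector of gene symbols.
#' @return tibble as in [fisher_fold_test()], with carrier counts split by
#'   consanguinity.
#' @export
consanguinity_gene_set_table <- function(rg, consang, gene_set) {
  stopifnot(all(c("sample", "consanguineous") %in% names(consang)))
  if (!all(unique(rg$sample) %in% consang$sample)) {
    abort("every RG sample needs a consanguinity classification")
  }
  hit_samples <- unique(rg$sample[rg$gene %in% gene_set])
  cons <- consang$consanguineous
  hits <- consang$sample %in% hit_samples
  fisher_fold_test(sum(hits & cons), sum(cons),
                   sum(hits & !cons), sum(!cons))
}
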