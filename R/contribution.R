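#' Attributable fraction from parental depletion
#'
#' The parental observed/expected ratio calibrates the expected biallelic
#' count: parents of affected children are depleted of damaging recessive
#' genotypes that cause severe disease, and the proband excess over the
#' parent-calibrated expectation, per proband, is the fraction of probands
#' whose disease is attributable to the variant class:
#' \deqn{(O_{pro} - E_{pro} \cdot O_{par}/E_{par}) / n_{probands}.}
#' The fraction can be negative under sampling noise and is reported as-is.
#'
#' @param exp_parents,obs_parents expected and observed RG counts in the
#'   parents.
#' @param exp_probands,obs_probands expected and observed RG counts in the
#'   probands.
#' @param n_probands number of probands.
#' @return the attributable fraction (proportion, not percent). Vectorized.
#' @examples
#' attributable_fraction(1418.0, 1181, 659.1, 630, 3716)   # ~0.022
#' attributable_fraction(156.5, 95, 69.9, 61, 3716)        # ~0.005
#' @export
attributable_fraction <- function(exp_parents, obs_parents, exp_probands,
                                  obs_probands, n_probands) {
  if (any(exp_parents <= 0) || any(exp_probands <= 0)) {
    abort("expected counts must be positive")
  }
  (obs_probands - exp_probands * obs_parents / exp_parents) / n_probands
}

# ---- internal machinery -----------------------------------------------------

contribution_class_filter <- function(variants, class) {
  class <- match.arg(class, c("damaging", "LoF", "synonymous"))
  keep <- switch(class,
                 damaging = variants$class %in% DAMAGING_CLASSES,
                 LoF = variants$class == "LoF",
                 synonymous = variants$class == "synonymous")
  variants[keep & is_rare(variants), ]
}

# drop (fam, variant) combinations where any trio member's carrier genotype
# fails QC, then drop failing rows themselves
qc_filter_trio <- function(genotypes, variants, pedigree) {
  pass <- passes_genotype_qc(genotypes, variants)
  fam_of <- setNames(pedigree$fam, pedigree$sample)
  g <- mutate(genotypes, fam = unname(fam_of[.data$sample]))
  bad <- distinct(g[!pass, ], .data$fam, .data$variant_id)
  anti_join(g, bad, by = c("fam", "variant_id")) |> select(-"fam")
}

# parental in-cohort allele frequencies with carrier co-occurrence pruning:
# of any same-gene variant pair co-occurring in more than `prune_threshold`
# of the rarer member's carriers, the rarer member is dropped
in_cohort_q <- function(genotypes, variants, parent_ids,
                        prune_threshold = 0.5) {
  par_geno <- genotypes |>
    filter(.data$sample %in% parent_ids) |>
    inner_join(select(variants, "variant_id", "gene"), by = "variant_id")
  n_par <- length(parent_ids)
  if (nrow(par_geno) == 0) {
    return(list(q_gene = tibble(gene = character(), q = numeric()),
                dropped = character()))
  }
  carriers <- distinct(par_geno, .data$sample, .data$variant_id, .data$gene)
  n_carr <- count(carriers, .data$variant_id, name = "n_carriers")
  pairs <- inner_join(carriers, carriers, by = c("sample", "gene"),
                      relationship = "many-to-many", suffix = c("1", "2")) |>
    filter(.data$variant_id1 < .data$variant_id2) |>
    count(.data$variant_id1, .data$variant_id2, name = "n_both")
  dropped <- character()
  if (nrow(pairs) > 0) {
    pairs <- pairs |>
      left_join(n_carr, by = c(variant_id1 = "variant_id")) |>
      rename(n1 = "n_carriers") |>
      left_join(n_carr, by = c(variant_id2 = "variant_id")) |>
      rename(n2 = "n_carriers") |>
      filter(.data$n_both / pmin(.data$n1, .data$n2) > prune_threshold)
    dropped <- unique(ifelse(pairs$n1 <= pairs$n2,
                             pairs$variant_id1, pairs$variant_id2))
  }
  q_gene <- par_geno |>
    filter(!.data$variant_id %in% dropped) |>
    count(.data$gene, wt = .data$dosage, name = "ac") |>
    mutate(q = .data$ac / (2 * n_par)) |>
    select("gene", "q")
  list(q_gene = q_gene, dropped = dropped)
}

#' Expected biallelic RG counts per individual
#'
#' Under random mating a biallelic damaging genotype in gene g needs two
#' independent damaging alleles (probability Q_g^2, with Q_g the gene's
#' damaging allele-frequency sum); with inbreeding coefficient F a single
#' allele drawn homozygous by descent suffices, so the per-individual,
#' per-gene expectation is (1 - F) Q_g^2 + F Q_g, summed over genes.
#'
#' @param q_gene tibble `gene`, `q` of in-cohort allele-frequency sums.
#' @param f numeric vector of inbreeding coefficients (one per individual).
#' @return numeric vector of expected biallelic genotype counts.
#' @export
expected_rg_counts <- function(q_gene, f) {
  if (any(is.na(f))) abort("missing inbreeding coefficient")
  s1 <- sum(q_gene$q)
  s2 <- sum(q_gene$q^2)
  (1 - f) * s2 + f * s1
}

# observed biallelic events: per individual per gene, a homozygous genotype
# or qualifying variants on both haplotypes (counted once per gene). When
# phase is unavailable any >= 2 distinct carried variants count, which
# includes cis pairs and overestimates relative to the trans-pair model.
observed_biallelic <- function(genotypes, variants) {
  g <- genotypes |>
    inner_join(select(variants, "variant_id", "gene"), by = "variant_id")
  if (nrow(g) == 0) {
    return(tibble(sample = character(), gene = character()))
  }
  if ("hap" %in% names(g) && !all(is.na(g$hap))) {
    h1 <- g$dosage >= 2L | (!is.na(g$hap) & g$hap == 1L)
    h2 <- g$dosage >= 2L | (!is.na(g$hap) & g$hap == 2L)
    c1 <- count(g[h1, ], .data$sample, .data$gene, name = "n1")
    c2 <- count(g[h2, ], .data$sample, .data$gene, name = "n2")
    inner_join(c1, c2, by = c("sample", "gene")) |>
      select("sample", "gene")
  } else {
    g |>
      count(.data$sample, .data$gene, wt = .data$dosage, name = "n_alleles") |>
      filter(.data$n_alleles >= 2L) |>
      select("sample", "gene")
  }
}

#' Estimate the recessive contribution to disease in a trio cohort
#'
#' Runs the full parental-depletion estimator on complete trios:
#' genotype-QC filtering (all three members must pass at a site), parental
#' in-cohort allele frequencies with carrier co-occurrence pruning,
#' expected counts per individual from (1-F) Q^2 + F Q, symmetric observed
#' biallelic counting in parents and probands, the attributable fraction,
#' and a nonparametric percentile bootstrap over trios.
#'
#' @param cohort an `rb_cohort` (or list with `genotypes`, `variants`,
#'   `pedigree`).
#' @param f_probands tibble `sample`, `f` for probands (e.g. from
#'   [estimate_f()] or the simulation truth). Parents are assumed outbred
#'   unless listed too.
#' @param class variant class: "damaging", "LoF" or "synonymous".
#' @param B bootstrap replicates (>= 100; 0 skips the CI).
#' @param seed integer seed for the bootstrap.
#' @param trios optional character vector of proband ids restricting the
#'   estimate to a subcohort (frequencies and expectations are recomputed
#'   within it).
#' @param prune_threshold carrier co-occurrence pruning threshold.
#' @param apply_qc apply the six-way genotype filter (default TRUE).
#' @return object of class `rb_contribution`: list with `estimate` (one-row
#'   tibble shaped like a contribution-table row), `per_trio` statistics,
#'   and the bootstrap draws.
#' @export
estimate_contribution <- function(cohort, f_probands, class = "damaging",
                                  B = 1000, seed = 1L, trios = NULL,
                                  prune_threshold = 0.5, apply_qc = TRUE) {
  class <- match.arg(class, c("damaging", "LoF", "synonymous"))
  if (B != 0 && B < 100) abort("`B` must be 0 or at least 100")
  ped <- as_tibble(cohort$pedigree)
  trio_ped <- filter(ped, .data$father != "0", .data$mother != "0")
  if (!is.null(trios)) trio_ped <- filter(trio_ped, .data$sample %in% trios)
  if (nrow(trio_ped) == 0) abort("no complete trios to analyse")

  variants <- cohort$variants
  if (!"class" %in% names(variants)) variants <- classify_variants(variants)
  vclass <- contribution_class_filter(variants, class)

  members <- c(trio_ped$sample, trio_ped$father, trio_ped$mother)
  geno <- filter(cohort$genotypes, .data$sample %in% members)
  if (apply_qc) {
    geno <- qc_filter_trio(geno, variants, ped)
  }
  geno <- semi_join(geno, vclass, by = "variant_id")

  parent_ids <- c(trio_ped$father, trio_ped$mother)
  qres <- in_cohort_q(geno, vclass, parent_ids, prune_threshold)

  f_map <- setNames(f_probands$f, f_probands$sample)
  f_pro <- unname(f_map[trio_ped$sample])
  if (any(is.na(f_pro))) abort("missing inbreeding coefficient for some probands")
  f_par <- dplyr::coalesce(unname(f_map[parent_ids]), 0)

  exp_pro <- expected_rg_counts(qres$q_gene, f_pro)
  exp_par_each <- expected_rg_counts(qres$q_gene, f_par)
  exp_par <- exp_par_each[seq_len(nrow(trio_ped))] +
    exp_par_each[nrow(trio_ped) + seq_len(nrow(trio_ped))]

  events <- observed_biallelic(geno, vclass)
  n_events <- count(events, .data$sample, name = "k")
  k_map <- setNames(n_events$k, n_events$sample)
  obs_of <- function(ids) dplyr::coalesce(unname(k_map[ids]), 0L)
  obs_pro <- obs_of(trio_ped$sample)
  obs_par <- obs_of(trio_ped$father) + obs_of(trio_ped$mother)

  per_trio <- tibble(
    proband = trio_ped$sample,
    obs_parents = obs_par, exp_parents = exp_par,
    obs_probands = obs_pro, exp_probands = exp_pro
  )
  n_trios <- nrow(per_trio)
  frac <- attributable_fraction(sum(exp_par), sum(obs_par),
                                sum(exp_pro), sum(obs_pro), n_trios)

  boot <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  if (B > 0) {
    set.seed(derive_seed(seed, 8L))
    M <- cbind(per_trio$exp_parents, per_trio$obs_parents,
               per_trio$exp_probands, per_trio$obs_probands)
    boot <- vapply(seq_len(B), function(b) {
      s <- colSums(M[sample.int(n_trios, n_trios, replace = TRUE), , drop = FALSE])
      if (s[1] <= 0 || s[3] <= 0) return(NA_real_)
      (s[4] - s[3] * s[2] / s[1]) / n_trios
    }, numeric(1))
    ci <- unname(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }

  estimate <- tibble(
    class = class,
    exp_parents = sum(exp_par), obs_parents = sum(obs_par),
    ratio_parents = sum(obs_par) / sum(exp_par),
    exp_probands = sum(exp_pro), obs_probands = sum(obs_pro),
    ratio_probands = sum(obs_pro) / sum(exp_pro),
    n_probands = n_trios,
    fraction = frac, ci_low = ci[1], ci_high = ci[2]
  )
  structure(list(estimate = estimate, per_trio = per_trio, boot = boot,
                 q_gene = qres$q_gene, dropped_variants = qres$dropped,
                 class = class, B = B),
            class = "rb_contribution")
}

#' @export
print.rb_contribution <- function(x, ...) {
  e <- x$estimate
  cat(sprintf("Recessive contribution (%s): %.2f%%", e$class, 100 * e$fraction))
  if (!is.na(e$ci_low)) {
    cat(sprintf("  [%.2f%%, %.2f%%]", 100 * e$ci_low, 100 * e$ci_high))
  }
  cat(sprintf("\n  parents: %d obs / %.1f exp   probands: %d obs / %.1f exp   trios: %d\n",
              e$obs_parents, e$exp_parents, e$obs_probands, e$exp_probands,
              e$n_probands))
  invisible(x)
}

#' Contribution estimates for several variant classes
#'
#' Convenience wrapper producing the synonymous / LoF / damaging
#' contribution table in one call.
#'
#' @inheritParams estimate_contribution
#' @param classes variant classes to estimate.
#' @return tibble of class `rb_contribution_table` with one row per class.
#' @export
contribution_table <- function(cohort, f_probands,
                               classes = c("synonymous", "LoF", "damaging"),
                               B = 1000, seed = 1L, ...) {
  rows <- purrr::map(classes, function(cl) {
    estimate_contribution(cohort, f_probands, class = cl, B = B,
                          seed = seed, ...)$estimate
  })
  out <- bind_rows(rows)
  class(out) <- c("rb_contribution_table", class(out))
  out
}

#' Stratified contribution estimates
#'
#' One parental-depletion estimate per cohort stratum (consanguinity bin,
#' phenotype class, ancestry label, ...). By default in-cohort frequencies
#' and expectations are recomputed within each stratum, mirroring the
#' within-subphenotype frequency convention; `shared_frequencies = TRUE`
#' reuses the whole-cohort per-trio statistics, in which case the
#' whole-cohort estimate is the trio-weighted combination of the strata.
#'
#' @inheritParams estimate_contribution
#' @param strata tibble `sample`, `stratum` covering trio probands.
#' @param shared_frequencies reuse whole-cohort frequencies (default FALSE).
#' @param min_trios strata below this size are estimated but flagged with a
#'   warning column (default 10).
#' @return tibble with one row per stratum (columns as in
#'   [contribution_table()] plus `stratum` and `small_stratum`).
#' @export
stratified_contribution <- function(cohort, f_probands, strata,
                                    class = "damaging", B = 1000, seed = 1L,
                                    shared_frequencies = FALSE,
                                    min_trios = 10, ...) {
  strata <- as_tibble(strata)
  stopifnot(all(c("sample", "stratum") %in% names(strata)))
  shared <- NULL
  if (shared_frequencies) {
    shared <- estimate_contribution(cohort, f_probands, class = class,
                                    B = 0, seed = seed, ...)
  }
  groups <- split(strata$sample, strata$stratum)
  rows <- purrr::imap(groups, function(ids, label) {
    if (shared_frequencies) {
      pt <- filter(shared$per_trio, .data$proband %in% ids)
      n <- nrow(pt)
      if (n == 0) return(NULL)
      est <- tibble(
        class = class,
        exp_parents = sum(pt$exp_parents), obs_parents = sum(pt$obs_parents),
        ratio_parents = sum(pt$obs_parents) / sum(pt$exp_parents),
        exp_probands = sum(pt$exp_probands), obs_probands = sum(pt$obs_probands),
        ratio_probands = sum(pt$obs_probands) / sum(pt$exp_probands),
        n_probands = n,
        fraction = attributable_fraction(sum(pt$exp_parents), sum(pt$obs_parents),
                                         sum(pt$exp_probands), sum(pt$obs_probands),
                                         n),
        ci_low = NA_real_, ci_high = NA_real_
      )
    } else {
      fit <- estimate_contribution(cohort, f_probands, class = class, B = B,
                                   seed = seed, trios = ids, ...)
      est <- fit$estimate
    }
    est$stratum <- label
    est$small_stratum <- est$n_probands < min_trios
    if (est$small_stratum) {
      warn(sprintf("stratum '%s' has only %d trios; estimate is unstable",
                   label, est$n_probands))
    }
    est
  })
  bind_rows(rows)
}
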