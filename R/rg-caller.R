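#' Call homozygous recessive genotypes
#'
#' One RG per (sample, gene) with a rare homozygous genotype of the
#' requested class. When several qualifying homozygotes exist in one gene
#' the most damaging variant is reported (LoF > D-mis > nonframeshift
#' indel, ties by lower population AF then position).
#'
#' @param genotypes long genotype tibble (`sample`, `variant_id`, `dosage`);
#'   hom-ref rows may be absent.
#' @param variants classified variant table (see [classify_variants()]) with
#'   `variant_id`, `gene`, `class`, `af_panel1`, `af_panel2`, `pos`.
#' @param class `"damaging"` (LoF + Dmis + nonframeshift indel) or
#'   `"synonymous"` (the negative-control stream).
#' @param rare_threshold allele-frequency cutoff passed to [is_rare()].
#' @return RG tibble: sample, gene, rg_type, variant1, variant2,
#'   damaging_class, phase_evidence.
#' @export
call_homozygotes <- function(genotypes, variants, class = "damaging",
                             rare_threshold = 1e-3) {
  v <- rg_candidate_variants(variants, class, rare_threshold)
  hits <- genotypes |>
    filter(.data$dosage == 2L) |>
    inner_join(v, by = "variant_id")
  if (nrow(hits) == 0) return(empty_rg())
  hits |>
    mutate(rank = damage_rank(.data$class),
           afk = af_sort_key(.data$af_panel1, .data$af_panel2)) |>
    group_by(.data$sample, .data$gene) |>
    arrange(.data$rank, .data$afk, .data$pos, .by_group = TRUE) |>
    slice_head(n = 1L) |>
    ungroup() |>
    mutate(
      rg_type = "hom", variant1 = .data$variant_id, variant2 = NA_character_,
      damaging_class = hom_damaging_class(.data$class),
      phase_evidence = "homozygous"
    ) |>
    select("sample", "gene", "rg_type", "variant1", "variant2",
           "damaging_class", "phase_evidence")
}

hom_damaging_class <- function(class) {
  dplyr::case_when(
    class == "synonymous" ~ "synonymous",
    class == "LoF" ~ "LoF_LoF",
    TRUE ~ "contains_Dmis"
  )
}

pair_damaging_class <- function(class1, class2) {
  dplyr::case_when(
    class1 == "synonymous" & class2 == "synonymous" ~ "synonymous",
    class1 == "LoF" & class2 == "LoF" ~ "LoF_LoF",
    TRUE ~ "contains_Dmis"
  )
}

rg_candidate_variants <- function(variants, class, rare_threshold) {
  class <- match.arg(class, c("damaging", "synonymous"))
  v <- as_tibble(variants)
  if (!"class" %in% names(v)) v <- classify_variants(v)
  keep <- if (class == "damaging") v$class %in% DAMAGING_CLASSES else v$class == "synonymous"
  v <- v[keep & is_rare(v, threshold = rare_threshold), ]
  select(v, "variant_id", "gene", "class", "af_panel1", "af_panel2", "pos")
}

empty_rg <- function() {
  tibble(sample = character(), gene = character(), rg_type = character(),
         variant1 = character(), variant2 = character(),
         damaging_class = character(), phase_evidence = character())
}

#' Call trio-phased compound heterozygotes
#'
#' A proband contributes a compound-heterozygous RG in a gene when it is
#' heterozygous for two or more rare qualifying variants with at least one
#' inherited from each parent. Parental origin is assigned conservatively:
#' a variant is maternal only when the mother carries it and the father does
#' not (and vice versa); sites carried by both parents are phase-ambiguous
#' and excluded, as are apparent de novos. Cis pairs (both alleles from one
#' parent) never qualify. When more than two variants qualify, the most
#' damaging maternal and paternal alleles are reported (one RG per
#' sample-gene).
#'
#' @inheritParams call_homozygotes
#' @param pedigree tibble with `sample`, `father`, `mother` (zero/NA for
#'   founders); only complete trios are used.
#' @return RG tibble (phase_evidence = "trio").
#' @export
call_comphet_trio <- function(genotypes, variants, pedigree,
                              class = "damaging", rare_threshold = 1e-3) {
  v <- rg_candidate_variants(variants, class, rare_threshold)
  trios <- pedigree |>
    filter(.data$father != "0", .data$mother != "0",
           !is.na(.data$father), !is.na(.data$mother))
  if (nrow(trios) == 0) return(empty_rg())

  dose <- genotypes |>
    select("sample", "variant_id", "dosage") |>
    semi_join(v, by = "variant_id")
  het <- dose |>
    filter(.data$dosage == 1L) |>
    inner_join(v, by = "variant_id") |>
    inner_join(select(trios, "sample", "father", "mother"), by = "sample")
  if (nrow(het) == 0) return(empty_rg())

  dose_key <- setNames(dose$dosage, paste(dose$sample, dose$variant_id))
  lookup <- function(s, vid) {
    d <- unname(dose_key[paste(s, vid)])
    dplyr::coalesce(d, 0L)
  }
  het$father_dosage <- lookup(het$father, het$variant_id)
  het$mother_dosage <- lookup(het$mother, het$variant_id)
  het <- het |>
    mutate(origin = dplyr::case_when(
      .data$mother_dosage > 0L & .data$father_dosage == 0L ~ "mother",
      .data$father_dosage > 0L & .data$mother_dosage == 0L ~ "father",
      TRUE ~ NA_character_
    ))
  n_ambig <- sum(is.na(het$origin) & (het$father_dosage > 0L | het$mother_dosage > 0L))
  n_denovo <- sum(het$father_dosage == 0L & het$mother_dosage == 0L)
  if (n_ambig + n_denovo > 0) {
    inform(sprintf(
      "call_comphet_trio: excluded %d phase-ambiguous and %d unexplained het site(s)",
      n_ambig, n_denovo))
  }
  het <- filter(het, !is.na(.data$origin))
  if (nrow(het) == 0) return(empty_rg())

  best <- het |>
    mutate(rank = damage_rank(.data$class),
           afk = af_sort_key(.data$af_panel1, .data$af_panel2)) |>
    group_by(.data$sample, .data$gene, .data$origin) |>
    arrange(.data$rank, .data$afk, .data$pos, .by_group = TRUE) |>
    slice_head(n = 1L) |>
    ungroup()

  mat <- filter(best, .data$origin == "mother")
  pat <- filter(best, .data$origin == "father")
  hits <- inner_join(
    select(mat, "sample", "gene", m_variant = "variant_id", m_class = "class"),
    select(pat, "sample", "gene", p_variant = "variant_id", p_class = "class"),
    by = c("sample", "gene")
  )
  if (nrow(hits) == 0) return(empty_rg())
  hits |>
    mutate(
      rg_type = "comphet",
      variant1 = pmin(.data$m_variant, .data$p_variant),
      variant2 = pmax(.data$m_variant, .data$p_variant),
      damaging_class = pair_damaging_class(.data$m_class, .data$p_class),
      phase_evidence = "trio"
    ) |>
    select("sample", "gene", "rg_type", "variant1", "variant2",
           "damaging_class", "phase_evidence")
}

#' Infer compound heterozygotes in parentless probands
#'
#' Same-gene rare qualifying heterozygous pairs in singleton probands are
#' inferred to be in trans when the pair has never been observed together in
#' one individual of the reference co-occurrence panel (count 0; a pair
#' absent from the panel index is treated as count 0). When several pairs
#' qualify the most damaging pair is reported.
#'
#' @inheritParams call_homozygotes
#' @param cooccurrence an `rb_cooccurrence` panel (see
#'   [simulate_cooccurrence_panel()]) or a tibble with `variant1`,
#'   `variant2`, `count` (canonical order `variant1 < variant2`).
#' @param samples optional character vector restricting the call to these
#'   probands (e.g. singletons only).
#' @return RG tibble (rg_type = "inferred_comphet", phase_evidence =
#'   "panel_absence").
#' @export
call_comphet_singleton <- function(genotypes, variants, cooccurrence,
                                   samples = NULL, class = "damaging",
                                   rare_threshold = 1e-3) {
  v <- rg_candidate_variants(variants, class, rare_threshold)
  pairs_tbl <- if (inherits(cooccurrence, "rb_cooccurrence")) cooccurrence$pairs else as_tibble(cooccurrence)
  het <- genotypes |>
    filter(.data$dosage == 1L) |>
    inner_join(v, by = "variant_id")
  if (!is.null(samples)) het <- filter(het, .data$sample %in% samples)
  multi <- het |>
    count(.data$sample, .data$gene) |>
    filter(.data$n >= 2L)
  het <- semi_join(het, multi, by = c("sample", "gene"))
  if (nrow(het) == 0) return(empty_rg())

  cand <- inner_join(het, het, by = c("sample", "gene"),
                     relationship = "many-to-many", suffix = c("1", "2")) |>
    filter(.data$variant_id1 < .data$variant_id2)
  cand <- left_join(cand,
                    select(pairs_tbl, variant1 = "variant1",
                           variant2 = "variant2", "count"),
                    by = c(variant_id1 = "variant1", variant_id2 = "variant2")) |>
    mutate(count = replace_na(.data$count, 0L)) |>
    filter(.data$count == 0L)
  if (nrow(cand) == 0) return(empty_rg())
  cand |>
    mutate(rank = damage_rank(.data$class1) + damage_rank(.data$class2),
           afk = af_sort_key(.data$af_panel11, .data$af_panel21) +
             af_sort_key(.data$af_panel12, .data$af_panel22)) |>
    group_by(.data$sample, .data$gene) |>
    arrange(.data$rank, .data$afk, .data$pos1, .by_group = TRUE) |>
    slice_head(n = 1L) |>
    ungroup() |>
    mutate(
      rg_type = "inferred_comphet",
      variant1 = .data$variant_id1, variant2 = .data$variant_id2,
      damaging_class = pair_damaging_class(.data$class1, .data$class2),
      phase_evidence = "panel_absence"
    ) |>
    select("sample", "gene", "rg_type", "variant1", "variant2",
           "damaging_class", "phase_evidence")
}

#' Call all recessive genotypes in a cohort
#'
#' Runs the homozygote caller on every proband, the trio comphet caller on
#' complete trios, and the panel-absence comphet caller on parentless
#' probands, then enforces one RG per sample-gene with homozygotes taking
#' precedence over compound heterozygotes.
#'
#' @inheritParams call_comphet_trio
#' @param cooccurrence optional co-occurrence panel for singleton inference.
#' @param probands optional character vector of proband ids (default: all
#'   samples with phenotype 2 in the pedigree, or all samples).
#' @param apply_qc apply [passes_genotype_qc()] before calling (default
#'   FALSE: QC is reserved for the contribution stage).
#' @return RG tibble sorted by sample and gene.
#' @export
call_recessive_genotypes <- function(genotypes, variants, pedigree,
                                     cooccurrence = NULL, class = "damaging",
                                     rare_threshold = 1e-3, probands = NULL,
                                     apply_qc = FALSE) {
  if (apply_qc) {
    genotypes <- genotypes[passes_genotype_qc(genotypes, variants), ]
  }
  if (is.null(probands)) {
    probands <- if ("phenotype" %in% names(pedigree)) {
      pedigree$sample[pedigree$phenotype == 2L]
    } else {
      unique(pedigree$sample)
    }
  }
  pro_geno <- filter(genotypes, .data$sample %in% probands)
  hom <- call_homozygotes(pro_geno, variants, class, rare_threshold)
  trio_pro <- pedigree$sample[pedigree$father != "0" & pedigree$mother != "0" &
                                pedigree$sample %in% probands]
  ch <- call_comphet_trio(genotypes, variants,
                          filter(pedigree, .data$sample %in% trio_pro),
                          class, rare_threshold)
  singles <- setdiff(probands, trio_pro)
  ich <- if (!is.null(cooccurrence) && length(singles) > 0) {
    call_comphet_singleton(pro_geno, variants, cooccurrence,
                           samples = singles, class = class,
                           rare_threshold = rare_threshold)
  } else {
    empty_rg()
  }
  comphets <- bind_rows(ch, ich) |>
    anti_join(hom, by = c("sample", "gene"))
  bind_rows(hom, comphets) |>
    arrange(.data$sample, .data$gene)
}

#' Tabulate recessive genotype counts and per-individual rates
#'
#' @param rg RG tibble from the callers.
#' @param n_samples number of probands in the cohort (rate denominator).
#' @param gene_sets optional named list of gene-symbol vectors; a block of
#'   rows is emitted per set in addition to the overall block.
#' @return tibble with columns `group`, `rg_type`, `n`, `rate`
#'   (rate = n / n_samples); `rg_type` includes the margin `"total"`.
#' @examples
#' rg <- tibble::tibble(sample = "s1", gene = "G1", rg_type = "hom")
#' tabulate_rg_rates(rg, n_samples = 10)
#' @export
tabulate_rg_rates <- function(rg, n_samples, gene_sets = NULL) {
  n_samples <- assert_count(n_samples, "n_samples", min = 1L)
  one_block <- function(r, label) {
    types <- c("hom", "comphet", "inferred_comphet")
    cnt <- vapply(types, function(t) sum(r$rg_type == t), integer(1))
    tibble(group = label,
           rg_type = c(types, "total"),
           n = c(unname(cnt), nrow(r))) |>
      mutate(rate = .data$n / n_samples)
  }
  out <- one_block(rg, "all_genes")
  if (!is.null(gene_sets)) {
    for (nm in names(gene_sets)) {
      out <- bind_rows(out, one_block(filter(rg, .data$gene %in% gene_sets[[nm]]), nm))
    }
  }
  out
}
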