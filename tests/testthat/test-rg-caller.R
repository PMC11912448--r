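# minimal hand-built fixture: one gene, configurable dosages
mini_variants <- function() {
  classify_variants(tibble::tibble(
    variant_id = c("vL", "vD", "vS", "vN", "vC"),
    chrom = "1", pos = c(100L, 200L, 300L, 400L, 500L),
    gene = "GENE1",
    consequence = c("stopgain", "missense", "synonymous",
                    "nonframeshift_indel", "missense"),
    metasvm = c(NA, "D", NA, NA, "D"),
    cadd = c(NA, 35, NA, NA, 12),
    af_panel1 = c(1e-4, 2e-4, 1e-4, 3e-4, 5e-4),
    af_panel2 = c(1e-4, 2e-4, 1e-4, 3e-4, 5e-4),
    segdup = FALSE
  ))
}

geno_rows <- function(sample, variant_id, dosage) {
  tibble::tibble(sample = sample, variant_id = variant_id,
                 dosage = as.integer(dosage), gq = 99L, dp = 50L, mq = 60,
                 alt_reads = 25L)
}

mini_ped <- function() {
  tibble::tibble(fam = "T1", sample = c("p1", "f1", "m1"),
                 father = c("f1", "0", "0"), mother = c("m1", "0", "0"),
                 sex = c(1L, 1L, 2L), phenotype = c(2L, 1L, 1L))
}

test_that("homozygote calling needs a rare damaging dosage-2 genotype", {
  v <- mini_variants()
  expect_equal(nrow(call_homozygotes(geno_rows("p1", "vL", 2), v)), 1L)
  expect_equal(call_homozygotes(geno_rows("p1", "vL", 2), v)$damaging_class,
               "LoF_LoF")
  expect_equal(nrow(call_homozygotes(geno_rows("p1", "vL", 1), v)), 0L)
  # common homozygote fails the rarity filter
  v5 <- dplyr::mutate(v, af_panel1 = 5e-3, af_panel2 = 5e-3)
  expect_equal(nrow(call_homozygotes(geno_rows("p1", "vL", 2), v5)), 0L)
  # synonymous stream is separate
  expect_equal(nrow(call_homozygotes(geno_rows("p1", "vS", 2), v)), 0L)
  syn <- call_homozygotes(geno_rows("p1", "vS", 2), v, class = "synonymous")
  expect_equal(syn$damaging_class, "synonymous")
})

test_that("trio comphets need one damaging allele from each parent", {
  v <- mini_variants()
  ped <- mini_ped()
  g_trans <- dplyr::bind_rows(
    geno_rows("p1", c("vL", "vD"), 1),
    geno_rows("m1", "vL", 1), geno_rows("f1", "vD", 1))
  rg <- call_comphet_trio(g_trans, v, ped)
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$rg_type, "comphet")
  expect_equal(sort(c(rg$variant1, rg$variant2)), c("vD", "vL"))
  expect_equal(rg$damaging_class, "contains_Dmis")

  # cis: both from the mother
  g_cis <- dplyr::bind_rows(
    geno_rows("p1", c("vL", "vD"), 1),
    geno_rows("m1", c("vL", "vD"), 1))
  expect_equal(nrow(call_comphet_trio(g_cis, v, ped)), 0L)

  # damaging + synonymous is not a damaging RG
  g_syn <- dplyr::bind_rows(
    geno_rows("p1", c("vL", "vS"), 1),
    geno_rows("m1", "vL", 1), geno_rows("f1", "vS", 1))
  expect_equal(nrow(call_comphet_trio(g_syn, v, ped)), 0L)

  # phase-ambiguous site (both parents carry) is excluded
  g_amb <- dplyr::bind_rows(
    geno_rows("p1", c("vL", "vD"), 1),
    geno_rows("m1", c("vL", "vD"), 1), geno_rows("f1", "vL", 1))
  expect_equal(suppressMessages(nrow(call_comphet_trio(g_amb, v, ped))), 0L)
})

test_that("trio comphet calls equal brute-force pair enumeration", {
  fix <- random_trio_cohort(120, n_genes = 4, n_var_per_gene = 3, seed = 42)
  keep <- fix$variants$class %in% c("LoF", "Dmis", "nonframeshift_indel") &
    is_rare(fix$variants)
  gene_of <- setNames(as.list(fix$variants$gene), fix$variants$variant_id)
  rg <- suppressMessages(
    call_comphet_trio(fix$genotypes, fix$variants, fix$pedigree))
  for (t in seq_along(fix$raw)) {
    r <- fix$raw[[t]]
    sub <- names(r$pro)[keep]
    pairs <- brute_force_comphet_pairs(r$pro[sub], r$fat[sub], r$mot[sub],
                                       gene_of)
    got <- rg[rg$sample == r$ids[["pro"]], ]
    # caller reports one best pair per gene; oracle enumerates all pairs
    oracle_genes <- sort(unique(vapply(pairs, function(p) gene_of[[p[1]]],
                                       character(1))))
    expect_equal(sort(got$gene), oracle_genes)
    # and each reported pair must be in the oracle's enumeration
    if (nrow(got) > 0) {
      for (i in seq_len(nrow(got))) {
        expect_true(list(sort(c(got$variant1[i], got$variant2[i]))) %in% pairs)
      }
    }
  }
})

test_that("singleton comphets require zero panel co-occurrence", {
  v <- mini_variants()
  coc0 <- tibble::tibble(gene = character(), variant1 = character(),
                         variant2 = character(), count = integer())
  g <- geno_rows("s1", c("vL", "vD"), 1)
  rg <- call_comphet_singleton(g, v, coc0)
  expect_equal(rg$rg_type, "inferred_comphet")
  expect_equal(rg$phase_evidence, "panel_absence")

  coc1 <- tibble::tibble(gene = "GENE1", variant1 = "vD", variant2 = "vL",
                         count = 1L)
  expect_equal(nrow(call_comphet_singleton(g, v, coc1)), 0L)
  expect_equal(nrow(call_comphet_singleton(geno_rows("s1", "vL", 1), v, coc0)),
               0L)
})

test_that("one RG per sample-gene with hom precedence and damage-ranked pairs", {
  v <- mini_variants()
  ped <- mini_ped()
  # proband hom at vL and also a comphet pair in the same gene
  g <- dplyr::bind_rows(
    geno_rows("p1", "vL", 2), geno_rows("p1", c("vD", "vN"), 1),
    geno_rows("m1", c("vL", "vD"), 1), geno_rows("f1", c("vL", "vN"), 1))
  rg <- suppressMessages(
    call_recessive_genotypes(g, v, ped))
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$rg_type, "hom")

  # >2 qualifying hets: best maternal (LoF) and best paternal (Dmis) chosen
  g2 <- dplyr::bind_rows(
    geno_rows("p1", c("vL", "vD", "vN"), 1),
    geno_rows("m1", c("vL", "vN"), 1), geno_rows("f1", "vD", 1))
  rg2 <- call_comphet_trio(g2, v, ped)
  expect_equal(nrow(rg2), 1L)
  expect_setequal(c(rg2$variant1, rg2$variant2), c("vL", "vD"))
})

test_that("calling is invariant to genotype row order", {
  fix <- random_trio_cohort(40, seed = 8)
  rg1 <- suppressMessages(
    call_recessive_genotypes(fix$genotypes, fix$variants, fix$pedigree))
  shuffled <- fix$genotypes[sample(nrow(fix$genotypes)), ]
  rg2 <- suppressMessages(
    call_recessive_genotypes(shuffled, fix$variants, fix$pedigree))
  expect_equal(rg1, rg2)
})

test_that("RG rates are counts per proband and satisfy the count identity", {
  rg <- tibble::tibble(
    sample = sprintf("s%04d", 1:1253), gene = "G1",
    rg_type = rep(c("hom", "comphet"), c(500, 753)))
  tab <- tabulate_rg_rates(rg, n_samples = 5424)
  total <- tab[tab$group == "all_genes" & tab$rg_type == "total", ]
  expect_equal(total$n, 1253L)
  expect_equal(round(total$rate, 3), 0.231)
  expect_equal(tab$rate * 5424, tab$n)

  empty <- tabulate_rg_rates(rg[0, ], n_samples = 10)
  expect_true(all(empty$n == 0) && all(empty$rate == 0))

  sets <- tabulate_rg_rates(rg, 5424, gene_sets = list(known = "G2"))
  expect_equal(sets$n[sets$group == "known" & sets$rg_type == "total"], 0L)
})
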