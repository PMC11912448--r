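#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the synthetic trio/singleton cohort.
#' Defaults reproduce the shape of the study cohort: 3,716 trios and 1,708
#' singleton probands, 12.4% of probands from consanguineous unions, rare
#' damaging allele-frequency mass per gene proportional to de novo
#' mutability and calibrated so that an outbred proband carries ~0.177
#' expected damaging biallelic genotypes (and ~0.525 synonymous ones).
#'
#' @param n_trios number of parent-offspring trios.
#' @param n_singletons number of parentless probands.
#' @param n_genes number of simulated genes.
#' @param seed integer seed; identical configs give byte-identical cohorts.
#' @param f_distribution data frame with columns `f` (inbreeding coefficient)
#'   and `prop` (cohort proportion, summing to 1). Each proband draws its
#'   true F from this mixture.
#' @param causal_genes data frame with columns `gene` and `penetrance`, or
#'   NULL to auto-select `n_causal_genes` genes after the panel is built.
#' @param n_causal_genes number of causal genes auto-selected when
#'   `causal_genes` is NULL.
#' @param target_attributable_fraction fraction of probands planted with a
#'   causal recessive genotype (in [0,1)).
#' @param af_scale scaling from per-gene mutability to the damaging
#'   allele-frequency sum (Q_g = af_scale * m_g). NULL auto-calibrates so
#'   that sum(Q_g^2) equals `target_rg_rate`.
#' @param target_rg_rate expected damaging biallelic genotypes per outbred
#'   proband used for auto-calibration (default 659.1/3716).
#' @param syn_rate_ratio ratio of synonymous to damaging biallelic rates
#'   (default sqrt(1951.5/659.1) applied on the allele-frequency scale).
#' @param founder optional list(gene=, af=, age=) planting a founder allele
#'   at cohort frequency `af` in `gene`.
#' @param map_rate genetic map rate in cM per Mb (default 1).
#' @param n_chrom,chrom_length_mb synthetic genome: number of autosomes and
#'   length of each in Mb.
#' @param roh_mean_length_mb mean length of an autozygous segment; segment
#'   count is tuned so the genome-wide autozygous fraction equals F.
#' @param qc_noise fraction of emitted genotypes given failing QC fields to
#'   exercise the genotype filters (default 0 = all passing).
#' @param mutability_meanlog,mutability_sdlog log-normal parameters of the
#'   per-gene de novo mutability.
#' @param causal_phenotype optional phenotype label assigned to causal
#'   probands (default: drawn like everyone else).
#' @return a validated list of class `rb_sim_config`.
#' @export
sim_config <- function(n_trios = 3716, n_singletons = 1708, n_genes = 19347,
                       seed = 1L,
                       f_distribution = default_f_distribution(),
                       causal_genes = NULL, n_causal_genes = 25,
                       target_attributable_fraction = 0.022,
                       af_scale = NULL,
                       target_rg_rate = 659.1 / 3716,
                       syn_rate_ratio = sqrt(1951.5 / 659.1),
                       founder = NULL, map_rate = 1,
                       n_chrom = 22, chrom_length_mb = 130,
                       roh_mean_length_mb = 20, qc_noise = 0,
                       mutability_meanlog = log(1e-5),
                       mutability_sdlog = 1,
                       causal_phenotype = NULL) {
  n_trios <- assert_count(n_trios, "n_trios")
  n_singletons <- assert_count(n_singletons, "n_singletons")
  n_genes <- assert_count(n_genes, "n_genes", min = 2L)
  if (n_trios + n_singletons < 1L) abort("cohort must contain at least one proband")
  target_attributable_fraction <-
    assert_prop(target_attributable_fraction, "target_attributable_fraction",
                max_open = TRUE)
  f_distribution <- as_tibble(f_distribution)
  stopifnot(all(c("f", "prop") %in% names(f_distribution)))
  if (abs(sum(f_distribution$prop) - 1) > 1e-8) {
    abort("`f_distribution$prop` must sum to 1")
  }
  if (any(f_distribution$f < 0 | f_distribution$f > 1)) {
    abort("all F values must lie in [0,1]")
  }
  if (!is.null(af_scale) && (!is.numeric(af_scale) || af_scale < 0)) {
    abort("`af_scale` must be a nonnegative number")
  }
  if (!is.null(causal_genes)) {
    causal_genes <- as_tibble(causal_genes)
    stopifnot(all(c("gene", "penetrance") %in% names(causal_genes)))
    if (any(causal_genes$penetrance < 0 | causal_genes$penetrance > 1)) {
      abort("penetrance values must lie in [0,1]")
    }
  }
  if (!is.null(founder)) {
    stopifnot(is.list(founder), all(c("gene", "af", "age") %in% names(founder)))
  }
  qc_noise <- assert_prop(qc_noise, "qc_noise")
  structure(list(
    n_trios = n_trios, n_singletons = n_singletons, n_genes = n_genes,
    seed = as.integer(seed), f_distribution = f_distribution,
    causal_genes = causal_genes, n_causal_genes = as.integer(n_causal_genes),
    target_attributable_fraction = target_attributable_fraction,
    af_scale = af_scale, target_rg_rate = target_rg_rate,
    syn_rate_ratio = syn_rate_ratio, founder = founder, map_rate = map_rate,
    n_chrom = as.integer(n_chrom), chrom_length_mb = chrom_length_mb,
    roh_mean_length_mb = roh_mean_length_mb, qc_noise = qc_noise,
    mutability_meanlog = mutability_meanlog,
    mutability_sdlog = mutability_sdlog,
    causal_phenotype = causal_phenotype
  ), class = "rb_sim_config")
}

#' Default inbreeding-coefficient mixture
#'
#' Places 12.4% of probands at F >= 0.0009 (the study's consanguineous
#' share) spread over four strata up to the first-cousin value 1/16; the
#' remainder are outbred. The study reports only the consanguineous share,
#' so the within-share split is a modeling choice.
#' @return tibble with columns `f` and `prop`.
#' @export
default_f_distribution <- function() {
  tibble(
    f = c(0, 0.0015, 0.004, 0.015, 0.0625),
    prop = c(0.876, 0.045, 0.040, 0.025, 0.014)
  )
}

#' Simulate a gene panel with mutability and a rare variant pool
#'
#' Draws per-gene de novo mutability from a log-normal, sets each gene's
#' damaging allele-frequency sum proportional to mutability
#' (Q_g = af_scale * m_g), and splits that mass over enough variants that
#' every simulated rare allele frequency stays below 1e-3. Each gene's pool
#' contains LoF, damaging missense, nonframeshift indel, synonymous and
#' benign missense variants with reference-panel frequencies consistent
#' with the true simulated frequencies.
#'
#' @param config an [sim_config()] object.
#' @return list of class `rb_gene_panel` with elements `variants` (one row
#'   per alternate allele, classified), `mutability` (gene, mutability),
#'   `genes` (per-gene truth: position, Q sums), and `af_scale` actually
#'   used.
#' @export
simulate_gene_panel <- function(config) {
  stopifnot(inherits(config, "rb_sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  ng <- config$n_genes
  genes <- sprintf("G%05d", seq_len(ng))
  m <- rlnorm(ng, config$mutability_meanlog, config$mutability_sdlog)

  af_scale <- config$af_scale %||% sqrt(config$target_rg_rate / sum(m^2))
  q_dam <- af_scale * m
  q_syn <- q_dam * config$syn_rate_ratio
  q_ben <- q_dam * 0.3

  # place genes round-robin on the synthetic genome
  chrom <- rep_len(seq_len(config$n_chrom), ng)
  chrom_bp <- config$chrom_length_mb * 1e6
  within <- stats::ave(seq_len(ng), chrom, FUN = seq_along)
  per_chrom <- tabulate(chrom, nbins = config$n_chrom)
  gene_pos <- floor(within / (per_chrom[chrom] + 1) * chrom_bp)

  split_pool <- function(q, k_min, class_fun) {
    # number of alleles per gene so each AF stays < 1e-3 (max share <= 3/k)
    k <- pmax(k_min, ceiling(3000 * q))
    idx <- rep(seq_along(q), k)
    w <- runif(sum(k), 0.5, 1.5)
    af <- q[idx] * w / stats::ave(w, idx, FUN = sum)
    ord <- stats::ave(seq_along(idx), idx, FUN = seq_along)
    tibble(gene_i = idx, allele_i = ord, af_true = af,
           class_slot = class_fun(ord, k[idx]))
  }

  dam <- split_pool(q_dam, 4L, function(ord, k) {
    # guarantee one of each damaging kind, rest drawn by weight
    base <- c("LoF", "Dmis", "nonframeshift_indel")
    out <- base[pmin(ord, 3L)]
    extra <- ord > 3L
    out[extra] <- sample(base, sum(extra), replace = TRUE,
                         prob = c(0.40, 0.45, 0.15))
    out
  })
  syn <- split_pool(q_syn, 2L, function(ord, k) rep("synonymous", length(ord)))
  ben <- split_pool(q_ben, 2L, function(ord, k) rep("benign_missense", length(ord)))

  pool <- bind_rows(dam, syn, ben)
  # unique per-gene position slots across the three pools
  pool$slot <- stats::ave(seq_len(nrow(pool)), pool$gene_i, FUN = seq_along)
  n_v <- nrow(pool)
  cons <- dplyr::case_when(
    pool$class_slot == "LoF" ~ sample(LOF_CONSEQUENCES, n_v, replace = TRUE,
                                      prob = c(0.4, 0.05, 0.35, 0.2)),
    pool$class_slot %in% c("Dmis", "benign_missense") ~ "missense",
    pool$class_slot == "nonframeshift_indel" ~ "nonframeshift_indel",
    TRUE ~ "synonymous"
  )
  # D-mis via MetaSVM for half, via CADD alone for the rest
  dmis_by_cadd <- pool$class_slot == "Dmis" & runif(n_v) < 0.5
  metasvm <- dplyr::case_when(
    pool$class_slot == "Dmis" & !dmis_by_cadd ~ "D",
    pool$class_slot %in% c("Dmis", "benign_missense") ~ "T",
    TRUE ~ NA_character_
  )
  cadd <- rep(NA_real_, n_v)
  cadd[dmis_by_cadd] <- runif(sum(dmis_by_cadd), 30, 50)
  cadd[pool$class_slot == "Dmis" & !dmis_by_cadd] <- runif(sum(pool$class_slot == "Dmis" & !dmis_by_cadd), 10, 40)
  cadd[pool$class_slot == "benign_missense"] <- runif(sum(pool$class_slot == "benign_missense"), 0, 25)

  pos <- gene_pos[pool$gene_i] + 10L * pool$slot
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_v, replace = TRUE)
  alt_off <- sample(1:3, n_v, replace = TRUE)
  alt <- bases[((match(ref, bases) - 1L + alt_off) %% 4L) + 1L]

  # reference-panel AFs track the true frequency; ~5% missing per panel
  af_p1 <- pool$af_true * runif(n_v, 0.4, 1.0)
  af_p2 <- pool$af_true * runif(n_v, 0.4, 1.0)
  af_p1[runif(n_v) < 0.05] <- NA_real_
  af_p2[runif(n_v) < 0.05] <- NA_real_

  variants <- tibble(
    chrom = chrom[pool$gene_i], pos = pos, ref = ref, alt = alt,
    gene = genes[pool$gene_i], consequence = cons, metasvm = metasvm,
    cadd = cadd, af_panel1 = af_p1, af_panel2 = af_p2, segdup = FALSE,
    af_true = pool$af_true
  )

  if (!is.null(config$founder)) {
    fg <- config$founder$gene
    if (!fg %in% genes) abort(sprintf("founder gene '%s' not in panel", fg))
    gi <- match(fg, genes)
    variants <- bind_rows(variants, tibble(
      chrom = chrom[gi], pos = gene_pos[gi] + 5L, ref = "A", alt = "T",
      gene = fg, consequence = "missense", metasvm = "D", cadd = 28,
      af_panel1 = 9e-4, af_panel2 = 8e-4, segdup = FALSE,
      af_true = config$founder$af
    ))
  }

  variants <- variants |>
    mutate(variant_id = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":")) |>
    classify_variants()

  gene_truth <- variants |>
    filter(.data$af_true < 1e-3) |>
    group_by(.data$gene) |>
    summarise(
      q_damaging = sum(.data$af_true[.data$class %in% DAMAGING_CLASSES]),
      q_synonymous = sum(.data$af_true[.data$class == "synonymous"]),
      .groups = "drop"
    ) |>
    left_join(tibble(gene = genes, mutability = m, chrom = chrom,
                     gene_pos = gene_pos), by = "gene") |>
    arrange(.data$gene)

  structure(list(
    variants = variants,
    mutability = tibble(gene = genes, mutability = m),
    genes = gene_truth,
    af_scale = af_scale,
    config = config
  ), class = "rb_gene_panel")
}

# integer key stride for (parent, gene) transmission draws
ng_total <- function(gene_i_of_v) max(gene_i_of_v) + 1

# concatenated genome coordinate helpers -------------------------------------

genome_offsets <- function(config) {
  (seq_len(config$n_chrom) - 1) * config$chrom_length_mb * 1e6
}

# draw autozygous segments for each sample; returns tibble in concatenated
# genome coordinates with one row per segment
draw_roh_segments <- function(f, config) {
  genome_bp <- config$n_chrom * config$chrom_length_mb * 1e6
  mean_len <- config$roh_mean_length_mb * 1e6
  n_seg <- rpois(length(f), f * genome_bp / mean_len)
  idx <- rep(seq_along(f), n_seg)
  if (length(idx) == 0) {
    return(tibble(sample_i = integer(), start = numeric(), end = numeric()))
  }
  start <- runif(length(idx), 0, genome_bp)
  len <- rexp(length(idx), 1 / mean_len)
  tibble(sample_i = idx, start = start, end = pmin(start + len, genome_bp))
}

#' Simulate a trio/singleton cohort from a gene panel
#'
#' Parental haplotypes are drawn from the panel's true allele frequencies;
#' each proband inherits one haplotype per parent per gene (so two variants
#' on the same parental haplotype co-transmit, giving genuine cis pairs).
#' Probands draw a true inbreeding coefficient from the configured mixture;
#' autozygous segments with mean length `roh_mean_length_mb` cover fraction
#' F of the genome, and genes inside a segment become homozygous by descent
#' (with both parents set to carry the shared allele). A fraction
#' `target_attributable_fraction` of probands is planted with a causal
#' damaging recessive genotype (homozygous or compound heterozygous) in a
#' causal gene. Per-genotype QC fields default to passing values; `qc_noise`
#' injects failures.
#'
#' Singleton probands (no parents) are generated from the same allele
#' frequencies and F mixture.
#'
#' @param config an [sim_config()] object.
#' @param panel result of [simulate_gene_panel()] for the same config.
#' @return list of class `rb_cohort` with `genotypes` (sparse long tibble:
#'   sample, variant_id, dosage, gq, dp, mq, alt_reads), `pedigree` (6-column
#'   convention plus a `role` column), `samples`, `truth` (per-proband causal
#'   flag, causal gene, true F), `gene_truth`, `variants`, `mutability`.
#' @export
simulate_trios <- function(config, panel) {
  stopifnot(inherits(config, "rb_sim_config"), inherits(panel, "rb_gene_panel"))
  set.seed(derive_seed(config$seed, 2L))
  nt <- config$n_trios
  ns <- config$n_singletons
  npro <- nt + ns

  variants <- panel$variants
  genes_tbl <- panel$genes
  gene_ids <- genes_tbl$gene

  causal_genes <- config$causal_genes
  if (is.null(causal_genes) && config$target_attributable_fraction > 0) {
    # causal disease genes are ordinary genes, not the most polymorphic ones:
    # pick the genes closest to the median damaging allele-frequency mass
    med <- stats::median(genes_tbl$q_damaging)
    pick <- genes_tbl |>
      arrange(abs(.data$q_damaging - med)) |>
      slice_head(n = min(config$n_causal_genes, nrow(genes_tbl)))
    causal_genes <- tibble(gene = pick$gene, penetrance = 1)
  }
  if (!is.null(causal_genes) && !all(causal_genes$gene %in% gene_ids)) {
    abort("causal genes absent from the simulated panel")
  }

  # ---- sample sheet ---------------------------------------------------------
  trio_fam <- sprintf("F%05d", seq_len(nt))
  pro_t <- paste0(trio_fam, "_P")
  fat <- paste0(trio_fam, "_F")
  mot <- paste0(trio_fam, "_M")
  pro_s <- if (ns > 0) sprintf("S%05d_P", seq_len(ns)) else character()
  probands <- c(pro_t, pro_s)

  fmix <- config$f_distribution
  f_true <- sample(fmix$f, npro, replace = TRUE, prob = fmix$prop)

  phenos <- c("laterality", "left_sided", "right_sided", "conotruncal", "other")
  phenotype <- sample(phenos, npro, replace = TRUE,
                      prob = c(0.15, 0.25, 0.10, 0.20, 0.30))

  causal <- rep(FALSE, npro)
  causal_gene <- rep(NA_character_, npro)
  if (!is.null(causal_genes) && config$target_attributable_fraction > 0) {
    causal <- runif(npro) < config$target_attributable_fraction
    causal_gene[causal] <- sample(causal_genes$gene, sum(causal), replace = TRUE,
                                  prob = causal_genes$penetrance)
    if (!is.null(config$causal_phenotype)) {
      phenotype[causal] <- config$causal_phenotype
    }
  }

  pedigree <- bind_rows(
    tibble(fam = trio_fam, sample = pro_t, father = fat, mother = mot,
           sex = sample(1:2, nt, replace = TRUE), phenotype = 2L, role = "proband"),
    tibble(fam = trio_fam, sample = fat, father = "0", mother = "0",
           sex = 1L, phenotype = 1L, role = "father"),
    tibble(fam = trio_fam, sample = mot, father = "0", mother = "0",
           sex = 2L, phenotype = 1L, role = "mother"),
    if (ns > 0) tibble(fam = sprintf("S%05d", seq_len(ns)), sample = pro_s,
                       father = "0", mother = "0",
                       sex = sample(1:2, ns, replace = TRUE), phenotype = 2L,
                       role = "proband")
  )

  samples <- tibble(
    sample = probands, role = "proband",
    f_true = f_true, phenotype_class = phenotype,
    is_trio = c(rep(TRUE, nt), rep(FALSE, ns))
  )

  # ---- parental / singleton haplotype carriers -----------------------------
  # chromosome index space: trios contribute 4 parental chromosomes each
  # (father 1,2; mother 3,4); singletons contribute 2 own chromosomes.
  n_par_chrom <- 4 * nt
  n_sing_chrom <- 2 * ns
  n_chrom_tot <- n_par_chrom + n_sing_chrom

  af <- variants$af_true
  n_carr <- rbinom(length(af), n_chrom_tot, af)
  vidx <- rep(seq_along(af), n_carr)
  chrom_idx <- sample.int(n_chrom_tot, length(vidx), replace = TRUE)
  keep <- !duplicated(paste(vidx, chrom_idx))
  vidx <- vidx[keep]; chrom_idx <- chrom_idx[keep]

  carrier <- tibble(v = vidx, chrom_idx = chrom_idx)
  carrier$gene <- variants$gene[carrier$v]
  is_par <- carrier$chrom_idx <= n_par_chrom

  par <- carrier[is_par, ]
  par$trio <- ((par$chrom_idx - 1L) %/% 4L) + 1L
  slot <- ((par$chrom_idx - 1L) %% 4L) + 1L    # 1,2 father; 3,4 mother
  par$from_father <- slot <= 2L
  par$parent <- ifelse(par$from_father, fat[par$trio], mot[par$trio])
  par$hap <- ifelse(slot %% 2L == 1L, 1L, 2L)

  sing <- carrier[!is_par, ]
  if (nrow(sing) > 0) {
    si <- ((sing$chrom_idx - n_par_chrom - 1L) %/% 2L) + 1L
    sing$sample <- pro_s[si]
    sing$hap <- ((sing$chrom_idx - n_par_chrom - 1L) %% 2L) + 1L
  }

  # ---- transmission: one haplotype per (parent, gene) ----------------------
  gene_i_of_v <- match(variants$gene, gene_ids)
  par$gene_i <- gene_i_of_v[par$v]
  par$parent_i <- (par$trio - 1L) * 2L + ifelse(slot <= 2L, 1L, 2L)
  key <- (as.numeric(par$parent_i) - 1) * ng_total(gene_i_of_v) + par$gene_i
  ukey <- unique(key)
  transmitted_hap <- sample(1:2, length(ukey), replace = TRUE)
  par$transmitted <- transmitted_hap[match(key, ukey)] == par$hap
  par$child <- pro_t[par$trio]

  # aggregate carrier rows to genotypes; haplotype 1/2 for hets, 0 for homs
  # (phase is emitted because cohort genotypes are phased upstream of this
  # pipeline; the contribution stage consumes it)
  aggregate_alleles <- function(sample, v, hap) {
    al <- distinct(tibble(sample = as.character(sample), v = as.integer(v),
                          hap = as.integer(hap)))
    cnt <- count(al, .data$sample, .data$v, name = "dosage")
    first <- distinct(al, .data$sample, .data$v, .keep_all = TRUE)
    out <- left_join(cnt, first, by = c("sample", "v"))
    out$hap[out$dosage >= 2L] <- 0L
    out$dosage <- pmin(out$dosage, 2L)
    out
  }

  trans <- par[par$transmitted, ]
  pro_alleles <- aggregate_alleles(trans$child, trans$v,
                                   ifelse(trans$from_father, 1L, 2L))
  par_geno <- aggregate_alleles(par$parent, par$v, par$hap)
  sing_geno <- if (nrow(sing) > 0) {
    aggregate_alleles(sing$sample, sing$v, sing$hap)
  } else {
    tibble(sample = character(), v = integer(), dosage = integer(),
           hap = integer())
  }

  # ---- autozygosity ---------------------------------------------------------
  segs <- draw_roh_segments(f_true, config)
  offsets <- genome_offsets(config)
  gene_cat <- offsets[genes_tbl$chrom] + genes_tbl$gene_pos
  ord <- order(gene_cat)
  gene_cat_s <- gene_cat[ord]
  auto_pairs <- NULL
  if (nrow(segs) > 0) {
    lo <- findInterval(segs$start, gene_cat_s) + 1L
    hi <- findInterval(segs$end, gene_cat_s)
    keep_seg <- hi >= lo
    if (any(keep_seg)) {
      lo <- lo[keep_seg]; hi <- hi[keep_seg]
      samp_i <- segs$sample_i[keep_seg]
      reps <- hi - lo + 1L
      gi <- ord[unlist(Map(seq.int, lo, hi))]
      auto_pairs <- distinct(tibble(sample = probands[rep(samp_i, reps)],
                                    gene = gene_ids[gi]))
    }
  }

  planted_auto <- NULL
  if (!is.null(auto_pairs) && nrow(auto_pairs) > 0) {
    # drop transmitted alleles in autozygous (sample, gene); replace by an
    # IBD draw: homozygous for allele v with probability af_true(v)
    vg <- tibble(v = seq_along(af), gene = variants$gene, af = af)
    cand <- inner_join(auto_pairs, vg, by = "gene", relationship = "many-to-many")
    hit <- runif(nrow(cand)) < cand$af
    planted_auto <- cand[hit, c("sample", "gene", "v")]
    # one allele per autozygous gene copy: keep first hit per (sample, gene)
    planted_auto <- planted_auto[!duplicated(paste(planted_auto$sample, planted_auto$gene)), ]

    pro_alleles <- anti_join(
      mutate(pro_alleles, gene = variants$gene[.data$v]),
      auto_pairs, by = c("sample", "gene")
    ) |> select(-"gene")
    if (nrow(sing_geno) > 0) {
      sing_geno <- anti_join(
        mutate(sing_geno, gene = variants$gene[.data$v]),
        auto_pairs, by = c("sample", "gene")
      ) |> select(-"gene")
    }
  }

  # ---- assemble proband genotypes ------------------------------------------
  pro_geno <- bind_rows(pro_alleles, sing_geno)
  extra_parent <- NULL
  if (!is.null(planted_auto) && nrow(planted_auto) > 0) {
    pro_geno <- bind_rows(pro_geno,
                          tibble(sample = planted_auto$sample,
                                 v = planted_auto$v, dosage = 2L, hap = 0L))
    # parents of autozygous trio probands must carry the shared allele
    trio_auto <- planted_auto[planted_auto$sample %in% pro_t, ]
    if (nrow(trio_auto) > 0) {
      ti <- match(trio_auto$sample, pro_t)
      extra_parent <- tibble(
        sample = c(fat[ti], mot[ti]),
        v = rep(trio_auto$v, 2L), dosage = 1L,
        hap = sample(1:2, 2L * nrow(trio_auto), replace = TRUE)
      )
    }
  }

  # ---- causal planting ------------------------------------------------------
  dam_v <- which(variants$class %in% DAMAGING_CLASSES & variants$af_true < 1e-3)
  dam_by_gene <- split(dam_v, variants$gene[dam_v])
  planted_rows <- list()
  parent_rows <- list()
  truth_type <- rep(NA_character_, npro)
  for (i in which(causal)) {
    g <- causal_gene[i]
    vs <- dam_by_gene[[g]]
    if (is.null(vs) || length(vs) == 0) next
    s <- probands[i]
    is_trio_i <- i <= nt
    w <- af[vs] / sum(af[vs])
    as_hom <- length(vs) < 2 || runif(1) < 0.5
    if (as_hom) {
      v1 <- if (length(vs) == 1) vs else sample(vs, 1, prob = w)
      truth_type[i] <- "hom"
      planted_rows[[length(planted_rows) + 1L]] <-
        tibble(sample = s, v = v1, dosage = 2L, hap = 0L)
      if (is_trio_i) {
        parent_rows[[length(parent_rows) + 1L]] <-
          tibble(sample = c(fat[i], mot[i]), v = v1, dosage = 1L,
                 hap = sample(1:2, 2L, replace = TRUE))
      }
    } else {
      v12 <- sample(vs, 2, prob = w)
      truth_type[i] <- "comphet"
      planted_rows[[length(planted_rows) + 1L]] <-
        tibble(sample = s, v = v12, dosage = 1L, hap = c(1L, 2L))
      if (is_trio_i) {
        parent_rows[[length(parent_rows) + 1L]] <-
          tibble(sample = c(fat[i], mot[i]), v = v12, dosage = 1L,
                 hap = sample(1:2, 2L, replace = TRUE))
      }
    }
  }
  if (length(planted_rows) > 0) {
    planted <- bind_rows(planted_rows)
    # planted genotype replaces whatever the gene carried before
    pro_geno <- bind_rows(
      anti_join(mutate(pro_geno, gene = variants$gene[.data$v]),
                distinct(mutate(planted, gene = variants$gene[.data$v]),
                         .data$sample, .data$gene),
                by = c("sample", "gene")) |> select(-"gene"),
      planted
    )
    parent_rows <- bind_rows(parent_rows)
  } else {
    parent_rows <- NULL
  }

  # merge parent genotype additions (max dosage wins)
  par_geno <- bind_rows(par_geno, extra_parent, parent_rows) |>
    arrange(dplyr::desc(.data$dosage)) |>
    distinct(.data$sample, .data$v, .keep_all = TRUE)

  geno <- bind_rows(pro_geno, par_geno) |>
    arrange(dplyr::desc(.data$dosage)) |>
    distinct(.data$sample, .data$v, .keep_all = TRUE) |>
    mutate(dosage = as.integer(.data$dosage))

  # ---- QC fields ------------------------------------------------------------
  ngeno <- nrow(geno)
  dp <- rpois(ngeno, 40) + 8L
  vaf_true <- ifelse(geno$dosage == 2L, 0.97, 0.5)
  alt_reads <- rbinom(ngeno, dp, vaf_true)
  alt_reads <- pmin(pmax(alt_reads, 1L), dp)
  gq <- sample(60:99, ngeno, replace = TRUE)
  mq <- pmin(pmax(rnorm(ngeno, 60, 1.5), 41), 70)
  if (config$qc_noise > 0) {
    bad <- runif(ngeno) < config$qc_noise
    which_field <- sample(4, sum(bad), replace = TRUE)
    bi <- which(bad)
    gq[bi[which_field == 1]] <- sample(0:19, sum(which_field == 1), replace = TRUE)
    dp[bi[which_field == 2]] <- sample(0:7, sum(which_field == 2), replace = TRUE)
    mq[bi[which_field == 3]] <- runif(sum(which_field == 3), 10, 39)
    lo <- bi[which_field == 4]
    alt_reads[lo] <- pmin(2L, dp[lo])
    alt_reads <- pmin(alt_reads, dp)
  }

  genotypes <- tibble(
    sample = geno$sample,
    variant_id = variants$variant_id[geno$v],
    dosage = geno$dosage,
    hap = geno$hap,
    gq = as.integer(gq), dp = as.integer(dp), mq = mq,
    alt_reads = as.integer(alt_reads)
  ) |> arrange(.data$sample, .data$variant_id)

  truth <- tibble(
    sample = probands, causal = causal, causal_gene = causal_gene,
    planted_type = truth_type, true_f = f_true, phenotype_class = phenotype,
    is_trio = samples$is_trio
  )

  structure(list(
    genotypes = genotypes, pedigree = pedigree, samples = samples,
    truth = truth, gene_truth = genes_tbl, variants = variants,
    mutability = panel$mutability, config = config
  ), class = "rb_cohort")
}

#' Simulate a reference co-occurrence panel
#'
#' Generates `n_individuals` reference genomes from the panel's allele
#' frequencies (two haplotypes each, so two rare variants in one gene land
#' in trans unless they hit the same haplotype) and tabulates, per gene, how
#' many individuals carry both members of each same-gene variant pair. Used
#' by the singleton compound-heterozygote caller: a pair never observed
#' together in the panel is predicted to be in trans.
#'
#' @param panel an `rb_gene_panel`.
#' @param n_individuals panel size (>= 1).
#' @param seed integer seed.
#' @return list of class `rb_cooccurrence`: `pairs` (gene, variant1,
#'   variant2, count; canonical order variant1 < variant2, only observed
#'   pairs emitted), `carriers` (individual-level genotypes, for auditing),
#'   `n_individuals`.
#' @export
simulate_cooccurrence_panel <- function(panel, n_individuals, seed = 1L) {
  stopifnot(inherits(panel, "rb_gene_panel"))
  n_individuals <- assert_count(n_individuals, "n_individuals", min = 1L)
  set.seed(derive_seed(seed, 3L))
  variants <- panel$variants
  af <- variants$af_true
  n_hap <- 2L * n_individuals
  n_carr <- rbinom(length(af), n_hap, af)
  vidx <- rep(seq_along(af), n_carr)
  hap <- sample.int(n_hap, length(vidx), replace = TRUE)
  keep <- !duplicated(paste(vidx, hap))
  carriers <- tibble(
    v = vidx[keep],
    individual = ((hap[keep] - 1L) %/% 2L) + 1L,
    hap = ((hap[keep] - 1L) %% 2L) + 1L,
    variant_id = variants$variant_id[vidx[keep]],
    gene = variants$gene[vidx[keep]]
  ) |> distinct(.data$individual, .data$variant_id, .keep_all = TRUE)

  pairs <- inner_join(
    carriers, carriers,
    by = c("individual", "gene"), relationship = "many-to-many",
    suffix = c("1", "2")
  ) |>
    filter(.data$variant_id1 < .data$variant_id2) |>
    count(.data$gene, variant1 = .data$variant_id1,
          variant2 = .data$variant_id2, name = "count")

  structure(list(pairs = pairs, carriers = carriers,
                 n_individuals = n_individuals),
            class = "rb_cooccurrence")
}

#' Simulate founder carrier haplotypes around a focal variant
#'
#' Each carrier chromosome retains the ancestral founder haplotype over a
#' segment around the focal variant whose one-sided genetic lengths are
#' independent exponentials with rate `age` (in inverse Morgans per side,
#' i.e. one expected crossover per Morgan per generation); off-segment
#' marker alleles are resampled from the population marker frequencies.
#'
#' @param age founder allele age in generations (>= 1).
#' @param n_chromosomes number of carrier chromosomes (>= 2).
#' @param marker_spacing_cm marker spacing in cM (default 0.02, i.e. one
#'   marker per 20 kb at 1 cM/Mb).
#' @param region_cm one-sided extent of the simulated region in cM.
#' @param map_rate cM per Mb used to lay markers onto physical coordinates.
#' @param seed integer seed.
#' @return list of class `rb_founder_sim`: `haplotypes` (chromosomes x
#'   markers, 0/1 alleles), `positions_cm` (signed, focal at 0),
#'   `positions_bp`, `focal_index`, `breakpoints` (true one-sided lengths in
#'   Morgans), `marker_freq`.
#' @export
simulate_founder_haplotypes <- function(age, n_chromosomes,
                                        marker_spacing_cm = 0.02,
                                        region_cm = 40, map_rate = 1,
                                        seed = 1L) {
  if (age < 1) abort("`age` must be at least 1 generation")
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes", min = 2L)
  set.seed(derive_seed(seed, 4L))
  pos_cm <- seq(-region_cm, region_cm, by = marker_spacing_cm)
  focal <- which.min(abs(pos_cm))
  nm <- length(pos_cm)
  freq <- runif(nm, 0.1, 0.9)
  ancestral <- as.integer(runif(nm) < freq)
  left <- rexp(n_chromosomes, rate = age)    # Morgans
  right <- rexp(n_chromosomes, rate = age)
  hap <- matrix(0L, n_chromosomes, nm)
  for (i in seq_len(n_chromosomes)) {
    on_seg <- pos_cm >= -100 * left[i] & pos_cm <= 100 * right[i]
    resampled <- as.integer(runif(nm) < freq)
    hap[i, ] <- ifelse(on_seg, ancestral, resampled)
  }
  # all carriers share the focal allele by construction
  hap[, focal] <- 1L
  structure(list(
    haplotypes = hap, positions_cm = pos_cm,
    positions_bp = as.integer(round((pos_cm + region_cm) / map_rate * 1e6)) + 1L,
    focal_index = focal,
    breakpoints = tibble(chromosome = seq_len(n_chromosomes),
                         left_morgans = left, right_morgans = right),
    marker_freq = freq
  ), class = "rb_founder_sim")
}

#' Simulate a gene-by-cell-type mean expression matrix
#'
#' Background genes are broadly expressed (independent gamma draws per cell
#' type). Planted lineage-specific genes get their designated cell type
#' raised to at least `fold` times every other cell type, so they satisfy a
#' downstream `fold`-change specificity rule by construction.
#'
#' @param n_genes number of background genes.
#' @param cell_types character vector of cell-type labels.
#' @param planted_specific named character vector: names are gene labels,
#'   values the cell type each is specific to. Planted genes are appended to
#'   the background.
#' @param fold specificity fold (> 1).
#' @param seed integer seed.
#' @return tibble with a `gene` column and one numeric column per cell type.
#' @export
simulate_expression_matrix <- function(n_genes = 100,
                                       cell_types = c("cardiomyocytes", "notochord",
                                                      "gut", "brain", "somite",
                                                      "blood"),
                                       planted_specific = NULL, fold = 5,
                                       seed = 1L) {
  if (fold <= 1) abort("`fold` must exceed 1")
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  set.seed(derive_seed(seed, 5L))
  k <- length(cell_types)
  bg <- matrix(rgamma2(n_genes * k), n_genes, k)
  genes <- sprintf("BG%04d", seq_len(n_genes))
  if (!is.null(planted_specific)) {
    pm <- matrix(rgamma2(length(planted_specific) * k),
                 length(planted_specific), k)
    for (i in seq_along(planted_specific)) {
      j <- match(planted_specific[[i]], cell_types)
      if (is.na(j)) abort("planted cell type not among `cell_types`")
      pm[i, j] <- fold * 1.25 * max(pm[i, -j])
    }
    bg <- rbind(bg, pm)
    genes <- c(genes, names(planted_specific))
  }
  out <- as_tibble(bg, .name_repair = "minimal")
  names(out) <- cell_types
  bind_cols(tibble(gene = genes), out)
}

rgamma2 <- function(n) stats::rgamma(n, shape = 2, scale = 5)

#' Simulate dense marker genotypes for ROH-based F estimation
#'
#' Lays `n_markers` biallelic markers uniformly over the synthetic genome
#' with allele frequencies drawn uniformly from `freq_range`; outside
#' autozygous segments genotypes follow Hardy-Weinberg proportions, inside
#' them the two alleles are identical by descent (homozygous for a single
#' population draw). Autozygous segments are drawn exactly as in
#' [simulate_trios()], so the realized autozygous genome fraction matches
#' each sample's F in expectation.
#'
#' @param f numeric vector of true inbreeding coefficients, one per sample.
#' @param config an [sim_config()] (genome geometry and segment length).
#' @param n_markers total marker count across the genome (default 10000).
#' @param freq_range range of marker allele frequencies.
#' @param seed integer seed.
#' @return list of class `rb_marker_set`: `genotypes` (samples x markers
#'   integer matrix of alt-allele dosages), `map` (chrom, pos), `f_true`,
#'   `segments` (true autozygous segments).
#' @export
simulate_marker_genotypes <- function(f, config, n_markers = 10000,
                                      freq_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(inherits(config, "rb_sim_config"), all(f >= 0 & f <= 1))
  n_markers <- assert_count(n_markers, "n_markers", min = 10L)
  set.seed(derive_seed(seed, 6L))
  ns <- length(f)
  genome_bp <- config$n_chrom * config$chrom_length_mb * 1e6
  cat_pos <- sort(runif(n_markers, 0, genome_bp))
  chrom <- pmin(floor(cat_pos / (config$chrom_length_mb * 1e6)) + 1L, config$n_chrom)
  pos <- as.integer(round(cat_pos - (chrom - 1L) * config$chrom_length_mb * 1e6)) + 1L
  p <- runif(n_markers, freq_range[1], freq_range[2])

  segs <- draw_roh_segments(f, config)
  g <- matrix(0L, ns, n_markers)
  p2 <- p^2
  het <- 2 * p * (1 - p)
  for (i in seq_len(ns)) {
    u <- runif(n_markers)
    gi <- ifelse(u < p2, 2L, ifelse(u < p2 + het, 1L, 0L))
    si <- segs[segs$sample_i == i, ]
    if (nrow(si) > 0) {
      inroh <- rep(FALSE, n_markers)
      for (k in seq_len(nrow(si))) {
        inroh <- inroh | (cat_pos >= si$start[k] & cat_pos <= si$end[k])
      }
      # IBD: one population draw, duplicated
      gi[inroh] <- ifelse(runif(sum(inroh)) < p[inroh], 2L, 0L)
    }
    g[i, ] <- gi
  }
  rownames(g) <- if (!is.null(names(f))) names(f) else sprintf("S%05d", seq_len(ns))
  structure(list(
    genotypes = g, map = tibble(chrom = chrom, pos = pos),
    f_true = setNames(f, rownames(g)),
    segments = segs
  ), class = "rb_marker_set")
}
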