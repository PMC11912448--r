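#' Write a simulated cohort to VCF, PED and annotation tables
#'
#' Emits `cohort.vcf` (VCF v4.2, `GT:AD:DP:GQ` with per-site `MQ` in INFO;
#' one column per sample, hom-ref for non-carriers), `cohort.ped` (6-column
#' pedigree), `variants.tsv` (the annotation table: variant key, gene,
#' consequence, MetaSVM, CADD, two panel AFs, segdup flag), `truth.tsv` and
#' `samples.tsv`. Intended for modest cohort sizes: the VCF is dense over
#' samples.
#'
#' @param cohort an `rb_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  variants <- arrange(cohort$variants, .data$chrom, .data$pos)
  samples <- unique(cohort$pedigree$sample)

  geno <- cohort$genotypes
  vi <- match(geno$variant_id, variants$variant_id)
  si <- match(geno$sample, samples)
  nv <- nrow(variants)
  ns <- length(samples)

  hap <- if ("hap" %in% names(geno)) geno$hap else rep(NA_integer_, nrow(geno))
  gt_str <- dplyr::case_when(
    geno$dosage == 2L ~ "1|1",
    !is.na(hap) & hap == 1L ~ "1|0",
    !is.na(hap) & hap == 2L ~ "0|1",
    TRUE ~ "0/1"
  )
  ref_reads <- geno$dp - geno$alt_reads
  cell <- sprintf("%s:%d,%d:%d:%d", gt_str, ref_reads, geno$alt_reads,
                  geno$dp, geno$gq)
  body <- matrix("0/0:.,.:.:.", nv, ns)
  body[cbind(vi, si)] <- cell

  # mean carrier MQ per site as the INFO field
  mq_site <- rep(60, nv)
  mq_agg <- tapply(geno$mq, vi, mean)
  mq_site[as.integer(names(mq_agg))] <- round(unname(mq_agg), 2)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=recburden",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- paste(
    variants$chrom, variants$pos, variants$variant_id, variants$ref,
    variants$alt, ".", "PASS", sprintf("MQ=%s", mq_site), "GT:AD:DP:GQ",
    apply(body, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, lines), file.path(dir, "cohort.vcf"))

  readr::write_tsv(
    select(cohort$pedigree, "fam", "sample", "father", "mother", "sex",
           "phenotype"),
    file.path(dir, "cohort.ped"), col_names = FALSE)
  readr::write_tsv(
    select(variants, "variant_id", "chrom", "pos", "ref", "alt", "gene",
           "consequence", "metasvm", "cadd", "af_panel1", "af_panel2",
           "segdup"),
    file.path(dir, "variants.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(cohort$mutability, file.path(dir, "mutability.tsv"))
  invisible(dir)
}

#' Read a VCF into the sparse long genotype table
#'
#' Parses a VCF v4.2 with `GT:AD:DP:GQ` genotype fields and per-site `MQ`
#' in INFO (the layout written by [write_cohort()]) into the sparse long
#' genotype tibble used throughout the package; hom-ref genotypes are
#' dropped. Requires the vcfR package.
#'
#' @param path VCF file (plain or gzipped).
#' @return tibble: sample, variant_id, dosage, gq, dp, mq, alt_reads.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  vid <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                fix$ID)
  mq <- suppressWarnings(as.numeric(sub(".*MQ=([0-9.e+-]+).*", "\\1",
                                        fix$INFO)))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(apply(vcfR::extract.gt(v, element = "DP"), 2,
                               as.integer))
  gq <- suppressWarnings(apply(vcfR::extract.gt(v, element = "GQ"), 2,
                               as.integer))
  ad <- vcfR::extract.gt(v, element = "AD")
  dosage <- matrix(0L, nrow(gt), ncol(gt))
  dosage[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dosage[gt %in% c("1/1", "1|1")] <- 2L
  hap <- matrix(NA_integer_, nrow(gt), ncol(gt))
  hap[gt %in% c("1|0")] <- 1L
  hap[gt %in% c("0|1")] <- 2L
  hap[gt %in% c("1/1", "1|1")] <- 0L
  idx <- which(dosage > 0, arr.ind = TRUE)
  alt_reads <- suppressWarnings(
    as.integer(vapply(strsplit(ad[idx], ","), function(x) x[2], character(1))))
  tibble(
    sample = colnames(gt)[idx[, 2]],
    variant_id = vid[idx[, 1]],
    dosage = dosage[idx],
    hap = hap[idx],
    gq = gq[idx], dp = dp[idx],
    mq = mq[idx[, 1]],
    alt_reads = alt_reads
  ) |> arrange(.data$sample, .data$variant_id)
}

#' Read a 6-column PED file
#'
#' @param path PED file (fam, sample, father, mother, sex, phenotype).
#' @return pedigree tibble with a derived `role` column.
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, col_names = c("fam", "sample", "father",
                                             "mother", "sex", "phenotype"),
                         col_types = "ccccii", progress = FALSE)
  fathers <- unique(ped$father[ped$father != "0"])
  mothers <- unique(ped$mother[ped$mother != "0"])
  ped$role <- dplyr::case_when(
    ped$sample %in% fathers ~ "father",
    ped$sample %in% mothers ~ "mother",
    TRUE ~ "proband"
  )
  ped
}

#' Read the variant annotation table
#'
#' @param path TSV with variant_id, chrom, pos, ref, alt, gene, consequence,
#'   metasvm, cadd, af_panel1, af_panel2, segdup.
#' @return classified variant tibble.
#' @export
read_annotation <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    classify_variants()
}

#' Read a two-column gene mutability table
#' @param path TSV with columns gene, mutability.
#' @return tibble.
#' @export
read_mutability <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a gene-set file (one symbol per line, or first column of a TSV)
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_set <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE)
  unique(as.character(x[[1]]))
}

#' Read a gene-by-cell-type expression table
#' @param path TSV whose first column is the gene label.
#' @return expression tibble with a `gene` column.
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "gene"
  x
}

#' Convert segmental-duplication BED intervals to 1-based flags
#'
#' Marks variants whose position falls inside any interval of a BED file
#' (0-based half-open, converted internally to 1-based inclusive).
#'
#' @param variants variant tibble with `chrom` and `pos`.
#' @param bed tibble or file path with columns chrom, start, end.
#' @return logical vector: variant lies in a segdup region.
#' @export
flag_segdup_bed <- function(variants, bed) {
  if (is.character(bed)) {
    bed <- readr::read_tsv(bed, col_names = c("chrom", "start", "end"),
                           show_col_types = FALSE, progress = FALSE)
  }
  flag <- rep(FALSE, nrow(variants))
  for (ch in unique(bed$chrom)) {
    b <- bed[bed$chrom == ch, ]
    vi <- which(variants$chrom == ch)
    if (length(vi) == 0) next
    for (k in seq_len(nrow(b))) {
      flag[vi] <- flag[vi] |
        (variants$pos[vi] >= b$start[k] + 1L & variants$pos[vi] <= b$end[k])
    }
  }
  flag
}
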