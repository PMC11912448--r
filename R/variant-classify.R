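#' Classify variants into damaging and control classes
#'
#' Assigns each annotated variant to one of five classes:
#' \describe{
#'   \item{LoF}{likely loss of function: stopgain, stoploss, frameshift
#'     insertion/deletion, or a canonical splice-site change.}
#'   \item{Dmis}{damaging missense: missense predicted deleterious by the
#'     ensemble score (MetaSVM = "D") and/or with CADD at or above
#'     `cadd_threshold`. Either score alone is sufficient; a missense variant
#'     missing both scores is not called damaging.}
#'   \item{nonframeshift_indel}{in-frame insertion/deletion; counted as
#'     damaging unconditionally.}
#'   \item{synonymous}{the negative-control stream.}
#'   \item{non_damaging}{everything else (benign missense, other).}
#' }
#' The union LoF + Dmis + nonframeshift_indel is the "damaging" set used by
#' the recessive-genotype caller.
#'
#' @param variants data frame with at least `consequence` (character), and for
#'   missense calls `metasvm` ("D"/"T"/NA) and `cadd` (numeric, NA allowed).
#' @param cadd_threshold CADD score at or above which a missense variant is
#'   damaging regardless of MetaSVM (default 30).
#' @return the input as a tibble with a `class` column added, and a logical
#'   `damaging` convenience column.
#' @examples
#' v <- tibble::tibble(
#'   consequence = c("stopgain", "missense", "missense", "synonymous"),
#'   metasvm = c("T", "T", "D", NA),
#'   cadd = c(NA, 31, 10, NA)
#' )
#' classify_variants(v)$class
#' @export
classify_variants <- function(variants, cadd_threshold = 30) {
  stopifnot(is.data.frame(variants), "consequence" %in% names(variants))
  v <- as_tibble(variants)
  metasvm <- if ("metasvm" %in% names(v)) v$metasvm else rep(NA_character_, nrow(v))
  cadd <- if ("cadd" %in% names(v)) v$cadd else rep(NA_real_, nrow(v))
  cons <- v$consequence
  dmis <- cons == "missense" &
    ((!is.na(metasvm) & metasvm == "D") | (!is.na(cadd) & cadd >= cadd_threshold))
  cls <- dplyr::case_when(
    cons %in% LOF_CONSEQUENCES ~ "LoF",
    dmis ~ "Dmis",
    cons == "nonframeshift_indel" ~ "nonframeshift_indel",
    cons == "synonymous" ~ "synonymous",
    TRUE ~ "non_damaging"
  )
  v$class <- cls
  v$damaging <- cls %in% DAMAGING_CLASSES
  v
}

#' Rarity filter against two reference population panels
#'
#' A variant is rare when its allele frequency is below `threshold` in *both*
#' reference panels. A missing frequency counts as below threshold: absence
#' from a large reference panel is itself evidence of rarity. The convention
#' is configurable via `missing_is_rare`.
#'
#' @param variants data frame with `af_panel1` and `af_panel2` columns, or a
#'   numeric vector of panel-1 frequencies (then `af_panel2` must be passed).
#' @param threshold allele-frequency cutoff (default `1e-3`).
#' @param missing_is_rare treat NA frequencies as rare (default TRUE).
#' @param af_panel2 second-panel frequencies when `variants` is a vector.
#' @return logical vector, one entry per variant.
#' @examples
#' is_rare(tibble::tibble(af_panel1 = c(9e-4, 1.2e-3, NA),
#'                        af_panel2 = c(5e-4, 5e-4, NA)))
#' @export
is_rare <- function(variants, threshold = 1e-3, missing_is_rare = TRUE,
                    af_panel2 = NULL) {
  if (is.data.frame(variants)) {
    af1 <- variants$af_panel1
    af2 <- variants$af_panel2
  } else {
    af1 <- variants
    af2 <- af_panel2
  }
  ok1 <- if (missing_is_rare) is.na(af1) | af1 < threshold else !is.na(af1) & af1 < threshold
  ok2 <- if (missing_is_rare) is.na(af2) | af2 < threshold else !is.na(af2) & af2 < threshold
  ok1 & ok2
}

#' Per-genotype quality filter used in the contribution stage
#'
#' Applies the six-way genotype filter: GQ >= 20, DP >= 8, MQ >= 40, variant
#' allele fraction >= 25%, at least three reads supporting the alternate
#' allele, and the site not flagged as segmental duplication. The filter is
#' used when estimating the recessive contribution (where false-positive
#' genotypes inflate in-cohort allele frequencies); gene-discovery RG calling
#' does not apply it unless requested.
#'
#' @param genotypes data frame with `gq`, `dp`, `mq`, `alt_reads` columns and
#'   a `variant_id` key; hom-ref genotypes need not be present.
#' @param variants data frame with `variant_id` and logical `segdup`; when
#'   NULL, `genotypes` must already carry a `segdup` column (missing = FALSE).
#' @param min_gq,min_dp,min_mq,min_vaf,min_alt_reads filter thresholds.
#' @return logical vector, one entry per genotype row.
#' @export
passes_genotype_qc <- function(genotypes, variants = NULL, min_gq = 20,
                               min_dp = 8, min_mq = 40, min_vaf = 0.25,
                               min_alt_reads = 3) {
  g <- as_tibble(genotypes)
  if (!is.null(variants)) {
    seg <- variants$segdup[match(g$variant_id, variants$variant_id)]
  } else {
    seg <- if ("segdup" %in% names(g)) g$segdup else rep(FALSE, nrow(g))
  }
  seg <- dplyr::coalesce(seg, FALSE)
  vaf <- ifelse(g$dp > 0, g$alt_reads / g$dp, 0)
  g$gq >= min_gq & g$dp >= min_dp & g$mq >= min_mq &
    vaf >= min_vaf & g$alt_reads >= min_alt_reads & !seg
}
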