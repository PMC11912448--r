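#' @importFrom rlang %||% .data abort warn inform
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join anti_join semi_join bind_rows bind_cols n rename
#'   distinct slice slice_min slice_head count pull across if_else row_number
#'   first last
#' @importFrom tibble tibble as_tibble
#' @importFrom tidyr replace_na pivot_longer pivot_wider
#' @importFrom stats pbinom pchisq fisher.test ks.test p.adjust rbinom rpois
#'   rexp rlnorm runif rnorm rmultinom quantile setNames sd qgamma hclust dist
#'   as.dist cutree median complete.cases
#' @importFrom utils head
NULL

# variant classes counted as damaging throughout the package
DAMAGING_CLASSES <- c("LoF", "Dmis", "nonframeshift_indel")

LOF_CONSEQUENCES <- c("stopgain", "stoploss", "frameshift_indel", "canonical_splice")

# precedence used when a sample carries more than two qualifying alleles in a
# gene: LoF beats D-mis beats nonframeshift indel; ties broken by lower
# population AF, then position
damage_rank <- function(class) {
  match(class, c("LoF", "Dmis", "nonframeshift_indel", "synonymous", "non_damaging"))
}

af_sort_key <- function(af1, af2) {
  pmax(dplyr::coalesce(af1, 0), dplyr::coalesce(af2, 0))
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_prop <- function(x, name, max_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      (if (max_open) x >= 1 else x > 1)) {
    abort(sprintf("`%s` must be a proportion in [0,%s", name,
                  if (max_open) "1)" else "1]"))
  }
  as.numeric(x)
}

#' Derive a child stream seed from a base seed
#'
#' Keeps derived seeds inside the 32-bit integer range expected by
#' [set.seed()].
#'
#' @param seed base integer seed
#' @param offset small integer offset identifying the consumer stream
#' @keywords internal
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * offset) %% 2147483647)
}
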