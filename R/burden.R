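#' Fit the mutability-based expected RG count model
#'
#' Regresses observed per-gene RG counts on gene mutability with a
#' no-intercept polynomial under nonnegativity constraints (exact
#' active-set enumeration; least squares). With the default degree 2 the
#' quadratic term captures random-mating biallelic events (two independent
#' rare alleles, each with frequency proportional to mutability) and the
#' linear term captures autozygous events (a single allele drawn
#' homozygous by descent), so the fit adapts to the cohort's level of
#' consanguinity. Fitted values are floored at `floor` so downstream
#' binomial tests never divide by zero; floored genes are flagged.
#'
#' @param observed tibble with `gene` and `observed` RG counts; genes absent
#'   from it but present in `mutability` count as zero.
#' @param mutability tibble with `gene` and `mutability` (> 0), one row per
#'   gene; at least 100 genes.
#' @param n cohort size (probands), stored for the binomial tests.
#' @param degree polynomial degree (default 2).
#' @param floor lower bound on fitted expected counts (default 1e-6).
#' @return object of class `rb_expected_model`: list with `coefficients`,
#'   `fitted` (gene, mutability, observed, expected, floored), `n`,
#'   `degree`, `floor`.
#' @export
fit_expected_model <- function(observed, mutability, n, degree = 2,
                               floor = 1e-6) {
  mut <- as_tibble(mutability)
  stopifnot(all(c("gene", "mutability") %in% names(mut)))
  if (anyDuplicated(mut$gene)) abort("duplicate genes in mutability table")
  if (any(mut$mutability <= 0)) abort("mutability must be positive")
  if (nrow(mut) < 100) abort("need mutability for at least 100 genes")
  n <- assert_count(n, "n", min = 1L)

  obs <- as_tibble(observed)
  if (!all(obs$gene %in% mut$gene)) {
    warn("dropping observed counts for genes without mutability")
    obs <- filter(obs, .data$gene %in% mut$gene)
  }
  dat <- left_join(mut, obs, by = "gene") |>
    mutate(observed = replace_na(.data$observed, 0))

  X <- vapply(seq_len(degree), function(d) dat$mutability^d,
              numeric(nrow(dat)))
  y <- dat$observed
  if (all(y == 0)) {
    warn("all observed counts are zero; expected model is identically zero")
    beta <- rep(0, degree)
  } else {
    beta <- nnls_enumerate(X, y)
  }
  e <- as.numeric(X %*% beta)
  floored <- e < floor
  e <- pmax(e, floor)

  structure(list(
    coefficients = setNames(beta, paste0("m^", seq_len(degree))),
    fitted = tibble(gene = dat$gene, mutability = dat$mutability,
                    observed = y, expected = e, floored = floored),
    n = n, degree = degree, floor = floor
  ), class = "rb_expected_model")
}

# exact nonnegative least squares by enumerating active sets; suitable for
# the handful of polynomial coefficients used here
nnls_enumerate <- function(X, y) {
  p <- ncol(X)
  # scale columns to unit norm so wildly different monomial magnitudes
  # (m vs m^2 for m ~ 1e-5) do not defeat the QR rank detection
  scl <- sqrt(colSums(X^2))
  scl[scl == 0] <- 1
  Xs <- sweep(X, 2, scl, "/")
  best <- NULL
  best_rss <- Inf
  for (mask in 0:(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    beta <- rep(0, p)
    if (length(free) > 0) {
      fit <- tryCatch(qr.solve(Xs[, free, drop = FALSE], y),
                      error = function(e) NULL)
      if (is.null(fit) || any(!is.finite(fit)) || any(fit < 0)) next
      beta[free] <- fit / scl[free]
    }
    rss <- sum((y - X %*% beta)^2)
    if (rss < best_rss * (1 - 1e-9) - 1e-300) {
      best_rss <- rss
      best <- beta
    }
  }
  best %||% rep(0, p)
}

#' @export
print.rb_expected_model <- function(x, ...) {
  cat("Mutability-based expected RG count model\n")
  cat(sprintf("  genes: %d   cohort n: %d   degree: %d\n",
              nrow(x$fitted), x$n, x$degree))
  cat("  coefficients:",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  sum observed: %d   sum expected: %.1f\n",
              sum(x$fitted$observed), sum(x$fitted$expected)))
  invisible(x)
}

#' One-tailed binomial enrichment test
#'
#' Tests whether `observed` RG counts exceed `expected` under
#' X ~ Binomial(n, expected/n): p = P(X >= observed) (upper tail).
#' Vectorized over units.
#'
#' @param observed integer vector of observed RG counts.
#' @param expected positive expected counts (same length).
#' @param n cohort size; `expected` must be smaller than `n`.
#' @param unit optional unit labels (gene symbols or set names).
#' @return tibble of class `rb_enrichment`: unit, observed, expected,
#'   enrichment (= observed/expected), p_value.
#' @examples
#' binomial_gene_test(5, 5 / 176.8, 5424)    # p ~ 1.5e-10
#' @export
binomial_gene_test <- function(observed, expected, n, unit = NULL) {
  n <- assert_count(n, "n", min = 1L)
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0)) abort("`expected` must be positive")
  if (any(expected >= n)) abort("`expected` must be below the cohort size")
  if (any(observed > n)) abort("`observed` cannot exceed the cohort size")
  p <- pbinom(observed - 1, size = n, prob = expected / n, lower.tail = FALSE)
  out <- tibble(
    unit = unit %||% as.character(seq_along(observed)),
    observed = observed, expected = expected,
    enrichment = observed / expected, p_value = p
  )
  class(out) <- c("rb_enrichment", class(out))
  out
}

#' Per-gene burden test against a fitted expected model
#'
#' @param model an [fit_expected_model()] object.
#' @param observed optional tibble (`gene`, `observed`) overriding the
#'   counts stored in the model (e.g. counts from a cohort subset, with
#'   matching `n`).
#' @param n cohort size (defaults to the model's).
#' @return `rb_enrichment` tibble, one row per modeled gene.
#' @export
gene_burden_test <- function(model, observed = NULL, n = NULL) {
  stopifnot(inherits(model, "rb_expected_model"))
  fit <- model$fitted
  if (!is.null(observed)) {
    fit <- left_join(select(fit, -"observed"), as_tibble(observed),
                     by = "gene") |>
      mutate(observed = replace_na(.data$observed, 0))
  }
  binomial_gene_test(fit$observed, fit$expected, n %||% model$n,
                     unit = fit$gene)
}

#' Gene-set burden test
#'
#' Expected count for a set is the sum of per-gene expected counts
#' (additive over disjoint sets); the test is the same one-tailed binomial.
#' A singleton set reduces exactly to the per-gene test. Cohort subsets
#' (phenotype classes, consanguinity strata) are supported by passing the
#' subset's observed count and size.
#'
#' @param model an [fit_expected_model()] object.
#' @param genes non-empty character vector of set members (must all be
#'   modeled).
#' @param observed observed RG count in the set: a single number, or an RG
#'   tibble from which RGs in the set are counted.
#' @param n cohort size (defaults to the model's).
#' @param set_name label for the output row.
#' @return one-row `rb_enrichment` tibble.
#' @export
gene_set_test <- function(model, genes, observed, n = NULL,
                          set_name = "gene_set") {
  stopifnot(inherits(model, "rb_expected_model"))
  if (length(genes) == 0) abort("empty gene set")
  missing <- setdiff(genes, model$fitted$gene)
  if (length(missing) > 0) {
    abort(sprintf("gene set members not in the model: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  if (is.data.frame(observed)) {
    observed <- sum(observed$gene %in% genes)
  }
  expected <- sum(model$fitted$expected[model$fitted$gene %in% genes])
  res <- binomial_gene_test(observed, expected, n %||% model$n,
                            unit = set_name)
  if (observed == 0) res$enrichment <- 0
  res
}

#' Bonferroni threshold for the gene-based test
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_genes number of genes tested genome-wide (default 19347).
#' @return the per-test significance threshold alpha / n_genes.
#' @examples
#' bonferroni_threshold()   # 2.6e-6
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_genes = 19347) {
  alpha / n_genes
}

#' Multiple-testing adjustment for enrichment results
#'
#' Adds Benjamini-Hochberg q-values over the tested units and flags
#' Bonferroni significance at `alpha / n_genes`.
#'
#' @param results an `rb_enrichment` tibble (or any tibble with `p_value`).
#' @param alpha family-wise error rate.
#' @param n_genes Bonferroni denominator; defaults to the genome-wide 19347
#'   so that subset result tables are still held to the genome-wide bar.
#' @return `results` with `q_value` and `bonferroni_significant` columns;
#'   the threshold is stored in `attr(, "bonferroni_threshold")`.
#' @export
adjust_multiplicity <- function(results, alpha = 0.05, n_genes = 19347) {
  thr <- bonferroni_threshold(alpha, n_genes)
  out <- results |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH"),
           bonferroni_significant = .data$p_value < thr)
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Permutation test for the number of recurrent genes
#'
#' Drops the cohort's total RG count multinomially across genes with
#' probabilities proportional to the per-gene expected counts, and counts
#' genes receiving two or more RGs per permutation. The empirical p-value
#' uses the add-one correction (1 + #{permutations >= observed}) /
#' (1 + n_perm).
#'
#' @param observed_recurrent observed number of genes with >= 2 RGs.
#' @param total_rgs total number of RGs to drop (T >= 0).
#' @param probs per-gene drop probabilities (normalized internally;
#'   typically proportional to model expected counts).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return tibble: observed, expected (mean permutation statistic),
#'   enrichment, p_value, n_perm; the permutation distribution is kept in
#'   `attr(, "distribution")`.
#' @export
permutation_recurrent_genes <- function(observed_recurrent, total_rgs, probs,
                                        n_perm = 1000, seed = 1L) {
  total_rgs <- assert_count(total_rgs, "total_rgs")
  n_perm <- assert_count(n_perm, "n_perm", min = 1L)
  if (any(probs < 0) || sum(probs) <= 0) abort("invalid gene probabilities")
  probs <- probs / sum(probs)
  set.seed(derive_seed(seed, 7L))
  if (total_rgs == 0) {
    stat <- rep(0L, n_perm)
  } else {
    # chunked so genome-scale gene counts stay within memory
    chunk <- max(1L, floor(2e7 / length(probs)))
    stat <- integer(0)
    done <- 0L
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      draws <- rmultinom(b, total_rgs, probs)
      stat <- c(stat, colSums(draws >= 2L))
      done <- done + b
    }
  }
  expected <- mean(stat)
  out <- tibble(
    observed = observed_recurrent, expected = expected,
    enrichment = if (expected > 0) observed_recurrent / expected else NA_real_,
    p_value = (1 + sum(stat >= observed_recurrent)) / (1 + n_perm),
    n_perm = n_perm
  )
  attr(out, "distribution") <- stat
  out
}
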