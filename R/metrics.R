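## Affinity-accuracy and virtual-screening evaluation metrics: Pearson R,
## RMSE, ROC AUC, enrichment factors (fractional top-x% convention) and
## BEDROC (Truchon-Bayly).

#' Pearson correlation between predicted and experimental affinities
#'
#' @param pred,exp numeric vectors of equal length `>= 3`.
#' @return correlation in `[-1, 1]`; zero variance in either argument is an
#'   error (the statistic is undefined).
#' @export
pearson_r <- function(pred, exp) {
  if (length(pred) != length(exp)) stop("length mismatch")
  if (length(pred) < 3L) stop("need at least 3 points")
  if (stats::sd(pred) == 0 || stats::sd(exp) == 0)
    stop("undefined-value error: zero variance")
  stats::cor(pred, exp)
}

#' Root mean squared error
#'
#' @param pred,exp numeric vectors of equal length.
#' @return `sqrt(mean((pred - exp)^2))`, in the units of the inputs
#'   (kcal/mol for affinities).
#' @export
rmse <- function(pred, exp) {
  if (length(pred) != length(exp)) stop("length mismatch")
  sqrt(mean((pred - exp)^2))
}

#' Screening table
#'
#' Parallel score and activity-label sequences for enrichment metrics.
#' Scores follow the "lower is better" convention of predicted binding free
#' energies; set `higher_is_better = TRUE` to invert.
#'
#' @param scores numeric scores, lower = predicted more active by default.
#' @param labels logical (or coercible) activity labels, `TRUE` = active.
#' @param ids optional compound identifiers (default sequential).
#' @param higher_is_better invert the score polarity.
#' @return object of class `screening_table`.
#' @export
screening_table <- function(scores, labels, ids = NULL,
                            higher_is_better = FALSE) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(is.na(scores)) || any(is.na(labels))) stop("NA in screening table")
  if (is.null(ids)) ids <- seq_along(scores)
  if (higher_is_better) scores <- -scores
  structure(list(ids = ids, scores = as.numeric(scores), labels = labels),
            class = "screening_table")
}

check_two_classes <- function(tab) {
  if (!any(tab$labels) || all(tab$labels))
    stop("need at least one active and one inactive compound")
}

#' ROC AUC of a screening table
#'
#' Rank-based (Mann-Whitney) area under the ROC curve; tied scores
#' contribute 1/2.  1 means every active scores better (lower) than every
#' inactive.
#'
#' @param tab a [screening_table()].
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(tab) {
  check_two_classes(tab)
  # rank with average ties on -score so that better (lower) scores rank high
  r <- rank(-tab$scores, ties.method = "average")
  n_act <- sum(tab$labels)
  n_inact <- sum(!tab$labels)
  (sum(r[tab$labels]) - n_act * (n_act + 1) / 2) / (n_act * n_inact)
}

#' Enrichment factor at a screening fraction
#'
#' Ratio of the active rate in the top `fraction` of the ranking to the
#' overall active rate.  The default convention counts actives in the top
#' `fraction * N` compounds *fractionally*: when the cutoff falls inside a
#' compound, that compound contributes proportionally.  Under this
#' convention the theoretical maximum is `min(1/fraction, N/n_active)`,
#' matching the printed "(max = ...)" values convention; an integer-cutoff
#' mode (`interpolate = FALSE`, top `floor(fraction * N)` compounds) is also
#' provided.  Ties are broken by stable input order.
#'
#' @param tab a [screening_table()].
#' @param fraction screening fraction in (0, 1), e.g. 0.01 for EF1%.
#' @param interpolate fractional boundary counting (default `TRUE`).
#' @return enrichment factor, `>= 0`.
#' @export
enrichment_factor <- function(tab, fraction = 0.01, interpolate = TRUE) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n_act <- sum(tab$labels)
  if (n_act == 0L) stop("no actives in table")
  n <- length(tab$scores)
  ord <- order(tab$scores)  # stable; lower score = better
  lab <- tab$labels[ord]
  cut <- fraction * n
  if (interpolate) {
    k <- floor(cut)
    found <- sum(lab[seq_len(k)])
    if (k < n && cut > k) found <- found + (cut - k) * lab[k + 1L]
  } else {
    found <- sum(lab[seq_len(floor(cut))])
  }
  found / (n_act * fraction)
}

#' Maximum achievable enrichment factor
#'
#' Upper bound of [enrichment_factor()] under the fractional convention: all
#' actives ranked first gives `min(1/fraction, n_total/n_active)`.
#'
#' @param n_active number of actives.
#' @param n_total library size.
#' @param fraction screening fraction in (0, 1).
#' @return the maximum enrichment factor.
#' @examples
#' max_enrichment_factor(112, 5933, 0.01)  # 52.973
#' @export
max_enrichment_factor <- function(n_active, n_total, fraction = 0.01) {
  stopifnot(n_active > 0, n_active <= n_total, fraction > 0, fraction < 1)
  min(1 / fraction, n_total / n_active)
}

#' BEDROC early-recognition metric
#'
#' Boltzmann-enhanced discrimination of ROC (Truchon & Bayly): actives
#' ranked early are rewarded with exponential weight `exp(-alpha * rank/N)`,
#' and the resulting RIE is normalized to `[0, 1]`.  `alpha = 20` weights
#' roughly the top 8% of the library, `alpha = 100` the top 1.6%.
#'
#' @param tab a [screening_table()].
#' @param alpha exponential weight parameter, `> 0`.
#' @return BEDROC in `[0, 1]`.
#' @export
bedroc <- function(tab, alpha = 20) {
  check_two_classes(tab)
  stopifnot(alpha > 0)
  n <- length(tab$scores)
  n_act <- sum(tab$labels)
  ra <- n_act / n
  ord <- order(tab$scores)  # stable tie-break, documented
  ranks <- which(tab$labels[ord])
  s <- sum(exp(-alpha * ranks / n))
  rie <- s / (n_act * (1 - exp(-alpha)) / (n * (exp(alpha / n) - 1)))
  rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
}

#' Evaluate a full panel of screening metrics
#'
#' Convenience wrapper computing ROC AUC, enrichment factors, their maxima,
#' and BEDROC values in one call, as used when validating scoring functions
#' against active/decoy libraries.
#'
#' @param tab a [screening_table()].
#' @param ef_fractions enrichment-factor fractions (default 0.01).
#' @param bedroc_alphas BEDROC alpha values (default 20 and 100).
#' @return named list of metric values.
#' @export
screening_metrics <- function(tab, ef_fractions = 0.01,
                              bedroc_alphas = c(20, 100)) {
  check_two_classes(tab)
  out <- list(auc = roc_auc(tab))
  for (f in ef_fractions) {
    out[[sprintf("ef%g", 100 * f)]] <- enrichment_factor(tab, f)
    out[[sprintf("ef%g_max", 100 * f)]] <-
      max_enrichment_factor(sum(tab$labels), length(tab$labels), f)
  }
  for (a in bedroc_alphas)
    out[[sprintf("bedroc%g", a)]] <- bedroc(tab, a)
  out
}
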