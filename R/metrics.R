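#' Consensus score over ChemPLP, GoldScore and pharmacophore fit
#'
#' Each of the three score columns is min-max normalized over the supplied
#' population (the docked-hit set) and the normalized values are summed, so
#' the consensus lies in `[0, 3]`. A degenerate column (max = min) carries no
#' ranking information and contributes the neutral value 0.5 to every record.
#'
#' @param records data.frame with numeric columns `chemplp`, `goldscore`,
#'   `fit` (higher is better for all three).
#' @return `records` with a `consensus` column added, unchanged row order.
#' @export
consensus_score <- function(records) {
  if (!nrow(records)) stopf("consensus_score: empty input")
  cols <- c("chemplp", "goldscore", "fit")
  miss <- setdiff(cols, names(records))
  if (length(miss)) stopf("consensus_score: missing column(s) %s",
                          paste(miss, collapse = ", "))
  norm1 <- function(x) {
    rng <- range(x)
    if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else rep(0.5, length(x))
  }
  records$consensus <- norm1(records$chemplp) + norm1(records$goldscore) +
    norm1(records$fit)
  records
}

#' ROC area under the curve by rank-sum
#'
#' `AUC = P(score_active > score_decoy) + 0.5 P(tie)`, computed exactly via
#' the Mann-Whitney statistic with average ranks.
#'
#' @param active_scores,decoy_scores numeric vectors (non-empty).
#' @param higher_is_better direction of the score (default TRUE).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(active_scores, decoy_scores, higher_is_better = TRUE) {
  if (!length(active_scores) || !length(decoy_scores))
    stopf("roc_auc: both classes must be non-empty")
  a <- as.numeric(active_scores); d <- as.numeric(decoy_scores)
  if (!higher_is_better) { a <- -a; d <- -d }
  r <- rank(c(a, d))
  na <- length(a); nd <- length(d)
  (sum(r[seq_len(na)]) - na * (na + 1) / 2) / (na * nd)
}

#' ROC curve points
#'
#' @param active_scores,decoy_scores numeric vectors.
#' @param higher_is_better direction of the score.
#' @return data.frame with columns `fpr`, `tpr` (stepwise ROC curve).
#' @export
roc_curve <- function(active_scores, decoy_scores, higher_is_better = TRUE) {
  s <- c(active_scores, decoy_scores)
  lab <- rep(c(TRUE, FALSE), c(length(active_scores), length(decoy_scores)))
  if (!higher_is_better) s <- -s
  o <- order(-s)
  lab <- lab[o]
  data.frame(fpr = c(0, cumsum(!lab) / sum(!lab)),
             tpr = c(0, cumsum(lab) / sum(lab)))
}

#' Robust initial enhancement (RIE)
#'
#' Exponentially rank-weighted enrichment: `(1/n) * sum_i exp(-alpha r_i / N)`
#' over active ranks `r_i`, normalized by its expectation under uniform random
#' ranking, `(1/N) (1 - e^-alpha) / (e^(alpha/N) - 1)`. Values > 1 indicate
#' early enrichment; the weight concentrates on the top `N/alpha` fraction.
#'
#' @param labels logical vector ordered best rank first (TRUE = active).
#' @param alpha exponential weight parameter (default 20).
#' @return RIE value (>= 0).
#' @export
rie <- function(labels, alpha = 20.0) {
  labels <- as.logical(labels)
  N <- length(labels); n <- sum(labels)
  if (n == 0L || n == N) stopf("rie: need both actives and inactives")
  ranks <- which(labels)
  obs <- mean(exp(-alpha * ranks / N))
  expect <- (1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  obs / expect
}

#' Ligand-efficiency metrics
#'
#' `ligand_efficiency()` is potency per heavy atom, LE = pIC50 / HAC.
#' `lle()` is lipophilic ligand efficiency, LLE = pIC50 - logP.
#' `fit_quality()` normalizes LE by the size-dependent maximal-LE scale
#' `LE_scale(HAC) = 0.0715 + 7.5328/HAC + 25.7079/HAC^2 - 361.4722/HAC^3`
#' (fit to the potency-efficiency frontier), using the unrounded LE.
#'
#' @param pic50 potency as -log10 molar IC50.
#' @param hac heavy-atom count (>= 1).
#' @param logp octanol-water partition coefficient.
#' @return numeric metric value.
#' @export
ligand_efficiency <- function(pic50, hac) {
  if (any(hac <= 0)) stopf("ligand_efficiency: HAC must be >= 1")
  pic50 / hac
}

#' @rdname ligand_efficiency
#' @export
lle <- function(pic50, logp) pic50 - logp

#' @rdname ligand_efficiency
#' @export
le_scale <- function(hac) {
  if (any(hac <= 0)) stopf("le_scale: HAC must be >= 1")
  0.0715 + 7.5328 / hac + 25.7079 / hac^2 - 361.4722 / hac^3
}

#' @rdname ligand_efficiency
#' @export
fit_quality <- function(pic50, hac) ligand_efficiency(pic50, hac) / le_scale(hac)

#' Efficiency table
#'
#' @param table data.frame with columns `ligand_id`, `pIC50`, `logP`, `HAC`.
#' @return the table with `LE`, `LLE`, `FQ` columns appended.
#' @export
efficiency_table <- function(table) {
  stopifnot(all(c("pIC50", "logP", "HAC") %in% names(table)))
  table$LE <- ligand_efficiency(table$pIC50, table$HAC)
  table$LLE <- lle(table$pIC50, table$logP)
  table$FQ <- fit_quality(table$pIC50, table$HAC)
  table
}

#' Spearman rank correlation (tie-aware)
#'
#' Pearson correlation of average ranks; for tie-free data this equals
#' `1 - 6 sum(d^2) / (n (n^2 - 1))`.
#'
#' @param x,y numeric vectors of equal length (>= 2), not constant.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stopf("spearman_rho: need equal-length vectors of length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("spearman_rho: undefined for a constant vector")
  stats::cor(rank(x), rank(y))
}

#' Tanimoto coefficient of two bit vectors
#'
#' `|a AND b| / |a OR b|`; 1.0 when both vectors are empty, by convention.
#'
#' @param bits_a,bits_b logical (or 0/1) vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(bits_a, bits_b) {
  if (length(bits_a) != length(bits_b))
    stopf("tanimoto: bit-vector length mismatch")
  a <- as.logical(bits_a); b <- as.logical(bits_b)
  u <- sum(a | b)
  if (u == 0L) return(1.0)
  sum(a & b) / u
}
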