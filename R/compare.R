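#' Contingency table of two partitions
#'
#' @param a,b partitions (or naming systems / label vectors) of the same
#'   chips.
#' @return an object of class `contingency`: an integer `k1 x k2` matrix of
#'   co-occurrence counts with attribute `N`.
#' @export
contingency <- function(a, b) {
  a <- as_partition(a); b <- as_partition(b)
  if (length(a) != length(b))
    cp_stop("partitions cover different chip sets", "colorpart_domain_error")
  k1 <- n_categories(a); k2 <- n_categories(b)
  counts <- matrix(tabulate((unclass(a) - 1L) * k2 + unclass(b), k1 * k2),
                   nrow = k1, ncol = k2, byrow = TRUE)
  structure(counts, N = length(a), class = c("contingency", "matrix"))
}

as_contingency <- function(t) {
  if (inherits(t, "contingency")) return(t)
  structure(as.matrix(t), N = sum(t), class = c("contingency", "matrix"))
}

# pair counts from a contingency table: pairs co-clustered in both (TP),
# only in a (FP), only in b (FN)
pair_counts <- function(t) {
  t <- as_contingency(t)
  N <- attr(t, "N")
  TP <- sum(choose(t, 2))
  pa <- sum(choose(rowSums(t), 2))
  pb <- sum(choose(colSums(t), 2))
  c(TP = TP, FP = pa - TP, FN = pb - TP, total = choose(N, 2))
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected Rand index: 1 for identical clusterings,
#' 0 in expectation for independent ones, down to -1 for maximal
#' disagreement.
#'
#' @param t a [contingency()] table (or raw count matrix).
#' @return the ARI.
#' @export
ari <- function(t) {
  t <- as_contingency(t)
  N <- attr(t, "N")
  if (N < 2) cp_stop("need at least 2 items", "colorpart_domain_error")
  pc <- pair_counts(t)
  sum_ab <- (pc["TP"] + pc["FP"]) * (pc["TP"] + pc["FN"])
  expected <- sum_ab / pc["total"]
  maxi <- ((pc["TP"] + pc["FP"]) + (pc["TP"] + pc["FN"])) / 2
  if (maxi == expected) return(if (pc["FP"] + pc["FN"] == 0) 1 else 0)
  unname((pc["TP"] - expected) / (maxi - expected))
}

entropies <- function(t) {
  N <- attr(t, "N")
  pa <- rowSums(t) / N; pb <- colSums(t) / N; pij <- t / N
  Ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  Hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  Hab <- -sum(pij[pij > 0] * log(pij[pij > 0]))
  list(Ha = Ha, Hb = Hb, I = Ha + Hb - Hab)
}

#' Normalized mutual information
#'
#' `NMI = 2 I(a, b) / (H(a) + H(b))` with natural-log entropies; 1 for
#' identical clusterings, 0 when the clusterings are independent.  The
#' degenerate single-cluster-vs-single-cluster table (both entropies zero,
#' hence identical clusterings) is defined as 1.
#'
#' @param t a [contingency()] table.
#' @return the NMI in `[0, 1]`.
#' @export
nmi <- function(t) {
  t <- as_contingency(t)
  e <- entropies(t)
  if (e$Ha + e$Hb == 0) return(1)
  2 * e$I / (e$Ha + e$Hb)
}

#' Variation of information
#'
#' `VI = H(a) + H(b) - 2 I(a, b)` in nats: 0 for identical clusterings, at
#' most `2 log k` for two k-cluster clusterings.  VI is a metric on the
#' space of partitions.
#'
#' @param t a [contingency()] table.
#' @return the VI (non-negative, nats).
#' @export
vi <- function(t) {
  t <- as_contingency(t)
  e <- entropies(t)
  max(0, e$Ha + e$Hb - 2 * e$I)
}

#' Split/join (van Dongen) distance
#'
#' The number of item moves needed to turn each clustering into their
#' common refinement and back: `2N - sum_i max_j n_ij - sum_j max_i n_ij`.
#' Zero iff the clusterings are identical, bounded by `2N`.
#'
#' @param t a [contingency()] table.
#' @return an integer distance.
#' @export
split_join <- function(t) {
  t <- as_contingency(t)
  N <- attr(t, "N")
  as.integer(round(2 * N - sum(apply(t, 1, max)) - sum(apply(t, 2, max))))
}

#' Jaccard index over co-clustered pairs
#'
#' `J = TP / (TP + FP + FN)` with TP/FP/FN the chip pairs co-clustered in
#' both / only the first / only the second clustering; defined as 0 when no
#' pairs are co-clustered anywhere.
#'
#' @param t a [contingency()] table.
#' @return the Jaccard index in `[0, 1]`.
#' @export
jaccard_pairs <- function(t) {
  pc <- pair_counts(as_contingency(t))
  den <- pc["TP"] + pc["FP"] + pc["FN"]
  if (den == 0) return(0)
  unname(pc["TP"] / den)
}

#' Fowlkes-Mallows index
#'
#' `FM = TP / sqrt((TP + FP) (TP + FN))`; defined as 0 when either
#' clustering has no co-clustered pairs.
#'
#' @param t a [contingency()] table.
#' @return the FM index in `[0, 1]`.
#' @export
fowlkes_mallows <- function(t) {
  pc <- pair_counts(as_contingency(t))
  den <- (pc["TP"] + pc["FP"]) * (pc["TP"] + pc["FN"])
  if (den == 0) return(0)
  unname(pc["TP"] / sqrt(den))
}

#' All six comparison indices for a pair of clusterings
#'
#' @param a,b partitions or naming systems over the same chips.
#' @return an object of class `comparison_report`: list with elements
#'   `nmi`, `vi`, `sj`, `ari`, `jaccard`, `fm`.
#' @export
compare_all <- function(a, b) {
  t <- contingency(a, b)
  res <- list(nmi = nmi(t), vi = vi(t), sj = split_join(t), ari = ari(t),
              jaccard = jaccard_pairs(t), fm = fowlkes_mallows(t))
  class(res) <- "comparison_report"
  res
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("NMI = %.2f; VI = %.2f; SJ = %d; ARI = %.2f; J = %.2f; FM = %.2f\n",
              x$nmi, x$vi, x$sj, x$ari, x$jaccard, x$fm))
  invisible(x)
}
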