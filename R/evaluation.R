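#' ROC curve and AUC by threshold sweep
#'
#' Sweeps a decision threshold over the union of the two score sets and
#' returns the ROC points (FPR horizontal, TPR vertical) together with the
#' trapezoidal AUC. Tied scores produce diagonal segments, so the
#' trapezoidal area equals the Mann-Whitney statistic
#' \eqn{(\#\{pos > cand\} + \frac12 \#\{pos = cand\}) / (n_+ n_-)} exactly.
#'
#' @param positiveScores numeric scores of the true (held-out) positives.
#' @param candidateScores numeric scores of the candidate (unvalidated)
#'   pairs.
#' @return List with \code{roc} (data.frame of \code{fpr}, \code{tpr}) and
#'   \code{auc}.
#' @examples
#' rocAuc(c(3, 1), c(2, 0))$auc  # 0.75
#' @export
rocAuc <- function(positiveScores, candidateScores) {
  if (length(positiveScores) == 0L || length(candidateScores) == 0L)
    stop("both score lists must be nonempty")
  thr <- sort(unique(c(positiveScores, candidateScores)), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(positiveScores >= t), 0))
  fpr <- c(0, vapply(thr, function(t) mean(candidateScores >= t), 0))
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# Mann-Whitney win fraction of one score vs the candidate pool,
# and its midrank from the top among the candidates.
mwStats <- function(s, cand) {
  wins <- sum(cand < s) + 0.5 * sum(cand == s)
  c(u = wins / length(cand),
    rank = 1 + sum(cand > s) + 0.5 * sum(cand == s))
}

# rank-based pooled ROC over per-round midranks, on the grid k/N
rankRoc <- function(ranks, N) {
  k <- 0:N
  tpr <- vapply(k, function(ki) mean(ranks <= ki), 0)
  data.frame(fpr = k / N, tpr = tpr)
}

resolveScorer <- function(scorer, params, seed) {
  if (!is.null(scorer)) return(scorer)
  function(Amasked) scores(mdaPredict(Amasked, params, seed = seed))
}

#' Global leave-one-out cross-validation
#'
#' Masks each known association in turn, re-runs the entire pipeline (GIP
#' kernels, WKNKN completion, PCA features, both view fits) on the masked
#' matrix, and scores the held-out pair against the candidate set: all
#' pairs unvalidated in the original matrix. Because every derived matrix
#' is recomputed from the masked data, the held-out association cannot leak
#' into its own similarity profile or features. The reported AUC is the
#' exact pairwise (Mann-Whitney) statistic pooled over rounds; the ROC is
#' the rank-based pooled curve.
#'
#' With \code{leakageSafe = FALSE} the model is fit once on the full matrix
#' and held-out pairs are ranked from that single fit (faster, but the test
#' pair influences its own score; provided for comparison only).
#'
#' @param A binary-stage \linkS4class{AssociationMatrix}, or a path to an
#'   edge list.
#' @param params an [mdaParams()] list.
#' @param seed model-initialization seed (one stream; fold assignment does
#'   not apply to LOOCV).
#' @param scorer optional function(Amasked) returning an m x n score
#'   matrix; defaults to the full pipeline. Used to inject reference
#'   scorers in tests.
#' @param leakageSafe logical, recompute everything per round (default
#'   TRUE).
#' @return A \linkS4class{CVResult} with scheme \code{"loocv"}.
#' @export
globalLoocv <- function(A, params = mdaParams(), seed = 1L, scorer = NULL,
                        leakageSafe = TRUE) {
  if (is.character(A)) A <- readEdgeList(A)
  stopifnot(is(A, "AssociationMatrix"), stage(A) == "binary")
  pos <- which(A@.Data == 1)
  if (length(pos) < 2L)
    stop("need at least 2 known associations for LOOCV")
  cand <- which(A@.Data == 0)
  if (length(cand) == 0L) stop("no candidate (unvalidated) pairs")
  N <- length(cand)
  scorer <- resolveScorer(scorer, params, seed)
  u <- numeric(length(pos))
  rk <- numeric(length(pos))
  if (!leakageSafe) {
    S <- scorer(A)
    for (t in seq_along(pos)) {
      st <- mwStats(S[pos[t]], S[cand])
      u[t] <- st["u"]; rk[t] <- st["rank"]
    }
  } else {
    for (t in seq_along(pos)) {
      Am <- A@.Data
      Am[pos[t]] <- 0
      S <- scorer(associationMatrix(Am, stage = "binary"))
      st <- mwStats(S[pos[t]], S[cand])
      u[t] <- st["u"]; rk[t] <- st["rank"]
    }
  }
  new("CVResult", scheme = "loocv", auc = mean(u), aucSD = NA_real_,
      perRepeatAUC = numeric(0), ranks = rk, roc = rankRoc(rk, N),
      foldAssignments = list(), nCandidates = N)
}

#' Repeated k-fold cross-validation over known associations
#'
#' Randomly partitions the known associations into k near-equal folds
#' (sizes differ by at most one); each fold is masked in turn, the full
#' pipeline is re-run on the masked matrix, and the masked positives are
#' scored against the candidate pairs (unvalidated in the original
#' matrix). One AUC per repeat; mean and SD over repeats are reported.
#' Fold assignment and model initialization use two independent seed
#' streams so either can be varied alone.
#'
#' @inheritParams globalLoocv
#' @param k number of folds, default 5.
#' @param repeats number of random re-partitions, default 100.
#' @param foldSeed seed for the fold-assignment stream.
#' @param seed model-initialization seed.
#' @return A \linkS4class{CVResult} with scheme \code{"kfold"}.
#' @export
kfoldCv <- function(A, params = mdaParams(), k = 5L, repeats = 100L,
                    foldSeed = 1L, seed = 1L, scorer = NULL) {
  if (is.character(A)) A <- readEdgeList(A)
  stopifnot(is(A, "AssociationMatrix"), stage(A) == "binary")
  pos <- which(A@.Data == 1)
  if (k > length(pos)) stop("k exceeds the number of known associations")
  cand <- which(A@.Data == 0)
  N <- length(cand)
  scorer <- resolveScorer(scorer, params, seed)
  assignments <- withSeed(foldSeed, lapply(seq_len(repeats), function(r)
    sample(rep_len(seq_len(k), length(pos)))))
  aucs <- numeric(repeats)
  ranksAll <- numeric(0)
  for (r in seq_len(repeats)) {
    fa <- assignments[[r]]
    u <- numeric(length(pos))
    rk <- numeric(length(pos))
    for (f in seq_len(k)) {
      test <- which(fa == f)
      Am <- A@.Data
      Am[pos[test]] <- 0
      S <- scorer(associationMatrix(Am, stage = "binary"))
      for (t in test) {
        st <- mwStats(S[pos[t]], S[cand])
        u[t] <- st["u"]; rk[t] <- st["rank"]
      }
    }
    aucs[r] <- mean(u)
    ranksAll <- c(ranksAll, rk)
  }
  new("CVResult", scheme = "kfold", auc = mean(aucs),
      aucSD = if (repeats > 1L) stats::sd(aucs) else NA_real_,
      perRepeatAUC = aucs, ranks = ranksAll,
      roc = rankRoc(ranksAll, N), foldAssignments = assignments,
      nCandidates = N)
}
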