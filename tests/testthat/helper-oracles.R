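# Independent scalar-loop oracles. These deliberately avoid the vectorized
# code paths in R/ so each test compares two independent routes.

# pairwise-loop GIP kernel
gipOracle <- function(A, axis = "microbe", gammaPrime = 1) {
  P <- if (axis == "microbe") A else t(A)
  k <- nrow(P)
  norms <- numeric(k)
  for (i in seq_len(k)) norms[i] <- sum(P[i, ]^2)
  gamma <- gammaPrime * k / sum(norms)
  S <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    S[i, j] <- exp(-gamma * sum((P[i, ] - P[j, ])^2))
  S
}

# loop-based WKNKN: neighbor search, decayed weights, fusion, max with A
wknknOracle <- function(A, SM, SD, K, decay, w = c(1, 1)) {
  m <- nrow(A); n <- ncol(A)
  nbProfile <- function(S, deg, q, profiles) {
    known <- setdiff(which(deg > 0), q)
    if (length(known) == 0L) return(numeric(ncol(profiles)))
    sims <- S[known, q]
    ord <- known[order(-sims, known)]
    nb <- ord[seq_len(min(K, length(ord)))]
    Q <- 0; acc <- numeric(ncol(profiles))
    for (i in seq_along(nb)) {
      s <- S[nb[i], q]
      acc <- acc + decay^(i - 1) * s * profiles[nb[i], ]
      Q <- Q + s
    }
    if (Q == 0) numeric(ncol(profiles)) else acc / Q
  }
  Am <- matrix(0, m, n); Ad <- matrix(0, m, n)
  rdeg <- rowSums(A); cdeg <- colSums(A)
  for (q in seq_len(m)) Am[q, ] <- nbProfile(SM, rdeg, q, A)
  for (q in seq_len(n)) Ad[, q] <- nbProfile(SD, cdeg, q, t(A))
  Amd <- (w[1] * Am + w[2] * Ad) / sum(w)
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n))
    out[i, j] <- max(A[i, j], Amd[i, j])
  out
}

# scalar triple-loop objective
objectiveOracle <- function(G, P, F_, A, L, alpha, lambda,
                            useGraphReg = TRUE, useLpq = TRUE) {
  obj <- 0
  for (i in seq_along(F_)) {
    R <- F_[[i]] %*% t(P[[i]]) - G
    for (x in seq_len(nrow(R))) for (y in seq_len(ncol(R)))
      obj <- obj + R[x, y]^2
  }
  for (x in seq_len(nrow(G))) for (y in seq_len(ncol(G)))
    obj <- obj + alpha * (G[x, y] - A[x, y])^2
  if (useGraphReg) {
    LG <- L %*% G
    for (x in seq_len(nrow(G))) for (y in seq_len(ncol(G)))
      obj <- obj + G[x, y] * LG[x, y]
  }
  if (useLpq) {
    for (i in seq_along(P)) {
      for (x in seq_len(nrow(P[[i]]))) {
        rs <- 0
        for (y in seq_len(ncol(P[[i]]))) rs <- rs + abs(P[[i]][x, y])
        obj <- obj + lambda * rs^2
      }
    }
  }
  obj
}

# pairwise-count Mann-Whitney AUC with half-credit for ties
aucOracle <- function(pos, cand) {
  wins <- 0
  for (p in pos) for (c in cand) {
    if (p > c) wins <- wins + 1
    else if (p == c) wins <- wins + 0.5
  }
  wins / (length(pos) * length(cand))
}

# G-subproblem objective (fit + alpha + Laplacian terms, no P penalty)
gSubObjective <- function(G, F_, P, A, L, alpha) {
  obj <- alpha * sum((G - A)^2) + sum(G * (L %*% G))
  for (i in seq_along(F_)) obj <- obj + sum((F_[[i]] %*% t(P[[i]]) - G)^2)
  obj
}

# central-difference gradient of the (quadratic) G-subproblem
numGradG <- function(G, F_, P, A, L, alpha, h = 1e-3) {
  gr <- matrix(0, nrow(G), ncol(G))
  for (i in seq_len(nrow(G))) for (j in seq_len(ncol(G))) {
    Gp <- G; Gp[i, j] <- G[i, j] + h
    Gm <- G; Gm[i, j] <- G[i, j] - h
    gr[i, j] <- (gSubObjective(Gp, F_, P, A, L, alpha) -
                 gSubObjective(Gm, F_, P, A, L, alpha)) / (2 * h)
  }
  gr
}

# P-subproblem objective for one modality
pSubObjective <- function(P_i, F_i, G, lambda, useLpq = TRUE) {
  obj <- sum((F_i %*% t(P_i) - G)^2)
  if (useLpq) obj <- obj + lambda * sum(rowSums(abs(P_i))^2)
  obj
}

# random named binary association matrix with no empty rows/cols guaranteed
randomBinaryA <- function(m, n, density = 0.3, seed = 1) {
  set.seed(seed)
  A <- matrix(rbinom(m * n, 1, density), m, n,
              dimnames = list(paste0("m", seq_len(m)),
                              paste0("d", seq_len(n))))
  if (sum(A) == 0) A[1, 1] <- 1
  associationMatrix(A, stage = "binary")
}

# random factorization instance: features (with negatives), targets, PSD L
randomInstance <- function(k, l, dims = c(l, 3L), seed = 1) {
  set.seed(seed)
  F_ <- lapply(dims, function(g) matrix(rnorm(k * g), k, g))
  P <- lapply(dims, function(g) matrix(runif(l * g), l, g))
  G <- matrix(rnorm(k * l), k, l)
  A <- matrix(rbinom(k * l, 1, 0.3), k, l)
  W <- matrix(runif(k * k), k, k); W <- (W + t(W)) / 2; diag(W) <- 1
  L <- diag(rowSums(W)) - W
  list(F_ = F_, P = P, G = G, A = A, L = L)
}
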