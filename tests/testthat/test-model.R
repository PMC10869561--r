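test_that("graph Laplacian: identities and the quadratic-form identity", {
  expect_equal(graphLaplacian(diag(3)), matrix(0, 3, 3))
  expect_equal(graphLaplacian(matrix(1, 3, 3)), 3 * diag(3) - 1)
  set.seed(5)
  W <- matrix(runif(25), 5, 5); W <- (W + t(W)) / 2
  L <- graphLaplacian(W)
  expect_equal(rowSums(L), numeric(5), tolerance = 1e-12)
  for (r in 1:5) {
    x <- rnorm(5)
    quad <- sum(vapply(1:5, function(i) sum(W[i, ] * (x[i] - x)^2), 0)) / 2
    expect_equal(drop(t(x) %*% L %*% x), quad, tolerance = 1e-10)
  }
})

test_that("objective vanishes at a perfect fit and isolates the L1,2 term", {
  set.seed(1)
  k <- 5; l <- 4
  A <- matrix(rbinom(k * l, 1, 0.4), k, l)
  F_ <- list(A, A)                                    # F1 = F2 = A
  P <- list(diag(l), diag(l))                          # F P' = A
  L0 <- matrix(0, k, k)
  hp0 <- mdaParams(alpha = 2, lambda = 0)
  expect_equal(viewObjective(A, P, F_, A, L0, hp0), 0)

  # everything zeroed except lambda: objective = lambda * sum(rowsums^2)
  hp1 <- mdaParams(alpha = 0, lambda = 0.7, useGraphReg = FALSE)
  Z <- matrix(0, k, l)
  F0 <- list(matrix(0, k, 3), matrix(0, k, 2))
  P2 <- list(matrix(runif(l * 3), l, 3), matrix(runif(l * 2), l, 2))
  expect_equal(viewObjective(Z, P2, F0, Z, L0, hp1),
               0.7 * (sum(rowSums(P2[[1]])^2) + sum(rowSums(P2[[2]])^2)))
})

test_that("vectorized objective matches the triple-loop oracle", {
  for (s in 1:10) {
    inst <- randomInstance(6, 4, seed = s)
    hp <- mdaParams(alpha = 100, lambda = 1e-3)
    expect_equal(
      viewObjective(inst$G, inst$P, inst$F_, inst$A, inst$L, hp),
      objectiveOracle(inst$G, inst$P, inst$F_, inst$A, inst$L,
                      100, 1e-3),
      tolerance = 1e-10)
  }
})

test_that("G update is a fixed point at representable A and exact in limits", {
  set.seed(2)
  k <- 5; l <- 3
  A <- matrix(rbinom(k * l, 1, 0.5), k, l)
  P <- list(diag(l), diag(l))
  F_ <- list(A, A)                    # F(i) P(i)' = A for both modalities
  L0 <- matrix(0, k, k)
  hp <- mdaParams(alpha = 3, useGraphReg = FALSE)
  expect_equal(updateG(F_, A, L0, P, hp), A, tolerance = 1e-12)

  # alpha -> 0, L = 0: mean of the modality projections
  F2 <- list(matrix(rnorm(k * 2), k, 2), matrix(rnorm(k * 4), k, 4))
  P2 <- list(matrix(runif(l * 2), l, 2), matrix(runif(l * 4), l, 4))
  hp0 <- mdaParams(alpha = 0, useGraphReg = FALSE)
  expect_equal(updateG(F2, A, L0, P2, hp0),
               (tcrossprod(F2[[1]], P2[[1]]) +
                tcrossprod(F2[[2]], P2[[2]])) / 2,
               tolerance = 1e-12)
})

test_that("G update zeroes the subproblem gradient and beats perturbations", {
  for (s in 1:5) {
    inst <- randomInstance(6, 4, seed = s + 30)
    hp <- mdaParams(alpha = 100, lambda = 1e-3)
    G <- updateG(inst$F_, inst$A, inst$L, inst$P, hp)
    gr <- numGradG(G, inst$F_, inst$P, inst$A, inst$L, hp$alpha)
    expect_lt(max(abs(gr)), 1e-8)
    o <- gSubObjective(G, inst$F_, inst$P, inst$A, inst$L, hp$alpha)
    set.seed(s)
    for (r in 1:20) {
      Gp <- G + matrix(rnorm(length(G), sd = 0.1), nrow(G))
      expect_gt(gSubObjective(Gp, inst$F_, inst$P, inst$A, inst$L,
                              hp$alpha), o)
    }
  }
})

test_that("multiplicative P update keeps nonnegativity and fixed points", {
  set.seed(3)
  F_i <- matrix(rnorm(24), 6, 4)
  G <- matrix(rnorm(18), 6, 3)
  P <- matrix(runif(12), 3, 4)
  hp <- mdaParams(lambda = 1e-3)
  P1 <- updateP(F_i, G, P, hp)
  expect_true(all(P1 >= 0))
  expect_equal(updateP(F_i, G, matrix(0, 3, 4), hp), matrix(0, 3, 4))
  expect_error(updateP(F_i, G, -P, hp), "nonnegative")
})

test_that("P updates never increase the P-subproblem objective", {
  for (s in 1:5) {
    set.seed(s + 40)
    F_i <- matrix(rnorm(30), 6, 5)      # contains negatives
    G <- matrix(rnorm(24), 6, 4)
    P <- matrix(runif(20), 4, 5)
    hp <- mdaParams(lambda = 1e-2)
    o <- pSubObjective(P, F_i, G, hp$lambda)
    for (it in 1:50) {
      P <- updateP(F_i, G, P, hp)
      o2 <- pSubObjective(P, F_i, G, hp$lambda)
      expect_lte(o2, o + 1e-8)
      expect_true(all(P >= 0))
      o <- o2
    }
  }
})

test_that("fitView is deterministic, converges, and records a monotone trace", {
  sim <- simulateAssociations(m = 20, n = 8, rank = 2, density = 0.15,
                              seed = 3)
  A <- sim$A
  SM <- gipKernel(A, "microbe"); SD <- gipKernel(A, "disease")
  Aw <- wknknUpdate(A, SM, SD, mdaParams())
  fm <- buildFeatureSet(Aw, SM, "microbe")
  fit1 <- fitView(fm, Aw, SM, mdaParams(), seed = 7)
  fit2 <- fitView(fm, Aw, SM, mdaParams(), seed = 7)
  expect_identical(fit1@G, fit2@G)                   # bitwise determinism
  tr <- objectiveTrace(fit1)
  expect_true(all(diff(tr) <= 1e-8))
  expect_lt(tr[length(tr)], tr[1])
  expect_true(all(vapply(fit1@P, function(p) all(p >= 0), NA)))
})

test_that("fitted objective is robust to the restart seed", {
  sim <- simulateAssociations(m = 20, n = 8, rank = 2, density = 0.15,
                              seed = 11)
  A <- sim$A
  SM <- gipKernel(A, "microbe")
  Aw <- wknknUpdate(A, SM, gipKernel(A, "disease"), mdaParams())
  fm <- buildFeatureSet(Aw, SM, "microbe")
  finals <- vapply(1:10, function(s)
    min(objectiveTrace(fitView(fm, Aw, SM, mdaParams(maxIter = 300),
                               seed = s))), 0)
  expect_lt(max(finals) - min(finals), 0.01 * min(finals))
})

test_that("view fusion averages the aligned latent matrices", {
  Gm <- matrix(rnorm(12), 3, 4)
  mkFit <- function(G, view) new("ViewFit", G = G, P = list(),
                                 objectiveTrace = 1, converged = TRUE,
                                 iterations = 1L, view = view)
  pred <- predictAssociations(mkFit(Gm, "microbe"), mkFit(t(Gm), "disease"))
  expect_equal(scores(pred), Gm)
  predHalf <- predictAssociations(mkFit(Gm, "microbe"),
                                  mkFit(matrix(0, 4, 3), "disease"))
  expect_equal(scores(predHalf), Gm / 2)
  expect_equal(order(scores(predHalf)), order(Gm))  # rank order preserved
  # scalar-loop mean oracle
  Gd <- matrix(rnorm(12), 4, 3)
  got <- scores(predictAssociations(mkFit(Gm, "microbe"),
                                    mkFit(Gd, "disease")))
  for (i in 1:3) for (j in 1:4)
    expect_equal(got[i, j], (Gm[i, j] + Gd[j, i]) / 2)
  expect_error(predictAssociations(mkFit(Gm, "microbe"),
                                   mkFit(matrix(0, 3, 4), "disease")),
               "mismatch")
})

test_that("pipeline recovery beats the degree baseline on average", {
  aucs <- c(); base <- c()
  for (s in 1:3) {
    sim <- simulateAssociations(m = 100, n = 30, rank = 3, density = 0.05,
                                noise = 0, seed = s)
    mk <- maskPositives(sim$A, 0.2, seed = s + 100)
    held <- which(sim$A@.Data == 1 & mk$A@.Data == 0)
    negs <- which(sim$A@.Data == 0)
    S <- scores(mdaPredict(mk$A, mdaParams(), seed = s))
    B <- degreeBaseline(mk$A)
    aucs[s] <- rocAuc(S[held], S[negs])$auc
    base[s] <- rocAuc(B[held], B[negs])$auc
  }
  expect_gt(mean(aucs), mean(base))
  expect_gt(mean(aucs), 0.8)
})
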