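test_that("Bray-Curtis matches the defining formula", {
  m <- rbind(s1 = c(2, 2), s2 = c(4, 0), s3 = c(2, 2), s4 = c(0, 5))
  colnames(m) <- c("a", "b")
  d <- as.matrix(brayCurtis(m, normalize = FALSE))
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s2", "s4"], 1)          # disjoint
  expect_equal(d["s1", "s2"], 0.5)        # 1 - 2*2/8
  expect_true(all(abs(d - t(d)) < 1e-12))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))

  withr::with_seed(31, {
    r <- matrix(rpois(60, 20) + 1, nrow = 6)
    rownames(r) <- paste0("s", 1:6)
    dr <- as.matrix(brayCurtis(r, normalize = FALSE))
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(dr[i, j], oracle_bray(r[i, ], r[j, ]), tolerance = 1e-12)
    }
    # normalization built in equals manual per-sample proportions
    expect_equal(as.matrix(brayCurtis(r)),
                 as.matrix(brayCurtis(r / rowSums(r), normalize = FALSE)),
                 tolerance = 1e-12)
  })
  expect_error(brayCurtis(rbind(s1 = c(1, 1), s2 = c(0, 0))), "s2")
})

test_that("PERMANOVA partitions squared distances like the brute force", {
  withr::with_seed(41, {
    m <- matrix(rnorm(8 * 5), nrow = 8)
    m[5:8, ] <- m[5:8, ] + 2
    rownames(m) <- paste0("s", 1:8)
    d <- dist(m)
    g <- factor(rep(c("x", "y"), each = 4))
    res <- permanova(d, g, exact = TRUE)
    expect_equal(res$pseudo_F, oracle_permanova_F(as.matrix(d), g),
                 tolerance = 1e-10)
    expect_equal(res$p, oracle_permanova_exact_p(as.matrix(d), g))
    expect_equal(res$n_perm, choose(8, 4))
    expect_true(res$R2 >= 0 && res$R2 <= 1)
    # invariant to renaming the groups
    g2 <- factor(rep(c("B", "A"), each = 4))
    expect_equal(permanova(d, g2, exact = TRUE)$pseudo_F, res$pseudo_F)
  })
})

test_that("PERMANOVA degenerate inputs behave per contract", {
  m <- rbind(s1 = c(1, 0), s2 = c(1, 0), s3 = c(1, 0), s4 = c(1, 0))
  d <- brayCurtis(m, normalize = FALSE)
  res <- permanova(d, factor(c("a", "a", "b", "b")), n_perm = 19, seed = 1)
  expect_identical(res$pseudo_F, 0)
  expect_identical(res$p, 1)
  expect_error(permanova(d, factor(paste0("g", 1:4))), "fewer groups")
  expect_error(permanova(d, factor(rep("a", 4))), "at least 2")
})

test_that("PCoA embeds Euclidean configurations exactly", {
  withr::with_seed(51, {
    pts <- matrix(rnorm(14), ncol = 2)
    rownames(pts) <- paste0("s", 1:7)
    d <- dist(pts)
    ord <- pcoaOrdination(d)
    expect_false(ord$constrained)
    d2 <- dist(ord$coordinates[, 1:2])
    expect_equal(as.numeric(d2), as.numeric(d), tolerance = 1e-8)
    # axes ordered by eigenvalue; coordinates centred
    eig <- ord$eigenvalues
    expect_true(all(diff(eig) <= 1e-8))
    expect_true(all(abs(colMeans(ord$coordinates)) < 1e-9))
    # Gower identity: positive eigenvalue mass equals SS_total
    D2 <- as.matrix(d)^2
    expect_equal(sum(eig[eig > 1e-8]), sum(D2) / (2 * nrow(D2)),
                 tolerance = 1e-8)
  })
})

test_that("PCoA symmetry and duplicates", {
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord <- pcoaOrdination(as.dist(d))
  eig <- ord$eigenvalues[ord$eigenvalues > 1e-8]
  expect_identical(length(eig), 2L)
  expect_equal(eig[1], eig[2], tolerance = 1e-10)
  emb <- dist(ord$coordinates)
  expect_equal(max(emb) - min(emb), 0, tolerance = 1e-10)

  m <- rbind(s1 = c(5, 1, 0), s2 = c(5, 1, 0), s3 = c(0, 3, 3),
             s4 = c(1, 1, 4))
  ord2 <- pcoaOrdination(brayCurtis(m, normalize = FALSE))
  expect_equal(ord2$coordinates["s1", ], ord2$coordinates["s2", ],
               tolerance = 1e-8)
})

test_that("CAP separates planted groups and rejects degenerate groupings", {
  withr::with_seed(61, {
    m <- matrix(rpois(16 * 10, 30), nrow = 16)
    m[9:16, 1:3] <- m[9:16, 1:3] + 80
    rownames(m) <- paste0("s", 1:16)
    g <- factor(rep(c("early", "late"), each = 8))
    d <- brayCurtis(m)
    cap <- capOrdination(d, g)
    expect_true(cap$constrained)
    expect_lte(ncol(cap$coordinates), nlevels(g) - 1L)
    a1 <- cap$coordinates[, 1]
    ssb <- sum(tapply(a1, g, function(v) length(v) * mean(v)^2))
    ssw <- sum(tapply(a1, g, function(v) sum((v - mean(v))^2)))
    expect_gt(ssb, ssw)
    expect_error(capOrdination(d, rep("a", 16)), "at least 2")
    expect_error(capOrdination(d, g, n_pcoa_axes = 40), "samples - 1")
  })
})
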