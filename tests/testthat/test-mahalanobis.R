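# Build a measurement table with parent clusters and hybrid individuals at
# chosen positions; three features, several calls per individual.
placement_fixture <- function(hybrid_centers, spread = 0.3, seed = 1) {
  set.seed(seed)
  mk <- function(center, group, ind, n = 6)
    data.frame(group = group, individual = ind,
               duration_s = rnorm(n, center[1], spread),
               q50_hz = rnorm(n, center[2], spread),
               entropy = rnorm(n, center[3], spread))
  parents <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      mk(c(0, 0, 0), "tien_shan", paste0("ts", i)))),
    do.call(rbind, lapply(1:4, function(i)
      mk(c(4, 4, 4), "bank", paste0("bk", i)))))
  hybrids <- do.call(rbind, lapply(seq_along(hybrid_centers), function(i)
    mk(hybrid_centers[[i]], "hybrid", paste0("hy", i))))
  rbind(parents, hybrids)
}

test_that("distances match the explicit quadratic form", {
  d <- placement_fixture(list(c(2, 2, 2), c(3.5, 4.2, 3.8)), seed = 2)
  pl <- mahalanobis_placement(d)
  S <- attr(pl, "pooled_cov")
  mu <- attr(pl, "centroids")
  Sinv <- solve(S)  # oracle: direct inversion and quadratic form
  for (i in seq_len(nrow(pl))) {
    sel <- d$individual == pl$individual[i]
    xm <- colMeans(d[sel, c("duration_s", "q50_hz", "entropy")])
    da <- drop(t(xm - mu[1, ]) %*% Sinv %*% (xm - mu[1, ]))
    db <- drop(t(xm - mu[2, ]) %*% Sinv %*% (xm - mu[2, ]))
    expect_equal(pl$d2_tien_shan[i], da, tolerance = 1e-10)
    expect_equal(pl$d2_bank[i], db, tolerance = 1e-10)
  }
  expect_true(all(pl$d2_tien_shan >= 0 & pl$d2_bank >= 0))
})

test_that("an individual at a parent centroid has zero self-distance", {
  d <- placement_fixture(list(), seed = 3)
  pl0 <- mahalanobis_placement(d)
  mu <- attr(pl0, "centroids")
  # plant a hybrid individual whose calls average exactly to each centroid
  plant <- function(center, ind) {
    base <- data.frame(group = "hybrid", individual = ind,
                       duration_s = center[1] + c(-1, 1) * 0.1,
                       q50_hz = center[2] + c(-1, 1) * 0.1,
                       entropy = center[3] + c(-1, 1) * 0.1)
    base
  }
  d2 <- rbind(d, plant(mu[1, ], "hy_at_a"), plant(mu[2, ], "hy_at_b"))
  pl <- mahalanobis_placement(d2)
  at_a <- pl[pl$individual == "hy_at_a", ]
  at_b <- pl[pl$individual == "hy_at_b", ]
  expect_equal(at_a$d2_tien_shan, 0, tolerance = 1e-10)
  # its distance to the other parent is the centroid separation itself
  Sinv <- solve(attr(pl, "pooled_cov"))
  gap <- drop(t(mu[1, ] - mu[2, ]) %*% Sinv %*% (mu[1, ] - mu[2, ]))
  expect_equal(at_a$d2_bank, gap, tolerance = 1e-10)
  summ <- intermediacy_summary(pl)
  per <- summ$per_individual
  expect_identical(per$nearer[per$individual == "hy_at_b"], "bank")
})

test_that("intermediacy summary flags midpoints and nearer parents", {
  d <- placement_fixture(list(c(2, 2, 2), c(3.8, 3.8, 3.8), c(2.2, 2.2, 2.2)),
                         seed = 4)
  pl <- mahalanobis_placement(d)
  summ <- intermediacy_summary(pl)
  expect_equal(nrow(summ$per_individual), 3)
  expect_identical(summ$per_individual$nearer[2], "bank")
  expect_identical(summ$majority_nearer, "bank")
  # an exact tie is reported as such
  tie <- data.frame(group = "hybrid", individual = "hy_tie",
                    duration_s = 2.05, q50_hz = 2.05, entropy = 2.05)
  # symmetric parent clusters around the midpoint make the tie exact
  o1 <- c(0, 0.2, -0.1, 0.1)
  o2 <- c(0.2, -0.1, 0.1, 0)
  o3 <- c(-0.1, 0.1, 0, 0.2)
  sym <- rbind(
    data.frame(group = "tien_shan",
               individual = rep(c("t1", "t2"), each = 2),
               duration_s = o1, q50_hz = o2, entropy = o3),
    data.frame(group = "bank", individual = rep(c("b1", "b2"), each = 2),
               duration_s = 4 + o1, q50_hz = 4 + o2, entropy = 4 + o3),
    tie)
  pls <- mahalanobis_placement(sym)
  expect_identical(intermediacy_summary(pls)$per_individual$nearer, "tie")
})
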