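test_that("representation filter keeps genes observed in at least the floor fraction", {
  idx <- tiny_index(10)
  vals <- matrix(NA_real_, 3, 10,
                 dimnames = list(c("GA", "GB", "GC"), idx$disease_id))
  vals["GA", 1] <- 0.5                 # present in 1 of 10
  vals["GB", ] <- rnorm(10)            # present in all
  vals["GC", 1:3] <- 1
  fcm10 <- fcm_from_values(vals, idx, min_fraction = 0.10)
  expect_setequal(rownames(fcm10), c("GA", "GB", "GC"))
  fcm20 <- fcm_from_values(vals, idx, min_fraction = 0.20)
  expect_false("GA" %in% rownames(fcm20))
  expect_true(all(c("GB", "GC") %in% rownames(fcm20)))
  # ceiling arithmetic at the published scale: 121 diseases -> floor is 13
  idx121 <- build_index(records_with_ratios(seq_len(121) / 202, n_total = 1000))
  vals121 <- matrix(NA_real_, 2, 121,
                    dimnames = list(c("G12", "G13"), idx121$disease_id))
  vals121["G12", 1:12] <- 1
  vals121["G13", 1:13] <- 1
  fcm121 <- fcm_from_values(vals121, idx121, min_fraction = 0.10)
  expect_identical(rownames(fcm121), "G13")
})

test_that("diseases outside the index are ignored and logged", {
  idx <- tiny_index(5)
  de <- lapply(1:6, function(j) data.frame(gene_id = c("GA", "GB"),
                                           fold_change = rnorm(2)))
  names(de) <- c(idx$disease_id, "D_unknown")
  fcm <- assemble_matrix(de, idx, min_fraction = 0.1)
  expect_identical(colnames(fcm), idx$disease_id)
  expect_identical(attr(fcm, "dropped_diseases"), "D_unknown")
})

test_that("retained/q columns gate which fold changes enter the matrix", {
  idx <- tiny_index(4)
  de <- lapply(1:4, function(j) {
    data.frame(gene_id = c("GA", "GB"), fold_change = c(1, 2),
               q = c(0.01, 0.5))
  })
  names(de) <- idx$disease_id
  fcm <- assemble_matrix(de, idx, min_fraction = 0.1)
  expect_false("GB" %in% rownames(fcm))     # q > 0.05 everywhere
  expect_equal(sum(!is.na(fcm["GA", ])), 4L)
})

test_that("Spearman screen matches hand-computed coefficients", {
  idx <- tiny_index(3)
  vals <- rbind(up = c(0.1, 0.5, 0.9),
                down = c(0.9, 0.5, 0.1),
                mid = c(1, 3, 2))
  colnames(vals) <- idx$disease_id
  fcm <- fcm_from_values(vals, idx)
  sc <- gene_index_correlation(fcm, idx)
  got <- setNames(sc$rho, sc$gene_id)
  expect_equal(unname(got[c("up", "down", "mid")]), c(1, -1, 0.5))
  # exact Sum d^2 formula on a larger tie-free case
  set.seed(14)
  idx2 <- tiny_index(9)
  v2 <- matrix(rnorm(5 * 9), 5, 9, dimnames = list(NULL, idx2$disease_id))
  fcm2 <- fcm_from_values(v2, idx2)
  sc2 <- gene_index_correlation(fcm2, idx2)
  for (g in 1:5) {
    d <- rank(v2[g, ]) - rank(idx2$midrank)
    expect_equal(sc2$rho[g], 1 - 6 * sum(d^2) / (9 * (9^2 - 1)))
  }
})

test_that("genes observed in fewer than 3 diseases are excluded from scoring", {
  idx <- tiny_index(6)
  vals <- matrix(rnorm(12), 2, 6, dimnames = list(c("GA", "GB"), idx$disease_id))
  vals["GB", 3:6] <- NA
  fcm <- fcm_from_values(vals, idx)
  sc <- gene_index_correlation(fcm, idx)
  expect_true(is.na(sc$rho[sc$gene_id == "GB"]))
  pf <- permutation_pfdr(fcm, idx, n_perm = 120, seed = 1)
  expect_true(is.na(pf$pfdr[pf$gene_id == "GB"]))
})

test_that("rho is invariant under strictly increasing fold-change transforms", {
  set.seed(3)
  idx <- tiny_index(12)
  v <- matrix(rnorm(8 * 12), 8, 12, dimnames = list(NULL, idx$disease_id))
  v[sample(length(v), 20)] <- NA
  a <- gene_index_correlation(fcm_from_values(v, idx), idx)
  b <- gene_index_correlation(fcm_from_values(exp(v), idx), idx)
  expect_equal(a$rho, b$rho, tolerance = 1e-12)
})

test_that("a perfectly monotone gene among noise reaches pfdr below 0.01", {
  set.seed(21)
  idx <- tiny_index(20)
  v <- matrix(rnorm(20 * 20), 20, 20, dimnames = list(NULL, idx$disease_id))
  v[1, ] <- seq_len(20)               # monotone in index order
  fcm <- fcm_from_values(v, idx)
  pf <- permutation_pfdr(fcm, idx, n_perm = 500, seed = 9)
  expect_lt(pf$pfdr[1], 0.01)
  expect_true(all(pf$pfdr >= 0 & pf$pfdr <= 1))
  # monotone enforcement: pfdr nonincreasing in |rho|
  ord <- order(abs(pf$rho), decreasing = TRUE)
  expect_true(all(diff(pf$pfdr[ord]) >= -1e-12))
})

test_that("pure-noise genes have unremarkable pfdr on average", {
  set.seed(4)
  idx <- tiny_index(15)
  v <- matrix(rnorm(30 * 15), 30, 15, dimnames = list(NULL, idx$disease_id))
  pf <- permutation_pfdr(fcm_from_values(v, idx), idx, n_perm = 300, seed = 2)
  expect_gt(mean(pf$pfdr), 0.3)
  expect_lt(mean(pf$pfdr < 0.01), 0.1)
})

test_that("pfdr is reproducible under a fixed seed and stable across seeds", {
  set.seed(6)
  idx <- tiny_index(12)
  v <- matrix(rnorm(40 * 12), 40, 12, dimnames = list(NULL, idx$disease_id))
  v[1:3, ] <- v[1:3, ] + outer(c(0.3, 0.4, 0.5), scale(seq_len(12))[, 1])
  fcm <- fcm_from_values(v, idx)
  a <- permutation_pfdr(fcm, idx, n_perm = 1000, seed = 11)
  b <- permutation_pfdr(fcm, idx, n_perm = 1000, seed = 11)
  expect_identical(a, b)
  c2 <- permutation_pfdr(fcm, idx, n_perm = 1000, seed = 99)
  expect_lt(max(abs(a$pfdr - c2$pfdr)), 0.1)
})

test_that("candidate selection filters, orders and signs the gene list", {
  scores <- data.frame(gene_id = c("A", "B", "C", "D"),
                       rho = c(0.9, -0.8, 0.2, -0.95),
                       n_obs = 10L, p_raw = 0.01,
                       pfdr = c(0.001, 0.005, 0.5, 1))
  sel <- select_candidates(scores, alpha = 0.01)
  expect_identical(sel$gene_id, c("A", "B"))
  expect_identical(sel$direction, c("positive", "negative"))
  expect_identical(nrow(select_candidates(transform(scores, pfdr = 1))), 0L)
  expect_identical(nrow(select_candidates(scores, alpha = 1.01)), 4L)
})
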