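test_that("gene dichotomization splits at the median with the documented tie rule", {
  expect_identical(binarize_gene(c(1, 2, 3, 4)), c(-1L, -1L, 1L, 1L))
  # odd n: the median sample goes to -1
  expect_identical(binarize_gene(c(1, 2, 3)), c(-1L, -1L, 1L))
  # constant gene: all -1 (uninformative)
  expect_identical(binarize_gene(c(5, 5, 5, 5)), rep(-1L, 4))
  # rank invariance under strictly monotone transforms
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1))
    expect_identical(binarize_gene(x), binarize_gene(2^x))
    expect_identical(binarize_gene(x), binarize_gene(exp(x)))
  }
  expect_error(binarize_gene(c(1)), "length >= 2")
})

test_that("signature score sums gene contributions; worked example gives all zeros", {
  mat <- toy_matrix(c(1, 2, 3, 4,
                      4, 3, 2, 1),
                    c("g1", "g2"), sprintf("s%d", 1:4))
  expect_warning(st <- signature_score(mat, c("g1", "g2")),
                 "all scores identical")
  expect_identical(st$score, rep(0L, 4))
  expect_identical(st$n_genes_used, rep(2L, 4))
  expect_true(all(is.na(st$group)))

  # single-gene signature: every score in {-1, +1}
  st1 <- signature_score(mat, "g1")
  expect_true(all(st1$score %in% c(-1L, 1L)))
  expect_identical(st1$n_genes_used, rep(1L, 4))

  # missing genes dropped, not imputed; none present is an error
  st2 <- signature_score(mat, c("g1", "nope"))
  expect_identical(st2$n_genes_used, rep(1L, 4))
  expect_error(signature_score(mat, c("nope1", "nope2")), "no signature gene")
})

test_that("score invariants: zero-sum, parity, monotone invariance, permutation equivariance", {
  set.seed(99)
  for (i in 1:25) {
    n_genes <- sample(3:12, 1)
    n_samples <- 2 * sample(3:10, 1)  # even cohort
    mat <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
                  dimnames = list(paste0("g", seq_len(n_genes)),
                                  paste0("s", seq_len(n_samples))))
    sig <- rownames(mat)
    st <- suppressWarnings(signature_score(mat, sig))
    # zero-sum with even n and no within-gene ties
    expect_identical(sum(st$score), 0L)
    # parity: score and n_genes_used share parity
    expect_true(all((st$score - st$n_genes_used) %% 2L == 0L))
    # monotone invariance
    st_t <- suppressWarnings(signature_score(2^mat, sig))
    expect_identical(st$score, st_t$score)
    # permutation equivariance
    perm <- sample(n_samples)
    st_p <- suppressWarnings(signature_score(mat[, perm], sig))
    expect_identical(st_p$score,
                     st$score[match(st_p$sample_id, st$sample_id)])
  }
})

test_that("high/low groups split strictly above the median score", {
  expect_identical(assign_groups(c(-3, -1, 1, 3)),
                   c("low", "low", "high", "high"))
  expect_identical(assign_groups(c(-1, 0, 2)), c("low", "low", "high"))
  expect_error(assign_groups(c(1, 1, 1)), "identical")
})

test_that("gene-score correlation screen keeps positive correlates passing both cuts", {
  set.seed(7)
  n <- 60
  score <- rnorm(n)
  mat <- rbind(
    mirror = score,
    anti = -score,
    flat = rep(1, n),
    noise = rnorm(n))
  colnames(mat) <- paste0("s", 1:n)
  got <- correlate_genes_with_score(mat, setNames(score, colnames(mat)))
  expect_true("mirror" %in% got$gene_id)
  expect_equal(got$r[got$gene_id == "mirror"], 1)
  # strong negative correlate excluded by the one-sided r cut
  expect_false("anti" %in% got$gene_id)
  # constant gene excluded (undefined r)
  expect_false("flat" %in% got$gene_id)
  # sorted by descending r
  expect_identical(got$r, sort(got$r, decreasing = TRUE))
})

test_that("under the null about half of the 5% false positives pass the one-sided screen", {
  set.seed(17)
  n <- 200
  n_genes <- 2000
  score <- rnorm(n)
  mat <- matrix(rnorm(n_genes * n), nrow = n_genes,
                dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:n)))
  got <- correlate_genes_with_score(mat, setNames(score, colnames(mat)),
                                    r_threshold = 0.05, p_threshold = 0.05)
  frac <- nrow(got) / n_genes
  # expected 2.5%, Monte-Carlo 3-sigma band
  expect_lt(abs(frac - 0.025), 3 * sqrt(0.025 * 0.975 / n_genes))
})
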