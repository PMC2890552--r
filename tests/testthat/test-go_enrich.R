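test_that("Z score equals exact hypergeometric standardization", {
  # centered case: r at the hypergeometric mean
  expect_equal(z_score(1, 10, 10, 100), 0)
  # enumeration-derived example: N=20, R=5, n=4 has mean 1, var 0.63158
  hm <- hyper_moments(20, 5, 4)
  expect_equal(hm$mean, 1)
  expect_equal(hm$sd^2, 12 / 19, tolerance = 1e-12)
  expect_equal(z_score(3, 4, 5, 20), (3 - 1) / hm$sd)
  expect_equal(z_score(3, 4, 5, 20), 2.5166, tolerance = 1e-4)
  # r = n = R against a large background
  hm <- hyper_moments(1000, 5, 5)
  z <- z_score(5, 5, 5, 1000)
  expect_gt(z, 0)
  expect_equal(z, (5 - hm$mean) / hm$sd)
  # degenerate nulls are defined as 0 with a warning
  expect_warning(z0 <- z_score(3, 3, 0, 10), "zero-variance")
  expect_equal(z0, 0)
})

test_that("Z score sweep agrees with enumeration over a grid of small N", {
  for (N in c(5, 12, 23)) {
    for (R in c(1, floor(N / 3), N - 1)) {
      for (n in c(1, floor(N / 2), N - 1)) {
        if (n >= N) next
        hm <- hyper_moments(N, R, n)
        for (r in max(0, n - (N - R)):min(n, R)) {
          expect_equal(z_score(r, n, R, N), (r - hm$mean) / hm$sd,
                       tolerance = 1e-12,
                       label = sprintf("N=%d R=%d n=%d r=%d", N, R, n, r))
        }
      }
    }
  }
})

test_that("permutation p is deterministic, bounded away from 0, and tracks the hypergeometric tail", {
  set.seed(30)
  ann <- data.frame(
    gene_id = sprintf("g%03d", sample(100, 300, replace = TRUE)),
    term_id = sprintf("T%02d", sample(8, 300, replace = TRUE)))
  ann <- unique(ann)
  changed <- sprintf("g%03d", sample(100, 20))
  a <- permutation_p(ann, changed, n_perm = 2000, seed = 9)
  b <- permutation_p(ann, changed, n_perm = 2000, seed = 9)
  expect_identical(a, b)
  expect_true(all(a$permute_p >= 1 / 2001))

  # the label permutation draws r from the hypergeometric, and z is
  # monotone in r, so p should match the exact tail within Monte Carlo
  # error (3 sigma binomial)
  N <- length(unique(ann$gene_id))
  R <- sum(unique(ann$gene_id) %in% changed)
  for (i in seq_len(nrow(a))) {
    tail_p <- phyper(a$n_changed[i] - 1, R, N - R, a$n_measured[i],
                     lower.tail = FALSE)
    mc_se <- sqrt(tail_p * (1 - tail_p) / 2000)
    expect_lt(abs(a$permute_p[i] - tail_p), 3 * mc_se + 2 / 2001)
  }
})

test_that("a term holding every changed gene is significant; z=0 terms are not", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:100)
  changed <- genes[1:5]
  ann <- rbind(
    data.frame(gene_id = changed, term_id = "T_hit"),
    data.frame(gene_id = sample(genes, 60), term_id = "T_bg"))
  ann <- unique(ann)
  res <- permutation_p(ann, changed, n_perm = 2000, seed = 4)
  expect_lte(res$permute_p[res$term_id == "T_hit"], 0.01)

  # observed z = 0 -> p >= 0.5: N=100, R=10, term n=10 with r=1 (the mean)
  ann0 <- rbind(data.frame(gene_id = genes, term_id = "T_bg"),
                data.frame(gene_id = c(genes[1], genes[12:20]),
                           term_id = "T_mid"))
  res0 <- permutation_p(ann0, genes[1:10], n_perm = 1000, seed = 2)
  mid <- res0[res0$term_id == "T_mid", ]
  expect_equal(mid$z_score, 0)
  expect_gte(mid$permute_p, 0.5)
})

test_that("ranked filter applies all four criteria with the stated boundaries", {
  rows <- data.frame(
    term_id = c("keep", "low_r", "boundary_pct", "low_z", "high_p"),
    n_changed = c(8, 1, 3, 5, 6),
    n_measured = c(22, 2, 30, 20, 20),
    z_score = c(5.2, 8, 4, 1.9, 4),
    permute_p = c(0.0005, 0.001, 0.001, 0.001, 0.02))
  out <- rank_and_filter(rows)
  expect_equal(out$term_id, "keep")
  expect_equal(out$percent_changed, 100 * 8 / 22)

  # strict 10% boundary
  b <- data.frame(term_id = "b", n_changed = 2, n_measured = 20,
                  z_score = 3, permute_p = 0.001)
  expect_equal(nrow(rank_and_filter(b)), 0)   # exactly 10.0% -> dropped

  # ordering: p ascending, ties by z descending
  many <- data.frame(term_id = c("a", "b", "c"),
                     n_changed = c(4, 4, 4), n_measured = c(10, 10, 10),
                     z_score = c(3, 5, 4), permute_p = c(0.005, 0.001, 0.001))
  expect_equal(rank_and_filter(many)$term_id, c("b", "c", "a"))
})

test_that("annotation rollup propagates through chains and diamonds, rejects cycles", {
  ann <- data.frame(gene_id = "g1", term_id = "C")
  chain <- data.frame(child = c("C", "B"), parent = c("B", "A"))
  out <- rollup_annotations(ann, chain)
  expect_setequal(out$term_id, c("A", "B", "C"))

  # idempotent
  expect_equal(rollup_annotations(out, chain), out)

  # no edges -> identity (set semantics)
  expect_equal(rollup_annotations(ann, chain[0, ]), ann)

  # diamond: gene counted once per ancestor
  diamond <- data.frame(child = c("D", "D", "B", "C"),
                        parent = c("B", "C", "A", "A"))
  out <- rollup_annotations(data.frame(gene_id = "g1", term_id = "D"),
                            diamond)
  expect_equal(sum(out$term_id == "A"), 1)
  expect_setequal(out$term_id, c("A", "B", "C", "D"))

  cyc <- data.frame(child = c("A", "B"), parent = c("B", "A"))
  expect_error(rollup_annotations(ann, cyc), "cycle")
})

test_that("a planted enriched term is recovered by the full filter", {
  hits <- 0
  for (seed in 1:20) {
    g <- gen_go_annotation(n_genes = 500, n_terms = 30, seed = seed)
    res <- go_enrichment(g$annotation, sprintf("g%04d", 1:500), g$changed,
                         n_perm = 1000, seed = seed)
    if (g$truth$planted_term %in% res$ranked$term_id) hits <- hits + 1
  }
  expect_gte(hits, 19)
})
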