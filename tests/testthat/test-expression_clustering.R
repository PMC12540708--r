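# DEG filtering, profile scaling, k-means clustering, JNK-dependence
# assignment, overlaps and half-life cross-referencing.

test_that("the DEG filter applies all four criteria jointly", {
  tab <- toy_deg_table()
  expect_identical(filter_degs(tab), "g1")
  expect_identical(filter_degs(tab[0, ]), character(0))
  # significant at a single late timepoint is enough
  late <- tab[1, ]
  late$gene_id <- "g7"
  late[paste0("log2fc_", c(2, 4, 6, 8), "h")] <- c(0.1, 0.2, -1.4, 0.3)
  expect_identical(filter_degs(rbind(tab, late)), c("g1", "g7"))
  expect_error(filter_degs(tab[, setdiff(names(tab), "fdr")]), "fdr")
})

test_that("the filter is idempotent and order-independent", {
  g <- gen_deg_table(300, c(fdr = 0.7, log2fc = 0.7, max_group_mean = 0.7,
                            biotype = 0.8), seed = 2)
  hit <- filter_degs(g$table)
  expect_setequal(hit, g$expected)
  shuffled <- g$table[sample(nrow(g$table)), ]
  expect_setequal(filter_degs(shuffled), hit)
  expect_setequal(filter_degs(g$table[g$table$gene_id %in% hit, ]), hit)
})

test_that("profile matrices anchor t=0 and scale per gene", {
  tab <- toy_deg_table()[1, ]
  tab[paste0("log2fc_", c(2, 4, 6, 8), "h")] <- c(1, 2, 3, 4)
  M <- build_profile_matrix(tab, "g1")
  expect_equal(unname(M[1, ]), c(0, 0.25, 0.5, 0.75, 1))
  tab[paste0("log2fc_", c(2, 4, 6, 8), "h")] <- 0
  expect_equal(unname(build_profile_matrix(tab, "g1")[1, ]), rep(0, 5))
  big <- gen_archetype_deg_table(seed = 4)
  genes <- filter_degs(big$table)
  Mb <- build_profile_matrix(big$table, genes)
  expect_identical(nrow(Mb), length(genes))
  # per-row scaling preserves the peak timepoint
  raw <- cbind(0, as.matrix(big$table[match(genes, big$table$gene_id),
                                      paste0("log2fc_", c(2, 4, 6, 8), "h")]))
  expect_equal(unname(apply(Mb, 1, which.max)),
               unname(apply(raw, 1, which.max)))
  expect_error(build_profile_matrix(big$table, "absent_gene"), "absent")
})

test_that("k selection finds the three archetypes and flags degeneracy", {
  adt <- gen_archetype_deg_table(seed = 3)
  M <- build_profile_matrix(adt$table, filter_degs(adt$table))
  ck <- choose_k(M, 2:6, seed = 1)
  expect_identical(ck$k, 3L)
  expect_identical(nrow(ck$diagnostics), 5L)
  expect_false(ck$degenerate)

  flat <- matrix(0.5, 30, 5)
  ckd <- choose_k(flat, 2:5, seed = 1)
  expect_true(ckd$degenerate)
  expect_identical(ckd$k, 2L)
  expect_error(choose_k(M[1:5, ], 2:10), "too few")
})

test_that("clustering recovers archetype membership across seeds", {
  adt <- gen_archetype_deg_table(seed = 3)
  M <- build_profile_matrix(adt$table, filter_degs(adt$table))
  truth <- adt$truth$archetype[match(rownames(M), adt$truth$gene_id)]
  for (sd in 1:5) {
    cs <- cluster_genes(M, 3, seed = sd)
    expect_gt(ari(cs$labels, truth), 0.9)
    agree <- max(table(cs$labels, truth)) # plurality within each archetype
    tabm <- table(truth, cs$labels)
    expect_gte(sum(apply(tabm, 1, max)) / length(truth), 0.95)
  }
  expect_identical(cluster_genes(M, 3, seed = 2)$labels,
                   cluster_genes(M, 3, seed = 2)$labels)
  # one cluster per gene in the degenerate k = n case
  small <- M[1:6, ]
  cs6 <- cluster_genes(small, 6, seed = 1)
  expect_identical(sort(unname(cs6$labels)), 1:6)
})

test_that("cluster labels are ordered by descending peak time", {
  adt <- gen_archetype_deg_table(seed = 6)
  M <- build_profile_matrix(adt$table, filter_degs(adt$table))
  cs <- cluster_genes(M, 3, seed = 1, condition = "sustained")
  peaks <- cs$timepoints[apply(cs$centers, 1, which.max)]
  expect_true(all(diff(peaks) <= 0))
  prof <- cluster_profile(cs, 1)
  expect_s3_class(prof, "expression_profile")
  expect_equal(range(prof$values), c(0, 1))
})

test_that("JNK-dependent genes are thresholded and tallied per cluster", {
  contrast <- data.frame(
    gene_id = paste0("g", 1:5),
    log2fc_2h = c(2, 0.5, -1.5, 0.2, 0.9),
    log2fc_8h = c(0.1, 0.3, 0.2, 0.4, 0.5)
  )
  jd <- jnk_dependent_genes(contrast)
  expect_setequal(jd$genes, c("g1", "g3"))
  expect_setequal(jnk_dependent_genes(
    within(contrast, {log2fc_2h <- 0; log2fc_8h <- 0}))$genes, character(0))
  expect_identical(jnk_dependent_genes(contrast, signed = TRUE)$genes, "g1")

  labels <- setNames(c(1L, 1L, 2L, 2L, 2L), paste0("g", 1:5))
  cs <- structure(list(k = 2L, labels = labels), class = "cluster_set")
  jd2 <- jnk_dependent_genes(contrast, cs)
  expect_identical(sum(jd2$per_cluster),
                   length(intersect(jd2$genes, names(labels))))
  expect_error(jnk_dependent_genes(data.frame(gene_id = "g")), "log2fc")
})

test_that("overlap metrics follow set arithmetic and are symmetric", {
  a <- as.character(1:10)
  b <- as.character(6:15)
  ov <- cluster_overlap(a, b)
  expect_equal(ov$jaccard, 5 / 15)
  expect_equal(ov$frac_a, 0.5)
  expect_equal(ov$frac_b, 0.5)
  expect_equal(ov$headline_fraction, 0.5)
  expect_equal(cluster_overlap(a, a)[c("jaccard", "frac_a", "frac_b")],
               list(jaccard = 1, frac_a = 1, frac_b = 1))
  disj <- cluster_overlap(a, as.character(20:25))
  expect_equal(disj$jaccard, 0)
  expect_equal(cluster_overlap(b, a)$jaccard, ov$jaccard)
  expect_error(cluster_overlap(character(0), a), "non-empty")
})

test_that("half-life cross-referencing averages matches and keeps gaps", {
  labels <- setNames(c(1L, 1L, 2L), c("g1", "g2", "g3"))
  cs <- structure(list(k = 2L, labels = labels), class = "cluster_set")
  tabs <- data.frame(
    study_id = c("A", "A", "B"),
    gene_id = c("g1", "g2", "g1"),
    half_life_h = c(2, 4, 6)
  )
  xr <- crossref_halflives(cs, tabs)
  expect_identical(nrow(xr), 4L)             # 2 clusters x 2 studies
  a1 <- xr[xr$cluster == 1 & xr$study_id == "A", ]
  expect_equal(a1$mean_half_life_h, 3)
  expect_identical(a1$n_matched, 2L)
  expect_true(is.na(xr$mean_half_life_h[xr$cluster == 2 & xr$study_id == "B"]))
  expect_error(crossref_halflives(cs, list()), "at least one")
})
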