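cfg <- synthetic_config(seed = 3)

test_that("generators are byte-identical under a fixed seed and change with it", {
  expect_identical(gen_expression_studies(cfg), gen_expression_studies(cfg))
  expect_identical(gen_tumor_normal_matrix(cfg), gen_tumor_normal_matrix(cfg))
  expect_identical(gen_target_votes(cfg), gen_target_votes(cfg))
  expect_identical(gen_ppi(cfg), gen_ppi(cfg))
  expect_identical(gen_pathways(cfg), gen_pathways(cfg))
  expect_identical(gen_sequences(cfg), gen_sequences(cfg))
  expect_identical(gen_clinical(cfg), gen_clinical(cfg))
  cfg2 <- synthetic_config(seed = 4)
  expect_false(identical(gen_tumor_normal_matrix(cfg)$study$values,
                         gen_tumor_normal_matrix(cfg2)$study$values))
  # generator calls do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_ppi(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("config validation rejects degenerate settings", {
  expect_error(synthetic_config(sigma = 0), "sigma")
  expect_error(synthetic_config(study_n_tumor = 1), "group sizes")
  expect_error(synthetic_config(de_fraction = 1.2), "de_fraction")
  expect_error(synthetic_config(hub_module_size = 200, graph_nodes = 100),
               "hub_module_size")
  expect_error(synthetic_config(de_fraction = 1e-5), "fit inside")
  expect_error(synthetic_config(de_fraction = 0.02, hub_module_size = 25L),
               "fit inside")
})

test_that("planted truth partitions the universe with the exact DE count", {
  truth <- planted_truth(cfg)
  n_de <- floor(cfg$de_fraction * cfg$n_genes)
  expect_identical(length(truth$de_genes), as.integer(n_de))
  expect_true(all(truth$anchors %in% truth$module))
  expect_true(all(truth$module %in% truth$de_genes))
  expect_true(all(truth$de_genes %in% truth$genes))
  tn <- gen_tumor_normal_matrix(cfg)
  expect_setequal(c(tn$truth$de_genes, setdiff(truth$genes, tn$truth$de_genes)),
                  truth$genes)
})

test_that("null-marker studies give per-study effects near zero", {
  cfg0 <- synthetic_config(seed = 8, planted_smd = 0,
                           study_n_tumor = 150, study_n_normal = 150)
  eff <- study_effects(gen_expression_studies(cfg0))
  expect_true(all(abs(eff$g) < 0.4))
})

test_that("target votes hit the binomial operating point", {
  # perfect databases: 12 votes on targets, 0 elsewhere
  cfgp <- synthetic_config(seed = 1, db_sensitivity = 1, db_specificity = 1)
  v <- gen_target_votes(cfgp)
  truth <- planted_truth(cfgp)
  expect_true(all(rowSums(v)[truth$targets] == cfgp$n_databases))
  expect_true(all(rowSums(v)[setdiff(truth$genes, truth$targets)] == 0))
  # sensitivity 0.7: recall at the >=5-vote rule ~ P(Binom(12, 0.7) >= 5)
  cfg7 <- synthetic_config(seed = 2, db_sensitivity = 0.7, n_genes = 4000,
                           de_fraction = 0.25)
  v7 <- gen_target_votes(cfg7)
  t7 <- planted_truth(cfg7)
  recall <- mean(rowSums(v7)[t7$targets] >= 5)
  expect_equal(recall, pbinom(4, 12, 0.7, lower.tail = FALSE), tolerance = 0.02)
  # specificity 0.9: non-target pass rate ~ P(Binom(12, 0.1) >= 5) ~ 2.8e-3
  cfg9 <- synthetic_config(seed = 2, db_specificity = 0.9, n_genes = 4000)
  v9 <- gen_target_votes(cfg9)
  t9 <- planted_truth(cfg9)
  fp <- mean(rowSums(v9)[setdiff(t9$genes, t9$targets)] >= 5)
  expect_lt(abs(fp - pbinom(4, 12, 0.1, lower.tail = FALSE)), 5e-3)
})

test_that("the interaction graph is simple and its planted module dominates degree", {
  ppi <- gen_ppi(cfg)
  key <- paste(ppi$edges$node_a, ppi$edges$node_b)
  expect_false(any(duplicated(key)))
  expect_false(any(ppi$edges$node_a == ppi$edges$node_b))
  expect_true(all(ppi$edges$score >= 0 & ppi$edges$score <= 1))
  g <- filter_edges(ppi_graph(ppi$edges))
  deg <- igraph::degree(g)
  top15 <- names(sort(deg, decreasing = TRUE))[1:15]
  expect_gte(length(intersect(top15, ppi$truth$module)), 13)
})

test_that("pathway collections respect sizes, anchors and overlap controls", {
  pw <- gen_pathways(cfg)
  truth <- attr(pw, "truth")
  expect_identical(length(pw), cfg$n_pathways)
  anchors <- planted_truth(cfg)$anchors
  for (p in truth$designated) expect_true(all(anchors %in% pw[[p]]))
  # anchors' common pathways are exactly the designated trio
  common <- Reduce(intersect, lapply(anchors, function(a) {
    names(pw)[vapply(pw, function(s) a %in% s, logical(1))]
  }))
  expect_setequal(common, truth$designated)
  sizes <- lengths(pw)
  expect_true(all(sizes >= cfg$pathway_size_range[1]))
  # zero overlap rate disconnects the cluster pathways' shared pool
  cfg0 <- synthetic_config(seed = 3, overlap_rate = 0)
  pw0 <- gen_pathways(cfg0)
  expect_equal(length(intersect(pw0$P04, pw0$P05)), 0)
})

test_that("planted seed sites are exact, AU-embedded, and absent from negatives", {
  sq <- gen_sequences(cfg)
  site <- rna_revcomp(substr(sq$mirna, 2, 8))
  expect_identical(site, "GCACUUU")
  for (id in unique(sq$truth$utr_id)) {
    planted <- sq$truth$start[sq$truth$utr_id == id]
    found <- seed_sites(sq$mirna, sq$utrs[[id]])$start
    expect_identical(found, planted)
    for (st in planted) {
      window <- substr(sq$utrs[[id]], st - 4, st + 12)  # planted 17-nt window
      expect_gte(au_fraction(window), 0.6)
    }
  }
  negatives <- setdiff(names(sq$utrs), sq$truth$utr_id)
  expect_gt(length(negatives), 0)
  for (id in negatives) {
    expect_identical(nrow(seed_sites(sq$mirna, sq$utrs[[id]])), 0L)
  }
  expect_error(gen_sequences(cfg, mirna = "UAAAGXGC"), "invalid")
  expect_error(gen_sequences(cfg, mirna = "UAAAGU"), "shorter")
})

test_that("clinical covariates carry one expression-dependent item and null survival", {
  clin <- gen_clinical(cfg)
  marker <- attr(clin, "marker")
  expect_identical(nrow(clin), cfg$n_clinical)
  kw <- kruskal.test(marker, clin$lymph_nodes)
  expect_lt(kw$p.value, 0.05)
  # independent covariates stay null in aggregate over replicates
  ps <- vapply(1:30, function(s) {
    cl <- gen_clinical(synthetic_config(seed = 100 + s))
    kruskal.test(attr(cl, "marker"), cl$race)$p.value
  }, numeric(1))
  expect_gt(mean(ps), 0.3)  # roughly uniform, mean ~ 0.5
  expect_lt(mean(ps < 0.05), 0.3)
  # survival independent of expression: Cox coefficient near zero on average
  co <- vapply(1:10, function(s) {
    cl <- gen_clinical(synthetic_config(seed = 200 + s))
    fit <- survival::coxph(survival::Surv(cl$os_time, cl$os_status) ~ attr(cl, "marker"))
    unname(coef(fit))
  }, numeric(1))
  expect_lt(abs(mean(co)), 0.1)
})

test_that("validation cohorts shift only the anchor genes", {
  vs <- gen_validation_studies(cfg)
  truth <- planted_truth(cfg)
  expect_identical(length(vs), cfg$n_validation_studies)
  pv <- gene_study_pvals(vs[1:2])
  anchor_p <- pv[truth$anchors, ]
  expect_true(all(anchor_p < 1e-3))
  null_p <- pv[setdiff(rownames(pv), truth$anchors), 1]
  expect_gt(mean(null_p), 0.4)  # approximately uniform
})
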