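# small hand-built fit: 2 TFs, 4 target genes + the TF transcript rows
signing_fixture <- function() {
  stages <- c("c0", sprintf("s%d", 1:5))
  A <- rbind(TFa = c(0, 1, 2, 1.5, 0.5, 0.2),
             TFb = c(0, -0.5, -1, 0.5, 1, 1.5))
  colnames(A) <- stages
  S <- rbind(gPos = c(0.9, 0),      # follows TFa
             gNeg = c(-0.8, 0),     # mirrors TFa
             gB   = c(0, 0.7),
             gBoth = c(0.5, -0.4),
             TFa = c(1, 0),
             TFb = c(0, 1))
  colnames(S) <- rownames(A)
  E <- expression_matrix(S %*% A, "c0")
  list(fit = fake_fit(S, A, unclass(E), "c0"), E = E, S = S, A = A)
}

test_that("edge signs follow the TF-target expression correlation", {
  fx <- signing_fixture()
  edges <- assign_edge_signs(fx$fit, fx$E)
  look <- function(tf, g) edges[edges$tf == tf & edges$gene == g, ]
  expect_equal(look("TFa", "gPos")$sign, 1L)
  expect_gt(look("TFa", "gPos")$correlation, 0.9)
  expect_equal(look("TFa", "gNeg")$sign, -1L)
  expect_lt(look("TFa", "gNeg")$correlation, -0.9)
  expect_false(any(look("TFa", "gPos")$tie_break))
  # zero/undefined correlation falls back to the fitted-strength sign
  fit2 <- fx$fit
  E2 <- unclass(fx$E)
  E2["gB", ] <- 0                             # constant profile -> undefined r
  fit2$E <- E2
  E2x <- expression_matrix(E2, "c0")
  edges2 <- assign_edge_signs(fit2, E2x)
  gB <- edges2[edges2$gene == "gB" & edges2$tf == "TFb", ]
  expect_true(gB$tie_break)
  expect_equal(gB$sign, as.integer(sign(fx$S["gB", "TFb"])))
  # missing TF expression row errors
  E3 <- fx$E[setdiff(rownames(fx$E), "TFb"), ]
  E3 <- expression_matrix(unclass(E3), "c0")
  expect_error(assign_edge_signs(fx$fit, E3), "TFb")
})

test_that("edge signs are invariant to positive rescaling of expression rows", {
  fx <- signing_fixture()
  scaled <- unclass(fx$E) * rep(runif(nrow(fx$E), 0.5, 4), ncol(fx$E))
  Es <- expression_matrix(scaled, "c0")
  expect_equal(assign_edge_signs(fx$fit, Es)$sign,
               assign_edge_signs(fx$fit, fx$E)$sign)
})

test_that("strength clustering groups shared regulator profiles", {
  S <- rbind(g1 = c(0.8, 0, 0), g2 = c(0.8, 0, 0),
             g3 = c(0, -0.9, 0), g4 = c(0, 0, 0.7))
  colnames(S) <- sprintf("t%d", 1:3)
  cl <- cluster_by_strength(S, k = 3)
  expect_equal(cl[["g1"]], cl[["g2"]])
  expect_length(unique(cl[c("g2", "g3", "g4")]), 3)
  expect_error(cluster_by_strength(S, k = 10), "more clusters")

  # planted regulator-profile groups recovered (ARI vs truth)
  set.seed(64)
  groups <- rep(1:3, each = 12)
  Sp <- matrix(0, 36, 3, dimnames = list(sprintf("g%02d", 1:36), sprintf("t%d", 1:3)))
  for (i in seq_along(groups))
    Sp[i, groups[i]] <- runif(1, 0.6, 1)   # shared signed regulator profile
  Sp <- Sp + matrix(rnorm(length(Sp), sd = 0.02), nrow(Sp))
  clp <- cluster_by_strength(Sp, k = 3)
  expect_gte(mclust::adjustedRandIndex(clp, groups), 0.9)
})

test_that("activity-expression agreement uses the 0.5 buckets", {
  stages <- c("c0", sprintf("s%d", 1:4))
  A <- rbind(TFa = c(0, 1, 2, 3, 4), TFb = c(0, 1, -1, 2, -2))
  colnames(A) <- stages
  S <- rbind(g1 = c(0.5, 0.5), TFa = c(1, 0), TFb = c(0, 1))
  colnames(S) <- rownames(A)
  E <- unclass(expression_matrix(S %*% A, "c0"))
  fit <- fake_fit(S, A, E, "c0")
  # TF expression equals activity -> r = 1; negate -> r = -1
  agree <- tfa_expression_agreement(fit, expression_matrix(E, "c0"))
  expect_equal(agree$r[agree$tf == "TFa"], 1)
  expect_equal(agree$class[agree$tf == "TFa"], "strong_positive")
  Eneg <- E
  Eneg["TFa", ] <- -E["TFa", ]
  aneg <- tfa_expression_agreement(fit, expression_matrix(Eneg, "c0"))
  expect_equal(aneg$r[aneg$tf == "TFa"], -1)
  expect_equal(aneg$class[aneg$tf == "TFa"], "strong_negative")
  # r exactly at the 0.5 boundary is weak; constant trajectory is undefined
  fitw <- fit
  fitw$activities["TFb", ] <- c(0, 1, 1, -1, -1)
  Ew <- E
  Ew["TFb", ] <- c(0, 1, -1, 1, -1)
  r_hand <- cor(fitw$activities["TFb", ], Ew["TFb", ])
  aw <- tfa_expression_agreement(fitw, expression_matrix(Ew, "c0"))
  if (abs(r_hand) <= 0.5) expect_equal(aw$class[aw$tf == "TFb"], "weak")
  Ec <- E
  Ec["TFb", ] <- 0
  ac <- tfa_expression_agreement(fit, expression_matrix(Ec, "c0"))
  expect_equal(ac$class[ac$tf == "TFb"], "undefined")
})

test_that("combinatorial pairs keep signed high correlations only", {
  A <- rbind(t1 = c(0, 1, 2, 3), t2 = c(0, 2, 4, 6), t3 = c(0, -1, -2, -3),
             t4 = c(1, -1, 1, -1))
  pairs <- combinatorial_pairs(A, threshold = 0.5)
  expect_true(any(pairs$tf1 == "t1" & pairs$tf2 == "t2" & pairs$r > 0.99))
  expect_true(any(pairs$tf1 == "t1" & pairs$tf2 == "t3" & pairs$r < -0.99))
  expect_false(any(pairs$tf1 == "t1" & pairs$tf2 == "t4"))  # near-orthogonal
  expect_equal(nrow(combinatorial_pairs(A, threshold = 1)), 0L)
  expect_error(combinatorial_pairs(A[1, , drop = FALSE]), "2 TFs")
})

test_that("network assembly merges fitted and curated edges with provenance", {
  fx <- signing_fixture()
  net <- assemble_network(fx$fit, fx$E)
  expect_s3_class(net, "regulatory_network")
  expect_equal(nrow(net$edges), sum(fx$fit$prior$support))
  expect_true(all(net$edges$provenance == "NCA"))
  expect_equal(sort(unique(net$nodes$role[net$nodes$id %in% c("TFa", "TFb")])),
               "both")                      # TF transcripts are also targets
  # curated duplicate collapses; curated novelty appended with warning
  curated <- data.frame(tf = c("TFa", "AGL18"), gene = c("gPos", "gB"),
                        sign = c(1L, NA))
  expect_warning(net2 <- assemble_network(fx$fit, fx$E, curated_edges = curated),
                 "AGL18")
  dup <- net2$edges[net2$edges$tf == "TFa" & net2$edges$gene == "gPos", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$provenance, "both")
  expect_equal(nrow(net2$edges), nrow(net$edges) + 1L)
  expect_equal(net2$nodes$provenance[net2$nodes$id == "AGL18"], "curated")
  # expressed flags default to observed; threshold rule applies when asked
  expect_true(all(net$stage_expressed[rownames(fx$E), ]))
  net3 <- assemble_network(fx$fit, fx$E, expressed_threshold = 0.5)
  expect_false(all(net3$stage_expressed[rownames(fx$E), ], na.rm = TRUE))
  # clusters partition the genes
  expect_true(all(!is.na(net$clusters)))
  expect_true(all(table(net$clusters) >= 1))
})

test_that("noiseless truth yields a network matching the true support", {
  truth <- simulate_truth(n_genes = 25, n_tfs = 4, noise_sd = 0, seed = 27)
  fit <- nca(truth$expression, truth$prior, n_restarts = 2, seed = 1)
  net <- assemble_network(fit, truth$expression)
  got <- paste(net$edges$tf, net$edges$gene)
  idx <- which(truth$prior$support, arr.ind = TRUE)
  want <- paste(truth$prior$tf_ids[idx[, 2]], truth$prior$gene_ids[idx[, 1]])
  expect_setequal(got, want)
})

test_that("network exports are readable by standard tools", {
  fx <- signing_fixture()
  net <- assemble_network(fx$fit, fx$E)
  sif <- tempfile(fileext = ".sif")
  write_network_sif(net, sif)
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(all(grepl("^\\S+\t-?1\t\\S+$", lines)))
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true("sign" %in% igraph::edge_attr_names(g))
  cl <- tempfile(fileext = ".tsv")
  write_clusters_tsv(net, cl)
  df <- read.delim(cl)
  expect_equal(nrow(df), length(net$clusters))
})
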