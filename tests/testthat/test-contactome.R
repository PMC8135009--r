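protein_row <- function(id, hits, length_aa = 300) {
  tibble::tibble(protein_id = id, length_aa = length_aa,
                 hits_rep1 = hits[1], hits_rep2 = hits[2], hits_rep3 = hits[3])
}

test_that("spectral-support filtering applies the hits/replicates rule", {
  p <- dplyr::bind_rows(
    protein_row("keep", c(12, 11, 0)),
    protein_row("drop_one_rep", c(12, 0, 0)),
    protein_row("drop_low", c(9, 9, 9)),
    protein_row("keep_exact", c(10, 10, 0))
  )
  kept <- filter_proteins(p, min_hits = 10, min_replicates = 2)
  expect_equal(kept$protein_id, c("keep", "keep_exact"))
  # idempotent
  expect_identical(filter_proteins(kept), kept)
})

test_that("length normalization reranks outsized proteins", {
  expect_equal(normalized_degree(500, 250), 2)
  expect_equal(normalized_degree(0, 100), 0)
  titin <- normalized_degree(100, 34000)
  small <- normalized_degree(10, 300)
  expect_equal(round(titin, 4), 0.0029)
  expect_gt(small, titin)
  expect_error(normalized_degree(1, 0), "positive")
})

test_that("hub and connector classification follows degree and separation rules", {
  # star of 6: center is a central hub
  star <- tibble::tibble(protein_a = "hub", protein_b = sprintf("leaf%d", 1:5))
  lab <- classify_hubs(star)
  expect_equal(lab$role[lab$protein_id == "hub"], "central_hub")
  expect_equal(lab$degree[lab$protein_id == "hub"], 5)

  two_stars <- dplyr::bind_rows(
    tibble::tibble(protein_a = "hubA", protein_b = sprintf("a%d", 1:5)),
    tibble::tibble(protein_a = "hubB", protein_b = sprintf("b%d", 1:5))
  )
  # joined through one degree-2 node: that node is a hub connector
  bridged <- dplyr::bind_rows(
    two_stars,
    tibble::tibble(protein_a = "link", protein_b = c("hubA", "hubB"))
  )
  lab <- classify_hubs(bridged)
  expect_equal(lab$role[lab$protein_id == "link"], "hub_connector")
  expect_equal(sum(lab$role == "hub_connector"), 1)
  # two parallel bridges: neither is a connector
  parallel <- dplyr::bind_rows(
    two_stars,
    tibble::tibble(protein_a = "link1", protein_b = c("hubA", "hubB")),
    tibble::tibble(protein_a = "link2", protein_b = c("hubA", "hubB"))
  )
  lab <- classify_hubs(parallel)
  expect_equal(sum(lab$role == "hub_connector"), 0)
  expect_equal(length(unique(lab$cluster_id)), 1)
})

test_that("connector labels equal the remove-and-test oracle on random graphs", {
  for (seed in 1:12) {
    g <- random_edge_table(n_nodes = sample(30:200, 1),
                           n_edges = sample(40:320, 1), seed = seed + 100)
    lab <- classify_hubs(g$edges, proteins = tibble::tibble(protein_id = g$ids))
    want <- oracle_connectors(g$ids, g$edges)
    got <- setNames(lab$role == "hub_connector", lab$protein_id)
    expect_equal(got[g$ids], want)
    # role counts are conserved
    expect_equal(sum(lab$role %in% c("central_hub", "hub_connector", "other")),
                 length(g$ids))
  }
})

test_that("role tallies cover empty graphs and single edges", {
  empty <- classify_hubs(tibble::tibble(protein_a = character(),
                                        protein_b = character()))
  expect_equal(unlist(count_roles(empty)),
               c(n_clusters = 0, n_central_hubs = 0, n_connectors = 0, n_other = 0))
  single <- classify_hubs(tibble::tibble(protein_a = "A", protein_b = "B"))
  tall <- count_roles(single)
  expect_equal(tall$n_clusters, 1)
  expect_equal(tall$n_central_hubs, 0)
  expect_equal(tall$n_connectors, 0)
})

test_that("annotation enrichment matches the closed form and enumeration", {
  bg_all <- tibble::tibble(protein_id = sprintf("p%d", 1:20), tags = "RNA-binding")
  expect_equal(annotation_enrichment(sprintf("p%d", 1:5), "RNA-binding", bg_all)$p, 1)
  bg <- tibble::tibble(protein_id = sprintf("p%d", 1:100),
                       tags = c(rep("RNA-binding", 5), rep("", 95)))
  res <- annotation_enrichment(sprintf("p%d", 1:5), "RNA-binding", bg)
  expect_equal(res$count, 5)
  expect_equal(res$p, 1 / choose(100, 5), tolerance = 1e-12)
  # enumeration agreement on small universes
  set.seed(111)
  for (i in 1:20) {
    N <- sample(10:50, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    ids <- sprintf("q%02d", 1:N)
    bg <- tibble::tibble(protein_id = ids,
                         tags = c(rep("tag", K), rep("", N - K)))
    sel <- sample(ids, n)
    k <- sum(sel %in% ids[1:K])
    res <- annotation_enrichment(sel, "tag", bg)
    expect_equal(res$p, oracle_hyper_upper(k, K, N, n), tolerance = 1e-10)
  }
  expect_error(annotation_enrichment("x", "t", bg[0, ]), "empty")
})

test_that("simulated contactomes are recovered exactly after filtering", {
  sim <- simulate_contactome(n_clusters = 11, n_central_hubs = 24,
                             n_connectors = 4, n_peripheral = 6,
                             n_dropouts = 3, seed = 7)
  net <- build_contactome(sim$proteins, sim$edges)
  # planted dropouts vanish, keepers remain
  expect_equal(sort(net$proteins$protein_id),
               sort(sim$truth$protein_id[sim$truth$kept]))
  lab <- classify_hubs(net)
  tall <- count_roles(lab)
  expect_equal(tall$n_clusters, 11)
  expect_equal(tall$n_central_hubs, 24)
  expect_equal(tall$n_connectors, 4)
  # per-protein roles match the planted truth
  truth_kept <- sim$truth[sim$truth$kept, ]
  merged <- dplyr::left_join(truth_kept, lab, by = "protein_id")
  expect_equal(merged$role.x, merged$role.y)
})

test_that("planted roles are recovered across seeded scenarios", {
  for (seed in 1:40) {
    ncl <- sample(2:6, 1)
    nh <- ncl + sample(0:8, 1)
    nc <- sample(0:max(0, nh - ncl), 1)
    sim <- simulate_contactome(n_clusters = ncl, n_central_hubs = nh,
                               n_connectors = nc,
                               n_peripheral = sample(0:5, 1),
                               n_dropouts = sample(0:3, 1), seed = seed)
    net <- build_contactome(sim$proteins, sim$edges)
    lab <- classify_hubs(net)
    tall <- count_roles(lab)
    expect_equal(tall$n_clusters, ncl)
    expect_equal(tall$n_central_hubs, nh)
    expect_equal(tall$n_connectors, nc)
    truth_kept <- sim$truth[sim$truth$kept, ]
    merged <- dplyr::left_join(truth_kept, lab, by = "protein_id")
    expect_equal(merged$role.x, merged$role.y)
  }
  # minimal case: 2 hubs, 1 connector
  sim <- simulate_contactome(n_clusters = 1, n_central_hubs = 2,
                             n_connectors = 1, seed = 3)
  lab <- classify_hubs(build_contactome(sim$proteins, sim$edges))
  expect_equal(lab$protein_id[lab$role == "hub_connector"], "conn01")
  # generator validation
  expect_error(simulate_contactome(n_clusters = 5, n_central_hubs = 6,
                                   n_connectors = 4), "joinable")
})
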