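test_that("build_network computes consistent bipartite degrees", {
  edges <- tibble::tibble(mirna_id = c("m1", "m1", "m2"),
                          gene_id = c("g1", "g2", "g1"))
  net <- build_network(edges)
  expect_equal(tibble::deframe(net$mirna_degree), c(m1 = 2L, m2 = 1L))
  expect_equal(tibble::deframe(net$gene_degree), c(g1 = 2L, g2 = 1L))
  expect_equal(sum(net$mirna_degree$degree), nrow(net$edges))
  expect_equal(sum(net$gene_degree$degree), nrow(net$edges))

  single <- build_network(tibble::tibble(mirna_id = "m", gene_id = "g"))
  expect_equal(single$mirna_degree$degree, 1L)
  expect_equal(single$gene_degree$degree, 1L)

  empty <- build_network(tibble::tibble(mirna_id = character(0),
                                        gene_id = character(0)))
  expect_equal(nrow(empty$edges), 0)
})

test_that("duplicate pairs are rejected at network construction", {
  dup <- tibble::tibble(mirna_id = c("m1", "m1"), gene_id = c("g1", "g1"))
  expect_error(build_network(dup), "deduplicate")
})

test_that("degree-class abundance counts nodes sharing each degree", {
  net <- network_with_gene_degrees(c(94, 94, 3, 1, 1, 1))
  da <- degree_abundance(net, "gene")
  expect_equal(da$abundance[da$degree == 94], 2L)
  expect_equal(da$abundance[da$degree == 1], 3L)
  expect_equal(sum(da$abundance), 6L)
  expect_true(all(diff(da$degree) > 0))

  # all-distinct degrees: every abundance is one
  net2 <- network_with_gene_degrees(c(1, 2, 3, 5))
  expect_equal(degree_abundance(net2, "gene")$abundance, rep(1L, 4))
})

test_that("degree multiset is reconstructible from its abundance table", {
  for (seed in 1:3) {
    degs <- withr::with_seed(seed, sample(1:30, 40, replace = TRUE))
    net <- network_with_gene_degrees(degs)
    da <- degree_abundance(net, "gene")
    rebuilt <- rep(da$degree, da$abundance)
    expect_equal(sort(rebuilt), sort(degs))
  }
})

test_that("hub detection uses a strict threshold", {
  net <- network_with_gene_degrees(c(25, 21, 20, 5))
  hubs <- find_hubs(net, "gene", 20)
  expect_equal(nrow(hubs), 2)
  expect_equal(hubs$degree, c(25L, 21L)) # sorted by degree desc
  expect_true(all(hubs$degree > 20))
  expect_error(find_hubs(net, "gene", -1), "non-negative")
})

test_that("hub thresholds are monotone and threshold 0 returns all nodes", {
  net <- network_with_gene_degrees(c(30, 22, 21, 20, 7, 1))
  all_nodes <- find_hubs(net, "gene", 0)
  expect_equal(nrow(all_nodes), 6)
  prev <- all_nodes$id
  for (t in c(5, 20, 21, 25)) {
    cur <- find_hubs(net, "gene", t)$id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("pairwise target overlap reports sizes and sorted members", {
  edges <- dplyr::bind_rows(
    tibble::tibble(mirna_id = "mA", gene_id = c("a", "b", "c")),
    tibble::tibble(mirna_id = "mB", gene_id = c("b", "c", "d")),
    tibble::tibble(mirna_id = "mC", gene_id = c("x", "y"))
  )
  net <- build_network(edges)
  ov <- target_overlap(net, c("mA", "mB"), "pairwise")
  expect_equal(ov$n_common, 2)
  expect_equal(ov$common[[1]], c("b", "c"))
  disjoint <- target_overlap(net, c("mA", "mC"), "pairwise")
  expect_equal(disjoint$n_common, 0)
  expect_error(target_overlap(net, c("mA", "mZ")), "mZ")
})

test_that("full-mode Venn regions match brute-force enumeration", {
  sets <- list(mA = c("a", "b", "c"), mB = c("b", "c", "d"),
               mC = c("c", "d", "e"))
  edges <- purrr::imap_dfr(sets, function(g, m) {
    tibble::tibble(mirna_id = m, gene_id = g)
  })
  net <- build_network(edges)
  regions <- target_overlap(net, names(sets), "full")

  # independent brute force: classify each gene by exact membership
  genes <- sort(unique(unlist(sets)))
  expected <- table(vapply(genes, function(g) {
    paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
          collapse = "&")
  }, character(1)))
  got <- setNames(regions$n, regions$region)
  expect_equal(got[names(expected)], unclass(expected), ignore_attr = TRUE)
  expect_equal(unname(got["mA"]), 1)        # only-A
  expect_equal(unname(got["mA&mB"]), 1)     # A and B only
  expect_equal(unname(got["mA&mB&mC"]), 1)  # triple intersection
})

test_that("overlap sizes obey inclusion-exclusion", {
  edges <- withr::with_seed(11, tibble::tibble(
    mirna_id = sample(paste0("m", 1:4), 60, replace = TRUE),
    gene_id = sample(paste0("g", 1:25), 60, replace = TRUE)
  )) |> dplyr::distinct()
  net <- build_network(edges)
  ov <- target_overlap(net, paste0("m", 1:4), "pairwise")
  for (i in seq_len(nrow(ov))) {
    a <- unique(net$edges$gene_id[net$edges$mirna_id == ov$a[i]])
    b <- unique(net$edges$gene_id[net$edges$mirna_id == ov$b[i]])
    expect_equal(ov$size_a[i] + ov$size_b[i] - ov$n_common[i],
                 length(union(a, b)))
  }
})

test_that("degree abundance plot builds", {
  net <- network_with_gene_degrees(c(10, 5, 5, 1, 1, 1))
  p <- ggplot2::autoplot(degree_abundance(net, "gene"))
  expect_s3_class(p, "ggplot")
})
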