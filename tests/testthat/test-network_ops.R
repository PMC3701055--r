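test_that("subnetwork query: star, isolated seed, filter-then-truncate oracle", {
  star <- ranked_edges(rep("hub", 5), paste0("g", 1:5), 5:1,
                       directed = FALSE, method = "m")
  expect_equal(nrow(subnetwork(star, "hub")), 5L)
  expect_warning(s0 <- subnetwork(star, "nowhere"), "no seed")
  expect_equal(nrow(s0), 0L)

  # identity on the full node set
  expect_equal(nrow(subnetwork(star, c("hub", paste0("g", 1:5)))), 5L)

  # 20-edge random net, 2 seeds, top_edges = 5 vs brute force
  set.seed(33)
  g <- sprintf("n%02d", 1:10)
  pairs <- t(combn(g, 2))
  keep <- sample(nrow(pairs), 20)
  net <- ranked_edges(pairs[keep, 1], pairs[keep, 2], runif(20),
                      directed = FALSE, method = "m")
  seeds <- c("n01", "n05")
  sub <- subnetwork(net, seeds, top_edges = 5)
  df <- as.data.frame(net)
  brute <- df[df$regulator %in% seeds | df$target %in% seeds, ]
  brute <- head(brute[order(-brute$score), ], 5)
  expect_equal(as.data.frame(sub)[c("regulator", "target", "score")],
               brute[c("regulator", "target", "score")],
               ignore_attr = TRUE)
})

test_that("subnetwork tf_first_connections keeps only TF-rooted edges", {
  net <- ranked_edges(c("tf1", "g2", "tf2"), c("g1", "g3", "g4"),
                      c(3, 2, 1), directed = TRUE, method = "m")
  sub <- subnetwork(net, c("tf1", "g2"), mode = "tf_first_connections",
                    tfs = c("tf1", "tf2"))
  expect_equal(paste(sub$regulator, sub$target), "tf1 g1")
})

blast_row <- function(q, s, evalue, bits) {
  data.frame(query_id = q, subject_id = s, pct_identity = 90,
             aln_len = 100, mismatches = 1, gap_opens = 0, q_start = 1,
             q_end = 100, s_start = 1, s_end = 100, evalue = evalue,
             bit_score = bits, stringsAsFactors = FALSE)
}

test_that("reciprocal best hits: definition, ties, duplicated-genome rule", {
  ab <- rbind(blast_row("a1", "b1", 1e-50, 200),
              blast_row("a1", "b2", 1e-40, 150),
              blast_row("a2", "b1", 1e-30, 120))
  ba <- rbind(blast_row("b1", "a1", 1e-50, 200),
              blast_row("b2", "a1", 1e-40, 150))
  p <- rbh_orthologs(ab, ba)
  # a1<->b1 mutual best; a2's best is b1 but b1's best is a1
  expect_equal(nrow(p), 1L)
  expect_equal(unlist(p[1, ], use.names = FALSE), c("a1", "b1"))

  # exact (bit score, E-value) tie: both hits eligible, both reciprocal
  ab2 <- rbind(blast_row("a1", "b1", 1e-50, 200),
               blast_row("a1", "b2", 1e-50, 200))
  ba2 <- rbind(blast_row("b1", "a1", 1e-50, 200),
               blast_row("b2", "a1", 1e-50, 200))
  p2 <- rbh_orthologs(ab2, ba2)
  expect_equal(nrow(p2), 2L)

  # best-two-hits budget for a duplicated genome
  ab3 <- rbind(blast_row("a1", "b1", 1e-50, 200),
               blast_row("a1", "b2", 1e-45, 180))
  ba3 <- rbind(blast_row("b1", "a1", 1e-50, 200),
               blast_row("b2", "a1", 1e-45, 180))
  expect_equal(nrow(rbh_orthologs(ab3, ba3)), 1L)
  expect_equal(nrow(rbh_orthologs(ab3, ba3, max_hits_ab = 2)), 2L)

  # E-value filter removes weak hits entirely
  ab4 <- blast_row("a1", "b1", 1e-3, 50)
  ba4 <- blast_row("b1", "a1", 1e-3, 50)
  expect_equal(nrow(rbh_orthologs(ab4, ba4)), 0L)

  # symmetry: swapping tables mirrors the pair set
  ps <- rbh_orthologs(ba2, ab2)
  expect_setequal(paste(ps$gene_a, ps$gene_b),
                  paste(p2$gene_b, p2$gene_a))
})

test_that("metagene clusters: pairs, triangles, flagged chains, determinism", {
  pair <- function(a, b) data.frame(gene_a = a, gene_b = b,
                                    stringsAsFactors = FALSE)
  # single M-L pair -> one 2-member metagene
  mg1 <- build_metagenes(list("M-L" = pair("m1", "l1")))
  expect_equal(length(unique(mg1$metagene_id)), 1L)
  expect_equal(nrow(mg1), 2L)
  expect_false(any(mg1$flagged))

  # triangle M-L, M-G, L-G -> one 3-member metagene
  mg2 <- build_metagenes(list("M-L" = pair("m1", "l1"),
                              "M-G" = pair("m1", "g1"),
                              "L-G" = pair("l1", "g1")))
  expect_equal(length(unique(mg2$metagene_id)), 1L)
  expect_equal(nrow(mg2), 3L)

  # chain M1-L1, L1-G1, G1-M2: one 4-member component with two M members
  mg3 <- build_metagenes(list("M-L" = pair("m1", "l1"),
                              "L-G" = pair("l1", "g1"),
                              "G-M" = pair("g1", "m2")))
  expect_equal(length(unique(mg3$metagene_id)), 1L)
  expect_equal(nrow(mg3), 4L)
  expect_true(all(mg3$flagged))
  # with M declared duplicated, two members are within budget
  mg3b <- build_metagenes(list("M-L" = pair("m1", "l1"),
                               "L-G" = pair("l1", "g1"),
                               "G-M" = pair("g1", "m2")),
                          duplicated_species = "M")
  expect_false(any(mg3b$flagged))

  # invariant to input pair order
  mg4 <- build_metagenes(list("G-M" = pair("g1", "m2"),
                              "M-L" = pair("m1", "l1"),
                              "L-G" = pair("l1", "g1")))
  expect_equal(mg3[order(mg3$species, mg3$gene_id), c("species", "gene_id")],
               mg4[order(mg4$species, mg4$gene_id), c("species", "gene_id")],
               ignore_attr = TRUE)
})

test_that("network comparison labels shared and private edges", {
  n1 <- ranked_edges(c("a", "b"), c("b", "c"), c(2, 1),
                     directed = FALSE, method = "alg1")
  n2 <- ranked_edges(c("a", "c"), c("b", "d"), c(5, 4),
                     directed = FALSE, method = "alg2")
  comp <- compare_networks(list(alg1 = n1, alg2 = n2))
  shared <- comp[comp$n_sources == 2, ]
  expect_equal(paste(shared$regulator, shared$target), "a b")
  expect_equal(sum(comp$n_sources == 1), 2L)

  # identical networks: every edge labelled by all sources
  comp2 <- compare_networks(list(x = n1, y = n1))
  expect_true(all(comp2$n_sources == 2))

  # two species networks sharing one orthologous edge through metagenes
  pair <- function(a, b) data.frame(gene_a = a, gene_b = b,
                                    stringsAsFactors = FALSE)
  mg <- build_metagenes(list("M-L" = pair(c("m1", "m2"), c("l1", "l2"))))
  netM <- ranked_edges("m1", "m2", 1, directed = FALSE, method = "M")
  netL <- ranked_edges(c("l1", "l1"), c("l2", "l3"), c(2, 1),
                       directed = FALSE, method = "L")
  compS <- compare_networks(list(M = netM, L = netL), metagenes = mg,
                            species = c("M", "L"))
  expect_equal(nrow(compS), 1L)        # l1-l3 dropped (l3 unmapped)
  expect_equal(compS$n_sources, 2)
})

test_that("chi-square enrichment: proportional null, extreme 2x2, boundaries", {
  universe <- sprintf("g%02d", 1:20)
  subnet <- universe[1:10]
  # proportional term: half of subnet and half of the rest -> chi2 ~ 0
  annot <- c(
    setNames(rep(list("T1"), 10), universe[c(1:5, 11:15)]),
    setNames(rep(list("T2"), 10), universe[c(1:10)]))
  res <- go_enrichment(subnet, universe, annot)
  t1 <- res[res$term == "T1", ]
  expect_lt(t1$chi2, 1e-10)
  expect_gt(t1$pvalue, 0.99)

  # all 10 subnet genes have the term, none outside: chi2 = N = 20
  t2 <- res[res$term == "T2", ]
  expect_equal(t2$chi2, 20, tolerance = 1e-12)
  expect_equal(t2$pvalue, 7.7e-6, tolerance = 0.01)
  expect_equal(t2$direction, "enriched")
  # cross-check against the stock chi-square test without correction
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(10, 0, 0, 10), 2), correct = FALSE))
  expect_equal(t2$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(t2$pvalue, ref$p.value, tolerance = 1e-12)

  # all subnet genes unannotated: depletion reported, no enrichment
  annot2 <- setNames(rep(list("T3"), 5), universe[16:20])
  res2 <- go_enrichment(subnet, universe, annot2)
  expect_equal(res2$direction, "depleted")
  expect_error(go_enrichment("zz", universe, annot), "subset")
})
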