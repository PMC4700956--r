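# targeting network construction, redundancy statistics, exports

toy_sites <- function(edges) {
  data.frame(mirna_id = vapply(edges, `[`, "", 1),
             gene_id = vapply(edges, `[`, "", 2),
             expectation = rep(1.0, length(edges)),
             stringsAsFactors = FALSE)
}

toy_genes <- function(...) {
  rows <- list(...)
  data.frame(gene_id = vapply(rows, `[`, "", 1),
             species = vapply(rows, `[`, "", 2),
             family_id = vapply(rows, `[`, "", 3), stringsAsFactors = FALSE)
}

test_that("homology edges follow the family/species invariants", {
  genes <- toy_genes(c("g1", "spA", "f1"), c("g2", "spA", "f1"))
  net <- build_network(toy_sites(list(c("m1", "g1"))), genes)
  expect_equal(nrow(net$homology), 1)
  expect_equal(net$homology$relation, "paralog")
  genes2 <- toy_genes(c("g1", "spA", "f1"), c("g2", "spB", "f1"))
  net2 <- build_network(toy_sites(list(c("m1", "g1"))), genes2)
  expect_equal(net2$homology$relation, "ortholog")
  # no homology across families
  genes3 <- toy_genes(c("g1", "spA", "f1"), c("g2", "spA", "f2"))
  net3 <- build_network(toy_sites(list(c("m1", "g1"))), genes3)
  expect_equal(nrow(net3$homology), 0)
  expect_error(build_network(toy_sites(list(c("m1", "gX"))), genes),
               "missing from family_map.*gX")
})

test_that("edge sets equal brute-force pair classification", {
  set.seed(20)
  for (rep in 1:20) {
    fx <- random_network_tables()
    net <- build_network(fx$sites, fx$genes)
    g <- fx$genes
    want <- list()
    for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
      if (g$family_id[i] != g$family_id[j]) next
      want[[length(want) + 1]] <- c(
        sort(c(g$gene_id[i], g$gene_id[j])),
        if (g$species[i] == g$species[j]) "paralog" else "ortholog")
    }
    got <- apply(net$homology, 1, function(r)
      c(sort(c(r[["gene_a"]], r[["gene_b"]])), r[["relation"]]))
    want_m <- vapply(want, paste, "", collapse = "|")
    got_m <- if (nrow(net$homology)) apply(got, 2, paste, collapse = "|")
             else character(0)
    expect_setequal(got_m, want_m)
  }
})

test_that("unique/shared counts match hand enumeration", {
  genes <- toy_genes(c("g1", "spA", "f1"), c("g2", "spA", "f1"),
                     c("g3", "spA", "f2"), c("g4", "spA", "f2"),
                     c("g5", "spA", "f3"), c("g6", "spA", "f3"))
  # m1 -> g1,g2,g3 ; m2 -> g2,g3,g4 ; m3 -> g5
  net <- build_network(toy_sites(list(
    c("m1", "g1"), c("m1", "g2"), c("m1", "g3"),
    c("m2", "g2"), c("m2", "g3"), c("m2", "g4"),
    c("m3", "g5"))), genes)
  us <- unique_shared_counts(net)
  expect_equal(us$n_unique[us$mirna_id == "m1"], 1)   # g1
  expect_equal(us$n_shared[us$mirna_id == "m1"], 2)   # g2, g3
  expect_equal(us$n_unique[us$mirna_id == "m2"], 1)   # g4
  expect_equal(us$n_unique[us$mirna_id == "m3"], 1)   # g5
  expect_equal(us$n_shared[us$mirna_id == "m3"], 0)
  # single-miRNA network: everything unique
  net1 <- build_network(toy_sites(list(c("m1", "g1"), c("m1", "g2"))),
                        genes)
  us1 <- unique_shared_counts(net1)
  expect_equal(us1$n_unique, 2)
  expect_equal(us1$n_shared, 0)
})

test_that("homolog sharing matches the hand-built two-species fixture", {
  # 5 ortholog pairs: 3 intersect, 1 of them identical
  genes <- toy_genes(
    c("a1", "spA", "f1"), c("b1", "spB", "f1"),
    c("a2", "spA", "f2"), c("b2", "spB", "f2"),
    c("a3", "spA", "f3"), c("b3", "spB", "f3"),
    c("a4", "spA", "f4"), c("b4", "spB", "f4"),
    c("a5", "spA", "f5"), c("b5", "spB", "f5"))
  net <- build_network(toy_sites(list(
    c("m1", "a1"), c("m1", "b1"),                    # identical {m1}
    c("m1", "a2"), c("m1", "b2"), c("m2", "b2"),     # intersect, not equal
    c("m2", "a3"), c("m2", "b3"), c("m3", "a3"),     # intersect, not equal
    c("m1", "a4"), c("m2", "b4"),                    # disjoint
    c("m3", "a5"))), genes)                          # b5 empty
  sh <- homolog_sharing(net, "ortholog")
  expect_equal(sh$n_pairs, 5L)
  expect_equal(sh$frac_share_any, 3 / 5)
  expect_equal(sh$frac_identical, 1 / 5)
  expect_lte(sh$frac_identical, sh$frac_share_any)
})

test_that("degenerate sharing cases behave as specified", {
  genes <- toy_genes(c("a", "spA", "f1"), c("b", "spB", "f1"))
  net <- build_network(toy_sites(list(c("m1", "a"), c("m1", "b"))), genes)
  sh <- homolog_sharing(net, "ortholog")
  expect_equal(sh$frac_share_any, 1.0)
  expect_equal(sh$frac_identical, 1.0)
  # disjoint sets
  net2 <- build_network(toy_sites(list(c("m1", "a"), c("m2", "b"))), genes)
  sh2 <- homolog_sharing(net2, "ortholog")
  expect_equal(sh2$frac_share_any, 0.0)
  expect_equal(sh2$frac_identical, 0.0)
  # both genes empty -> excluded, zero included pairs -> NA
  net3 <- build_network(toy_sites(list()), genes)
  sh3 <- homolog_sharing(net3, "ortholog")
  expect_equal(sh3$n_pairs, 0L)
  expect_true(is.na(sh3$frac_share_any))
  # no pairs of the requested relation at all
  sh4 <- homolog_sharing(net, "paralog")
  expect_equal(sh4$n_pairs, 0L)
})

test_that("adding an edge never decreases frac_share_any", {
  set.seed(21)
  for (rep in 1:10) {
    fx <- random_network_tables()
    net <- build_network(fx$sites, fx$genes)
    base <- homolog_sharing(net, "paralog")
    # add one random new edge
    cand <- expand.grid(mirna_id = fx$mirnas,
                        gene_id = fx$genes$gene_id,
                        stringsAsFactors = FALSE)
    cand$key <- paste(cand$mirna_id, cand$gene_id)
    have <- paste(fx$sites$mirna_id, fx$sites$gene_id)
    cand <- cand[!cand$key %in% have, , drop = FALSE]
    if (!nrow(cand)) next
    pick <- cand[sample(nrow(cand), 1), c("mirna_id", "gene_id")]
    pick$expectation <- 1
    net2 <- build_network(rbind(fx$sites, pick), fx$genes)
    new <- homolog_sharing(net2, "paralog")
    if (!is.na(base$frac_share_any) && !is.na(new$frac_share_any) &&
        base$n_pairs == new$n_pairs)
      expect_gte(new$frac_share_any, base$frac_share_any - 1e-12)
  }
})

test_that("family-size correlation handles monotone and reversed cases", {
  mk <- function(counts) {
    # families of sizes 1,2,3 targeted by `counts` distinct miRNAs
    genes <- do.call(rbind, lapply(1:3, function(f)
      do.call(rbind, lapply(seq_len(f), function(g)
        data.frame(gene_id = sprintf("f%dg%d", f, g), species = "spA",
                   family_id = sprintf("f%d", f),
                   stringsAsFactors = FALSE)))))
    edges <- do.call(rbind, lapply(1:3, function(f)
      data.frame(mirna_id = sprintf("m%d", seq_len(counts[f])),
                 gene_id = sprintf("f%dg1", f), expectation = 1,
                 stringsAsFactors = FALSE)))
    build_network(edges, genes)
  }
  expect_equal(family_size_vs_mirna_count(mk(c(1, 2, 3)))$rho, 1.0)
  expect_equal(family_size_vs_mirna_count(mk(c(3, 2, 1)))$rho, -1.0)
  expect_warning(res <- family_size_vs_mirna_count(mk(c(2, 2, 2))),
                 "constant")
  expect_true(is.na(res$rho))
})

test_that("exact permutation p equals full enumeration at n = 5", {
  set.seed(22)
  for (rep in 1:5) {
    sizes <- sample(1:4, 5, replace = TRUE)
    counts <- sample(1:4, 5, replace = TRUE)
    if (length(unique(sizes)) == 1 || length(unique(counts)) == 1) next
    genes <- do.call(rbind, lapply(1:5, function(f)
      do.call(rbind, lapply(seq_len(sizes[f]), function(g)
        data.frame(gene_id = sprintf("f%dg%d", f, g), species = "spA",
                   family_id = sprintf("f%d", f),
                   stringsAsFactors = FALSE)))))
    edges <- do.call(rbind, lapply(1:5, function(f) {
      if (counts[f] == 0) return(NULL)
      data.frame(mirna_id = sprintf("m%d", seq_len(counts[f])),
                 gene_id = sprintf("f%dg1", f), expectation = 1,
                 stringsAsFactors = FALSE)
    }))
    net <- build_network(edges, genes)
    got <- family_size_vs_mirna_count(net)
    tab <- got$table
    expect_equal(got$p_value,
                 oracle_spearman_p(tab$size, tab$n_mirna))
  }
})

test_that("targeted_fraction uses the full denominator", {
  genes <- do.call(rbind, lapply(1:10, function(i)
    data.frame(gene_id = sprintf("g%d", i), species = "spA",
               family_id = "f1", stringsAsFactors = FALSE)))
  net <- build_network(toy_sites(list(c("m1", "g1"), c("m1", "g2"))),
                       genes)
  tf <- targeted_fraction(net, "spA")
  expect_equal(tf$n_targeted, 2)
  expect_equal(tf$n_total, 10)
  expect_equal(tf$fraction, 0.2)
  net0 <- build_network(toy_sites(list())[0, ], genes)
  expect_equal(targeted_fraction(net0, "spA")$fraction, 0)
  expect_error(targeted_fraction(net, "spX"), "no genes")
})

test_that("network exports round-trip and preserve counts", {
  set.seed(23)
  fx <- random_network_tables()
  net <- build_network(fx$sites, fx$genes)
  tsv <- tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  net2 <- import_network(tsv)
  tsv2 <- tempfile(fileext = ".tsv")
  export_network(net2, tsv2, "tsv")
  expect_identical(readLines(tsv), readLines(tsv2))
  expect_equal(nrow(net2$targeting), nrow(net$targeting))
  expect_equal(nrow(net2$genes), nrow(net$genes))
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_equal(length(readLines(sif)),
               nrow(net$targeting) + nrow(net$homology))
  gml <- tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), length(net$mirnas) + nrow(net$genes))
  expect_equal(igraph::ecount(g),
               nrow(net$targeting) + nrow(net$homology))
  expect_error(export_network(net, tempfile(), "dot"), "arg")
})

test_that("fallback family clustering is single-linkage", {
  pairs <- data.frame(gene_a = c("a", "b", "x"),
                      gene_b = c("b", "c", "y"),
                      evalue = c(1e-10, 1e-10, 1e-3))
  fam <- cluster_families(pairs, c("a", "b", "c", "x", "y", "z"))
  f <- setNames(fam$family_id, fam$gene_id)
  expect_equal(f[["a"]], f[["b"]])
  expect_equal(f[["b"]], f[["c"]])
  expect_false(f[["x"]] == f[["y"]])      # 1e-3 fails the cutoff
  expect_false(f[["z"]] == f[["a"]])
})
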